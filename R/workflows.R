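## End-to-end workflows: fit, predict, simulate, compare.  Each run writes
## a self-describing directory (config copy, metadata, per-parameter draw
## CSVs) so that every result is reproducible from its persisted config
## and seed.  These functions are also the backend of the thin command
## line script installed at inst/cli/svcmap.R.

readConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  config
}

cfgGet <- function(config, key, default = NULL) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  node <- config
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]])) return(default)
    node <- node[[p]]
  }
  node
}

## Validate a fit config, collecting all problems before failing.
validateFitConfig <- function(config) {
  problems <- character()
  need <- function(key) {
    v <- cfgGet(config, key)
    if (is.null(v)) problems <<- c(problems, paste0("missing config key: ", key))
    v
  }
  tt <- need("data.tract_table")
  adj <- need("data.adjacency")
  variant <- need("model.variant")
  if (!is.null(variant) && !variant %in% c("M1", "M2", "M3"))
    problems <- c(problems, "model.variant must be M1, M2 or M3")
  for (f in c(tt, adj))
    if (!is.null(f) && !file.exists(f))
      problems <- c(problems, paste0("input file not found: ", f))
  if (identical(variant, "M3")) {
    cf <- cfgGet(config, "data.coords")
    if (is.null(cf)) problems <- c(problems, "missing config key: data.coords (required for M3)")
    else if (!file.exists(cf)) problems <- c(problems, paste0("input file not found: ", cf))
  }
  if (is.null(cfgGet(config, "output.dir")))
    problems <- c(problems, "missing config key: output.dir")
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(TRUE)
}

## Persist draws as a directory of per-parameter CSVs (chain, iter, value)
## plus deviance, the DIC plug-in vector and a JSON metadata file.

#' Write / read PosteriorDraws to a run directory
#' @param draws a PosteriorDraws
#' @param dir output directory (created)
#' @export
writeDraws <- function(draws, dir) {
  dir.create(file.path(dir, "draws"), recursive = TRUE, showWarnings = FALSE)
  nm <- paramNames(draws)
  nKeep <- nRetained(draws)
  for (p in nm) {
    per <- extractDraws(draws, p, pool = FALSE)
    df <- do.call(rbind, lapply(seq_along(per), function(ch)
      data.frame(chain = ch, iter = seq_len(nKeep), value = per[[ch]][, 1L])))
    fn <- gsub("\\[", "_", gsub("\\]", "", p))
    utils::write.csv(df, file.path(dir, "draws", paste0(fn, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  dev <- draws@deviance
  devDf <- do.call(rbind, lapply(seq_len(ncol(dev)), function(ch)
    data.frame(chain = ch, iter = seq_len(nrow(dev)), value = dev[, ch])))
  utils::write.csv(devDf, file.path(dir, "draws", "deviance.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(log_theta_mean = draws@logThetaMean),
                   file.path(dir, "draws", "log_theta_mean.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(package = "svcmap",
               version = as.character(utils::packageVersion("svcmap")),
               variant = draws@spec@variant,
               sdUpper = draws@spec@sdUpper,
               decayBounds = draws@spec@decayBounds,
               coefPriorSd = draws@spec@coefPriorSd,
               includeIcar = draws@spec@includeIcar,
               includeHet = draws@spec@includeHet,
               nChains = draws@settings@nChains, nIter = draws@settings@nIter,
               nBurnin = draws@settings@nBurnin, thin = draws@settings@thin,
               seed = draws@settings@seed,
               cityIds = draws@cityIds, nTracts = unname(draws@nTracts),
               dataFingerprint = draws@dataFingerprint,
               parameters = nm)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeDraws
#' @export
readDraws <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  spec <- modelSpec(meta$variant, sdUpper = meta$sdUpper,
                    decayBounds = if (meta$variant == "M3") meta$decayBounds else NULL,
                    coefPriorSd = meta$coefPriorSd,
                    includeIcar = meta$includeIcar, includeHet = meta$includeHet)
  settings <- mcmcSettings(meta$nChains, meta$nIter, meta$nBurnin, meta$thin,
                           meta$seed)
  readOne <- function(p) {
    fn <- gsub("\\[", "_", gsub("\\]", "", p))
    utils::read.csv(file.path(dir, "draws", paste0(fn, ".csv")))
  }
  nm <- meta$parameters
  nCh <- meta$nChains
  first <- readOne(nm[1L])
  nKeep <- sum(first$chain == 1L)
  draws <- lapply(seq_len(nCh), function(ch) {
    m <- matrix(NA_real_, nKeep, length(nm), dimnames = list(NULL, nm))
    m
  })
  for (p in nm) {
    df <- readOne(p)
    for (ch in seq_len(nCh))
      draws[[ch]][, p] <- df$value[df$chain == ch]
  }
  devDf <- utils::read.csv(file.path(dir, "draws", "deviance.csv"))
  dev <- matrix(NA_real_, nKeep, nCh)
  for (ch in seq_len(nCh)) dev[, ch] <- devDf$value[devDf$chain == ch]
  ltm <- utils::read.csv(file.path(dir, "draws", "log_theta_mean.csv"))$log_theta_mean
  new("PosteriorDraws", draws = draws, deviance = dev, logThetaMean = ltm,
      spec = spec, settings = settings, cityIds = meta$cityIds,
      nTracts = setNames(as.integer(meta$nTracts), meta$cityIds),
      dataFingerprint = meta$dataFingerprint, accept = numeric())
}

#' Fit a model from a config and write a run directory
#'
#' Reads the tract table, adjacency and (for M3) city coordinates named in
#' the config, fits the requested variant, and writes draws, a convergence
#' report (JSON + text), the DIC, the per-city RR table and (M2/M3) the
#' pooled RR into the output directory.
#'
#' @param config YAML file path or equivalent nested list.  Keys:
#'   \code{data.tract_table}, \code{data.columns} (optional mapping),
#'   \code{data.adjacency}, \code{data.coords}, \code{data.crs},
#'   \code{model.variant}, \code{model.sd_upper}, \code{model.decay_bounds},
#'   \code{mcmc.preset}, \code{mcmc.n_chains}, \code{mcmc.n_iter},
#'   \code{mcmc.n_burnin}, \code{mcmc.thin}, \code{seed},
#'   \code{output.dir}.
#' @param allowUnconverged if FALSE (default) a failed convergence check
#'   raises a warning and is recorded; the CLI wrapper turns it into a
#'   nonzero exit status.
#' @param verbose print progress.
#' @return invisibly, a list with the run directory, the PosteriorDraws,
#'   the ConvergenceReport and the DicResult.
#' @export
fitRun <- function(config, allowUnconverged = FALSE, verbose = FALSE) {
  config <- readConfig(config)
  validateFitConfig(config)
  colMap <- cfgGet(config, "data.columns")
  data <- readTractTable(cfgGet(config, "data.tract_table"),
                         columns = if (!is.null(colMap)) unlist(colMap))
  adjacency <- readAdjacencyEdges(cfgGet(config, "data.adjacency"), data)
  variantLab <- cfgGet(config, "model.variant")
  geo <- NULL
  if (!is.null(cfgGet(config, "data.coords")))
    geo <- readCityCoords(cfgGet(config, "data.coords"),
                          crs = cfgGet(config, "data.crs", "projected_km"))
  db <- cfgGet(config, "model.decay_bounds")
  spec <- modelSpec(variantLab,
                    sdUpper = cfgGet(config, "model.sd_upper", 10),
                    decayBounds = if (variantLab == "M3" && !is.null(db)) as.numeric(db),
                    coefPriorSd = cfgGet(config, "model.coef_prior_sd", Inf))
  settings <- mcmcSettings(cfgGet(config, "mcmc.n_chains"),
                           cfgGet(config, "mcmc.n_iter"),
                           cfgGet(config, "mcmc.n_burnin"),
                           cfgGet(config, "mcmc.thin"),
                           seed = cfgGet(config, "seed", 1L),
                           preset = cfgGet(config, "mcmc.preset", "desk"))
  outDir <- cfgGet(config, "output.dir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  draws <- runMcmc(data, adjacency, spec, settings, geo = geo, verbose = verbose)
  writeDraws(draws, outDir)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  if (!is.null(geo))
    utils::write.csv(data.frame(city_id = cityIds(geo),
                                x = coords(geo)[, 1L], y = coords(geo)[, 2L]),
                     file.path(outDir, "cities.csv"), row.names = FALSE,
                     quote = FALSE)

  conv <- checkConvergence(draws)
  jsonlite::write_json(list(pass = conv@pass, rhatMax = conv@rhatMax,
                            essMin = conv@essMin, table = conv@table),
                       file.path(outDir, "convergence.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- utils::capture.output(show(conv))
  writeLines(txt, file.path(outDir, "convergence.txt"))

  d <- dic(draws, data)
  jsonlite::write_json(list(dbar = d@dbar, dAtMean = d@dAtMean, pD = d@pD,
                            dic = d@dic),
                       file.path(outDir, "dic.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(cityRR(draws), file.path(outDir, "city_rr.csv"),
                   row.names = FALSE, quote = FALSE)
  if (spec@variant != "M1") {
    prr <- pooledRR(draws)
    utils::write.csv(data.frame(rr = prr["mean"], lower = prr["lower"],
                                upper = prr["upper"]),
                     file.path(outDir, "pooled_rr.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (!conv@pass && !allowUnconverged)
    warning("convergence check failed; see ", file.path(outDir, "convergence.txt"))
  invisible(list(dir = outDir, draws = draws, convergence = conv, dic = d))
}

#' Krige the slope surface from a fitted M3 run directory
#'
#' @param runDir a directory written by \code{\link{fitRun}} for an M3 fit.
#' @param grid either a matrix of locations, or a list with \code{bbox},
#'   \code{dx}, \code{dy} passed to \code{\link{makeGrid}}.
#' @param outDir where to write surface.csv / effective_range.json
#'   (default: the run directory).
#' @param geojson also write a GeoJSON point file.
#' @param seed seed for the conditional simulation.
#' @return invisibly, the \code{\link{SurfaceSummary-class}}.
#' @export
predictRun <- function(runDir, grid, outDir = runDir, geojson = FALSE,
                       seed = 1L) {
  draws <- readDraws(runDir)
  if (variant(draws) != "M3")
    stop("kriging requires an M3 run; this run is ", variant(draws))
  cityFile <- file.path(runDir, "cities.csv")
  if (!file.exists(cityFile)) stop("run directory has no cities.csv")
  cfg <- tryCatch(yaml::read_yaml(file.path(runDir, "config.yaml")),
                  error = function(e) NULL)
  crs <- if (!is.null(cfg)) cfgGet(cfg, "data.crs", "projected_km") else "projected_km"
  geo <- readCityCoords(cityFile, crs = crs)
  if (is.list(grid) && !is.null(grid$bbox))
    grid <- makeGrid(as.numeric(grid$bbox), grid$dx, grid$dy)
  cd <- krigeCoefficient(draws, geo, grid, which = "slope", seed = seed)
  surf <- predictSurface(cd)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeSurface(surf, file.path(outDir, "surface.csv"),
               geojson = if (geojson) file.path(outDir, "surface.geojson"))
  er <- effectiveRangeSummary(draws)
  jsonlite::write_json(as.list(er), file.path(outDir, "effective_range.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(surf)
}

#' Compare fitted runs by DIC
#'
#' @param runDirs character vector (>= 2) of directories written by
#'   \code{\link{fitRun}} on the same dataset.
#' @return data.frame from \code{\link{compareModels}}.  Runs fitted to
#'   different datasets (fingerprint mismatch) are an error.
#' @export
compareRuns <- function(runDirs) {
  if (length(runDirs) < 2L) stop("need at least 2 runs to compare")
  metas <- lapply(runDirs, function(d)
    jsonlite::read_json(file.path(d, "metadata.json"), simplifyVector = TRUE))
  fps <- vapply(metas, function(m) m$dataFingerprint, "")
  if (length(unique(fps)) != 1L)
    stop("runs were fitted to different datasets (fingerprint mismatch)")
  dics <- lapply(runDirs, function(d) {
    j <- jsonlite::read_json(file.path(d, "dic.json"), simplifyVector = TRUE)
    new("DicResult", dbar = j$dbar, dAtMean = j$dAtMean, pD = j$pD, dic = j$dic)
  })
  names(dics) <- vapply(seq_along(runDirs), function(i)
    paste0(metas[[i]]$variant, " (", basename(runDirs[i]), ")"), "")
  compareModels(dics)
}

#' Simulate a dataset and write its input files
#'
#' Writes tract_table.csv, adjacency.csv, cities.csv and truth.json into
#' the output directory, ready to be fitted with \code{\link{fitRun}}.
#'
#' @param config YAML path or list with keys \code{simulate.J},
#'   \code{simulate.n_per_city}, \code{simulate.region_km}, optional
#'   \code{simulate.truth} overrides of \code{\link{defaultTruth}},
#'   \code{seed}, \code{output.dir}.
#' @return invisibly, the \code{\link{SyntheticDataset-class}}.
#' @export
simulateRun <- function(config) {
  config <- readConfig(config)
  outDir <- cfgGet(config, "output.dir")
  if (is.null(outDir)) stop("missing config key: output.dir")
  seed <- cfgGet(config, "seed", 1L)
  layout <- simulateLayout(J = cfgGet(config, "simulate.J", 31L),
                           nPerCity = unlist(cfgGet(config, "simulate.n_per_city", 36L)),
                           regionKm = cfgGet(config, "simulate.region_km", 1000),
                           seed = seed)
  truth <- utils::modifyList(defaultTruth(),
                             lapply(cfgGet(config, "simulate.truth", list()), unlist))
  ds <- simulateDataset(layout, truth, seed = seed + 1L)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeTractTable(ds@data, file.path(outDir, "tract_table.csv"))
  writeAdjacencyEdges(ds@adjacency, file.path(outDir, "adjacency.csv"))
  utils::write.csv(data.frame(city_id = cityIds(ds@geo),
                              x = coords(ds@geo)[, 1L], y = coords(ds@geo)[, 2L]),
                   file.path(outDir, "cities.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- ds@truth
  jsonlite::write_json(tr[c("alpha", "beta", "sigma1", "phi1", "sigma2",
                            "phi2", "sigmaS", "sigmaH")],
                       file.path(outDir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(ds)
}
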