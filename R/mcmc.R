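## MCMC driver, convergence diagnostics, DIC and model comparison.

## Assemble the flat C++ sampler inputs from the S4 containers: global CSR
## adjacency, global component labels, city index.
samplerInputs <- function(data, adjacency) {
  stopifnot(is(data, "TractData"), is(adjacency, "TractAdjacency"))
  if (!identical(cityIds(data), cityIds(adjacency)))
    stop("data and adjacency disagree on the city set")
  nD <- tractsPerCity(data); nA <- tractsPerCity(adjacency)
  if (!all(nD == nA))
    stop("data and adjacency disagree on tracts per city")
  J <- nCities(data)
  offsets <- cumsum(c(0L, unname(nD)))[seq_len(J)]
  N <- sum(nD)
  nbr <- vector("list", N)
  e <- adjacency@edges
  if (nrow(e)) {
    jidx <- match(e$city, cityIds(data))
    gFrom <- offsets[jidx] + e$from
    gTo <- offsets[jidx] + e$to
    for (k in seq_along(gFrom)) {
      nbr[[gFrom[k]]] <- c(nbr[[gFrom[k]]], gTo[k])
      nbr[[gTo[k]]] <- c(nbr[[gTo[k]]], gFrom[k])
    }
  }
  counts <- vapply(nbr, length, 0L)
  adjPtr <- cumsum(c(0L, counts))
  adjIdx <- unlist(nbr, use.names = FALSE)
  if (is.null(adjIdx)) adjIdx <- integer()
  comp <- integer(N)
  nComp <- 0L
  for (j in seq_len(J)) {
    cc <- cityComponents(adjacency, cityIds(data)[j])
    comp[offsets[j] + seq_along(cc)] <- nComp + cc
    nComp <- nComp + max(cc)
  }
  list(O = as.numeric(observed(data)), E = as.numeric(expected(data)),
       X = as.numeric(covariate(data)), city = cityIndex(data) - 1L, J = J,
       adjPtr = as.integer(adjPtr), adjIdx = as.integer(adjIdx - 1L),
       comp = as.integer(comp - 1L), nComp = nComp, N = N)
}

## Overdispersed random initial state for one chain (drawn from the current
## RNG stream, i.e. after the chain seed is set).
randomInit <- function(J, spec, bounds) {
  init <- list(b1 = rnorm(J, 0, 0.2), b2 = rnorm(J, 0, 0.02),
               sigmaS = runif(J, 0.02, 0.3), sigmaH = runif(J, 0.02, 0.3))
  if (spec@variant != "M1") {
    init$alpha <- rnorm(1, 0, 0.2)
    init$beta <- rnorm(1, 0, 0.02)
  }
  if (spec@variant == "M2") {
    init$sigmaB1 <- runif(1, 0.05, 0.3)
    init$sigmaB2 <- runif(1, 0.01, 0.1)
  }
  if (spec@variant == "M3") {
    init$sigma1 <- runif(1, 0.05, 0.3)
    init$sigma2 <- runif(1, 0.01, 0.1)
    init$phi1 <- runif(1, bounds[1L] + 0.2 * diff(bounds), bounds[2L] - 0.2 * diff(bounds))
    init$phi2 <- runif(1, bounds[1L] + 0.2 * diff(bounds), bounds[2L] - 0.2 * diff(bounds))
  }
  init
}

## Parameter column names in the order the sampler writes them.
samplerParamNames <- function(J, variant) {
  nm <- c(sprintf("b1[%d]", 1:J), sprintf("b2[%d]", 1:J),
          sprintf("sigmaS[%d]", 1:J), sprintf("sigmaH[%d]", 1:J))
  if (variant == "M2") nm <- c(nm, "alpha", "beta", "sigmaB1", "sigmaB2")
  if (variant == "M3") nm <- c(nm, "alpha", "beta", "sigma1", "phi1", "sigma2", "phi2")
  nm
}

#' Fit a model by Metropolis-within-Gibbs MCMC
#'
#' Runs \code{settings@nChains} independent chains (one master seed spawns
#' per-chain streams) of a componentwise sampler: single-site
#' random-walk Metropolis for the tract random effects (intrinsic-CAR
#' proposals are balanced within each graph component, so the field obeys
#' its per-component sum-to-zero identifiability constraint at every
#' sweep), per-city Metropolis for the coefficients, conjugate Gibbs for
#' alpha/beta and for all variances, and random-walk Metropolis for the
#' decay parameters.  Proposal scales adapt during burn-in only and are
#' frozen afterwards.
#'
#' @param data a \code{\link{TractData-class}}.
#' @param adjacency a \code{\link{TractAdjacency-class}} on the same tracts.
#' @param spec a \code{\link{ModelSpec-class}}.  For M3 with unset
#'   decayBounds, \code{\link{defaultDecayBounds}} of the distance matrix
#'   is used.
#' @param settings an \code{\link{McmcSettings-class}}.
#' @param geo a \code{\link{CityGeo-class}} (required for M3).
#' @param useLikelihood set FALSE for a prior-only run (requires proper
#'   coefficient priors, i.e. finite \code{spec@coefPriorSd} and variant
#'   M2/M3).
#' @param verbose print per-chain progress.
#' @return a \code{\link{PosteriorDraws-class}}.
#' @export
runMcmc <- function(data, adjacency, spec, settings = mcmcSettings(),
                    geo = NULL, useLikelihood = TRUE, verbose = FALSE) {
  stopifnot(is(spec, "ModelSpec"), is(settings, "McmcSettings"))
  validObject(settings)
  si <- samplerInputs(data, adjacency)
  D <- matrix(0, 1L, 1L)
  bounds <- c(NA_real_, NA_real_)
  if (spec@variant == "M3") {
    if (is.null(geo)) stop("M3 requires city coordinates (geo)")
    if (!identical(cityIds(geo), cityIds(data)))
      stop("geo and data disagree on the city set")
    D <- distances(geo)
    bounds <- spec@decayBounds
    if (!all(is.finite(bounds))) {
      bounds <- defaultDecayBounds(D)
      spec@decayBounds <- bounds
    }
  }
  if (!useLikelihood &&
      (spec@variant == "M1" || !is.finite(spec@coefPriorSd)))
    stop("prior-only runs need proper coefficient priors ",
         "(finite coefPriorSd, variant M2 or M3)")

  set.seed(settings@seed)
  chainSeeds <- sample.int(.Machine$integer.max - 1L, settings@nChains)
  nKeep <- (settings@nIter - settings@nBurnin) %/% settings@thin
  nmAll <- samplerParamNames(si$J, spec@variant)
  keepCols <- rep(TRUE, length(nmAll))
  if (!spec@includeIcar) keepCols[grepl("^sigmaS", nmAll)] <- FALSE
  if (!spec@includeHet) keepCols[grepl("^sigmaH", nmAll)] <- FALSE

  draws <- vector("list", settings@nChains)
  deviance <- matrix(NA_real_, nKeep, settings@nChains)
  logThetaSum <- numeric(si$N)
  accept <- NULL
  for (ch in seq_len(settings@nChains)) {
    if (verbose)
      message(sprintf("[%s] chain %d/%d (%s, %d iterations)", format(Sys.time(), "%H:%M:%S"),
                      ch, settings@nChains, spec@variant, settings@nIter))
    set.seed(chainSeeds[ch])
    init <- randomInit(si$J, spec, bounds)
    res <- .svc_sampler(si$O, si$E, si$X, si$city, si$J, si$adjPtr, si$adjIdx,
                        si$comp, si$nComp, D,
                        match(spec@variant, c("M1", "M2", "M3")),
                        spec@sdUpper,
                        if (is.finite(bounds[1L])) bounds[1L] else 0,
                        if (is.finite(bounds[2L])) bounds[2L] else 1,
                        spec@coefPriorSd, spec@includeIcar, spec@includeHet,
                        useLikelihood, settings@nIter, settings@nBurnin,
                        settings@thin, TRUE, init, list())
    m <- res$samples
    colnames(m) <- nmAll
    draws[[ch]] <- m[, keepCols, drop = FALSE]
    deviance[, ch] <- res$deviance
    logThetaSum <- logThetaSum + as.numeric(res$logThetaSum)
    acc <- unlist(res$accept)
    accept <- if (is.null(accept)) acc else accept + acc
  }
  accept <- accept / settings@nChains
  new("PosteriorDraws", draws = draws, deviance = deviance,
      logThetaMean = logThetaSum / (nKeep * settings@nChains),
      spec = spec, settings = settings, cityIds = cityIds(data),
      nTracts = setNames(as.integer(tractsPerCity(data)), cityIds(data)),
      dataFingerprint = dataFingerprint(data), accept = accept)
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Plain between/within form: with m chains of length n, W the mean
#' within-chain variance and B/n the variance of the chain means,
#' \code{rhat = sqrt(((n-1)/n W + B/n) / W)}.  Note the small-sample
#' factor (n-1)/n: for m identical chains (B = 0) the statistic is
#' \code{sqrt((n-1)/n)}, marginally below 1.
#'
#' @param x numeric matrix (draws x chains) or list of equal-length
#'   numeric vectors, one per chain.
#' @return the scale reduction factor (about 1 at convergence).
#' @export
rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("rhat needs at least 2 chains")
  if (n < 2L) stop("rhat needs at least 2 draws per chain")
  W <- mean(apply(x, 2L, var))
  B_n <- var(colMeans(x))            # = B/n
  if (W == 0) return(if (B_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_n) / W)
}

#' Autocorrelation-based effective sample size
#'
#' Initial-positive-sequence estimator (Geyer): for each chain the lag
#' autocorrelations are summed in pairs until a pair sum goes negative;
#' chain ESS values n / (1 + 2 sum rho) are added across chains.
#'
#' @param x numeric vector (one chain), matrix (draws x chains) or list of
#'   chains.
#' @return effective number of independent draws.  A constant chain yields
#'   the total draw count with a warning.
#' @export
effectiveSampleSize <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  total <- 0
  for (ch in seq_len(ncol(x))) {
    v <- x[, ch]
    n <- length(v)
    if (var(v) == 0) {
      warning("constant chain: reporting nominal draw count as ESS")
      total <- total + n
      next
    }
    rho <- as.numeric(acf(v, lag.max = min(n - 1L, 1000L), plot = FALSE,
                          demean = TRUE)$acf)[-1L]
    ssum <- 0
    k <- 1L
    while (k + 1L <= length(rho)) {
      pair <- rho[k] + rho[k + 1L]
      if (pair < 0) break
      ssum <- ssum + pair
      k <- k + 2L
    }
    total <- total + n / (1 + 2 * ssum)
  }
  total
}

#' Convergence report over all monitored parameters
#'
#' Applies the paper-style rule: every parameter must have
#' \code{rhat < rhatMax} and total effective sample size \code{> essMin}.
#'
#' @param draws a \code{\link{PosteriorDraws-class}} (>= 2 chains).
#' @param rhatMax,essMin thresholds (defaults 1.1 and 100).
#' @return a \code{\link{ConvergenceReport-class}}.
#' @export
checkConvergence <- function(draws, rhatMax = 1.1, essMin = 100) {
  if (length(draws@draws) < 2L) stop("need at least 2 chains")
  nm <- paramNames(draws)
  r <- e <- numeric(length(nm))
  for (k in seq_along(nm)) {
    per <- lapply(draws@draws, function(m) m[, nm[k]])
    mat <- do.call(cbind, per)
    if (all(apply(mat, 2L, var) == 0) && var(colMeans(mat)) == 0) {
      r[k] <- 1; e[k] <- suppressWarnings(effectiveSampleSize(mat))
    } else {
      r[k] <- rhat(mat)
      e[k] <- suppressWarnings(effectiveSampleSize(mat))
    }
  }
  tab <- data.frame(parameter = nm, rhat = r, ess = e,
                    pass = r < rhatMax & e > essMin)
  new("ConvergenceReport", table = tab, rhatMax = rhatMax, essMin = essMin,
      pass = all(tab$pass))
}

#' Deviance information criterion
#'
#' Dbar is the posterior mean of the deviance (-2 log-likelihood) over the
#' retained draws; the plug-in deviance is evaluated at the posterior mean
#' of each tract's log relative risk (linear-predictor scale, the
#' WinBUGS-style convention for this model class); pD = Dbar - Dhat and
#' DIC = Dbar + pD.
#'
#' @param draws a \code{\link{PosteriorDraws-class}} from a fit with the
#'   likelihood active.
#' @param data the \code{\link{TractData-class}} the model was fit to.
#' @return a \code{\link{DicResult-class}}.
#' @export
dic <- function(draws, data) {
  if (any(is.na(draws@deviance)))
    stop("draws carry no likelihood information (prior-only run?)")
  if (!identical(draws@dataFingerprint, dataFingerprint(data)))
    stop("draws were not fit to this dataset (fingerprint mismatch)")
  dbar <- mean(draws@deviance)
  m <- draws@logThetaMean
  dAtMean <- -2 * poissonLogLikelihood(m, data)
  pD <- dbar - dAtMean
  new("DicResult", dbar = dbar, dAtMean = dAtMean, pD = pD, dic = dbar + pD)
}

#' Compare models by DIC
#'
#' Sorts ascending by DIC and annotates each model's difference from the
#' best with the conventional bands: negligible (< 3), moderate (3-7),
#' clear (> 7).
#'
#' @param results named list of \code{\link{DicResult-class}} objects (or
#'   plain DIC numbers); >= 2 entries.
#' @return data.frame (model, dic, pD, deltaDic, band), best model first.
#' @export
compareModels <- function(results) {
  if (length(results) < 2L) stop("need at least 2 models to compare")
  lab <- names(results)
  if (is.null(lab)) lab <- paste0("model", seq_along(results))
  dics <- vapply(results, function(r) if (is(r, "DicResult")) r@dic else as.numeric(r), 0)
  pds <- vapply(results, function(r) if (is(r, "DicResult")) r@pD else NA_real_, 0)
  ord <- order(dics)
  delta <- dics[ord] - dics[ord][1L]
  band <- cut(delta, breaks = c(-Inf, 3, 7, Inf),
              labels = c("negligible", "moderate", "clear"), right = FALSE)
  band <- as.character(band)
  band[1L] <- "best"
  data.frame(model = lab[ord], dic = dics[ord], pD = pds[ord],
             deltaDic = delta, band = band, row.names = NULL)
}
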