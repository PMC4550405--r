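## Central S4 containers.  Validity methods enforce the domain invariants;
## all slot access from user code goes through the accessors in accessors.R.

#' TractData: tract-level observed/expected counts and covariate
#'
#' One row per census tract, grouped by city.  Holds the observed count
#' (O_ij), the expected count from indirect standardization (E_ij) and the
#' tract-level covariate (X_ij, e.g. an unemployment percentage).
#'
#' @slot tracts data.frame with columns \code{city} (factor), \code{tract}
#'   (character, unique within city), \code{observed}, \code{expected},
#'   \code{covariate}.  Rows are ordered by city then tract.
#' @slot cityIds character vector of city labels, in model order j = 1..J.
#' @export
setClass("TractData",
  representation(tracts = "data.frame", cityIds = "character"))

setValidity("TractData", function(object) {
  tr <- object@tracts
  msgs <- character()
  need <- c("city", "tract", "observed", "expected", "covariate")
  if (!all(need %in% names(tr)))
    return(paste("missing column(s):", paste(setdiff(need, names(tr)), collapse = ", ")))
  if (!is.factor(tr$city)) msgs <- c(msgs, "city must be a factor")
  else if (!identical(levels(tr$city), object@cityIds))
    msgs <- c(msgs, "cityIds must equal levels(tracts$city)")
  bad <- which(!is.finite(tr$expected) | tr$expected <= 0)
  if (length(bad))
    msgs <- c(msgs, paste0("expected counts must be > 0 (row ", bad[1L], ")"))
  badO <- which(tr$observed < 0 | tr$observed != round(tr$observed))
  if (length(badO))
    msgs <- c(msgs, paste0("observed counts must be nonnegative integers (row ", badO[1L], ")"))
  if (anyDuplicated(paste(tr$city, tr$tract, sep = "\r")))
    msgs <- c(msgs, "duplicated (city, tract) pair")
  if (any(tabulate(tr$city, nbins = length(object@cityIds)) < 1L))
    msgs <- c(msgs, "every city must have at least one tract")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TractAdjacency: per-city undirected tract neighbourhood graphs
#'
#' Support structure for the intrinsic CAR prior.  Edges connect tracts of
#' the same city only; the graph is stored as a deduplicated edge list on
#' within-city 1-based tract indices with \code{from < to}.
#'
#' @slot cityIds character, city labels in model order.
#' @slot nTracts integer vector, tracts per city (named by city).
#' @slot tractLabels list of character vectors mapping within-city index to
#'   the tract label used in the input files.
#' @slot edges data.frame with columns \code{city} (character), \code{from},
#'   \code{to} (integer within-city indices, from < to).
#' @export
setClass("TractAdjacency",
  representation(cityIds = "character", nTracts = "integer",
                 tractLabels = "list", edges = "data.frame"))

setValidity("TractAdjacency", function(object) {
  e <- object@edges
  if (!all(c("city", "from", "to") %in% names(e)))
    return("edges needs columns city, from, to")
  if (nrow(e)) {
    if (!all(e$city %in% object@cityIds)) return("edge references unknown city")
    if (any(e$from >= e$to)) return("edges must satisfy from < to (no self-loops)")
    n <- object@nTracts[match(e$city, object@cityIds)]
    if (any(e$from < 1L | e$to > n)) return("edge tract index out of range")
    if (anyDuplicated(paste(e$city, e$from, e$to))) return("duplicated edge")
  }
  if (length(object@nTracts) != length(object@cityIds))
    return("nTracts/cityIds length mismatch")
  TRUE
})

#' CityGeo: city locations and intercity distance matrix
#'
#' @slot cityIds character, city labels in model order.
#' @slot coords numeric J x 2 matrix (columns x, y): projected km or
#'   longitude/latitude degrees according to \code{crs}.
#' @slot crs either \code{"projected_km"} or \code{"lonlat"}.
#' @slot D symmetric J x J intercity distance matrix in km, zero diagonal,
#'   strictly positive off-diagonal (cities are distinct points).
#' @export
setClass("CityGeo",
  representation(cityIds = "character", coords = "matrix",
                 crs = "character", D = "matrix"))

setValidity("CityGeo", function(object) {
  J <- length(object@cityIds)
  if (J < 2L) return("need at least 2 cities")
  if (!object@crs %in% c("projected_km", "lonlat")) return("unknown crs")
  if (!all(dim(object@coords) == c(J, 2L))) return("coords must be J x 2")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  D <- object@D
  if (!all(dim(D) == c(J, J))) return("D must be J x J")
  if (any(abs(diag(D)) > 1e-12)) return("D diagonal must be zero")
  if (max(abs(D - t(D))) > 1e-9) return("D must be symmetric")
  off <- D[upper.tri(D)]
  if (any(off <= 0)) return("off-diagonal distances must be > 0 (duplicate city coordinates?)")
  TRUE
})

#' ModelSpec: model variant and prior hyperparameters
#'
#' @slot variant one of \code{"M1"}, \code{"M2"}, \code{"M3"}.
#' @slot sdUpper upper limit l of the Uniform(0, l) priors on all standard
#'   deviations (log-relative-risk scale).
#' @slot decayBounds numeric(2), the Uniform(a, b) support of the decay
#'   parameters (per km); finite only for M3 (may be NA, in which case
#'   \code{\link{runMcmc}} fills in \code{\link{defaultDecayBounds}}).
#' @slot coefPriorSd prior SD of the Normal(0, sd^2) priors on the
#'   population coefficients alpha and beta; \code{Inf} (the default) means
#'   improper flat priors as in the models' definition.
#' @slot includeIcar,includeHet switch the tract-level spatial /
#'   heterogeneity random effects on or off (both on for the full BYM
#'   structure).
#' @export
setClass("ModelSpec",
  representation(variant = "character", sdUpper = "numeric",
                 decayBounds = "numeric", coefPriorSd = "numeric",
                 includeIcar = "logical", includeHet = "logical"))

setValidity("ModelSpec", function(object) {
  if (!object@variant %in% c("M1", "M2", "M3")) return("variant must be M1, M2 or M3")
  if (!is.finite(object@sdUpper) || object@sdUpper <= 0) return("sdUpper must be > 0")
  db <- object@decayBounds
  if (length(db) != 2L) return("decayBounds must have length 2")
  if (object@variant != "M3" && any(is.finite(db)))
    return("decayBounds only apply to variant M3")
  if (object@variant == "M3" && all(is.finite(db))) {
    if (db[1L] <= 0 || db[1L] >= db[2L]) return("decayBounds must satisfy 0 < a < b")
  }
  if (object@coefPriorSd <= 0) return("coefPriorSd must be > 0 (Inf for flat)")
  TRUE
})

#' McmcSettings: chain layout for the Metropolis-within-Gibbs sampler
#'
#' @slot nChains,nIter,nBurnin,thin,seed integers; retained draws per chain
#'   are \code{floor((nIter - nBurnin)/thin)} and must be >= 1.
#' @export
setClass("McmcSettings",
  representation(nChains = "integer", nIter = "integer", nBurnin = "integer",
                 thin = "integer", seed = "integer"))

setValidity("McmcSettings", function(object) {
  if (object@nChains < 1L) return("nChains must be >= 1")
  if (object@nBurnin < 0L || object@nBurnin >= object@nIter)
    return("need 0 <= nBurnin < nIter")
  if (object@thin < 1L) return("thin must be >= 1")
  if ((object@nIter - object@nBurnin) %/% object@thin < 1L)
    return("settings yield zero retained draws")
  TRUE
})

#' PosteriorDraws: retained multi-chain MCMC samples
#'
#' @slot draws list with one numeric matrix per chain (retained draw x
#'   parameter, identical parameter columns across chains).
#' @slot deviance matrix (retained draw x chain) of -2 log-likelihood.
#' @slot logThetaMean posterior mean of log(theta_ij) per tract (plug-in
#'   point for DIC).
#' @slot spec,settings the ModelSpec and McmcSettings used.
#' @slot cityIds character; \code{nTracts} integer per city.
#' @slot dataFingerprint character summarising the data the model was fit
#'   to (guards DIC comparison across runs).
#' @slot accept named numeric vector of post-burn-in acceptance rates.
#' @export
setClass("PosteriorDraws",
  representation(draws = "list", deviance = "matrix", logThetaMean = "numeric",
                 spec = "ModelSpec", settings = "McmcSettings",
                 cityIds = "character", nTracts = "integer",
                 dataFingerprint = "character", accept = "numeric"))

setValidity("PosteriorDraws", function(object) {
  if (!length(object@draws)) return("no chains")
  cn <- colnames(object@draws[[1L]])
  nk <- nrow(object@draws[[1L]])
  for (m in object@draws) {
    if (!identical(colnames(m), cn)) return("parameter columns differ across chains")
    if (nrow(m) != nk) return("unequal draw counts across chains")
  }
  TRUE
})

#' ConvergenceReport: per-parameter R-hat / effective-sample-size verdicts
#'
#' @slot table data.frame with columns parameter, rhat, ess, pass.
#' @slot rhatMax,essMin the thresholds applied.
#' @slot pass overall verdict (all parameters pass).
#' @export
setClass("ConvergenceReport",
  representation(table = "data.frame", rhatMax = "numeric",
                 essMin = "numeric", pass = "logical"))

#' DicResult: deviance information criterion decomposition
#'
#' @slot dbar posterior mean deviance.
#' @slot dAtMean deviance at the posterior mean of log(theta_ij) (plug-in
#'   on the linear-predictor scale).
#' @slot pD effective number of parameters, dbar - dAtMean.
#' @slot dic dbar + pD.
#' @export
setClass("DicResult",
  representation(dbar = "numeric", dAtMean = "numeric",
                 pD = "numeric", dic = "numeric"))

setValidity("DicResult", function(object) {
  if (abs(object@dic - (object@dbar + object@pD)) > 1e-9 * max(1, abs(object@dic)))
    return("dic must equal dbar + pD")
  TRUE
})

#' SurfaceSummary: per-grid-point posterior summaries of the kriged RR
#'
#' @slot locations numeric G x 2 matrix of grid coordinates.
#' @slot rrMean,rrSd,probGt1 numeric vectors of length G: posterior mean of
#'   the relative risk, its posterior SD, and P(RR > 1) (strict inequality).
#' @export
setClass("SurfaceSummary",
  representation(locations = "matrix", rrMean = "numeric",
                 rrSd = "numeric", probGt1 = "numeric"))

setValidity("SurfaceSummary", function(object) {
  G <- nrow(object@locations)
  if (length(object@rrMean) != G || length(object@rrSd) != G ||
      length(object@probGt1) != G) return("summary length mismatch")
  if (any(object@rrMean <= 0)) return("rrMean must be > 0")
  if (any(object@rrSd < 0)) return("rrSd must be >= 0")
  if (any(object@probGt1 < 0 | object@probGt1 > 1)) return("probGt1 must be in [0,1]")
  TRUE
})

#' SyntheticLayout: simulated city locations plus per-city tract lattices
#'
#' @slot geo CityGeo of simulated city centroids.
#' @slot adjacency TractAdjacency of rook-adjacency grid lattices.
#' @slot nPerCity integer tracts per city.
#' @export
setClass("SyntheticLayout",
  representation(geo = "CityGeo", adjacency = "TractAdjacency",
                 nPerCity = "integer"))

#' SyntheticDataset: tract table generated under the geostatistical model
#'
#' @slot data TractData of simulated counts.
#' @slot adjacency,geo the layout the data were generated on.
#' @slot truth named list: generating parameters plus the realized b1, b2,
#'   S, H and log-relative-risk vectors.
#' @export
setClass("SyntheticDataset",
  representation(data = "TractData", adjacency = "TractAdjacency",
                 geo = "CityGeo", truth = "list"))
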