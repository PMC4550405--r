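## Accessors and show methods.

#' @rdname TractData-class
#' @param object,x a \code{TractData}
#' @export
setGeneric("cityIds", function(x) standardGeneric("cityIds"))

#' @rdname TractData-class
#' @export
setMethod("cityIds", "TractData", function(x) x@cityIds)

#' @rdname TractAdjacency-class
#' @export
setMethod("cityIds", "TractAdjacency", function(x) x@cityIds)

#' @rdname CityGeo-class
#' @export
setMethod("cityIds", "CityGeo", function(x) x@cityIds)

#' Number of cities
#' @param x a TractData, TractAdjacency or CityGeo
#' @export
setGeneric("nCities", function(x) standardGeneric("nCities"))

#' @rdname nCities
#' @export
setMethod("nCities", "TractData", function(x) length(x@cityIds))
#' @rdname nCities
#' @export
setMethod("nCities", "CityGeo", function(x) length(x@cityIds))
#' @rdname nCities
#' @export
setMethod("nCities", "TractAdjacency", function(x) length(x@cityIds))

#' Tracts per city
#' @param x a TractData or TractAdjacency
#' @return named integer vector, one entry per city in model order.
#' @export
setGeneric("tractsPerCity", function(x) standardGeneric("tractsPerCity"))

#' @rdname tractsPerCity
#' @export
setMethod("tractsPerCity", "TractData", function(x)
  setNames(tabulate(x@tracts$city, nbins = length(x@cityIds)), x@cityIds))
#' @rdname tractsPerCity
#' @export
setMethod("tractsPerCity", "TractAdjacency", function(x) x@nTracts)

#' Column accessors for TractData
#' @param x a TractData
#' @name tract-columns
#' @export
observed <- function(x) x@tracts$observed
#' @rdname tract-columns
#' @export
expected <- function(x) x@tracts$expected
#' @rdname tract-columns
#' @export
covariate <- function(x) x@tracts$covariate
#' @rdname tract-columns
#' @export
cityIndex <- function(x) as.integer(x@tracts$city)

#' Intercity distance matrix of a CityGeo
#' @param x a CityGeo
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname distances
#' @export
setMethod("distances", "CityGeo", function(x) x@D)

#' City coordinates of a CityGeo
#' @param x a CityGeo
#' @export
coords <- function(x) x@coords

#' Edge list of a TractAdjacency
#' @param x a TractAdjacency
#' @export
adjacencyEdges <- function(x) x@edges

#' Neighbour counts per tract, in city/tract order
#' @param x a TractAdjacency
#' @return list of integer vectors, one per city.
#' @export
neighborCounts <- function(x) {
  out <- lapply(seq_along(x@cityIds), function(j) {
    n <- x@nTracts[j]
    e <- x@edges[x@edges$city == x@cityIds[j], , drop = FALSE]
    tabulate(c(e$from, e$to), nbins = n)
  })
  names(out) <- x@cityIds
  out
}

#' Isolated (neighbourless) tracts
#' @param x a TractAdjacency
#' @return data.frame (city, tract index, tract label) of isolated tracts.
#' @export
isolatedTracts <- function(x) {
  nc <- neighborCounts(x)
  out <- do.call(rbind, lapply(seq_along(nc), function(j) {
    idx <- which(nc[[j]] == 0L)
    if (!length(idx)) return(NULL)
    data.frame(city = x@cityIds[j], index = idx,
               tract = x@tractLabels[[j]][idx], stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(city = character(), index = integer(), tract = character())
  out
}

#' Model variant of a ModelSpec or PosteriorDraws
#' @param x a ModelSpec or PosteriorDraws
#' @export
setGeneric("variant", function(x) standardGeneric("variant"))
#' @rdname variant
#' @export
setMethod("variant", "ModelSpec", function(x) x@variant)
#' @rdname variant
#' @export
setMethod("variant", "PosteriorDraws", function(x) x@spec@variant)

#' Parameter names of a PosteriorDraws
#' @param x a PosteriorDraws
#' @export
paramNames <- function(x) colnames(x@draws[[1L]])

#' Number of chains / retained draws per chain
#' @param x a PosteriorDraws
#' @export
nChains <- function(x) length(x@draws)
#' @rdname nChains
#' @export
nRetained <- function(x) nrow(x@draws[[1L]])

#' Extract draws for a set of parameters
#'
#' @param x a PosteriorDraws
#' @param params character vector of parameter names (regular names like
#'   \code{"beta"} or indexed like \code{"b2[3]"}).
#' @param pool if TRUE (default), chains are stacked into a single matrix
#'   (draw x parameter); otherwise a list of per-chain matrices.
#' @export
extractDraws <- function(x, params, pool = TRUE) {
  stopifnot(is(x, "PosteriorDraws"))
  missing <- setdiff(params, paramNames(x))
  if (length(missing))
    stop("unknown parameter(s): ", paste(missing, collapse = ", "))
  per <- lapply(x@draws, function(m) m[, params, drop = FALSE])
  if (pool) do.call(rbind, per) else per
}

#' DIC components
#' @param x a DicResult
#' @name dic-accessors
#' @export
dicValue <- function(x) x@dic
#' @rdname dic-accessors
#' @export
pD <- function(x) x@pD
#' @rdname dic-accessors
#' @export
dbar <- function(x) x@dbar

#' Convergence verdict
#' @param x a ConvergenceReport
#' @export
convergencePass <- function(x) x@pass
#' @rdname convergencePass
#' @export
convergenceTable <- function(x) x@table

#' @export
#' @describeIn SurfaceSummary-class coerce to data.frame (x, y, rr_mean,
#'   rr_sd, prob_gt1)
setMethod("as.data.frame", "SurfaceSummary", function(x, ...) {
  data.frame(x = x@locations[, 1L], y = x@locations[, 2L],
             rr_mean = x@rrMean, rr_sd = x@rrSd, prob_gt1 = x@probGt1)
})

setMethod("show", "TractData", function(object) {
  n <- tractsPerCity(object)
  cat("TractData:", nrow(object@tracts), "tracts in", length(object@cityIds),
      "cities\n  tracts/city:", paste(range(n), collapse = "-"),
      "\n  total observed:", sum(object@tracts$observed),
      " total expected:", format(sum(object@tracts$expected), digits = 6), "\n")
})

setMethod("show", "TractAdjacency", function(object) {
  iso <- nrow(isolatedTracts(object))
  cat("TractAdjacency:", nrow(object@edges), "edges over",
      sum(object@nTracts), "tracts in", length(object@cityIds), "cities",
      if (iso) paste0(" (", iso, " isolated)"), "\n")
})

setMethod("show", "CityGeo", function(object) {
  cat("CityGeo:", length(object@cityIds), "cities (", object@crs, ")\n",
      " intercity distances [km]:",
      paste(format(range(object@D[upper.tri(object@D)]), digits = 4), collapse = " - "),
      "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec variant", object@variant, " sdUpper =", object@sdUpper)
  if (object@variant == "M3")
    cat("  decayBounds = (", paste(format(object@decayBounds, digits = 4), collapse = ", "), ")")
  cat("\n")
})

setMethod("show", "McmcSettings", function(object) {
  cat("McmcSettings:", object@nChains, "chains x", object@nIter,
      "iterations (burn-in", object@nBurnin, ", thin", object@thin,
      ") -> ", (object@nIter - object@nBurnin) %/% object@thin,
      "retained draws/chain, seed", object@seed, "\n")
})

setMethod("show", "PosteriorDraws", function(object) {
  cat("PosteriorDraws (", object@spec@variant, "): ", length(object@draws),
      " chains x ", nrow(object@draws[[1L]]), " retained draws, ",
      ncol(object@draws[[1L]]), " parameters\n", sep = "")
})

setMethod("show", "ConvergenceReport", function(object) {
  cat("ConvergenceReport:", if (object@pass) "PASS" else "FAIL",
      sprintf("(rhat < %.3g, ess > %.3g)\n", object@rhatMax, object@essMin))
  bad <- object@table[!object@table$pass, , drop = FALSE]
  if (nrow(bad)) {
    cat("  failing parameters:\n")
    print(utils::head(bad, 10L), row.names = FALSE)
  }
})

setMethod("show", "DicResult", function(object) {
  cat(sprintf("DIC = %.2f (Dbar = %.2f, pD = %.2f)\n",
              object@dic, object@dbar, object@pD))
})

setMethod("show", "SurfaceSummary", function(object) {
  cat("SurfaceSummary:", nrow(object@locations), "grid points; RR mean range",
      paste(format(range(object@rrMean), digits = 4), collapse = " - "), "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:\n")
  show(object@data)
  cat("  truth: beta =", object@truth$beta,
      " eff.range(phi2) =", format(-log(0.05) / object@truth$phi2, digits = 4), "km\n")
})
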