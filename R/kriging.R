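## Bayesian kriging of city-level coefficients onto a prediction grid.
##
## Under M3 the coefficient field (intercept or slope) is a stationary
## Gaussian random field with constant mean (alpha or beta) and exponential
## covariance sigma^2 exp(-phi d).  For each retained posterior draw the
## coefficient at the grid locations, conditional on that draw's city
## coefficients, is exactly multivariate normal; sampling one realization
## per draw integrates the predictions over the full posterior.  The field
## has no nugget, so it interpolates the city values exactly.

#' Build a regular prediction grid
#'
#' @param bbox numeric c(xmin, xmax, ymin, ymax), same coordinate system
#'   as the fitted \code{\link{CityGeo-class}}.
#' @param dx,dy grid spacings (km for projected coordinates), > 0.
#' @param mask optional polygon (two-column matrix of vertices, closed or
#'   open); only grid points strictly inside the polygon (even-odd rule)
#'   are kept.
#' @return numeric matrix with columns x, y in row-major order (y outer,
#'   x inner), with spacing metadata in attributes \code{dx}, \code{dy}.
#' @export
makeGrid <- function(bbox, dx, dy, mask = NULL) {
  if (length(bbox) != 4L || bbox[2L] <= bbox[1L] || bbox[4L] <= bbox[3L])
    stop("bbox must be c(xmin, xmax, ymin, ymax) with positive extents")
  if (dx <= 0 || dy <= 0) stop("spacings must be > 0")
  xs <- seq(bbox[1L], bbox[2L], by = dx)
  ys <- seq(bbox[3L], bbox[4L], by = dy)
  pts <- cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
  if (!is.null(mask)) {
    keep <- pointInPolygon(pts, mask)
    pts <- pts[keep, , drop = FALSE]
    if (!nrow(pts)) stop("mask excludes every grid point")
  }
  attr(pts, "dx") <- dx
  attr(pts, "dy") <- dy
  pts
}

#' Even-odd point-in-polygon test
#'
#' Ray casting along +x: a point is inside when a horizontal ray crosses
#' the polygon boundary an odd number of times.
#'
#' @param points two-column matrix of query points.
#' @param poly two-column matrix of polygon vertices (closure implied).
#' @return logical vector.
#' @export
pointInPolygon <- function(points, poly) {
  points <- rbind(points)
  nv <- nrow(poly)
  if (nv < 3L) stop("polygon needs at least 3 vertices")
  inside <- logical(nrow(points))
  for (p in seq_len(nrow(points))) {
    x <- points[p, 1L]; y <- points[p, 2L]
    cross <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      yi <- poly[i, 2L]; yj <- poly[j, 2L]
      if ((yi > y) != (yj > y)) {
        xint <- poly[i, 1L] + (y - yi) / (yj - yi) * (poly[j, 1L] - poly[i, 1L])
        if (x < xint) cross <- !cross
      }
      j <- i
    }
    inside[p] <- cross
  }
  inside
}

## Cross-distance matrix (km) between two coordinate sets under a crs.
crossDistances <- function(a, b, crs) {
  if (crs == "projected_km") {
    out <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(nrow(b)))
      out[, j] <- sqrt((a[, 1L] - b[j, 1L])^2 + (a[, 2L] - b[j, 2L])^2)
    out
  } else {
    out <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(nrow(b)))
      out[, j] <- geosphere::distHaversine(b[j, ], a) / 1000
    out
  }
}

#' Krige a city coefficient field onto grid locations
#'
#' For every retained posterior draw (b, mu, sigma, phi) of the M3 fit,
#' samples the exact conditional multivariate-normal distribution of the
#' coefficient at the grid locations given that draw's city coefficients.
#' A grid point within 1e-9 km of a city receives the city's coefficient
#' draw directly (the no-nugget field interpolates; this also avoids a
#' near-singular solve).
#'
#' @param draws a \code{\link{PosteriorDraws-class}} from an M3 fit.
#' @param geo the \code{\link{CityGeo-class}} the model was fitted with.
#' @param grid matrix of prediction locations (columns x, y), e.g. from
#'   \code{\link{makeGrid}}.
#' @param which \code{"slope"} (the covariate effect b2, default) or
#'   \code{"intercept"} (b1).
#' @param seed optional integer seed for the conditional simulation.
#' @param nDraws optionally subsample to this many (evenly spaced) draws.
#' @param joint if TRUE, each draw's grid values are sampled jointly (with
#'   their conditional cross-covariance); if FALSE each location is sampled
#'   from its marginal conditional — per-location summaries are identical,
#'   and the marginal path scales to large grids.  Default: joint for
#'   grids up to 250 points.
#' @param returnMoments also return the per-draw conditional means and
#'   (co)variances (used for verification).
#' @return matrix (draw x location) of coefficient draws with the grid in
#'   attribute \code{"locations"}; if \code{returnMoments}, a list with
#'   elements \code{draws}, \code{mean}, and \code{cov} (list of per-draw
#'   conditional covariance matrices, joint path) or \code{var} (matrix,
#'   marginal path).
#' @export
krigeCoefficient <- function(draws, geo, grid, which = c("slope", "intercept"),
                             seed = NULL, nDraws = NULL, joint = NULL,
                             returnMoments = FALSE) {
  which <- match.arg(which)
  if (variant(draws) != "M3")
    stop("kriging requires an M3 fit (no spatial coefficient field in ",
         variant(draws), ")")
  if (!is.null(seed)) set.seed(seed)
  grid <- rbind(grid)
  G <- nrow(grid)
  if (is.null(joint)) joint <- G <= 250L
  J <- length(draws@cityIds)
  pars <- if (which == "slope") c(sprintf("b2[%d]", 1:J), "beta", "sigma2", "phi2")
          else c(sprintf("b1[%d]", 1:J), "alpha", "sigma1", "phi1")
  M <- extractDraws(draws, pars)
  if (!is.null(nDraws) && nDraws < nrow(M))
    M <- M[round(seq(1L, nrow(M), length.out = nDraws)), , drop = FALSE]
  Td <- nrow(M)

  Dcc <- distances(geo)
  Dgc <- crossDistances(grid, coords(geo), geo@crs)
  nearest <- apply(Dgc, 1L, which.min)
  atCity <- Dgc[cbind(seq_len(G), nearest)] < 1e-9
  Dgg <- if (joint) crossDistances(grid, grid, geo@crs) else NULL

  out <- matrix(NA_real_, Td, G)
  meanOut <- if (returnMoments) matrix(NA_real_, Td, G) else NULL
  covOut <- if (returnMoments && joint) vector("list", Td) else NULL
  varOut <- if (returnMoments && !joint) matrix(NA_real_, Td, G) else NULL
  free <- which(!atCity)

  for (t in seq_len(Td)) {
    b <- M[t, 1:J]
    mu <- M[t, J + 1L]
    sig <- M[t, J + 2L]
    phi <- M[t, J + 3L]
    R <- exp(-phi * Dcc)
    Rsolve <- solve(R, b - mu)                 # R^{-1} (b - mu)
    vals <- numeric(G)
    vals[atCity] <- b[nearest[atCity]]
    cm <- numeric(G)
    cm[atCity] <- vals[atCity]
    if (length(free)) {
      C <- exp(-phi * Dgc[free, , drop = FALSE])     # G0 x J correlations
      cmean <- mu + drop(C %*% Rsolve)
      A <- solve(R, t(C))                            # J x G0
      if (joint) {
        condCorr <- exp(-phi * Dgg[free, free, drop = FALSE]) - C %*% A
        condCov <- sig^2 * (condCorr + t(condCorr)) / 2
        eg <- eigen(condCov, symmetric = TRUE)
        ev <- pmax(eg$values, 0)
        z <- eg$vectors %*% (sqrt(ev) * rnorm(length(ev)))
        vals[free] <- cmean + drop(z)
        if (returnMoments) covOut[[t]] <- condCov
      } else {
        cvar <- sig^2 * pmax(1 - colSums(t(C) * A), 0)
        vals[free] <- cmean + sqrt(cvar) * rnorm(length(free))
        if (returnMoments) varOut[t, free] <- cvar
      }
      cm[free] <- cmean
    }
    out[t, ] <- vals
    if (returnMoments) meanOut[t, ] <- cm
  }
  attr(out, "locations") <- grid
  attr(out, "which") <- which
  if (returnMoments) {
    res <- list(draws = out, mean = meanOut)
    if (joint) res$cov <- covOut else res$var <- varOut
    return(res)
  }
  out
}

#' Summarise kriged coefficient draws as a relative-risk surface
#'
#' Relative-risk draws are exp(coefficient draws); per location the
#' posterior mean, posterior SD and exceedance probability P(RR > 1)
#' (strict inequality: draws exactly at RR = 1 do not count) are reported.
#'
#' @param coefDraws matrix (draw x location) from
#'   \code{\link{krigeCoefficient}} (grid carried in its
#'   \code{"locations"} attribute), or any draw matrix plus explicit
#'   \code{locations}.
#' @param locations optional matrix of locations overriding the attribute.
#' @return a \code{\link{SurfaceSummary-class}}.
#' @export
predictSurface <- function(coefDraws, locations = NULL) {
  if (is.null(locations)) locations <- attr(coefDraws, "locations")
  if (is.null(locations))
    locations <- cbind(x = seq_len(ncol(coefDraws)), y = 0)
  if (!nrow(coefDraws)) stop("no draws")
  rr <- exp(coefDraws)
  new("SurfaceSummary", locations = as.matrix(locations)[, 1:2, drop = FALSE],
      rrMean = colMeans(rr),
      rrSd = apply(rr, 2L, sd),
      probGt1 = colMeans(rr > 1))
}

#' Write a surface summary as CSV (and optionally GeoJSON points)
#'
#' @param x a \code{\link{SurfaceSummary-class}}.
#' @param path output CSV path (columns x, y, rr_mean, rr_sd, prob_gt1).
#' @param geojson optional path for a GeoJSON point-feature file.
#' @export
writeSurface <- function(x, path, geojson = NULL) {
  df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(geojson)) {
    feats <- lapply(seq_len(nrow(df)), function(i) list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df$x[i], df$y[i])),
      properties = list(rr_mean = df$rr_mean[i], rr_sd = df$rr_sd[i],
                        prob_gt1 = df$prob_gt1[i])))
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         geojson, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
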