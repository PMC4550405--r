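## Synthetic multi-city datasets with the generative structure of the
## geostatistical model (M3); M1/M2 arise as degenerate cases.

#' Simulate a city layout: centroids plus per-city tract lattices
#'
#' City centroids are drawn uniformly over a square region of side
#' \code{regionKm} with a minimum intercity separation enforced by
#' rejection; each city's tracts form a rook-adjacency grid lattice
#' (adjacency topology, not realistic tract geometry, is what the
#' intrinsic-CAR prior consumes).
#'
#' @param J number of cities (>= 2).
#' @param nPerCity tracts per city: a single count, a range \code{c(lo, hi)}
#'   sampled uniformly per city, or an explicit length-J vector of counts.
#' @param regionKm side of the square study region, km.
#' @param seed integer seed.
#' @param minSep minimum intercity distance, km (default scales with the
#'   region and city count).
#' @return a \code{\link{SyntheticLayout-class}}.
#' @export
simulateLayout <- function(J = 31L, nPerCity = 36L, regionKm = 1000,
                           seed = 1L, minSep = 0.45 * regionKm / sqrt(J)) {
  if (J < 2L) stop("need J >= 2 cities")
  set.seed(seed)
  pts <- matrix(NA_real_, J, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < J) {
    if (tries > 10000L)
      stop("could not place ", J, " cities with minimum separation ", minSep, " km")
    p <- runif(2L, 0, regionKm)
    tries <- tries + 1L
    if (placed == 0L ||
        min(sqrt((pts[seq_len(placed), 1L] - p[1L])^2 +
                 (pts[seq_len(placed), 2L] - p[2L])^2)) >= minSep) {
      placed <- placed + 1L
      pts[placed, ] <- p
    }
  }
  ids <- sprintf("city%02d", seq_len(J))
  geo <- cityGeo(data.frame(city_id = ids, x = pts[, 1L], y = pts[, 2L]),
                 crs = "projected_km")
  if (length(nPerCity) == J && J != 2L) {
    n <- as.integer(nPerCity)
  } else if (length(nPerCity) == 2L) {
    n <- sample(seq(nPerCity[1L], nPerCity[2L]), J, replace = TRUE)
  } else if (length(nPerCity) == 1L) {
    n <- rep(as.integer(nPerCity), J)
  } else stop("nPerCity must be a count, a range, or a length-J vector")

  labels <- lapply(n, function(nj) sprintf("t%03d", seq_len(nj)))
  names(labels) <- ids
  rows <- list()
  for (j in seq_len(J)) {
    nr <- max(1L, floor(sqrt(n[j])))
    nc <- ceiling(n[j] / nr)
    idx <- function(r, c) (r - 1L) * nc + c        # row-major cell index
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      i <- idx(r, cc)
      if (i > n[j]) next
      if (cc < nc && idx(r, cc + 1L) <= n[j])
        rows[[length(rows) + 1L]] <- c(ids[j], i, idx(r, cc + 1L))
      if (r < nr && idx(r + 1L, cc) <= n[j])
        rows[[length(rows) + 1L]] <- c(ids[j], i, idx(r + 1L, cc))
    }
  }
  edges <- if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(city = m[, 1L], from = as.integer(m[, 2L]),
               to = as.integer(m[, 3L]), stringsAsFactors = FALSE)
  } else data.frame(city = character(), from = integer(), to = integer())
  adj <- new("TractAdjacency", cityIds = ids,
             nTracts = setNames(as.integer(n), ids),
             tractLabels = labels, edges = edges)
  new("SyntheticLayout", geo = geo, adjacency = adj,
      nPerCity = setNames(as.integer(n), ids))
}

#' Default generating-truth preset
#'
#' Mirrors the empirical scale of multi-city deprivation/mortality studies:
#' an overall relative risk of about 1.025 per 1% covariate increase
#' (beta = 0.025), spatially structured city effects with an effective
#' range of 400 km in a 1000 km region, modest between-city coefficient
#' spread (city relative risks informative but overlapping), tract-level
#' covariate in percentage units U(5, 30) and expected counts U(0.5, 5).
#'
#' @return named list of generating parameters for
#'   \code{\link{simulateDataset}}.
#' @export
defaultTruth <- function() {
  list(alpha = 0, beta = 0.025,
       sigma1 = 0.15, phi1 = decayForRange(400),
       sigma2 = 0.02, phi2 = decayForRange(400),
       sigmaS = 0.1, sigmaH = 0.05,
       covariateRange = c(5, 30), expectedRange = c(0.5, 5))
}

#' Simulate a tract-level dataset under the geostatistical model
#'
#' Draws b1 ~ MVN(alpha 1, sigma1^2 exp(-phi1 D)),
#' b2 ~ MVN(beta 1, sigma2^2 exp(-phi2 D)), a per-city intrinsic-CAR field
#' S (via \code{\link{sampleIcar}}), iid heterogeneity H, covariate and
#' expected counts from their uniform ranges, and counts
#' O ~ Poisson(E exp(b1 + b2 X + S + H)).  Setting a standard deviation to
#' zero switches the corresponding component off exactly.
#'
#' @param layout a \code{\link{SyntheticLayout-class}}.
#' @param truth parameter list as from \code{\link{defaultTruth}};
#'   \code{sigmaS}/\code{sigmaH} may be scalars (recycled over cities) or
#'   length-J vectors.
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @return a \code{\link{SyntheticDataset-class}}.
#' @export
simulateDataset <- function(layout, truth = defaultTruth(), seed = 1L) {
  stopifnot(is(layout, "SyntheticLayout"))
  set.seed(seed)
  geo <- layout@geo
  adj <- layout@adjacency
  ids <- cityIds(geo)
  J <- length(ids)
  n <- layout@nPerCity
  N <- sum(n)
  D <- distances(geo)
  er <- effectiveRange(truth$phi2)
  off <- D[upper.tri(D)]
  if (er < min(off) || er > max(off))
    warning("effective range of phi2 (", round(er), " km) lies outside the ",
            "span of intercity distances [", round(min(off)), ", ",
            round(max(off)), "] km; the simulation is weakly informative ",
            "about the decay")

  drawField <- function(mu, sigma, phi) {
    if (sigma == 0) return(rep(mu, J))
    Sg <- exponentialCovariance(D, sigma, phi)
    ch <- tryCatch(chol(Sg), error = function(e)
      stop("coefficient covariance not positive definite (duplicate cities?)"))
    mu + drop(t(ch) %*% rnorm(J))
  }
  b1 <- drawField(truth$alpha, truth$sigma1, truth$phi1)
  b2 <- drawField(truth$beta, truth$sigma2, truth$phi2)

  sigmaS <- rep(truth$sigmaS, length.out = J)
  sigmaH <- rep(truth$sigmaH, length.out = J)
  S <- H <- numeric(N)
  ci <- rep(seq_len(J), times = n)
  for (j in seq_len(J)) {
    S[ci == j] <- if (sigmaS[j] > 0) sampleIcar(adj, sigmaS[j], city = ids[j])
                  else numeric(n[j])
  }
  for (j in seq_len(J))
    H[ci == j] <- if (sigmaH[j] > 0) rnorm(n[j], 0, sigmaH[j]) else numeric(n[j])

  X <- runif(N, truth$covariateRange[1L], truth$covariateRange[2L])
  E <- runif(N, truth$expectedRange[1L], truth$expectedRange[2L])
  eta <- b1[ci] + b2[ci] * X + S + H
  O <- rpois(N, E * exp(eta))

  df <- data.frame(city = rep(ids, times = n),
                   tract = unlist(layout@adjacency@tractLabels, use.names = FALSE),
                   observed = O, expected = E, covariate = X,
                   stringsAsFactors = FALSE)
  data <- tractData(df)
  truthOut <- truth
  truthOut$sigmaS <- sigmaS
  truthOut$sigmaH <- sigmaH
  truthOut$b1 <- b1; truthOut$b2 <- b2
  truthOut$S <- S; truthOut$H <- H; truthOut$logTheta <- eta
  new("SyntheticDataset", data = data, adjacency = adj, geo = geo,
      truth = truthOut)
}

#' Parameter-recovery report
#'
#' For each requested scalar parameter: the generating truth, posterior
#' mean, equal-tailed 95% CI, whether the CI covers the truth, and the
#' posterior z-score (mean - truth)/sd.
#'
#' @param truth generating-parameter list (as stored in a
#'   \code{\link{SyntheticDataset-class}}'s \code{truth} slot).
#' @param draws a \code{\link{PosteriorDraws-class}}.
#' @param params parameter names to score; default: all scalar parameters
#'   present in both \code{truth} and the draws.  A requested name missing
#'   on either side is an error.
#' @return data.frame (parameter, truth, mean, lower, upper, covered, z).
#' @export
recoveryReport <- function(truth, draws, params = NULL) {
  scalarNames <- c("alpha", "beta", "sigma1", "phi1", "sigma2", "phi2",
                   "sigmaB1", "sigmaB2")
  if (is.null(params))
    params <- intersect(intersect(scalarNames, names(truth)), paramNames(draws))
  if (!length(params)) stop("no matching parameter names between truth and draws")
  miss <- setdiff(params, paramNames(draws))
  if (length(miss)) stop("parameter(s) not in draws: ", paste(miss, collapse = ", "))
  missT <- setdiff(params, names(truth))
  if (length(missT)) stop("parameter(s) not in truth: ", paste(missT, collapse = ", "))
  rows <- lapply(params, function(p) {
    v <- extractDraws(draws, p)[, 1L]
    qs <- quantile(v, c(0.025, 0.975))
    tv <- truth[[p]]
    s <- sd(v)
    data.frame(parameter = p, truth = tv, mean = mean(v),
               lower = unname(qs[1L]), upper = unname(qs[2L]),
               covered = tv >= qs[1L] && tv <= qs[2L],
               z = if (s > 0) (mean(v) - tv) / s else 0)
  })
  do.call(rbind, rows)
}

#' Aggregate coverage over replicate recovery reports
#'
#' @param reports list of data.frames from \code{\link{recoveryReport}}.
#' @param parameter which parameter's coverage to aggregate.
#' @return fraction of replicates whose 95% CI covered the truth.
#' @export
coverageRate <- function(reports, parameter) {
  hits <- vapply(reports, function(r) {
    row <- r[r$parameter == parameter, , drop = FALSE]
    if (!nrow(row)) stop("parameter '", parameter, "' not in report")
    row$covered
  }, logical(1L))
  mean(hits)
}
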