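## Spatial building blocks: intrinsic CAR log-density and sampler,
## exponential distance-decay covariance, decay bounds, effective range.

#' Intrinsic CAR log-density (up to an additive constant)
#'
#' For a city's tract field s with neighbourhood graph W the improper
#' intrinsic CAR prior has density proportional to
#' \deqn{\sigma^{-(n-c)} \exp\{-\frac{1}{2\sigma^2}\sum_{i\sim k, i<k}(s_i-s_k)^2\}}
#' where c is the number of connected components of the graph (the rank
#' deficiency of the structure matrix).  Isolated tracts form singleton
#' components and drop out of both the quadratic form and the exponent.
#' The returned value is
#' \code{-q/(2 sd^2) - ((n - c)/2) * log(sd^2)}; graph-dependent constants
#' are omitted, so only differences across \code{s} and \code{sd} are
#' meaningful.
#'
#' @param s numeric vector over the city's tracts (length n_j).
#' @param adjacency a \code{\link{TractAdjacency-class}}.
#' @param sd conditional standard deviation sigma_Sj (> 0).
#' @param city which city's graph to use (default: the first).
#' @return log density up to a constant.  Invariant under s + t for scalar
#'   t (level shifts within each component).
#' @export
icarLogDensity <- function(s, adjacency, sd, city = cityIds(adjacency)[1L]) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  j <- match(city, adjacency@cityIds)
  if (is.na(j)) stop("unknown city: ", city)
  n <- adjacency@nTracts[[j]]
  if (length(s) != n)
    stop("s has length ", length(s), " but city '", city, "' has ", n, " tracts")
  e <- adjacency@edges[adjacency@edges$city == city, , drop = FALSE]
  q <- sum((s[e$from] - s[e$to])^2)
  comp <- graphComponents(n, e$from, e$to)
  c_ <- max(comp)
  -q / (2 * sd^2) - ((n - c_) / 2) * log(sd^2)
}

#' Draw one realization of an intrinsic CAR field
#'
#' Samples the proper distribution obtained by constraining the intrinsic
#' CAR to sum to zero within every connected component: the spectral
#' decomposition of the structure matrix Q0 = diag(degree) - W is taken and
#' independent Normal(0, sd^2/lambda_k) coefficients are drawn on the
#' eigenvectors with lambda_k > 0.  Isolated tracts get the value 0.
#'
#' @inheritParams icarLogDensity
#' @param seed optional integer; if supplied, \code{set.seed} is called
#'   first (otherwise the current RNG stream is used).
#' @return numeric vector of length n_j summing to zero per component.
#' @export
sampleIcar <- function(adjacency, sd, city = cityIds(adjacency)[1L], seed = NULL) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (!is.null(seed)) set.seed(seed)
  j <- match(city, adjacency@cityIds)
  if (is.na(j)) stop("unknown city: ", city)
  n <- adjacency@nTracts[[j]]
  e <- adjacency@edges[adjacency@edges$city == city, , drop = FALSE]
  if (!nrow(e)) return(numeric(n))
  Q0 <- matrix(0, n, n)
  for (i in seq_len(nrow(e))) {
    a <- e$from[i]; b <- e$to[i]
    Q0[a, b] <- Q0[a, b] - 1
    Q0[b, a] <- Q0[b, a] - 1
    Q0[a, a] <- Q0[a, a] + 1
    Q0[b, b] <- Q0[b, b] + 1
  }
  eg <- eigen(Q0, symmetric = TRUE)
  pos <- eg$values > 1e-9 * max(eg$values)
  z <- rnorm(sum(pos), 0, sd / sqrt(eg$values[pos]))
  drop(eg$vectors[, pos, drop = FALSE] %*% z)
}

#' Exponential distance-decay covariance matrix
#'
#' Sigma = sd^2 * exp(-decay * D), elementwise: variance sd^2 on the
#' diagonal, decaying with intercity distance at rate \code{decay} per km.
#' Positive definite for any set of distinct city locations.
#'
#' @param D symmetric nonnegative distance matrix (km), zero diagonal.
#' @param sd marginal standard deviation (> 0).
#' @param decay decay parameter phi (> 0, per km).
#' @return J x J covariance matrix.
#' @export
exponentialCovariance <- function(D, sd, decay) {
  if (!all(is.finite(D))) stop("D must be finite")
  if (max(abs(D - t(D))) > 1e-9) stop("D must be symmetric")
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (!is.finite(decay) || decay <= 0) stop("decay must be > 0")
  sd^2 * exp(-decay * D)
}

#' Effective range of the exponential correlation function
#'
#' The distance R at which the correlation exp(-phi * d) has decayed to
#' 0.05: R = -ln(0.05) / phi.
#'
#' @param decay phi, per km (> 0).
#' @return effective range in km.  Strictly decreasing in phi.
#' @export
effectiveRange <- function(decay) {
  if (any(!is.finite(decay) | decay <= 0)) stop("decay must be > 0")
  -log(0.05) / decay
}

#' @rdname effectiveRange
#' @param rangeKm effective range in km (> 0).
#' @return \code{decayForRange} inverts the relation: phi = -ln(0.05)/R.
#' @export
decayForRange <- function(rangeKm) {
  if (any(!is.finite(rangeKm) | rangeKm <= 0)) stop("rangeKm must be > 0")
  -log(0.05) / rangeKm
}

#' Correlation-based bounds for the decay parameter
#'
#' Returns the interval (a, b) such that for phi in (a, b) the correlation
#' between the closest pair of cities stays at or below \code{rhoHi}
#' (a = -ln(rhoHi)/d_min) and the correlation between the farthest pair
#' stays at or above \code{rhoLo} (b = -ln(rhoLo)/d_max), avoiding
#' numerically degenerate correlation matrices.  When the two requirements
#' are jointly infeasible (a >= b), the interval is clamped to the ordered
#' pair with a warning.
#'
#' @param D intercity distance matrix (km).
#' @param rhoLo,rhoHi correlation floor and ceiling, 0 < rhoLo < rhoHi < 1.
#' @return numeric c(a, b) with 0 < a < b.
#' @export
decayBounds <- function(D, rhoLo = 0.01, rhoHi = 0.99) {
  if (!(rhoLo > 0 && rhoLo < rhoHi && rhoHi < 1))
    stop("need 0 < rhoLo < rhoHi < 1")
  off <- D[upper.tri(D)]
  if (!length(off) || all(off == 0)) stop("degenerate distance matrix")
  dMin <- min(off); dMax <- max(off)
  a <- -log(rhoHi) / dMin
  b <- -log(rhoLo) / dMax
  if (a >= b) {
    warning("correlation floor/ceiling jointly infeasible for this distance ",
            "matrix; clamping decay bounds")
    lo <- min(a, b); hi <- max(a, b)
    if (lo == hi) hi <- lo * (1 + 1e-6)
    return(c(lo, hi))
  }
  c(a, b)
}

#' Effective-range-based default decay bounds
#'
#' Bounds the decay parameter so that the effective range lies between the
#' closest intercity distance and 1.25 times the largest: below d_min no
#' pair of cities is informative about the decay, and above the span of
#' the study region the field is indistinguishable from a constant.  Used
#' as the default Uniform(a, b) support for phi when none is supplied.
#'
#' @param D intercity distance matrix (km).
#' @return numeric c(a, b), per km.
#' @export
defaultDecayBounds <- function(D) {
  off <- D[upper.tri(D)]
  if (!length(off) || all(off == 0)) stop("degenerate distance matrix")
  c(decayForRange(1.25 * max(off)), decayForRange(min(off)))
}
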