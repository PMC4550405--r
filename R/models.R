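## The three model variants: joint log-posterior and risk summaries.
##
## All variants share the tract level
##   O_ij ~ Poisson(E_ij * theta_ij)
##   log(theta_ij) = b1_j + b2_j * X_ij + S_ij + H_ij
##   S_.j ~ intrinsic CAR(sigma_Sj^2),  H_ij ~ Normal(0, sigma_Hj^2)
## and differ in the prior on the city coefficient vectors (b1, b2):
##   M1: flat (independent fixed effects per city)
##   M2: b1_j ~ N(alpha, sigma_b1^2), b2_j ~ N(beta, sigma_b2^2), iid given
##       the variances (exchangeable random coefficients)
##   M3: b1 ~ MVN(alpha 1, sigma_1^2 exp(-phi_1 D)),
##       b2 ~ MVN(beta 1, sigma_2^2 exp(-phi_2 D)) (geostatistical field)
## All standard deviations carry Uniform(0, l) priors; the decays carry
## Uniform(a, b); alpha and beta are flat (improper) by default.

#' Construct a ModelSpec
#'
#' @param variant "M1", "M2" or "M3".
#' @param sdUpper upper limit l of the Uniform(0, l) priors on standard
#'   deviations; 10 on the log-relative-risk scale is vague for
#'   epidemiological relative risks.
#' @param decayBounds Uniform support (a, b) for the decay parameters (M3
#'   only).  If NULL for M3, \code{\link{runMcmc}} derives
#'   \code{\link{defaultDecayBounds}} from the distance matrix.
#' @param coefPriorSd SD of optional Normal(0, sd^2) priors on alpha and
#'   beta; Inf (default) gives the flat priors of the model definition.
#' @param includeIcar,includeHet include the tract-level spatial /
#'   heterogeneity effects (default TRUE).
#' @return a \code{\link{ModelSpec-class}}.
#' @export
modelSpec <- function(variant = c("M1", "M2", "M3"), sdUpper = 10,
                      decayBounds = NULL, coefPriorSd = Inf,
                      includeIcar = TRUE, includeHet = TRUE) {
  variant <- match.arg(variant)
  if (is.null(decayBounds))
    decayBounds <- c(NA_real_, NA_real_)
  new("ModelSpec", variant = variant, sdUpper = as.numeric(sdUpper),
      decayBounds = as.numeric(decayBounds),
      coefPriorSd = as.numeric(coefPriorSd),
      includeIcar = isTRUE(includeIcar), includeHet = isTRUE(includeHet))
}

#' Construct McmcSettings
#'
#' The \code{"desk"} preset (4 chains x 5000 iterations, burn-in 1000,
#' thin 4) is sized for interactive work; \code{"paper-protocol"} mirrors
#' the large WinBUGS-style protocol (7 chains x 100000, burn-in 10000,
#' thin 126).
#'
#' @param nChains,nIter,nBurnin,thin,seed chain layout; any value supplied
#'   explicitly overrides the preset.
#' @param preset "desk" or "paper-protocol".
#' @return an \code{\link{McmcSettings-class}}.
#' @export
mcmcSettings <- function(nChains = NULL, nIter = NULL, nBurnin = NULL,
                         thin = NULL, seed = 1L,
                         preset = c("desk", "paper-protocol")) {
  preset <- match.arg(preset)
  def <- if (preset == "desk") list(nChains = 4L, nIter = 5000L, nBurnin = 1000L, thin = 4L)
         else list(nChains = 7L, nIter = 100000L, nBurnin = 10000L, thin = 126L)
  pick <- function(x, d) if (is.null(x)) d else as.integer(x)
  new("McmcSettings", nChains = pick(nChains, def$nChains),
      nIter = pick(nIter, def$nIter), nBurnin = pick(nBurnin, def$nBurnin),
      thin = pick(thin, def$thin), seed = as.integer(seed))
}

## ---- model state -----------------------------------------------------

## A model state is a plain named list:
##   b1, b2: numeric(J); alpha, beta: numeric(1) (M2/M3)
##   S, H: numeric(N) aligned to TractData rows (optional, default 0)
##   sigmaS, sigmaH: numeric(J)
##   M2: sigmaB1, sigmaB2;  M3: sigma1, phi1, sigma2, phi2

#' Tract-level linear predictor (log relative risks)
#'
#' log(theta_ij) = b1_j + b2_j X_ij + S_ij + H_ij, aligned to the rows of
#' \code{data}.
#'
#' @param state named list with elements \code{b1}, \code{b2} (length J)
#'   and optionally \code{S}, \code{H} (length N, default zero).
#' @param data a \code{\link{TractData-class}}.
#' @return numeric vector of log relative risks, one per tract row.
#' @export
linearPredictor <- function(state, data) {
  J <- nCities(data)
  if (length(state$b1) != J || length(state$b2) != J)
    stop("b1/b2 must have length J = ", J)
  ci <- cityIndex(data)
  n <- length(ci)
  S <- if (is.null(state$S)) numeric(n) else state$S
  H <- if (is.null(state$H)) numeric(n) else state$H
  if (length(S) != n || length(H) != n)
    stop("S/H must have length ", n)
  state$b1[ci] + state$b2[ci] * covariate(data) + S + H
}

#' Poisson log-likelihood of the tract counts
#'
#' sum_ij [ O_ij (log E_ij + log theta_ij) - E_ij theta_ij - log(O_ij!) ].
#'
#' @param logTheta log relative risks aligned to the rows of \code{data}.
#' @param data a \code{\link{TractData-class}}.
#' @return total log-likelihood (includes the factorial constant, so
#'   deviances are comparable across models).
#' @export
poissonLogLikelihood <- function(logTheta, data) {
  E <- expected(data)
  if (any(E <= 0)) stop("expected counts must be > 0")
  O <- observed(data)
  if (length(logTheta) != length(O))
    stop("logTheta length mismatch")
  sum(O * (log(E) + logTheta) - E * exp(logTheta) - lgamma(O + 1))
}

## Coefficient-prior log-density for one coefficient vector.
## M2: independent normals; M3: MVN with exponential covariance (via
## Cholesky).  Returns full normalized log-densities so that M3 -> M2 in
## the diagonal limit.
coefPriorLogDensity <- function(b, mean, variant, sd = NULL,
                                sigma = NULL, phi = NULL, D = NULL) {
  J <- length(b)
  if (variant == "M1") return(0)
  if (variant == "M2") {
    return(-0.5 * sum(((b - mean) / sd)^2) - J * log(sd) - J / 2 * log(2 * pi))
  }
  Sg <- exponentialCovariance(D, sigma, phi)
  ch <- chol(Sg)
  z <- backsolve(ch, b - mean, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(ch))) - J / 2 * log(2 * pi)
}

#' Unnormalized joint log-posterior of a model state
#'
#' Likelihood plus intrinsic-CAR terms (per city, own sigma_Sj), plus
#' heterogeneity terms (per city, own sigma_Hj), plus the variant's
#' coefficient prior.  Uniform priors on standard deviations and decays
#' contribute only through their support: any state outside the prior
#' support returns \code{-Inf}.  Flat priors on the city coefficients (M1)
#' and on alpha/beta contribute nothing unless \code{spec@coefPriorSd} is
#' finite, in which case Normal(0, coefPriorSd^2) terms are added.
#'
#' @param state model state list (see Details in the package vignette).
#' @param spec a \code{\link{ModelSpec-class}}.
#' @param data a \code{\link{TractData-class}}.
#' @param adjacency a \code{\link{TractAdjacency-class}}.
#' @param D intercity distance matrix (required for M3).
#' @return unnormalized log-posterior (finite on the interior of the
#'   support for finite data; -Inf outside).
#' @export
logPosterior <- function(state, spec, data, adjacency, D = NULL) {
  J <- nCities(data)
  l <- spec@sdUpper
  inBounds <- function(x) all(is.finite(x)) && all(x > 0) && all(x < l)
  if (spec@includeIcar && !inBounds(state$sigmaS)) return(-Inf)
  if (spec@includeHet && !inBounds(state$sigmaH)) return(-Inf)
  if (spec@variant == "M2" && (!inBounds(state$sigmaB1) || !inBounds(state$sigmaB2)))
    return(-Inf)
  if (spec@variant == "M3") {
    if (is.null(D)) stop("M3 requires the intercity distance matrix D")
    ab <- spec@decayBounds
    if (!all(is.finite(ab))) stop("M3 spec has no decay bounds")
    if (!inBounds(c(state$sigma1, state$sigma2))) return(-Inf)
    if (!all(is.finite(c(state$phi1, state$phi2)))) return(-Inf)
    if (state$phi1 <= ab[1L] || state$phi1 >= ab[2L] ||
        state$phi2 <= ab[1L] || state$phi2 >= ab[2L]) return(-Inf)
  }
  if (!all(is.finite(c(state$b1, state$b2)))) return(-Inf)

  lp <- poissonLogLikelihood(linearPredictor(state, data), data)
  ci <- cityIndex(data)
  if (spec@includeIcar) {
    for (j in seq_len(J)) {
      sj <- state$S[ci == j]
      lp <- lp + icarLogDensity(sj, adjacency, state$sigmaS[j],
                                city = cityIds(data)[j])
    }
  }
  if (spec@includeHet) {
    nj <- tractsPerCity(data)
    for (j in seq_len(J)) {
      hj <- state$H[ci == j]
      lp <- lp - 0.5 * sum(hj^2) / state$sigmaH[j]^2 -
        nj[j] * log(state$sigmaH[j]) - nj[j] / 2 * log(2 * pi)
    }
  }
  lp <- lp + switch(spec@variant,
    M1 = 0,
    M2 = coefPriorLogDensity(state$b1, state$alpha, "M2", sd = state$sigmaB1) +
         coefPriorLogDensity(state$b2, state$beta, "M2", sd = state$sigmaB2),
    M3 = coefPriorLogDensity(state$b1, state$alpha, "M3", sigma = state$sigma1,
                             phi = state$phi1, D = D) +
         coefPriorLogDensity(state$b2, state$beta, "M3", sigma = state$sigma2,
                             phi = state$phi2, D = D))
  if (spec@variant != "M1" && is.finite(spec@coefPriorSd)) {
    s0 <- spec@coefPriorSd
    lp <- lp - 0.5 * (state$alpha^2 + state$beta^2) / s0^2 - 2 * log(s0) - log(2 * pi)
  }
  unname(lp)
}

## Posterior summary (mean + equal-tailed 95% CI) of exp(draws).
rrSummary <- function(draws) {
  rr <- exp(draws)
  c(mean = mean(rr), lower = unname(quantile(rr, 0.025)),
    upper = unname(quantile(rr, 0.975)))
}

#' Per-city relative risks per 1% covariate increase
#'
#' Posterior mean and equal-tailed 95% credible interval of exp(b2_j) for
#' each city, from the retained draws.
#'
#' @param draws a \code{\link{PosteriorDraws-class}} (any variant), or a
#'   numeric matrix of b2 draws (draw x city).
#' @return data.frame (city, rr, lower, upper).
#' @export
cityRR <- function(draws) {
  if (is(draws, "PosteriorDraws")) {
    J <- length(draws@cityIds)
    m <- extractDraws(draws, sprintf("b2[%d]", seq_len(J)))
    ids <- draws@cityIds
  } else {
    m <- as.matrix(draws)
    ids <- colnames(m)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
  }
  if (!nrow(m)) stop("no draws")
  out <- t(apply(m, 2L, rrSummary))
  data.frame(city = ids, rr = out[, "mean"], lower = out[, "lower"],
             upper = out[, "upper"], row.names = NULL)
}

#' Overall pooled relative risk (M2/M3)
#'
#' Posterior summary of exp(beta), the relative risk per 1% covariate
#' increase for the population of cities the study cities are drawn from.
#' Undefined for M1, whose city coefficients are independent fixed effects.
#'
#' @param draws a \code{\link{PosteriorDraws-class}} from an M2 or M3 fit,
#'   or a numeric vector of beta draws.
#' @return named numeric: mean, lower, upper (95% CI).
#' @export
pooledRR <- function(draws) {
  if (is(draws, "PosteriorDraws")) {
    if (variant(draws) == "M1")
      stop("pooled RR is undefined for M1 (no common beta)")
    b <- extractDraws(draws, "beta")[, 1L]
  } else b <- as.numeric(draws)
  if (!length(b)) stop("no draws")
  rrSummary(b)
}

#' Posterior summary of the effective range (M3)
#'
#' Mean and 95% CI in km of \code{\link{effectiveRange}}(phi2) over the
#' retained draws.
#'
#' @param draws a \code{\link{PosteriorDraws-class}} from an M3 fit.
#' @param which "slope" (phi2, default) or "intercept" (phi1).
#' @return named numeric: mean, lower, upper (km).
#' @export
effectiveRangeSummary <- function(draws, which = c("slope", "intercept")) {
  which <- match.arg(which)
  if (variant(draws) != "M3") stop("effective range requires an M3 fit")
  phi <- extractDraws(draws, if (which == "slope") "phi2" else "phi1")[, 1L]
  r <- effectiveRange(phi)
  c(mean = mean(r), lower = unname(quantile(r, 0.025)),
    upper = unname(quantile(r, 0.975)))
}
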