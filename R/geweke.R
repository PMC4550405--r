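## Joint-distribution (Geweke-style) self-consistency check of the MCMC
## transition kernel: draws of (parameters, data) obtained by repeated
## prior sampling + data simulation ("marginal-conditional") must match
## draws obtained by alternating MCMC parameter transitions with data
## re-simulation ("successive-conditional").  Any bug that perturbs the
## sampler's stationary distribution shows up as a marginal mismatch.

## One prior draw of the full M3 state on a layout, plus its linear
## predictor.  Proper priors throughout (finite coefPriorSd).
priorDraw <- function(layout, spec, bounds) {
  geo <- layout@geo
  adj <- layout@adjacency
  J <- length(cityIds(geo))
  n <- layout@nPerCity
  N <- sum(n)
  D <- distances(geo)
  l <- spec@sdUpper
  s0 <- spec@coefPriorSd
  st <- list(alpha = rnorm(1, 0, s0), beta = rnorm(1, 0, s0),
             sigma1 = runif(1, 0, l), sigma2 = runif(1, 0, l),
             phi1 = runif(1, bounds[1L], bounds[2L]),
             phi2 = runif(1, bounds[1L], bounds[2L]),
             sigmaS = runif(J, 0, l), sigmaH = runif(J, 0, l))
  ch1 <- chol(exponentialCovariance(D, st$sigma1, st$phi1))
  st$b1 <- st$alpha + drop(t(ch1) %*% rnorm(J))
  ch2 <- chol(exponentialCovariance(D, st$sigma2, st$phi2))
  st$b2 <- st$beta + drop(t(ch2) %*% rnorm(J))
  ci <- rep(seq_len(J), times = n)
  S <- H <- numeric(N)
  for (j in seq_len(J)) {
    S[ci == j] <- sampleIcar(adj, st$sigmaS[j], city = cityIds(geo)[j])
    H[ci == j] <- rnorm(n[j], 0, st$sigmaH[j])
  }
  st$S <- S; st$H <- H
  st
}

#' Geweke-style sampler correctness check
#'
#' Compares the marginal prior distribution of selected parameters with
#' the marginals of a successive-conditional chain that alternates MCMC
#' transitions (fixed, non-adapting kernel) with data re-simulation, on a
#' small M3 configuration with proper priors.  If the transition kernel
#' leaves the posterior invariant, both samples come from the same
#' distribution; two-sample Kolmogorov-Smirnov p-values are reported.
#'
#' @param J,nPerCity,regionKm layout of the test configuration.
#' @param nMC marginal-conditional (pure prior) sample size.
#' @param nOuter successive-conditional outer iterations.
#' @param sweepsPerOuter MCMC sweeps between data re-simulations.
#' @param thinOut keep every thinOut-th successive-conditional iterate for
#'   the comparison (reduces autocorrelation in the KS test).
#' @param sdUpper,coefPriorSd prior hyperparameters of the test model
#'   (kept small so that prior draws produce numerically benign counts).
#' @param seed integer seed.
#' @return data.frame (parameter, ksP, meanPrior, meanChain).
#' @export
gewekeCheck <- function(J = 3L, nPerCity = 4L, regionKm = 600, nMC = 2000L,
                        nOuter = 3000L, sweepsPerOuter = 4L, thinOut = 2L,
                        sdUpper = 0.5, coefPriorSd = 0.3, seed = 1L) {
  set.seed(seed)
  layout <- simulateLayout(J, nPerCity, regionKm, seed = seed + 1L)
  geo <- layout@geo
  D <- distances(geo)
  bounds <- defaultDecayBounds(D)
  spec <- modelSpec("M3", sdUpper = sdUpper, decayBounds = bounds,
                    coefPriorSd = coefPriorSd)
  n <- layout@nPerCity
  N <- sum(n)
  ci <- rep(seq_len(J), times = n)
  # fixed covariates: modest scale keeps prior-predictive counts bounded
  X <- runif(N, -1, 1)
  E <- runif(N, 0.5, 2)

  dataFrom <- function(O) {
    tractData(data.frame(city = rep(cityIds(geo), times = n),
                         tract = unlist(layout@adjacency@tractLabels,
                                        use.names = FALSE),
                         observed = O, expected = E, covariate = X))
  }
  track <- c("alpha", "beta", "sigma2", "phi2")

  # marginal-conditional: pure prior draws
  mc <- matrix(NA_real_, nMC, length(track), dimnames = list(NULL, track))
  for (r in seq_len(nMC)) {
    st <- priorDraw(layout, spec, bounds)
    mc[r, ] <- unlist(st[track])
  }

  # successive-conditional chain
  st <- priorDraw(layout, spec, bounds)
  eta <- st$b1[ci] + st$b2[ci] * X + st$S + st$H
  O <- rpois(N, E * exp(eta))
  si <- samplerInputs(dataFrom(O), layout@adjacency)
  scales <- list(S = rep(0.4, N), H = rep(0.4, N), b1 = rep(0.3, J),
                 b2 = rep(0.3, J), phi = rep(0.3 * diff(bounds), 2L))
  sc <- matrix(NA_real_, nOuter, length(track), dimnames = list(NULL, track))
  for (r in seq_len(nOuter)) {
    res <- .svc_sampler(as.numeric(O), E, X, si$city, J, si$adjPtr, si$adjIdx,
                        si$comp, si$nComp, D, 3L, sdUpper,
                        bounds[1L], bounds[2L], coefPriorSd,
                        TRUE, TRUE, TRUE,
                        sweepsPerOuter, 0L, sweepsPerOuter, FALSE,
                        st, scales)
    fs <- res$finalState
    st <- list(b1 = fs$b1, b2 = fs$b2, S = fs$S, H = fs$H,
               sigmaS = fs$sigmaS, sigmaH = fs$sigmaH,
               alpha = fs$alpha, beta = fs$beta,
               sigma1 = fs$sigma1, phi1 = fs$phi1,
               sigma2 = fs$sigma2, phi2 = fs$phi2)
    eta <- st$b1[ci] + st$b2[ci] * X + st$S + st$H
    O <- rpois(N, E * exp(eta))
    sc[r, ] <- unlist(st[track])
  }
  scThin <- sc[seq(thinOut, nOuter, by = thinOut), , drop = FALSE]

  out <- lapply(track, function(p) {
    ks <- suppressWarnings(ks.test(mc[, p], scThin[, p]))
    data.frame(parameter = p, ksP = ks$p.value,
               meanPrior = mean(mc[, p]), meanChain = mean(scThin[, p]))
  })
  do.call(rbind, out)
}
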