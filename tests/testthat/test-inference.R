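# MCMC driver, convergence diagnostics, DIC, model comparison.

test_that("settings bookkeeping: retained draws and validity", {
  st <- mcmcSettings(nChains = 3, nIter = 1003, nBurnin = 100, thin = 7, seed = 2)
  expect_equal((st@nIter - st@nBurnin) %/% st@thin, 129L)
  expect_error(mcmcSettings(nIter = 100, nBurnin = 100),
               "nBurnin")
  expect_error(mcmcSettings(nIter = 101, nBurnin = 100, thin = 5),
               "zero retained")
  paper <- mcmcSettings(preset = "paper-protocol")
  expect_equal(paper@nChains, 7L)
  expect_equal(paper@nIter, 100000L)
  expect_equal(paper@thin, 126L)
  fit <- smallFit()
  expect_equal(nRetained(fit$dr), 200L)
})

test_that("same seed reproduces draws exactly; different seed does not", {
  lay <- simulateLayout(J = 3, nPerCity = 4, regionKm = 500, seed = 31)
  ds <- suppressWarnings(simulateDataset(lay, defaultTruth(), seed = 32))
  st <- mcmcSettings(nChains = 2, nIter = 300, nBurnin = 100, thin = 2, seed = 9)
  d1 <- runMcmc(ds@data, ds@adjacency, modelSpec("M2"), st)
  d2 <- runMcmc(ds@data, ds@adjacency, modelSpec("M2"), st)
  expect_identical(d1@draws, d2@draws)
  st2 <- mcmcSettings(nChains = 2, nIter = 300, nBurnin = 100, thin = 2, seed = 10)
  d3 <- runMcmc(ds@data, ds@adjacency, modelSpec("M2"), st2)
  expect_false(identical(d1@draws, d3@draws))
})

test_that("M3 without coordinates and prior-only M1 are refused", {
  lay <- simulateLayout(J = 3, nPerCity = 4, regionKm = 500, seed = 31)
  ds <- suppressWarnings(simulateDataset(lay, defaultTruth(), seed = 32))
  st <- mcmcSettings(nChains = 1, nIter = 50, nBurnin = 10, thin = 1, seed = 1)
  expect_error(runMcmc(ds@data, ds@adjacency, modelSpec("M3"), st),
               "coordinates")
  expect_error(runMcmc(ds@data, ds@adjacency, modelSpec("M1"), st,
                       useLikelihood = FALSE), "proper")
})

test_that("intercept posterior matches 1-D quadrature in the conjugate-style reduction", {
  # one informative city, covariate off, random effects off: the only free
  # parameter is the intercept, with a flat prior
  set.seed(14)
  n <- 20
  df <- data.frame(city = c(rep("a", n)), tract = as.character(1:n),
                   observed = rpois(n, 1.2), expected = 1, covariate = 0)
  data <- tractData(df)
  adj <- suppressWarnings(buildAdjacency(
    data.frame(city = character(), tract_a = character(),
               tract_b = character()), data))
  spec <- modelSpec("M1", includeIcar = FALSE, includeHet = FALSE)
  dr <- runMcmc(data, adj, spec,
                mcmcSettings(nChains = 2, nIter = 11000, nBurnin = 1000,
                             thin = 2, seed = 3))
  b1 <- extractDraws(dr, "b1[1]")[, 1L]
  # grid quadrature of the exact posterior density over b1
  sumO <- sum(observed(data)); sumE <- sum(expected(data))
  grid <- seq(-2, 2, length.out = 20001)
  logpost <- sumO * grid - sumE * exp(grid)
  w <- exp(logpost - max(logpost)); w <- w / sum(w)
  exactMean <- sum(grid * w)
  mcse <- sd(b1) / sqrt(effectiveSampleSize(b1))
  expect_lt(abs(mean(b1) - exactMean), 3 * mcse + 1e-4)
})

test_that("prior-only runs recover the prior moments", {
  lay <- simulateLayout(J = 4, nPerCity = 6, regionKm = 500, seed = 41)
  ds <- simulateDataset(lay, defaultTruth(), seed = 42)
  l <- 2
  spec <- modelSpec("M2", sdUpper = l, coefPriorSd = 0.5)
  dr <- runMcmc(ds@data, ds@adjacency, spec,
                mcmcSettings(nChains = 2, nIter = 6000, nBurnin = 500,
                             thin = 2, seed = 6),
                useLikelihood = FALSE)
  sigS <- extractDraws(dr, "sigmaS[1]")[, 1L]
  # Uniform(0, l): mean l/2, sd l/sqrt(12)
  expect_equal(mean(sigS), l / 2, tolerance = 0.08)
  expect_equal(sd(sigS), l / sqrt(12), tolerance = 0.08)
  al <- extractDraws(dr, "alpha")[, 1L]
  expect_equal(mean(al), 0, tolerance = 0.06)
  expect_equal(sd(al), 0.5, tolerance = 0.06)
})

test_that("rhat: identical, separated and iid chains", {
  n <- 500
  x <- rnorm(n)
  # identical chains: plain B/W form gives sqrt((n-1)/n), just below 1
  expect_equal(rhat(cbind(x, x)), sqrt((n - 1) / n), tolerance = 1e-12)
  expect_gt(rhat(cbind(rep(0, 4), rep(5, 4))), 1.1)
  set.seed(2)
  expect_true(rhat(matrix(rnorm(4000), 1000, 4)) < 1.02)
  expect_error(rhat(matrix(1:5, ncol = 1)), "2 chains")
})

test_that("effective sample size: iid, AR(1) and constant chains", {
  set.seed(5)
  N <- 4000
  expect_equal(effectiveSampleSize(rnorm(N)), N, tolerance = 0.2)
  # AR(1) with coefficient 0.9: ESS is about N (1-rho)/(1+rho)
  rho <- 0.9
  e <- rnorm(N)
  ar <- as.numeric(stats::filter(e, rho, method = "recursive"))
  expect_equal(effectiveSampleSize(ar), N * (1 - rho) / (1 + rho),
               tolerance = 0.3)
  expect_warning(essConst <- effectiveSampleSize(rep(1, 100)), "constant")
  expect_equal(essConst, 100)
})

test_that("convergence report applies the rhat/ess rule per parameter", {
  set.seed(8)
  nm <- c("alpha", "beta")
  mk <- function(shift) {
    m <- matrix(rnorm(2000), 1000, 2)
    colnames(m) <- nm
    m[, 2] <- m[, 2] + shift
    m
  }
  good <- fakeDraws(list(mk(0), mk(0)))
  rep1 <- checkConvergence(good)
  expect_true(convergencePass(rep1))
  expect_identical(convergenceTable(rep1)$parameter, nm)

  # frozen, separated second parameter: that parameter fails, overall fail
  b1 <- mk(0); b2 <- mk(0)
  b1[, 2] <- 0; b2[, 2] <- 5
  bad <- checkConvergence(fakeDraws(list(b1, b2)))
  tab <- convergenceTable(bad)
  expect_false(convergencePass(bad))
  expect_false(tab$pass[tab$parameter == "beta"])
  expect_true(tab$pass[tab$parameter == "alpha"])
  expect_error(checkConvergence(fakeDraws(list(mk(0)))), "2 chains")
})

test_that("DIC: degenerate draws, identity, and conjugate quadrature oracle", {
  fit <- smallFit()
  d <- dic(fit$dr, fit$ds@data)
  expect_equal(d@dic, d@dbar + d@pD, tolerance = 1e-12)
  expect_error(dic(fit$dr, tinyTractData()), "fingerprint")

  # degenerate draws at a single state: pD = 0, dic = deviance there
  data <- tinyTractData()
  lt <- rep(0.1, 4)
  dev0 <- -2 * poissonLogLikelihood(lt, data)
  m <- matrix(0, 20, 1, dimnames = list(NULL, "b2[1]"))
  dg <- fakeDraws(list(m), data = data,
                  deviance = matrix(dev0, 20, 1), logThetaMean = lt,
                  cityIds = cityIds(data), nTracts = tractsPerCity(data))
  dd <- dic(dg, data)
  expect_equal(dd@pD, 0, tolerance = 1e-12)
  expect_equal(dd@dic, dev0, tolerance = 1e-12)

  # Poisson-gamma toy: draws sampled exactly from the known posterior
  O <- 3L; E <- 2
  a0 <- 2; b0 <- 1                       # Gamma(shape, rate) prior on theta
  aP <- a0 + O; bP <- b0 + E
  one <- tractData(data.frame(city = c("a", "b"), tract = "1",
                              observed = c(O, 0L), expected = c(E, 1e-9 + 1),
                              covariate = 0))
  set.seed(33)
  th <- rgamma(40000, aP, rate = bP)
  devDraws <- -2 * (dpois(O, E * th, log = TRUE) + dpois(0, 1e-9 + 1, log = TRUE))
  ltm <- c(mean(log(th)), 0)
  m2 <- matrix(0, 40000, 1, dimnames = list(NULL, "b2[1]"))
  dg2 <- fakeDraws(list(m2), data = one, deviance = cbind(devDraws),
                   logThetaMean = ltm, cityIds = cityIds(one),
                   nTracts = tractsPerCity(one))
  res <- dic(dg2, one)
  dbarExact <- stats::integrate(function(t)
    -2 * dpois(O, E * t, log = TRUE) * dgamma(t, aP, rate = bP),
    0, 20)$value - 2 * dpois(0, 1e-9 + 1, log = TRUE)
  mcse <- sd(devDraws) / sqrt(length(devDraws))
  expect_lt(abs(res@dbar - dbarExact), 4 * mcse + 1e-6)
  # plug-in at E[log theta] = digamma(aP) - log(bP), known in closed form
  ltExact <- digamma(aP) - log(bP)
  dAtExact <- -2 * (dpois(O, E * exp(ltExact), log = TRUE) +
                    dpois(0, 1e-9 + 1, log = TRUE))
  expect_equal(res@dAtMean, dAtExact, tolerance = 5e-3)
})

test_that("model comparison sorts by DIC and bands the differences", {
  tab <- compareModels(list(M1 = 36408.6, M2 = 36392.1, M3 = 36389.0))
  expect_equal(tab$model, c("M3", "M2", "M1"))
  expect_equal(tab$band, c("best", "moderate", "clear"))
  tie <- compareModels(list(x = 10, y = 10))
  expect_equal(tie$band, c("best", "negligible"))
  expect_error(compareModels(list(only = 1)), "at least 2")
})
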