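# Linear predictor, Poisson likelihood, joint log-posterior, risk summaries.

test_that("linear predictor: null model, arithmetic, loop oracle", {
  td <- tinyTractData()
  J <- nCities(td); n <- length(observed(td))
  st0 <- list(b1 = numeric(J), b2 = numeric(J))
  expect_equal(linearPredictor(st0, td), numeric(n))
  st1 <- list(b1 = numeric(J), b2 = rep(0.02, J))
  expect_equal(linearPredictor(st1, td), 0.02 * covariate(td))
  set.seed(1)
  st2 <- list(b1 = rnorm(J), b2 = rnorm(J), S = rnorm(n), H = rnorm(n))
  lt <- linearPredictor(st2, td)
  ci <- cityIndex(td); X <- covariate(td)
  for (i in seq_len(n))
    expect_equal(exp(lt[i]),
                 exp(st2$b1[ci[i]] + st2$b2[ci[i]] * X[i] + st2$S[i] + st2$H[i]))
  expect_error(linearPredictor(list(b1 = 0, b2 = 0), td), "length J")
})

test_that("Poisson log-likelihood: closed forms and dpois oracle", {
  one <- function(O, E, ...) tractData(data.frame(
    city = c("a", "b"), tract = "1", observed = c(O, 0L),
    expected = c(E, 1), covariate = 0))
  # O=0, E=1, theta=1 contributes -1 (and the second dummy tract too)
  td0 <- one(0L, 1)
  expect_equal(poissonLogLikelihood(c(0, 0), td0), -2)
  td1 <- one(3L, 2)
  expect_equal(poissonLogLikelihood(c(0, 0), td1),
               (3 * log(2) - 2 - log(6)) + (-1), tolerance = 1e-12)
  set.seed(4)
  df <- data.frame(city = rep(c("a", "b"), each = 10),
                   tract = as.character(rep(1:10, 2)),
                   observed = rpois(20, 3), expected = runif(20, 0.5, 4),
                   covariate = 0)
  td <- tractData(df)
  lt <- rnorm(20, 0, 0.4)
  oracle <- sum(dpois(observed(td), expected(td) * exp(lt), log = TRUE))
  expect_equal(poissonLogLikelihood(lt, td), oracle, tolerance = 1e-10)
})

test_that("log-posterior support: out-of-bound SDs give -Inf", {
  fx <- randomGraphFixture(6, seed = 2)
  spec <- modelSpec("M1", sdUpper = 2)
  st <- list(b1 = 0.1, b2 = 0.01, S = sampleIcar(fx$adjacency, 0.2, seed = 1),
             H = rnorm(6, 0, 0.1), sigmaS = 0.5, sigmaH = 0.5)
  base <- logPosterior(st, spec, fx$data, fx$adjacency)
  expect_true(is.finite(base))
  st$sigmaS <- 2.5                        # > sdUpper
  expect_identical(logPosterior(st, spec, fx$data, fx$adjacency), -Inf)
  st$sigmaS <- 0.5; st$sigmaH <- -0.1
  expect_identical(logPosterior(st, spec, fx$data, fx$adjacency), -Inf)
})

test_that("M2 coefficient prior flattens as its SD grows", {
  fx <- randomGraphFixture(6, seed = 3)
  big <- 1e8
  spec <- modelSpec("M2", sdUpper = 1e9)
  mk <- function(b2) list(b1 = 0.1, b2 = b2,
                          S = numeric(6), H = numeric(6),
                          sigmaS = 0.5, sigmaH = 0.5, alpha = 0, beta = 0,
                          sigmaB1 = big, sigmaB2 = big)
  lpDiff <- logPosterior(mk(0.05), spec, fx$data, fx$adjacency) -
            logPosterior(mk(-0.02), spec, fx$data, fx$adjacency)
  likDiff <- poissonLogLikelihood(linearPredictor(mk(0.05), fx$data), fx$data) -
             poissonLogLikelihood(linearPredictor(mk(-0.02), fx$data), fx$data)
  expect_equal(lpDiff, likDiff, tolerance = 1e-6)
})

test_that("M3 log-posterior matches a dense MVN + explicit-loop oracle", {
  # J = 3 cities, 2 tracts each, single edge per city
  df <- data.frame(city = rep(c("a", "b", "c"), each = 2),
                   tract = rep(c("1", "2"), 3),
                   observed = c(1L, 2L, 0L, 1L, 3L, 1L),
                   expected = c(1, 2, 1.5, 0.5, 2, 1),
                   covariate = c(5, 10, 8, 12, 20, 3))
  data <- tractData(df)
  adj <- buildAdjacency(data.frame(city = c("a", "b", "c"),
                                   tract_a = "1", tract_b = "2"), data)
  geo <- cityGeo(data.frame(city_id = c("a", "b", "c"),
                            x = c(0, 100, 250), y = c(0, 50, 10)))
  D <- distances(geo)
  spec <- modelSpec("M3", sdUpper = 5, decayBounds = c(1e-4, 0.1))
  set.seed(8)
  S <- as.vector(vapply(c("a", "b", "c"),
                        function(cc) sampleIcar(adj, 0.3, city = cc), numeric(2)))
  st <- list(b1 = c(0.1, -0.05, 0.02), b2 = c(0.01, 0.03, -0.02),
             alpha = 0.01, beta = 0.015, S = S, H = rnorm(6, 0, 0.1),
             sigmaS = rep(0.3, 3), sigmaH = rep(0.2, 3),
             sigma1 = 0.2, phi1 = 0.01, sigma2 = 0.05, phi2 = 0.005)
  mine <- logPosterior(st, spec, data, adj, D = D)

  # independent oracle: dpois + explicit ICAR/het sums + dense MVN algebra
  lt <- st$b1[cityIndex(data)] + st$b2[cityIndex(data)] * covariate(data) +
    st$S + st$H
  oracle <- sum(dpois(observed(data), expected(data) * exp(lt), log = TRUE))
  for (j in 1:3) {
    sj <- st$S[cityIndex(data) == j]
    oracle <- oracle - (sj[1] - sj[2])^2 / (2 * st$sigmaS[j]^2) -
      ((2 - 1) / 2) * log(st$sigmaS[j]^2)
    hj <- st$H[cityIndex(data) == j]
    oracle <- oracle + sum(dnorm(hj, 0, st$sigmaH[j], log = TRUE))
  }
  mvn <- function(x, mu, Sg) {
    k <- length(x)
    -0.5 * drop(t(x - mu) %*% solve(Sg) %*% (x - mu)) -
      0.5 * determinant(Sg)$modulus[1] - k / 2 * log(2 * pi)
  }
  oracle <- oracle +
    mvn(st$b1, rep(st$alpha, 3), st$sigma1^2 * exp(-st$phi1 * D)) +
    mvn(st$b2, rep(st$beta, 3), st$sigma2^2 * exp(-st$phi2 * D))
  expect_equal(mine, oracle, tolerance = 1e-8)

  # decay outside its uniform support
  st$phi2 <- 0.2
  expect_identical(logPosterior(st, spec, data, adj, D = D), -Inf)
})

test_that("M1 log-posterior factorizes over cities", {
  fx <- randomGraphFixture(5, seed = 6)
  df1 <- fx$data@tracts
  df1$city <- as.character(df1$city)
  df2 <- df1
  df2$city <- "b"
  both <- tractData(rbind(df1, df2))
  e <- adjacencyEdges(fx$adjacency)
  lab <- fx$adjacency@tractLabels[["a"]]
  edges <- rbind(data.frame(city = "a", tract_a = lab[e$from], tract_b = lab[e$to]),
                 data.frame(city = "b", tract_a = lab[e$from], tract_b = lab[e$to]))
  adj <- buildAdjacency(edges, both)
  spec <- modelSpec("M1")
  set.seed(2)
  mk <- function(b1a) list(b1 = c(b1a, 0.05), b2 = c(0.01, -0.01),
                           S = numeric(10), H = numeric(10),
                           sigmaS = c(0.3, 0.4), sigmaH = c(0.2, 0.3))
  # changing city a's block shifts the log posterior by a city-a-only term,
  # independent of city b's configuration
  d1 <- logPosterior(mk(0.3), spec, both, adj) -
        logPosterior(mk(0.0), spec, both, adj)
  mk2 <- function(b1a) { s <- mk(b1a); s$b2[2] <- 0.07; s$sigmaH[2] <- 0.9; s }
  d2 <- logPosterior(mk2(0.3), spec, both, adj) -
        logPosterior(mk2(0.0), spec, both, adj)
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("city and pooled RR summaries match the lognormal oracle", {
  # constants
  const <- fakeDraws(list(matrix(0, 50, 1, dimnames = list(NULL, "b2[1]"))))
  expect_error(cityRR(matrix(numeric(0), 0, 1)), "no draws")
  rr <- cityRR(matrix(0, 10, 1))
  expect_equal(rr$rr, 1)
  expect_equal(rr$lower, 1)
  rr2 <- cityRR(matrix(log(2), 10, 1))
  expect_equal(rr2$rr, 2)

  set.seed(11)
  draws <- rnorm(10000, 0.025, 0.005)
  out <- cityRR(matrix(draws, ncol = 1))
  expect_equal(out$rr, exp(0.025 + 0.005^2 / 2), tolerance = 3e-4)
  expect_equal(out$lower, qlnorm(0.025, 0.025, 0.005), tolerance = 5e-4)
  expect_equal(out$upper, qlnorm(0.975, 0.025, 0.005), tolerance = 5e-4)

  pooled <- pooledRR(rnorm(10000, 0.023, 0.002))
  expect_equal(unname(pooled["mean"]), exp(0.023 + 0.002^2 / 2),
               tolerance = 2e-4)
  # pooled RR is undefined for M1 fits
  m1 <- fakeDraws(list(matrix(0, 5, 1, dimnames = list(NULL, "b2[1]"))),
                  variant = "M1")
  expect_error(pooledRR(m1), "M1")
})
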