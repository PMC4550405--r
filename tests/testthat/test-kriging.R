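# Prediction grids, point-in-polygon masking, conditional-MVN kriging and
# surface summaries.

test_that("makeGrid counts, row-major order and masking", {
  g <- makeGrid(c(0, 10, 0, 10), 5, 5)
  expect_equal(nrow(g), 9L)
  expect_equal(g[1:3, 1], c(0, 5, 10))       # x varies fastest
  expect_equal(g[1:3, 2], c(0, 0, 0))
  expect_error(makeGrid(c(0, 10, 0, 10), -1, 5), "spacings")
  expect_error(makeGrid(c(10, 0, 0, 10), 1, 1), "bbox")
  far <- rbind(c(100, 100), c(101, 100), c(101, 101))
  expect_error(makeGrid(c(0, 10, 0, 10), 5, 5, mask = far), "excludes")
  unit <- rbind(c(2, 2), c(8, 2), c(8, 8), c(2, 8))
  gm <- makeGrid(c(0, 10, 0, 10), 1, 1, mask = unit)
  expect_true(all(gm[, 1] >= 2 & gm[, 1] <= 8 & gm[, 2] >= 2 & gm[, 2] <= 8))
  # all strictly interior lattice points are retained
  expect_true(all(paste(rep(3:7, 5), rep(3:7, each = 5)) %in%
                  paste(gm[, 1], gm[, 2])))
})

test_that("point-in-polygon matches the mgcv ray-casting oracle", {
  skip_if_not_installed("mgcv")
  set.seed(4)
  # non-convex polygon
  poly <- rbind(c(0, 0), c(10, 0), c(10, 10), c(5, 5), c(0, 10))
  pts <- cbind(runif(300, -2, 12), runif(300, -2, 12))
  mine <- pointInPolygon(pts, poly)
  oracle <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
  expect_equal(mine, as.logical(oracle))
})

test_that("kriging reproduces city draws exactly and reaches the prior far away", {
  s <- syntheticM3Draws(J = 5, nDraw = 4000, seed = 2)
  grid <- rbind(coords(s$geo)[2, ] + c(0, 1e-12),  # at a city
                c(1e6, 1e6))                       # far beyond the range
  kc <- krigeCoefficient(s$draws, s$geo, grid, which = "slope", seed = 3)
  b2 <- extractDraws(s$draws, "b2[2]")[, 1L]
  expect_equal(kc[, 1], b2, tolerance = 1e-12)
  beta <- extractDraws(s$draws, "beta")[, 1L]
  sig2 <- extractDraws(s$draws, "sigma2")[, 1L]
  # far point: per draw Normal(beta, sigma2^2); integrated over draws
  expect_equal(mean(kc[, 2]), mean(beta), tolerance = 0.05)
  expect_equal(var(kc[, 2]), var(beta) + mean(sig2^2), tolerance = 0.05)
  # unsupported variants
  m2 <- fakeDraws(list(matrix(0, 5, 1, dimnames = list(NULL, "beta"))),
                  variant = "M2")
  expect_error(krigeCoefficient(m2, s$geo, grid), "M3")
})

test_that("per-draw conditional moments match dense block inversion", {
  s <- syntheticM3Draws(J = 4, nDraw = 50, seed = 5)
  set.seed(6)
  grid <- cbind(runif(3, 0, 500), runif(3, 0, 500))
  res <- krigeCoefficient(s$draws, s$geo, grid, which = "slope", seed = 7,
                          joint = TRUE, returnMoments = TRUE)
  M <- extractDraws(s$draws, c(sprintf("b2[%d]", 1:4), "beta", "sigma2", "phi2"))
  allxy <- rbind(coords(s$geo), grid)
  Dall <- as.matrix(dist(allxy))
  for (t in seq_len(50)) {
    b <- M[t, 1:4]; mu <- M[t, 5]; sig <- M[t, 6]; phi <- M[t, 7]
    Sg <- sig^2 * exp(-phi * Dall)
    Scc <- Sg[1:4, 1:4]; Sgc <- Sg[5:7, 1:4]; Sgg <- Sg[5:7, 5:7]
    cm <- mu + Sgc %*% solve(Scc) %*% (b - mu)
    cv <- Sgg - Sgc %*% solve(Scc) %*% t(Sgc)
    expect_lt(max(abs(res$mean[t, ] - drop(cm))), 1e-8)
    expect_lt(max(abs(res$cov[[t]] - cv)), 1e-8)
  }
})

test_that("marginal and joint kriging agree in distribution per location", {
  s <- syntheticM3Draws(J = 4, nDraw = 40, seed = 8)
  grid <- cbind(c(100, 300), c(100, 300))
  rj <- krigeCoefficient(s$draws, s$geo, grid, seed = 1, joint = TRUE,
                         returnMoments = TRUE)
  rm <- krigeCoefficient(s$draws, s$geo, grid, seed = 1, joint = FALSE,
                         returnMoments = TRUE)
  expect_equal(rj$mean, rm$mean, tolerance = 1e-10)
  for (t in 1:40)
    expect_equal(diag(rj$cov[[t]]), rm$var[t, ], tolerance = 1e-10)
})

test_that("conditional variance grows monotonically along an outward transect", {
  s <- syntheticM3Draws(J = 4, nDraw = 30, seed = 9)
  xmax <- max(coords(s$geo)[, 1])
  ymid <- mean(coords(s$geo)[, 2])
  transect <- cbind(xmax + seq(20, 600, by = 60), ymid)
  res <- krigeCoefficient(s$draws, s$geo, transect, seed = 2, joint = FALSE,
                          returnMoments = TRUE)
  for (t in 1:30)
    expect_true(all(diff(res$var[t, ]) >= -1e-12))
  surf <- predictSurface(res$draws)
  expect_gt(surf@rrSd[nrow(transect)], surf@rrSd[1L])
})

test_that("surface summaries: constants, normal-CDF oracle, permutation invariance", {
  z <- matrix(0, 100, 3)
  s0 <- predictSurface(z, locations = cbind(1:3, 0))
  expect_equal(s0@rrMean, rep(1, 3))
  expect_equal(s0@rrSd, rep(0, 3))
  expect_equal(s0@probGt1, rep(0, 3))     # strict inequality at RR = 1

  set.seed(10)
  d <- matrix(rnorm(20000, 0.03, 0.01), ncol = 1)
  s1 <- predictSurface(d, locations = cbind(0, 0))
  expect_equal(s1@probGt1, pnorm(3), tolerance = 0.005)

  dm <- matrix(rnorm(600), 200, 3)
  attr(dm, "locations") <- cbind(1:3, 0)
  sA <- predictSurface(dm)
  sB <- predictSurface(dm[sample(200), ], locations = cbind(1:3, 0))
  expect_equal(sA@rrMean, sB@rrMean)
  expect_equal(sA@probGt1, sB@probGt1)
  expect_error(predictSurface(dm[0, , drop = FALSE]), "no draws")
})

test_that("surfaces write to CSV and GeoJSON", {
  s <- new("SurfaceSummary", locations = cbind(c(0, 1), c(0, 1)),
           rrMean = c(1, 1.02), rrSd = c(0.1, 0.2), probGt1 = c(0.5, 0.8))
  f <- withr::local_tempfile(fileext = ".csv")
  g <- withr::local_tempfile(fileext = ".geojson")
  writeSurface(s, f, geojson = g)
  back <- read.csv(f)
  expect_equal(back$rr_mean, c(1, 1.02))
  gj <- jsonlite::read_json(g)
  expect_equal(length(gj$features), 2L)
  expect_equal(gj$features[[2]]$properties$prob_gt1, 0.8)
})
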