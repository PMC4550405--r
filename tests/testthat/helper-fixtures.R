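# Shared fixture builders: everything is generated in code at test time.

# Minimal valid tract table: 2 cities x 2 tracts.
tinyTractData <- function() {
  tractData(data.frame(
    city = c("a", "a", "b", "b"), tract = c("1", "2", "1", "2"),
    observed = c(1L, 0L, 2L, 3L), expected = rep(1, 4),
    covariate = c(10, 20, 5, 15)))
}

# Path graph 1-2-3 in one city (plus a second 1-tract city so J >= 2).
pathData <- function() {
  tractData(data.frame(
    city = c("a", "a", "a", "b"), tract = c("1", "2", "3", "1"),
    observed = c(1L, 2L, 0L, 1L), expected = c(1, 2, 1.5, 1),
    covariate = c(5, 10, 15, 8)))
}

pathAdjacency <- function(data = pathData()) {
  suppressWarnings(buildAdjacency(
    data.frame(city = c("a", "a"), tract_a = c("1", "2"),
               tract_b = c("2", "3")), data))
}

# Random connected single-city graph (spanning tree + extra edges) as a
# TractData + TractAdjacency pair; used for ICAR oracle checks.
randomGraphFixture <- function(n, extra = n %/% 2, seed = 1) {
  set.seed(seed)
  df <- data.frame(city = rep("a", n), tract = as.character(seq_len(n)),
                   observed = rpois(n, 2), expected = runif(n, 0.5, 2),
                   covariate = runif(n, 0, 10))
  data <- tractData(df)
  from <- to <- integer(0)
  for (v in 2:n) {                       # random spanning tree
    u <- sample(v - 1L, 1L)
    from <- c(from, u); to <- c(to, v)
  }
  for (k in seq_len(extra)) {
    pair <- sample(n, 2L)
    from <- c(from, pair[1L]); to <- c(to, pair[2L])
  }
  keep <- from != to
  edges <- data.frame(city = "a", tract_a = as.character(from[keep]),
                      tract_b = as.character(to[keep]))
  list(data = data, adjacency = suppressWarnings(buildAdjacency(edges, data)))
}

# Dense ICAR structure matrix Q0 = diag(degree) - W for one city.
denseStructureMatrix <- function(adjacency, city = cityIds(adjacency)[1L]) {
  n <- tractsPerCity(adjacency)[[city]]
  e <- adjacencyEdges(adjacency)
  e <- e[e$city == city, , drop = FALSE]
  Q <- matrix(0, n, n)
  for (i in seq_len(nrow(e))) {
    a <- e$from[i]; b <- e$to[i]
    Q[a, b] <- Q[a, b] - 1; Q[b, a] <- Q[b, a] - 1
    Q[a, a] <- Q[a, a] + 1; Q[b, b] <- Q[b, b] + 1
  }
  Q
}

# Hand-built PosteriorDraws (for summary/diagnostic tests that do not need
# a real fit).
fakeDraws <- function(perChain, variant = "M2", data = NULL,
                      deviance = NULL, logThetaMean = NULL,
                      cityIds = "a", nTracts = 1L) {
  nm <- colnames(perChain[[1L]])
  spec <- modelSpec(variant,
                    decayBounds = if (variant == "M3") c(1e-4, 1))
  nKeep <- nrow(perChain[[1L]])
  if (is.null(deviance)) deviance <- matrix(0, nKeep, length(perChain))
  if (is.null(logThetaMean)) logThetaMean <- numeric(sum(nTracts))
  new("PosteriorDraws", draws = perChain, deviance = deviance,
      logThetaMean = logThetaMean, spec = spec,
      settings = mcmcSettings(nChains = length(perChain),
                              nIter = nKeep, nBurnin = 0L, thin = 1L),
      cityIds = cityIds,
      nTracts = stats::setNames(as.integer(nTracts), cityIds),
      dataFingerprint = if (is.null(data)) "" else svcmap:::dataFingerprint(data),
      accept = numeric())
}

# Small fitted-run cache so several tests can share one MCMC fit.
.fitCache <- new.env(parent = emptyenv())
cachedFit <- function(key, maker) {
  if (is.null(.fitCache[[key]])) .fitCache[[key]] <- maker()
  .fitCache[[key]]
}

smallFit <- function() cachedFit("m3small", function() {
  lay <- simulateLayout(J = 4, nPerCity = 9, regionKm = 600, seed = 21)
  ds <- simulateDataset(lay, defaultTruth(), seed = 22)
  dr <- runMcmc(ds@data, ds@adjacency, modelSpec("M3"),
                mcmcSettings(nChains = 2, nIter = 600, nBurnin = 200,
                             thin = 2, seed = 5),
                geo = ds@geo)
  list(ds = ds, dr = dr)
})

# Hand-built M3 posterior draws on a known geometry (no MCMC needed).
syntheticM3Draws <- function(J, nDraw, seed = 1) {
  set.seed(seed)
  xy <- cbind(runif(J, 0, 500), runif(J, 0, 500))
  geo <- cityGeo(data.frame(city_id = sprintf("c%d", 1:J),
                            x = xy[, 1], y = xy[, 2]))
  nm <- c(sprintf("b1[%d]", 1:J), sprintf("b2[%d]", 1:J),
          "alpha", "beta", "sigma1", "phi1", "sigma2", "phi2")
  m <- matrix(NA_real_, nDraw, length(nm), dimnames = list(NULL, nm))
  m[, sprintf("b1[%d]", 1:J)] <- rnorm(nDraw * J, 0, 0.2)
  m[, sprintf("b2[%d]", 1:J)] <- rnorm(nDraw * J, 0.02, 0.02)
  m[, "alpha"] <- rnorm(nDraw, 0, 0.1)
  m[, "beta"] <- rnorm(nDraw, 0.02, 0.01)
  m[, "sigma1"] <- runif(nDraw, 0.05, 0.3)
  m[, "phi1"] <- runif(nDraw, 0.002, 0.02)
  m[, "sigma2"] <- runif(nDraw, 0.01, 0.08)
  m[, "phi2"] <- runif(nDraw, 0.002, 0.02)
  dr <- fakeDraws(list(m), variant = "M3", cityIds = cityIds(geo),
                  nTracts = rep(1L, J))
  list(draws = dr, geo = geo)
}
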