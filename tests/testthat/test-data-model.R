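# Tract table ingestion, adjacency construction, distance matrices and
# indirect standardization.

test_that("tract tables load, validate and order correctly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("city,tract,observed,expected,covariate",
               "c1,1,2,1.0,10", "c1,2,0,1.0,20",
               "c2,1,1,1.0,5", "c2,2,3,1.0,15"), f)
  td <- readTractTable(f)
  expect_equal(nCities(td), 2L)
  expect_equal(unname(tractsPerCity(td)), c(2L, 2L))
  expect_equal(cityIds(td), c("c1", "c2"))
  expect_equal(observed(td), c(2, 0, 1, 3))

  # column mapping
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ciudad,seccion,O,E,X", "c1,1,2,1.0,10", "c2,1,1,2.0,5"), f2)
  td2 <- readTractTable(f2, columns = c(city = "ciudad", tract = "seccion",
                                        observed = "O", expected = "E",
                                        covariate = "X"))
  expect_equal(expected(td2), c(1, 2))
  expect_error(readTractTable(f2, columns = c(observed = "missing")),
               "missing")
})

test_that("tract table invariant violations are rejected with row context", {
  df <- data.frame(city = c("a", "a", "a"), tract = c("1", "2", "3"),
                   observed = c(1L, 1L, 1L), expected = c(1, 1, 0),
                   covariate = 0)
  expect_error(tractData(df), "row 3")
  df2 <- data.frame(city = c("a", "a"), tract = c("1", "1"),
                    observed = 0L, expected = 1, covariate = 0)
  expect_error(tractData(df2), "duplicated")
  df3 <- data.frame(city = "a", tract = "1", observed = -1L,
                    expected = 1, covariate = 0)
  expect_error(tractData(df3), "nonnegative")
})

test_that("adjacency builder symmetrises, deduplicates and flags", {
  td <- tinyTractData()
  # duplicate edge given in both orientations collapses to one
  adj <- suppressWarnings(buildAdjacency(
    data.frame(city = c("a", "a"), tract_a = c("1", "2"),
               tract_b = c("2", "1")), td))
  expect_equal(nrow(adjacencyEdges(adj)), 1L)
  expect_equal(neighborCounts(adj)$a, c(1L, 1L))

  # self loop
  expect_error(buildAdjacency(
    data.frame(city = "a", tract_a = "1", tract_b = "1"), td), "self-loop")
  # unknown tract within the city (cross-city edges are inexpressible)
  expect_error(buildAdjacency(
    data.frame(city = "a", tract_a = "1", tract_b = "99"), td),
    "not in city")
  # city with no edges: all its tracts flagged isolated
  expect_warning(
    adj2 <- buildAdjacency(data.frame(city = "a", tract_a = "1",
                                      tract_b = "2"), td),
    "isolated")
  iso <- isolatedTracts(adj2)
  expect_equal(iso$city, c("b", "b"))
  expect_equal(nrow(iso), 2L)
})

test_that("edge lists round-trip through files", {
  fx <- randomGraphFixture(8, seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  writeAdjacencyEdges(fx$adjacency, f)
  back <- suppressWarnings(readAdjacencyEdges(f, fx$data))
  expect_equal(adjacencyEdges(back), adjacencyEdges(fx$adjacency))
})

test_that("GeoBUGS num/adj lists are parsed into the same graph", {
  data <- pathData()
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("num = c(1, 2,", "1)", "adj = c(2, 1, 3, 2)"), f)
  adj <- suppressWarnings(readGeoBUGSAdjacency(f, "a", data))
  expect_equal(adjacencyEdges(adj), adjacencyEdges(pathAdjacency(data)))
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("num = c(1, 2, 1)", "adj = c(2, 1, 3)"), f2)
  expect_error(readGeoBUGSAdjacency(f2, "a", data), "inconsistent")
})

test_that("distance matrices: euclidean closed form, haversine, errors", {
  xy <- rbind(c(0, 0), c(3, 4))
  D <- distanceMatrix(xy, "euclidean_km")
  expect_equal(D[1, 2], 5)
  expect_equal(diag(D), c(0, 0))
  expect_error(distanceMatrix(rbind(c(0, 0)), "euclidean_km"), "at least 2")
  expect_error(distanceMatrix(rbind(c(1, 2), c(1, 2)), "euclidean_km"),
               "identical")
  expect_error(distanceMatrix(rbind(c(10, 10), c(10, 10)), "haversine"),
               "identical")
  # one degree of longitude at the equator is about 111.2 km
  Dh <- distanceMatrix(rbind(c(0, 0), c(1, 0)), "haversine")
  expect_equal(Dh[1, 2], 111.2, tolerance = 0.01)
})

test_that("distance matrix is equivariant under city reordering", {
  set.seed(7)
  xy <- matrix(runif(10, 0, 100), 5, 2)
  D <- distanceMatrix(xy, "euclidean_km")
  p <- sample(5)
  Dp <- distanceMatrix(xy[p, , drop = FALSE], "euclidean_km")
  expect_equal(unname(Dp), unname(D[p, p]), tolerance = 1e-12)
})

test_that("cityGeo validates and stores distances", {
  g <- cityGeo(data.frame(city_id = c("a", "b"), x = c(0, 3), y = c(0, 4)))
  expect_equal(distances(g)[1, 2], 5)
  expect_error(cityGeo(data.frame(city_id = c("a", "a"), x = 1:2, y = 1:2)),
               "duplicated")
})

test_that("indirect standardization: closed form, conservation, oracle", {
  # single stratum closed form: rate 10/1000, tract population 100 -> E = 1
  s1 <- data.frame(city = c("a", "a"), tract = c("1", "2"), age = "all",
                   deaths = c(4, 6), population = c(100, 900))
  E1 <- indirectStandardization(s1)
  expect_equal(E1$expected[1L], 1)

  # conservation: sum(E) == sum(O) with the internal pooled reference
  set.seed(3)
  s2 <- expand.grid(city = c("a", "b", "c"), tract = c("1", "2"),
                    age = c("0-40", "40-65", "65+"))
  s2$deaths <- rpois(nrow(s2), 5)
  s2$population <- runif(nrow(s2), 200, 2000)
  E2 <- indirectStandardization(s2)
  expect_equal(sum(E2$expected), sum(s2$deaths), tolerance = 1e-9)

  # brute-force two-loop oracle on a hand-chosen 2-age x 3-tract table
  s3 <- data.frame(city = "a", tract = rep(c("1", "2", "3"), each = 2),
                   age = rep(c("y", "o"), 3),
                   deaths = c(2, 7, 0, 3, 5, 1),
                   population = c(100, 50, 200, 80, 150, 60))
  E3 <- indirectStandardization(s3)
  oracle <- numeric(3)
  for (tr in 1:3) {
    for (ag in c("y", "o")) {
      num <- 0; den <- 0
      for (i in seq_len(nrow(s3))) if (s3$age[i] == ag) {
        num <- num + s3$deaths[i]; den <- den + s3$population[i]
      }
      row <- which(s3$tract == as.character(tr) & s3$age == ag)
      oracle[tr] <- oracle[tr] + num / den * s3$population[row]
    }
  }
  expect_equal(E3$expected, oracle, tolerance = 1e-12)

  # error / warning paths
  bad <- data.frame(city = "a", tract = "1", age = "x", deaths = 1,
                    population = 0)
  expect_error(indirectStandardization(bad), "zero pooled population")
  warn <- data.frame(city = "a", tract = "1", age = c("x", "y"),
                     deaths = c(0, 2), population = c(0, 100))
  expect_warning(indirectStandardization(warn), "rate set to 0")
})
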