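test_that("weighted endemism follows its definition and conserves species count", {
  g <- buildHexGrid(c(0, 0, 3, 1), 1)
  pres <- matrix(c(TRUE, FALSE,
                   TRUE, TRUE,
                   TRUE, FALSE,
                   TRUE, FALSE), 4, 2, byrow = TRUE,
                 dimnames = list(c("0", "1", "2", "3"), c("wide", "rare")))
  s <- weightedEndemism(pres, g)
  v <- surfaceValues(s)
  expect_equal(v[1], 1 / 4 + 0)          # wide occupies 4 cells -> 0.25 each
  expect_equal(v[2], 1 / 4 + 1)          # rare occupies 1 cell -> full weight
  expect_equal(sum(v, na.rm = TRUE), 2)  # = number of species

  one <- matrix(TRUE, 1, 1, dimnames = list("0", "solo"))
  expect_equal(sum(surfaceValues(weightedEndemism(one, g)), na.rm = TRUE), 1)
})

test_that("resampled richness is exact for one species and seed-reproducible", {
  g <- buildHexGrid(c(0, 0, 2, 1), 1)
  tab <- oceub:::makeOccurrenceTable(rep("only", 7), runif(7, 0.3, 0.7),
                                     runif(7, 0.3, 0.7))
  s <- richnessResampled(tab, g, resampleConfig(reps = 10, seed = 1))
  expect_true(all(surfaceValues(s)[!is.na(surfaceValues(s))] == 1))

  set.seed(30)
  tab2 <- oceub:::makeOccurrenceTable(sample(paste0("s", 1:6), 80, TRUE),
                                      runif(80, 0.1, 1.9), runif(80, 0.1, 0.9))
  a <- richnessResampled(tab2, g, resampleConfig(reps = 50, seed = 7))
  b <- richnessResampled(tab2, g, resampleConfig(reps = 50, seed = 7))
  expect_identical(surfaceValues(a), surfaceValues(b))
  # cells with zero records are no-data, never zero
  expect_true(anyNA(surfaceValues(a)))
})

test_that("duplicating every record leaves the richness estimate distribution unchanged", {
  g <- buildHexGrid(c(0, 0, 1, 1), 1)
  set.seed(31)
  sp <- sample(paste0("s", 1:5), 40, TRUE)
  tab <- oceub:::makeOccurrenceTable(sp, runif(40, 0.4, 0.6), runif(40, 0.4, 0.6))
  tabDup <- oceub:::makeOccurrenceTable(rep(sp, 2), rep(tab$lon, 2), rep(tab$lat, 2))
  reps <- 400
  a <- mean(surfaceValues(richnessResampled(tab, g, resampleConfig(reps = reps, seed = 1))),
            na.rm = TRUE)
  b <- mean(surfaceValues(richnessResampled(tabDup, g, resampleConfig(reps = reps, seed = 2))),
            na.rm = TRUE)
  # same sampling distribution -> means agree within Monte-Carlo error
  expect_lt(abs(a - b), 4 * sqrt(2 * 1.0 / reps))
})

test_that("species dispersion centroids, distances and classes are correct", {
  tab <- oceub:::makeOccurrenceTable("single", -40, -10)
  d <- speciesDispersion(tab)
  expect_equal(d$max_dist_km, 0)
  expect_equal(d$gie_class, 1L)

  # two records ~99 km apart -> max distance ~49.5 km -> class 1
  lat2 <- 99 / 111.32
  tab2 <- oceub:::makeOccurrenceTable(rep("pair", 2), c(0, 0), c(0, lat2))
  d2 <- speciesDispersion(tab2)
  expect_equal(d2$lat, lat2 / 2, tolerance = 1e-6)
  half <- geosphere::distHaversine(c(0, lat2 / 2), c(0, 0)) / 1000
  expect_equal(d2$max_dist_km, half, tolerance = 1e-6)
  expect_lt(abs(d2$max_dist_km - 49.5), 0.2)
  expect_equal(d2$gie_class, 1L)

  # records at (0,0) and (0,2): half the great-circle span ~ 111.2 km -> class 2
  tab3 <- oceub:::makeOccurrenceTable(rep("two", 2), c(0, 0), c(0, 2))
  d3 <- speciesDispersion(tab3)
  half <- geosphere::distHaversine(c(0, 0), c(0, 2)) / 2000
  expect_equal(d3$max_dist_km, half, tolerance = 1e-6)
  expect_equal(d3$gie_class, 2L)
})

test_that("range-size classification is a monotone step function with a capped tail", {
  d <- sort(runif(200, 0, 3299))
  cls <- gieClass(d)
  expect_true(all(diff(cls) >= 0))
  expect_true(all(cls %in% 1:9))
  expect_warning(big <- gieClass(5000), "class 9")
  expect_equal(big, 9L)
  expect_error(gieClass(-1), ">= 0")
})

test_that("GIE consensus peaks at planted clusters and spans [0, 1]", {
  g <- buildHexGrid(c(0, 0, 12, 6), 1)
  ctr <- cellCenters(g)
  c1 <- ctr[cellOf(g, 2, 3) + 1L, ]          # two far-apart cluster centers
  c2 <- ctr[cellOf(g, 10, 3) + 1L, ]
  mk <- function(center, n, off) data.frame(
    species = paste0("sp", off + seq_len(n)),
    lon = center[1] + runif(n, -0.2, 0.2), lat = center[2] + runif(n, -0.2, 0.2),
    max_dist_km = runif(n, 60, 150))
  set.seed(12)
  disp <- rbind(mk(c1, 5, 0), mk(c2, 5, 5))
  disp$gie_class <- gieClass(disp$max_dist_km)
  s <- gieConsensus(disp, g)
  v <- surfaceValues(s)
  expect_equal(range(v), c(0, 1))
  top <- order(v, decreasing = TRUE)[1:6]
  d1 <- sqrt((ctr[top, 1] - c1[1])^2 + (ctr[top, 2] - c1[2])^2)
  d2 <- sqrt((ctr[top, 1] - c2[1])^2 + (ctr[top, 2] - c2[2])^2)
  expect_true(any(pmin(d1, d2) < 1.5))       # maxima near both planted centers
  expect_true(any(d1 < 1.5) && any(d2 < 1.5))

  # relabeling species leaves the surface unchanged
  disp2 <- disp; disp2$species <- rev(disp$species)
  expect_equal(surfaceValues(gieConsensus(disp2, g)), v)
})

test_that("correlation screen flags redundancy and corrects degrees of freedom", {
  g <- buildHexGrid(c(0, 0, 14, 9), 1)
  set.seed(40)
  a <- newSurface(g, rnorm(nCells(g)), "a")
  nega <- newSurface(g, -surfaceValues(a), "neg")
  b <- newSurface(g, rnorm(nCells(g)), "b")
  scr <- correlationScreen(list(a = a, neg = nega, b = b))
  expect_equal(scr$r["a", "neg"], -1)
  expect_equal(unname(diag(scr$r)), rep(1, 3))
  expect_lt(abs(scr$r["a", "b"]), 0.2)          # independent white noise
  expect_gt(scr$n_eff["a", "b"], 0.6 * scr$n)   # n_eff close to n
  expect_true(any(scr$flagged$a == "a" & scr$flagged$b == "neg"))

  expect_error(correlationScreen(list(a = a)), "two surfaces")
})
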