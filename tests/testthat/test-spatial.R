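# smooth planted field used by the interpolation tests
plantedField <- function(lon, lat) sin(lon / 2) + 0.5 * cos(lat / 1.5)

test_that("kriging is exact at samples, constant for constant fields", {
  g <- buildHexGrid(c(0, 0, 6, 4), 1)
  ctr <- cellCenters(g)
  set.seed(2)
  sampleIdx <- sort(sample(nCells(g), 25))
  const <- data.frame(lon = ctr[sampleIdx, 1], lat = ctr[sampleIdx, 2], value = 3.3)
  kc <- krige(const, g, krigeConfig(nSubsets = 3))
  expect_equal(surfaceValues(kc$prediction), rep(3.3, nCells(g)))
  expect_equal(surfaceValues(kc$spread), rep(0, nCells(g)))

  smooth <- data.frame(lon = ctr[sampleIdx, 1], lat = ctr[sampleIdx, 2],
                       value = plantedField(ctr[sampleIdx, 1], ctr[sampleIdx, 2]))
  k <- krige(smooth, g, krigeConfig(nugget = 0, nSubsets = 5))
  expect_equal(surfaceValues(k$prediction)[sampleIdx], smooth$value,
               tolerance = 1e-6)

  expect_error(krige(const[1:3, ], g), "at least 5")
  coll <- data.frame(lon = 1:6, lat = 1:6, value = rnorm(6))
  expect_error(krige(coll, g), "collinear")
})

test_that("kriging beats an inverse-distance-weighting baseline on held-out points", {
  g <- buildHexGrid(c(0, 0, 8, 6), 1)
  ctr <- cellCenters(g)
  set.seed(14)
  idx <- sample(nCells(g), 45)
  train <- idx[1:30]; test <- idx[31:45]
  z <- plantedField(ctr[, 1], ctr[, 2])
  samples <- data.frame(lon = ctr[train, 1], lat = ctr[train, 2], value = z[train])
  k <- krige(samples, g, krigeConfig(nSubsets = 8))
  maeK <- mean(abs(surfaceValues(k$prediction)[test] - z[test]))
  idw <- oracleIDW(as.matrix(samples[, 1:2]), samples$value,
                   ctr[test, , drop = FALSE])
  maeI <- mean(abs(idw - z[test]))
  expect_lt(maeK, maeI)
})

test_that("kernel density integrates to n and ranks clustered above uniform", {
  g <- buildHexGrid(c(-5, -5, 5, 5), 1)
  one <- kernelDensity(data.frame(lon = 0.2, lat = 0.1), g, bandwidthKm = 250)
  v <- surfaceValues(one)
  expect_identical(which.max(v) - 1L, cellOf(g, 0.2, 0.1))
  d <- haversineKm(c(0.2, 0.1), cellCenters(g))
  ord <- order(d)
  expect_true(all(diff(v[ord][1:5]) <= 1e-9))  # radially decreasing near peak

  set.seed(3)
  unif <- data.frame(lon = runif(200, -2, 2), lat = runif(200, -2, 2))
  du <- kernelDensity(unif, g)
  expect_equal(sum(surfaceValues(du)), 200, tolerance = 0.02 * 200)

  clus <- data.frame(lon = c(rnorm(100, -1.5, 0.15), rnorm(100, 1.5, 0.15)),
                     lat = c(rnorm(100, -1.5, 0.15), rnorm(100, 1.5, 0.15)))
  dc <- kernelDensity(clus, g)
  expect_gt(max(surfaceValues(dc)), max(surfaceValues(du)))

  expect_warning(kernelDensity(data.frame(lon = c(1, 1), lat = c(1, 1)), g),
                 "bandwidth")
})

test_that("Sorensen dissimilarity matches hand arithmetic and its contract", {
  pres <- matrix(c(TRUE, TRUE, TRUE, FALSE,   # {x,y,z}
                   TRUE, TRUE, FALSE, TRUE,   # {x,y,w}
                   TRUE, TRUE, TRUE, FALSE),  # {x,y,z} again
                 3, 4, byrow = TRUE,
                 dimnames = list(c("0", "1", "2"), c("x", "y", "z", "w")))
  d <- betaSorensen(pres)
  expect_equal(d["0", "1"], 1 / 3)
  expect_equal(d["0", "2"], 0)
  disj <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2,
                 dimnames = list(c("0", "1"), c("a", "b")))
  expect_equal(betaSorensen(disj)["0", "1"], 1)
})

test_that("PhyloSor dissimilarity reduces to Sorensen on a star tree", {
  star <- setUnitBranchLengths(ape::read.tree(text = "(a,b,c,d,e,f);"))
  pres <- randomPresence(5, star$tip.label, seed = 8)
  expect_equal(betaPhylosor(pres, star), betaSorensen(pres), tolerance = 1e-12)

  tr <- unitTree(9, seed = 9)
  pres2 <- randomPresence(6, tr$tip.label, seed = 10)
  d <- betaPhylosor(pres2, tr)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # spot-check against the per-pair edge-set oracle
  spOf <- function(i) colnames(pres2)[pres2[i, ]]
  expect_equal(d["0", "3"], 1 - oraclePhyloSor(tr, spOf(1), spOf(4)))
})

test_that("NMDS recovers exact metric configurations and handles duplicates", {
  pts <- rbind(c(0, 0), c(1, 0), c(0.3, 1.2), c(0.9, 0.8))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(1:4, 1:4)
  ord <- nmdsOrdination(d, ndim = 2, nRounds = 5, seed = 1)
  expect_lt(ord$stress, 0.01)

  d5 <- rbind(cbind(d, d[, 1]), c(d[1, ], 0))   # label 5 duplicates label 1
  dimnames(d5) <- list(1:5, 1:5)
  ord5 <- nmdsOrdination(d5, ndim = 2, nRounds = 5, seed = 1)
  expect_equal(ord5$points["5", ], ord5$points["1", ])
  expect_equal(colMeans(ord5$points), c(axis1 = 0, axis2 = 0), tolerance = 1e-8)

  expect_error(nmdsOrdination(matrix(0, 5, 5), ndim = 2), "degenerate")
})

test_that("best stress over more rounds never exceeds best over fewer (same seed)", {
  set.seed(77)
  n <- 9
  x <- matrix(runif(n * 5), n)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(seq_len(n), seq_len(n))
  s5 <- nmdsOrdination(d, ndim = 2, nRounds = 5, seed = 4)$stress
  s50 <- nmdsOrdination(d, ndim = 2, nRounds = 50, seed = 4)$stress
  expect_lte(s50, s5)
})

test_that("composition surfaces krige ordination axes onto the grid", {
  g <- buildHexGrid(c(0, 0, 6, 4), 1)
  set.seed(21)
  ids <- sort(sample(nCells(g), 12) - 1L)
  pts <- matrix(rnorm(24), 12, 2,
                dimnames = list(as.character(ids), c("axis1", "axis2")))
  ord <- structure(list(points = pts, stress = 0.01, n_rounds_used = 1, seed = 1),
                   class = "oceub_ordination")
  surfs <- compositionSurfaces(ord, g, krigeConfig(nSubsets = 3))
  expect_length(surfs, 2L)
  expect_equal(length(surfaceValues(surfs[[1]])), nCells(g))

  # constant axis -> constant surface
  ptsC <- pts; ptsC[, 1] <- 2.5
  ordC <- structure(list(points = ptsC[, 1, drop = FALSE], stress = 0,
                         n_rounds_used = 1, seed = 1), class = "oceub_ordination")
  sC <- compositionSurfaces(ordC, g, krigeConfig(nSubsets = 3))
  expect_equal(surfaceValues(sC[[1]]), rep(2.5, nCells(g)))
})
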