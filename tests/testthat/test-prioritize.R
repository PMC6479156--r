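# ten cells, one private species each, star tree: every coverage fraction is
# a simple cell count, which makes Eq.-style arithmetic exact and auditable
tenCellFixture <- function() {
  g <- buildHexGrid(c(0, 0, 10, 1), 1)
  sp <- paste0("s", 1:10)
  ids <- as.character(cellOf(g, seq(0.5, 9.5, 1), rep(0.5, 10)))
  pres <- matrix(FALSE, 10, 10, dimnames = list(ids, sp))
  diag(pres) <- TRUE
  tree <- setUnitBranchLengths(
    ape::read.tree(text = paste0("(", paste(sp, collapse = ","), ");")))
  list(grid = g, presence = pres, tree = tree)
}

test_that("within-region rescaling stretches each region to [0, 1]", {
  g <- buildHexGrid(c(0, 0, 6, 1), 1)
  lab <- rep(NA_integer_, nCells(g))
  lab[1:6] <- c(1L, 1L, 1L, 2L, 2L, 2L)
  rm <- new("RegionMap", grid = g, labels = lab, k = 2L, modelParams = list())
  v <- rep(NA_real_, nCells(g)); v[1:6] <- c(2, 4, 6, 10, 20, 15)
  s <- rescaleWithinRegions(newSurface(g, v, "x"), rm)
  out <- surfaceValues(s)
  expect_equal(out[1:3], c(0, 0.5, 1))
  expect_equal(min(out[4:6]), 0); expect_equal(max(out[4:6]), 1)
  expect_true(all(is.na(out[-(1:6)])))

  vC <- v; vC[4:6] <- 7
  expect_warning(sC <- rescaleWithinRegions(newSurface(g, vC, "x"), rm),
                 "constant")
  expect_equal(surfaceValues(sC)[4:6], c(0, 0, 0))
})

test_that("weighted summation matches elementwise arithmetic", {
  g <- buildHexGrid(c(0, 0, 4, 3), 1)
  set.seed(9)
  mk <- function(nm) newSurface(g, runif(nCells(g)), nm)
  surfs <- list(richness = mk("r"), endemism = mk("e"), aoe = mk("a"), pe = mk("p"))
  gen <- newGenome(0.5, 0.5, 0.5, 0.5, 0.5)
  got <- surfaceValues(weightedSum(surfs, gen))
  raw <- 0.5 * (surfaceValues(surfs$richness) + surfaceValues(surfs$endemism) +
                  surfaceValues(surfs$aoe) + surfaceValues(surfs$pe))
  expect_equal(got, (raw - min(raw)) / (max(raw) - min(raw)))

  # weights (1,0,0,0) return the (rescaled) richness surface
  gotR <- surfaceValues(weightedSum(surfs, newGenome(1, 0, 0, 0)))
  r <- surfaceValues(surfs$richness)
  expect_equal(gotR, (r - min(r)) / (max(r) - min(r)))

  # identical surfaces pass through unchanged once they span [0, 1]
  common <- newSurface(g, rescale01(runif(nCells(g))), "c")
  same <- list(richness = common, endemism = common, aoe = common, pe = common)
  expect_equal(surfaceValues(weightedSum(same, newGenome(0.9, 0.2, 0.4, 0.7))),
               surfaceValues(common))

  expect_warning(z <- weightedSum(surfs, newGenome(0, 0, 0, 0)), "zero")
  expect_true(all(surfaceValues(z) == 0))
})

test_that("quantization respects no-data and is monotone in the threshold", {
  g <- buildHexGrid(c(0, 0, 4, 3), 1)
  set.seed(10)
  v <- runif(nCells(g)); v[1:3] <- NA
  s <- newSurface(g, v, "rel")
  expect_equal(sum(quantizeSurface(s, 0)), sum(!is.na(v)))
  expect_equal(sum(quantizeSurface(s, 1.001)), 0L)
  sizes <- vapply(seq(0, 1, 0.1), function(th) sum(quantizeSurface(s, th)), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("coverage fractions reproduce brute-force enumeration and bounds", {
  fx <- tenCellFixture()
  inputs <- fitnessInputs(fx$presence, fx$tree, fx$grid, nTotalCells = 80)
  all10 <- as.integer(rownames(fx$presence))
  full <- coverageFractions(all10, inputs)
  expect_equal(unname(full[c("r", "pl", "e", "pe")]), rep(1, 4))
  none <- coverageFractions(integer(0), inputs)
  expect_equal(unname(none), c(0, 0, 0, 0, 0))

  eight <- coverageFractions(all10[1:8], inputs)
  expect_equal(unname(eight[c("r", "pl", "e", "pe")]), rep(0.8, 4))
  expect_equal(eight[["area_fraction"]], 8 / 80)

  # monotone under cell-set inclusion
  prev <- none
  for (k in 1:10) {
    cur <- coverageFractions(all10[seq_len(k)], inputs)
    expect_true(all(cur[c("r", "pl", "e", "pe")] >=
                      prev[c("r", "pl", "e", "pe")] - 1e-12))
    prev <- cur
  }

  # 3-cell/4-species/4-tip fixture against direct enumeration
  tr <- setUnitBranchLengths(ape::read.tree(text = "((A,B),(C,D));"))
  pres <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                   FALSE, TRUE, TRUE, FALSE,
                   FALSE, FALSE, TRUE, TRUE), 3, 4, byrow = TRUE,
                 dimnames = list(c("0", "1", "2"), c("A", "B", "C", "D")))
  g3 <- buildHexGrid(c(0, 0, 3, 1), 1)
  inp <- fitnessInputs(pres, tr, g3)
  got <- coverageFractions(0L, inputs = inp)       # first cell: A and B
  expect_equal(got[["r"]], 2 / 4)
  # captured branches: A, B tips + clade (A,B); total branch length 6
  expect_equal(got[["pl"]], 3 / 6)
  weS <- c(A = 1, B = 1 / 2, C = 1 / 2, D = 1)
  expect_equal(got[["e"]], (1 + 1 / 2) / 3)
  # branch endemism weights: tips 1, 1/2, 1/2, 1 and clades (A,B), (C,D) at 1/2
  expect_equal(got[["pe"]], (1 + 1 / 2 + 1 / 2) / 4)
})

test_that("fitness composes the chain and honours the defining identity", {
  fx <- tenCellFixture()
  inputs <- fitnessInputs(fx$presence, fx$tree, fx$grid)
  lab <- rep(1L, nCells(fx$grid))
  regions <- new("RegionMap", grid = fx$grid, labels = lab, k = 1L,
                 modelParams = list())
  set.seed(11)
  mk <- function(nm) rescaleWithinRegions(
    newSurface(fx$grid, runif(nCells(fx$grid)), nm), regions)
  surfs <- list(richness = mk("r"), endemism = mk("e"), aoe = mk("a"), pe = mk("p"))

  selectAll <- evaluateFitness(newGenome(threshold = 0), surfs, inputs)
  expect_equal(selectAll$value, 0)                  # capture all, pay all
  expect_equal(selectAll$r, 1)

  res <- evaluateFitness(newGenome(0.3, 0.9, 0.1, 0.6, 0.7), surfs, inputs)
  expect_equal(res$value, (res$r + res$pl + res$e + res$pe) / 4 - res$area_fraction)
  expect_gte(res$value, -1); expect_lte(res$value, 1)
})

test_that("the GA recovers a known optimum, monotonically and reproducibly", {
  concave <- function(g) 1 - sum((as.numeric(g) - 0.3)^2)
  cfg <- gaConfig(popSize = 20, maxGenerations = 100, seed = 3)
  out <- gaOptimize(concave, cfg)
  expect_true(all(abs(as.numeric(out$genome) - 0.3) < 0.05))
  expect_true(all(diff(out$history$best) >= 0))

  out2 <- gaOptimize(concave, cfg)
  expect_identical(out$history, out2$history)
  expect_identical(as.numeric(out$genome), as.numeric(out2$genome))

  # pure elitism with no operators returns the best of the initial population
  frozen <- gaConfig(popSize = 10, maxGenerations = 20, eliteFraction = 1,
                     randomPickFraction = 0, crossoverRate = 0, mutationRate = 0,
                     stallGenerations = 5, seed = 8)
  set.seed(8)
  pop0 <- matrix(runif(50), 10, 5); pop0[1, ] <- 0.5
  best0 <- max(apply(pop0, 1, concave))
  outF <- gaOptimize(concave, frozen)
  expect_equal(outF$fitness, best0)

  expect_error(gaConfig(popSize = 1), "popSize")
})

test_that("genome bounds are enforced", {
  expect_error(newGenome(1.2), "\\[0, 1\\]")
  expect_error(newGenome(threshold = -0.1), "\\[0, 1\\]")
})
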