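test_that("newick I/O enforces structure and round-trips topology", {
  f <- tempfile(fileext = ".nwk")
  writeLines("(A,(B,C));", f)
  tr <- readNewick(f)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  inc <- oceub:::branchIncidence(setUnitBranchLengths(tr))
  clades <- apply(inc, 1, function(r) paste(sort(colnames(inc)[r]), collapse = "+"))
  expect_true("B+C" %in% clades)

  fDup <- tempfile(fileext = ".nwk")
  writeLines("(A,(B,B));", fDup)
  expect_error(readNewick(fDup), "duplicate tip labels")

  tr20 <- unitTree(20, seed = 3)
  f2 <- tempfile(fileext = ".nwk")
  writeNewick(tr20, f2)
  back <- readNewick(f2)
  expect_equal(phangorn::RF.dist(ape::unroot(tr20), ape::unroot(back)), 0)
})

test_that("unit branch lengths are forced, total length = edge count, idempotent", {
  tr <- ape::read.tree(text = "((A:0.3,B:2.1):0.7,C:5);")
  u1 <- setUnitBranchLengths(tr)
  expect_true(all(u1$edge.length == 1))
  expect_equal(sum(u1$edge.length), nrow(u1$edge))
  expect_identical(setUnitBranchLengths(u1), u1)
})

test_that("Faith PD matches the path-union oracle and is monotone", {
  expect_warning(pd0 <- faithPD("nowhere", unitTree(5, 1)), "no species")
  expect_equal(pd0, 0)
  for (seed in 1:4) {
    tr <- unitTree(10, seed)
    expect_equal(faithPD(tr$tip.label, tr), sum(tr$edge.length))
    set.seed(seed + 100)
    prev <- 0
    picked <- character(0)
    for (k in 1:6) {
      picked <- union(picked, sample(tr$tip.label, 1))
      pd <- faithPD(picked, tr)
      expect_equal(pd, oraclePD(tr, picked))
      expect_gte(pd, prev)          # adding species never decreases PD
      prev <- pd
    }
    tip <- sample(tr$tip.label, 1)
    expect_equal(faithPD(tip, tr),
                 length(ape::nodepath(tr, 11L, match(tip, tr$tip.label))) - 1)
  }
})

test_that("PhyloSor matches the edge-set oracle, is symmetric, star = Sorensen", {
  for (seed in 1:4) {
    tr <- unitTree(10, seed)
    set.seed(seed + 50)
    a <- sample(tr$tip.label, 4); b <- sample(tr$tip.label, 5)
    expect_equal(phyloSor(a, b, tr), oraclePhyloSor(tr, a, b))
    expect_equal(phyloSor(a, b, tr), phyloSor(b, a, tr))
    expect_equal(phyloSor(a, a, tr), 1)
  }
  star <- setUnitBranchLengths(
    ape::read.tree(text = "(A,B,C,D,E,F);"))
  a <- c("A", "B", "C"); b <- c("B", "C", "D", "E")
  expect_equal(phyloSor(a, b, star),
               2 * length(intersect(a, b)) / (length(a) + length(b)))
  expect_error(phyloSor(character(0), a, star), "no tree species")
})

test_that("PWE equals branch-range enumeration and conserves total length", {
  # 3-cell, 4-tip fixture
  tr <- setUnitBranchLengths(ape::read.tree(text = "((A,B),(C,D));"))
  pres <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                   FALSE, TRUE, TRUE, FALSE,
                   FALSE, FALSE, TRUE, TRUE), 3, 4, byrow = TRUE,
                 dimnames = list(c("0", "1", "2"), c("A", "B", "C", "D")))
  g <- buildHexGrid(c(0, 0, 3, 1), 1)
  s <- pweSurface(pres, tr, g)
  got <- surfaceValues(s)[as.integer(rownames(pres)) + 1L]
  expect_equal(unname(got), unname(oraclePWE(tr, pres)))
  expect_equal(sum(got), sum(tr$edge.length))

  # single cell holding all species -> total tree length
  pres1 <- matrix(TRUE, 1, 4, dimnames = list("0", c("A", "B", "C", "D")))
  expect_equal(sum(surfaceValues(pweSurface(pres1, tr, g)), na.rm = TRUE),
               sum(tr$edge.length))

  for (seed in 5:7) {
    tr <- unitTree(8, seed)
    pres <- randomPresence(5, tr$tip.label, seed)
    g <- buildHexGrid(c(0, 0, 5, 1), 1)
    got <- surfaceValues(pweSurface(pres, tr, g))
    expect_equal(unname(got[as.integer(rownames(pres)) + 1L]),
                 unname(oraclePWE(tr, pres)))
    expect_equal(sum(got, na.rm = TRUE), sum(tr$edge.length))
  }
})

test_that("MRP encoding matches hand and brute-force clade enumeration", {
  t1 <- ape::read.tree(text = "(A,(B,C));")
  m1 <- mrpEncode(list(t1))
  expect_identical(dim(mrpMatrix(m1)), c(3L, 1L))
  expect_identical(mrpMatrix(m1)[c("A", "B", "C"), 1], c(A = "0", B = "1", C = "1"))

  mDouble <- mrpEncode(list(t1, t1))       # duplicated columns kept
  expect_identical(ncol(mrpMatrix(mDouble)), 2L)
  expect_identical(mrpMatrix(mDouble)[, 1], mrpMatrix(mDouble)[, 2])

  t2 <- ape::read.tree(text = "((A,B),D);")
  m <- mrpMatrix(mrpEncode(list(t1, t2)))
  expect_identical(ncol(m), 2L)
  expect_identical(m[c("A", "B", "C", "D"), 1], c(A = "0", B = "1", C = "1", D = "?"))
  expect_identical(m[c("A", "B", "C", "D"), 2], c(A = "1", B = "1", C = "?", D = "0"))

  expect_warning(mrpEncode(list(t1, ape::read.tree(text = "(A,B);"))), "skipped")
})

test_that("supertree search is self-consistent and displays compatible sources", {
  tr <- unitTree(8, seed = 9)
  st <- buildSupertree(mrpEncode(list(tr)), nRestarts = 3, seed = 1)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), st), 0)

  t1 <- ape::read.tree(text = "((A,B),((C,D),E));")
  t2 <- ape::read.tree(text = "(((A,B),C),F);")
  st2 <- buildSupertree(mrpEncode(list(t1, t2)), nRestarts = 5, seed = 2)
  for (src in list(t1, t2)) {
    pruned <- ape::keep.tip(st2, src$tip.label)
    expect_equal(phangorn::RF.dist(ape::unroot(src), ape::unroot(pruned)), 0)
  }

  tA <- ape::read.tree(text = "(A,(B,C));")
  tB <- ape::read.tree(text = "(D,(E,F));")
  expect_error(buildSupertree(mrpEncode(list(tA, tB))), "disconnected|backbone")
})

test_that("5-taxon supertree attains the exhaustive-search parsimony optimum", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((B,C),(D,E));")
  mrp <- mrpEncode(list(t1, t2))
  st <- buildSupertree(mrp, nRestarts = 10, seed = 4)
  all5 <- phangorn::allTrees(5, tip.label = rownames(mrpMatrix(mrp)))
  scores <- vapply(all5, function(tr) oracleFitch(tr, mrpMatrix(mrp)), numeric(1))
  expect_equal(attr(st, "pscore"), min(scores))
  expect_true(all(attr(st, "pscore") <= scores))
})

test_that("independent cross-check: PD and PhyloSor agree with picante", {
  tr <- unitTree(12, seed = 21)
  pres <- randomPresence(4, tr$tip.label, seed = 22) * 1
  pd <- picante::pd(pres, tr, include.root = TRUE)
  mine <- vapply(seq_len(nrow(pres)), function(i)
    faithPD(colnames(pres)[pres[i, ] > 0], tr), numeric(1))
  expect_equal(mine, pd$PD, tolerance = 1e-10, ignore_attr = TRUE)
  ps <- as.matrix(picante::phylosor(pres, tr))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(phyloSor(colnames(pres)[pres[i, ] > 0],
                          colnames(pres)[pres[j, ] > 0], tr),
                 ps[i, j], tolerance = 1e-10)
  }
})
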