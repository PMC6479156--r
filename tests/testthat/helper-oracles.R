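# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package internals.

# Winding-number point-in-polygon (closed or open ring); edge points inside.
windingInside <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  m <- nrow(ring)
  if (x[1] == x[m] && y[1] == y[m]) { x <- x[-m]; y <- y[-m]; m <- m - 1L }
  wn <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    # edge check
    cross <- (x[j] - x[i]) * (py - y[i]) - (y[j] - y[i]) * (px - x[i])
    if (abs(cross) < 1e-12 &&
        px >= min(x[i], x[j]) - 1e-12 && px <= max(x[i], x[j]) + 1e-12 &&
        py >= min(y[i], y[j]) - 1e-12 && py <= max(y[i], y[j]) + 1e-12)
      return(TRUE)
    if (y[i] <= py) {
      if (y[j] > py && cross > 0) wn <- wn + 1
    } else {
      if (y[j] <= py && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Edge set (row indices of a postorder edge table) used by an assemblage:
# union of all tip-to-root paths, found with ape::nodepath.
oracleEdgeSet <- function(tree, species) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  tips <- match(species, tree$tip.label)
  tips <- tips[!is.na(tips)]
  edges <- matrix(numeric(0), 0, 2)
  for (tp in tips) {
    path <- ape::nodepath(tree, root, tp)
    for (i in seq_len(length(path) - 1L))
      edges <- rbind(edges, c(path[i], path[i + 1L]))
  }
  unique(edges)
}

oraclePD <- function(tree, species) {
  es <- oracleEdgeSet(tree, species)
  if (!nrow(es)) return(0)
  idx <- apply(es, 1, function(e)
    which(tree$edge[, 1] == e[1] & tree$edge[, 2] == e[2]))
  sum(tree$edge.length[idx])
}

oraclePhyloSor <- function(tree, a, b) {
  ea <- oracleEdgeSet(tree, a); eb <- oracleEdgeSet(tree, b)
  key <- function(m) paste(m[, 1], m[, 2])
  shared <- key(ea)[key(ea) %in% key(eb)]
  idx <- match(shared, key(tree$edge))
  sum(tree$edge.length[idx]) / (0.5 * (oraclePD(tree, a) + oraclePD(tree, b)))
}

# Per-cell PWE by direct branch-range enumeration over a presence matrix.
oraclePWE <- function(tree, presence) {
  nt <- length(tree$tip.label)
  cells <- rownames(presence)
  vals <- setNames(numeric(length(cells)), cells)
  for (ei in seq_len(nrow(tree$edge))) {
    child <- tree$edge[ei, 2]
    tips <- if (child <= nt) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    tips <- intersect(tips, colnames(presence))
    if (!length(tips)) next
    inCell <- rowSums(presence[, tips, drop = FALSE]) > 0
    rb <- sum(inCell)
    if (rb > 0) vals[inCell] <- vals[inCell] + tree$edge.length[ei] / rb
  }
  vals
}

# Fitch parsimony length of a character matrix ("0"/"1"/"?") on a tree,
# computed by rooting arbitrarily and counting set-intersection failures.
oracleFitch <- function(tree, mat) {
  mat <- mat[tree$tip.label, , drop = FALSE]
  nt <- length(tree$tip.label)
  total <- 0L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  for (j in seq_len(ncol(mat))) {
    states <- integer(nt + tree$Nnode)   # bitmask: 1 = "0", 2 = "1", 3 = "?"
    states[seq_len(nt)] <- c("0" = 1L, "1" = 2L, "?" = 3L)[mat[, j]]
    count <- 0L
    visit <- function(node) {
      if (node <= nt) return(states[node])
      s <- 3L
      for (ch in kids[[as.character(node)]]) {
        cs <- visit(ch)
        inter <- bitwAnd(s, cs)
        if (inter == 0L) { count <<- count + 1L; s <- bitwOr(s, cs) }
        else s <- inter
      }
      s
    }
    visit(nt + 1L)
    total <- total + count
  }
  total
}

# Inverse-distance-weighting interpolation baseline (power 2).
oracleIDW <- function(coords, values, targets, power = 2) {
  vapply(seq_len(nrow(targets)), function(i) {
    d <- geosphere::distHaversine(targets[i, ], coords) / 1000
    if (any(d < 1e-9)) return(values[which.min(d)])
    w <- 1 / d^power
    sum(w * values) / sum(w)
  }, numeric(1))
}

# Random rooted tree with unit branch lengths.
unitTree <- function(n, seed) {
  set.seed(seed)
  setUnitBranchLengths(ape::rtree(n))
}

# Small presence fixture: nCells x nSpecies random logical matrix with at
# least one TRUE per row and column.
randomPresence <- function(nCells, species, seed, p = 0.4) {
  set.seed(seed)
  repeat {
    m <- matrix(runif(nCells * length(species)) < p, nCells, length(species),
                dimnames = list(as.character(seq_len(nCells) - 1L), species))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
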