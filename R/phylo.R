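#' @importFrom ape read.tree write.tree reorder.phylo
NULL

#' Read / write newick trees
#'
#' Thin wrappers around ape's newick I/O that enforce the invariants the
#' downstream metrics rely on: a single rooted-or-unrooted tree per file and
#' unique tip labels.
#'
#' @param path newick file.
#' @return an `ape::phylo` tree.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree in ", path)
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' @rdname readNewick
#' @param tree an `ape::phylo`.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Set every branch length to one
#'
#' Branch lengths from different source phylogenies are not comparable (and
#' are often missing), so the pipeline works throughout with unit branch
#' lengths: each edge contributes equally to diversity and endemism.
#'
#' @param tree an `ape::phylo`.
#' @return the tree with all edge lengths exactly 1 (topology unchanged).
#' @export
setUnitBranchLengths <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

# Edge-by-tip descendant incidence: E x Ntip logical matrix, TRUE where the
# tip descends from (the child end of) the edge. Root-path convention: the
# edges "used" by an assemblage are exactly the edges with >= 1 descendant
# tip in it, i.e. the minimal root-inclusive spanning subtree.
branchIncidence <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  E <- nrow(tr$edge)
  nn <- nt + tr$Nnode
  sets <- matrix(FALSE, nn, nt)
  sets[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  inc <- matrix(FALSE, E, nt)
  for (i in seq_len(E)) {
    child <- tr$edge[i, 2]
    inc[i, ] <- sets[child, ]
    parent <- tr$edge[i, 1]
    sets[parent, ] <- sets[parent, ] | sets[child, ]
  }
  colnames(inc) <- tr$tip.label
  attr(inc, "edge.length") <- tr$edge.length %||% rep(1, E)
  inc
}

# Restrict an assemblage to tree tips, warning about the dropped remainder.
.matchTips <- function(species, tree, what = "assemblage") {
  hit <- intersect(species, tree$tip.label)
  miss <- length(species) - length(hit)
  if (miss > 0)
    warning(sprintf("%d %s species absent from the tree were dropped", miss, what))
  hit
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the assemblage's
#' tips to the root (root-path inclusive, so a single tip returns its depth
#' and the full tip set returns the total tree length).
#'
#' @param species character vector of species ids (the assemblage).
#' @param tree an `ape::phylo`.
#' @param incidence optional precomputed [branchIncidence()] matrix.
#' @return nonnegative numeric; 0 (with a warning) when no species overlaps
#'   the tree tips.
#' @export
faithPD <- function(species, tree, incidence = NULL) {
  inc <- incidence %||% branchIncidence(tree)
  len <- attr(inc, "edge.length")
  hit <- intersect(species, colnames(inc))
  if (!length(hit)) {
    warning("assemblage shares no species with the tree; PD = 0")
    return(0)
  }
  used <- rowSums(inc[, hit, drop = FALSE]) > 0
  sum(len[used])
}

#' PhyloSor similarity between two assemblages
#'
#' Branch length shared by the two minimal root-inclusive subtrees divided by
#' the mean of their Faith PDs. On a star tree this reduces exactly to
#' Sorensen similarity. The dissimilarity used in beta-diversity matrices is
#' `1 - phyloSor(...)`.
#'
#' @param a,b character vectors of species ids.
#' @inheritParams faithPD
#' @return similarity in `[0, 1]`.
#' @export
phyloSor <- function(a, b, tree, incidence = NULL) {
  inc <- incidence %||% branchIncidence(tree)
  len <- attr(inc, "edge.length")
  ha <- intersect(a, colnames(inc))
  hb <- intersect(b, colnames(inc))
  if (!length(ha) || !length(hb))
    stop("phyloSor undefined for an assemblage with no tree species")
  ea <- rowSums(inc[, ha, drop = FALSE]) > 0
  eb <- rowSums(inc[, hb, drop = FALSE]) > 0
  pda <- sum(len[ea]); pdb <- sum(len[eb])
  sum(len[ea & eb]) / (0.5 * (pda + pdb))
}

# Cell-by-edge incidence for a presence matrix: TRUE where >= 1 descendant
# tip of the edge is present in the cell. Shared engine of pweSurface,
# betaPhylosor and the fitness inputs.
cellEdgeIncidence <- function(presence, tree, incidence = NULL) {
  inc <- incidence %||% branchIncidence(tree)
  tips <- intersect(colnames(presence), colnames(inc))
  if (!length(tips)) stop("no presence-matrix species found among tree tips")
  dropped <- ncol(presence) - length(tips)
  if (dropped > 0)
    message(sprintf("%d species absent from the tree excluded from phylogenetic metrics",
                    dropped))
  m <- (presence[, tips, drop = FALSE] %*% t(inc[, tips, drop = FALSE])) > 0
  attr(m, "edge.length") <- attr(inc, "edge.length")
  m
}

#' Phylogenetic weighted endemism surface
#'
#' Each branch contributes its length divided by its occurrence area (the
#' number of grid cells holding at least one descendant tip) to every cell
#' where it occurs. Summed over all cells this returns exactly the total
#' branch length represented in the data: range-restricted lineages
#' concentrate their full weight in few cells.
#'
#' @param presence logical presence matrix from [assignCells()].
#' @param tree an `ape::phylo` (unit branch lengths by convention).
#' @param grid the [HexGrid-class] the presence rows refer to.
#' @return a [Surface-class]; cells without records are no-data.
#' @export
pweSurface <- function(presence, tree, grid) {
  ce <- cellEdgeIncidence(presence, tree)
  len <- attr(ce, "edge.length")
  rb <- colSums(ce)
  w <- ifelse(rb > 0, len / pmax(rb, 1), 0)
  pwe <- as.numeric(ce %*% w)
  vals <- rep(NA_real_, nCells(grid))
  vals[as.integer(rownames(presence)) + 1L] <- pwe
  newSurface(grid, vals, "phylogenetic_weighted_endemism")
}

## ---- MRP supertree -------------------------------------------------------

#' Encode source trees as an MRP character matrix
#'
#' One binary character per informative clade (internal node that is neither
#' the root nor a single tip) per source tree; taxa absent from a tree are
#' scored `"?"` in its characters. Characters constant over their scored
#' taxa are dropped.
#'
#' @param trees list of `ape::phylo` objects (trees with < 3 tips are skipped
#'   with a warning).
#' @return an [MRPMatrix-class].
#' @export
mrpEncode <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("at least one source tree is required")
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  cols <- list(); prov <- list()
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    nt <- length(tr$tip.label)
    if (nt < 3L) {
      warning(sprintf("source tree %d has < 3 tips and was skipped", ti))
      next
    }
    inc <- branchIncidence(tr)
    root <- nt + 1L
    tr2 <- stats::reorder(tr, "postorder")
    for (i in seq_len(nrow(tr2$edge))) {
      child <- tr2$edge[i, 2]
      if (child <= nt) next                       # single tip
      clade <- colnames(inc)[inc[i, ]]
      if (length(clade) <= 1L || length(clade) >= nt) next
      col <- rep("?", length(taxa)); names(col) <- taxa
      col[tr$tip.label] <- "0"
      col[clade] <- "1"
      scored <- col[col != "?"]
      if (length(unique(scored)) < 2L) next       # constant over scored taxa
      cols[[length(cols) + 1L]] <- col
      prov[[length(prov) + 1L]] <- data.frame(tree = ti, node = child)
    }
  }
  if (!length(cols)) stop("no informative clades found in the source trees")
  mat <- do.call(cbind, cols)
  colnames(mat) <- sprintf("c%03d", seq_len(ncol(mat)))
  new("MRPMatrix", matrix = mat, provenance = do.call(rbind, prov))
}

# Union-find connectivity of source-tree taxon sets: supertree assembly
# needs every pair of trees linked through shared taxa.
.checkTaxonOverlap <- function(mrp) {
  trees <- unique(mrp@provenance$tree)
  if (length(trees) < 2L) return(invisible(TRUE))
  taxaOf <- lapply(trees, function(ti) {
    cols <- which(mrp@provenance$tree == ti)
    rownames(mrp@matrix)[rowSums(mrp@matrix[, cols, drop = FALSE] != "?") > 0]
  })
  parent <- seq_along(trees)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(trees)) for (j in seq_along(trees)) {
    if (i < j && length(intersect(taxaOf[[i]], taxaOf[[j]])))
      parent[find(j)] <- find(i)
  }
  if (length(unique(vapply(seq_along(trees), find, 1L))) > 1L)
    stop("source trees fall into disconnected taxon sets; ",
         "supply a common backbone tree linking them")
  invisible(TRUE)
}

#' Build a supertree by matrix representation with parsimony
#'
#' Heuristic Fitch-parsimony search over the MRP matrix: random-addition
#' starting trees followed by NNI hill climbing, repeated `nRestarts` times;
#' the best tree found is returned with its parsimony score attached as
#' attribute `"pscore"`. Branch lengths are set to one.
#'
#' @param mrp an [MRPMatrix-class] with >= 4 taxa.
#' @param nRestarts number of random-addition restarts.
#' @param seed RNG seed for reproducible searches.
#' @return an `ape::phylo` (unrooted, as is standard for MRP supertrees).
#' @export
buildSupertree <- function(mrp, nRestarts = 5, seed = 1) {
  mat <- mrp@matrix
  if (nrow(mat) < 4L) stop("supertree search needs >= 4 taxa")
  .checkTaxonOverlap(mrp)
  dat <- phangorn::phyDat(mat, type = "USER", levels = c("0", "1"),
                          ambiguity = "?")
  set.seed(seed)
  best <- NULL; bestScore <- Inf
  for (r in seq_len(nRestarts)) {
    start <- phangorn::random.addition(dat)
    opt <- phangorn::optim.parsimony(start, dat, method = "fitch",
                                     rearrangements = "NNI", trace = 0)
    sc <- phangorn::parsimony(opt, dat, method = "fitch")
    if (sc < bestScore) { bestScore <- sc; best <- opt }
  }
  best <- setUnitBranchLengths(best)
  attr(best, "pscore") <- as.numeric(bestScore)
  best
}

#' Export an MRP matrix as a relaxed PHYLIP character file
#' @param mrp an [MRPMatrix-class].
#' @param path output file.
#' @export
writeMRP <- function(mrp, path) {
  mat <- mrp@matrix
  lines <- c(sprintf("%d %d", nrow(mat), ncol(mat)),
             sprintf("%s  %s", format(rownames(mat)),
                     apply(mat, 1, paste0, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}
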