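#' @importFrom mclust Mclust mclustBIC adjustedRandIndex
NULL

#' Classify cells into biogeographic regions
#'
#' Gaussian maximum-likelihood classification of the per-cell vector of
#' composition values, fitted unsupervised as an EM Gaussian mixture; every
#' unmasked cell is assigned its maximum-posterior component. With
#' `k = "auto"` the number of regions is chosen by BIC over `kRange`.
#' Exactly duplicated input surfaces are dropped before fitting (they carry
#' no extra information and would make covariances singular), so the
#' partition is invariant to duplication. Labels are canonicalized by
#' descending region size.
#'
#' @param surfaces list of [Surface-class] objects on one grid (species
#'   composition axes followed by phylogenetic composition axes).
#' @param k integer number of regions, or `"auto"`.
#' @param seed RNG seed (the EM fit is deterministic given the seed).
#' @param kRange candidate region counts for `k = "auto"`.
#' @param smooth optional majority-filter post-pass over hex neighbours
#'   (off by default).
#' @return a [RegionMap-class].
#' @export
classifyRegions <- function(surfaces, k = "auto", seed = 1, kRange = 2:12,
                            smooth = FALSE) {
  if (!length(surfaces)) stop("need at least one surface")
  grid <- surfaces[[1]]@grid
  X <- vapply(surfaces, surfaceValues, numeric(nCells(grid)))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(surfaces))
  ok <- rowSums(is.na(X)) == 0L
  Xo <- X[ok, , drop = FALSE]
  # drop exactly duplicated columns
  dup <- duplicated(lapply(seq_len(ncol(Xo)), function(j) round(Xo[, j], 12)))
  Xo <- Xo[, !dup, drop = FALSE]
  if (is.character(k) && k == "auto") {
    G <- kRange[kRange <= nrow(Xo)]
  } else {
    k <- as.integer(k)
    if (k > nrow(Xo)) stop("k exceeds the number of unmasked cells")
    if (k == 1L) {
      lab <- rep(NA_integer_, nCells(grid)); lab[ok] <- 1L
      return(new("RegionMap", grid = grid, labels = lab, k = 1L,
                 modelParams = list(list(mean = colMeans(Xo), cov = stats::cov(Xo)))))
    }
    G <- k
  }
  set.seed(seed)
  fit <- mclust::Mclust(Xo, G = G, verbose = FALSE)
  if (is.null(fit)) {
    warning("EM fit failed; retrying with ridge-regularized (diagonal) models")
    fit <- mclust::Mclust(Xo + matrix(stats::rnorm(length(Xo), sd = 1e-8), nrow(Xo)),
                          G = G, modelNames = c("EII", "VII", "EEI", "VVI"),
                          verbose = FALSE)
    if (is.null(fit)) stop("maximum-likelihood classification failed")
  }
  cls <- fit$classification
  # canonicalize by descending size (ties by original label)
  sizes <- table(cls)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  cls <- relabel[cls]
  lab <- rep(NA_integer_, nCells(grid))
  lab[ok] <- as.integer(cls)
  if (smooth) lab <- .majorityFilter(lab, grid)
  means <- fit$parameters$mean
  params <- lapply(seq_along(ord), function(newg) {
    oldg <- as.integer(names(sizes))[ord][newg]
    list(mean = if (is.matrix(means)) means[, oldg] else means[oldg],
         variance = tryCatch(fit$parameters$variance$sigma[, , oldg],
                             error = function(e) NULL),
         n = as.integer(sizes[as.character(oldg)]))
  })
  new("RegionMap", grid = grid, labels = lab, k = as.integer(fit$G),
      modelParams = params)
}

# One-pass hex-neighbour majority filter (optional label smoothing).
.majorityFilter <- function(labels, grid) {
  adj <- hexAdjacency(grid)
  nb <- vector("list", length(labels))
  for (i in seq_len(nrow(adj))) {
    a <- adj[i, 1] + 1L; b <- adj[i, 2] + 1L
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  out <- labels
  for (i in which(!is.na(labels))) {
    v <- labels[nb[[i]]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    tab <- table(c(v, labels[i]))
    out[i] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}

#' Region contiguity diagnostics
#'
#' Regions may legitimately be disjoint; this reports, per region, the cell
#' count, the number of connected components under hexagonal adjacency, and
#' the bounding box of the region's cell centers.
#'
#' @param map a [RegionMap-class].
#' @return data.frame with one row per non-empty region.
#' @export
regionContiguityReport <- function(map) {
  grid <- map@grid
  adj <- hexAdjacency(grid)
  lab <- map@labels
  out <- lapply(sort(unique(lab[!is.na(lab)])), function(g) {
    cells <- which(lab == g)            # 1-based indices
    comp <- seq_along(cells)
    idx <- match(seq_len(nCells(grid)), cells)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (r in seq_len(nrow(adj))) {
      a <- idx[adj[r, 1] + 1L]; b <- idx[adj[r, 2] + 1L]
      if (!is.na(a) && !is.na(b)) comp[find(a)] <- find(b)
    }
    ncomp <- length(unique(vapply(seq_along(cells), find, 1L)))
    ctr <- cellCenters(grid)[cells, , drop = FALSE]
    data.frame(region = g, n_cells = length(cells), n_components = ncomp,
               lon_min = min(ctr[, 1]), lon_max = max(ctr[, 1]),
               lat_min = min(ctr[, 2]), lat_max = max(ctr[, 2]))
  })
  do.call(rbind, out)
}
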