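#' Weighted endemism surface
#'
#' Each species gets an endemism weight equal to the inverse of its
#' distribution area, measured as the number of occupied grid cells; a
#' cell's endemicity is the sum of the weights of its species. Summed over
#' all cells the surface equals the number of species exactly, so the whole
#' weight of a range-restricted species concentrates where it lives.
#'
#' @param presence logical presence matrix from [assignCells()].
#' @param grid the [HexGrid-class] the presence rows refer to.
#' @return a [Surface-class] (no-data outside occupied cells); the per-species
#'   weights are attached as attribute `"we_species"`.
#' @export
weightedEndemism <- function(presence, grid) {
  if (!nrow(presence) || !ncol(presence)) stop("empty presence matrix")
  weS <- 1 / colSums(presence)
  cellWE <- as.numeric(presence %*% weS)
  vals <- rep(NA_real_, nCells(grid))
  vals[as.integer(rownames(presence)) + 1L] <- cellWE
  out <- newSurface(grid, vals, "weighted_endemism")
  attr(out, "we_species") <- weS
  out
}

#' Resampling configuration for richness estimation
#'
#' Defaults follow the uniform-sampling design: 50 records drawn per hexagon,
#' a 25% subsample counted, averaged over 1,000 repetitions.
#'
#' @param n_per_sample records drawn (with replacement) per cell and rep.
#' @param subsample_fraction fraction of the sample kept (without
#'   replacement); the subsample size is `floor(n_per_sample * fraction)`.
#' @param reps number of repetitions averaged.
#' @param seed RNG seed.
#' @export
resampleConfig <- function(n_per_sample = 50, subsample_fraction = 0.25,
                           reps = 1000, seed = 1) {
  stopifnot(n_per_sample >= 1, subsample_fraction > 0, subsample_fraction <= 1,
            reps >= 1)
  structure(list(n_per_sample = as.integer(n_per_sample),
                 subsample_fraction = subsample_fraction,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "resample_config")
}

#' Resampling-based species richness
#'
#' Simulates a uniform sampling effort: in every cell and repetition,
#' `n_per_sample` records are drawn with replacement from the cell's records,
#' a fixed-size subsample is taken without replacement, and the number of
#' distinct species in the subsample is counted. The cell value is the mean
#' over repetitions. Because every cell is surveyed with the same simulated
#' effort, the estimate is insensitive to how many records a cell happens to
#' have (duplicating all records leaves the estimate distribution unchanged).
#'
#' @param table an `occurrence_table`.
#' @param grid a [HexGrid-class].
#' @param cfg a [resampleConfig()].
#' @return a [Surface-class]; cells with zero records are no-data.
#' @export
richnessResampled <- function(table, grid, cfg = resampleConfig()) {
  byCell <- recordsPerCell(table, grid)
  vals <- rep(NA_real_, nCells(grid))
  m <- max(1L, floor(cfg$n_per_sample * cfg$subsample_fraction))
  set.seed(cfg$seed)
  for (cellKey in names(byCell)) {          # names are sorted cell ids
    sp <- table$species[byCell[[cellKey]]]
    uniq <- unique(sp)
    if (length(uniq) == 1L) {
      vals[as.integer(cellKey) + 1L] <- 1
      next
    }
    spi <- match(sp, uniq)
    acc <- 0L
    for (r in seq_len(cfg$reps)) {
      draw <- spi[sample.int(length(spi), cfg$n_per_sample, replace = TRUE)]
      sub <- draw[sample.int(cfg$n_per_sample, m, replace = FALSE)]
      acc <- acc + length(unique(sub))
    }
    vals[as.integer(cellKey) + 1L] <- acc / cfg$reps
  }
  newSurface(grid, vals, "richness_resampled")
}

#' Naive per-cell species count
#'
#' The direct richness estimate the resampling procedure is designed to
#' replace; kept for effort-sensitivity comparisons.
#'
#' @inheritParams richnessResampled
#' @return a [Surface-class].
#' @export
richnessNaive <- function(table, grid) {
  byCell <- recordsPerCell(table, grid)
  vals <- rep(NA_real_, nCells(grid))
  for (cellKey in names(byCell))
    vals[as.integer(cellKey) + 1L] <- length(unique(table$species[byCell[[cellKey]]]))
  newSurface(grid, vals, "richness_naive")
}

## ---- geographic interpolation of endemism --------------------------------

# Upper class edges (km) of the nine range-size groups.
GIE_CLASS_EDGES <- c(50, 200, 400, 600, 800, 1000, 1500, 2000, 3299)

#' Range-size class for the geographic interpolation of endemism
#'
#' Nine classes by the distance from a species' range centroid to its
#' farthest occurrence: up to 50 km, 51-200, 201-400, 401-600, 601-800,
#' 801-1000, 1001-1500, 1501-2000 and 2001-3299 km. Distances beyond the
#' last edge are assigned class 9 with a warning.
#'
#' @param max_dist_km nonnegative numeric vector.
#' @return integer classes in 1..9.
#' @export
gieClass <- function(max_dist_km) {
  if (any(max_dist_km < 0)) stop("max_dist_km must be >= 0")
  cls <- findInterval(max_dist_km, GIE_CLASS_EDGES, left.open = TRUE) + 1L
  if (any(cls > 9L)) {
    warning("distances beyond 3299 km assigned to class 9")
    cls[cls > 9L] <- 9L
  }
  cls
}

#' Per-species range dispersion
#'
#' Centroid (arithmetic mean of lon/lat), great-circle distance to the
#' farthest occurrence, and the resulting range-size class, per species with
#' at least one valid record.
#'
#' @param table an `occurrence_table`.
#' @return data.frame with `species`, `lon`, `lat`, `max_dist_km`, `gie_class`.
#' @export
speciesDispersion <- function(table) {
  keep <- table$valid_geo & table$valid_taxon
  tab <- table[keep, , drop = FALSE]
  if (!nrow(tab)) stop("no valid records")
  out <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$species), function(ix) {
    lon <- mean(tab$lon[ix]); lat <- mean(tab$lat[ix])
    d <- if (length(ix) == 1L) 0 else
      max(haversineKm(c(lon, lat), cbind(tab$lon[ix], tab$lat[ix])))
    data.frame(species = tab$species[ix[1]], lon = lon, lat = lat,
               max_dist_km = d)
  }))
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  out$gie_class <- gieClass(out$max_dist_km)
  out
}

#' Consensus areas-of-endemism surface (GIE)
#'
#' For every range-size class, a kernel density of the centroids of that
#' class's species is computed with an Epanechnikov kernel whose radius is
#' the class's upper edge; the class surfaces are summed with weight
#' `1 / edge` so narrow-ranged species dominate, and the result is min-max
#' rescaled to `[0, 1]`.
#'
#' @param dispersions output of [speciesDispersion()].
#' @param grid a [HexGrid-class].
#' @return a [Surface-class] in `[0, 1]`.
#' @export
gieConsensus <- function(dispersions, grid) {
  if (!nrow(dispersions)) stop("no species dispersions supplied")
  ctr <- cellCenters(grid)
  total <- rep(0, nCells(grid))
  for (k in sort(unique(dispersions$gie_class))) {
    dk <- dispersions[dispersions$gie_class == k, , drop = FALSE]
    r <- GIE_CLASS_EDGES[k]
    dens <- rep(0, nCells(grid))
    for (i in seq_len(nrow(dk))) {
      d <- haversineKm(c(dk$lon[i], dk$lat[i]), ctr)
      inside <- d < r
      if (any(inside))
        dens[inside] <- dens[inside] + 2 / (pi * r^2) * (1 - (d[inside] / r)^2)
    }
    total <- total + dens / r
  }
  newSurface(grid, rescale01(total), "areas_of_endemism")
}

## ---- redundancy screen ---------------------------------------------------

# Distance-class correlogram matrix: R[i,j] = estimated autocorrelation of
# the surface at the distance class of cells i,j (diagonal 1, clamped).
.correlogramMatrix <- function(values, dmat, breaks) {
  n <- length(values)
  cls <- matrix(findInterval(dmat, breaks, left.open = TRUE), n, n)
  v <- values - mean(values)
  s2 <- mean(v^2)
  R <- diag(n)
  for (k in sort(unique(cls[upper.tri(cls)]))) {
    sel <- which(cls == k & upper.tri(cls), arr.ind = TRUE)
    if (nrow(sel) < 2L) next
    rho <- mean(v[sel[, 1]] * v[sel[, 2]]) / s2
    rho <- max(-1, min(1, rho))
    R[cls == k & row(cls) != col(cls)] <- rho
  }
  R
}

#' Pairwise correlation screen with spatially corrected degrees of freedom
#'
#' Pearson correlations between surfaces over their jointly unmasked cells,
#' with the effective sample size reduced for spatial autocorrelation
#' (Dutilleul/Clifford-Richardson style: `n_eff = 1 + n^2 / tr(Rx Ry)` from
#' distance-class correlograms). Pairs whose `|r|` exceeds the threshold are
#' flagged as redundant for manual drop.
#'
#' @param surfaces named list of [Surface-class] objects on one grid.
#' @param threshold absolute-correlation flag level (default 0.7).
#' @param nclass number of distance classes for the correlograms.
#' @return list with matrices `r`, `n_eff`, `p`, and a data.frame `flagged`.
#' @export
correlationScreen <- function(surfaces, threshold = 0.7, nclass = 10) {
  if (length(surfaces) < 2L) stop("need at least two surfaces")
  vals <- vapply(surfaces, surfaceValues, numeric(nCells(surfaces[[1]]@grid)))
  joint <- rowSums(is.na(vals)) == 0L
  if (sum(joint) < 3L) stop("fewer than 3 jointly unmasked cells")
  vals <- vals[joint, , drop = FALSE]
  ctr <- cellCenters(surfaces[[1]]@grid)[joint, , drop = FALSE]
  dmat <- haversineMatrixKm(ctr)
  breaks <- seq(0, max(dmat), length.out = nclass + 1L)[-1L]
  n <- nrow(vals); p <- ncol(vals)
  nm <- names(surfaces) %||% paste0("s", seq_len(p))
  Rs <- lapply(seq_len(p), function(j) .correlogramMatrix(vals[, j], dmat, breaks))
  rmat <- stats::cor(vals)
  neff <- matrix(n, p, p); pmat <- matrix(NA_real_, p, p)
  dimnames(rmat) <- dimnames(neff) <- dimnames(pmat) <- list(nm, nm)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    ne <- 1 + n^2 / sum(Rs[[i]] * t(Rs[[j]]))
    ne <- max(3, min(n, ne))
    neff[i, j] <- ne
    r <- rmat[i, j]
    tstat <- r * sqrt((ne - 2) / max(1e-12, 1 - r^2))
    pmat[i, j] <- 2 * stats::pt(-abs(tstat), df = ne - 2)
  }
  flag <- which(abs(rmat) > threshold & upper.tri(rmat), arr.ind = TRUE)
  flagged <- data.frame(a = nm[flag[, 1]], b = nm[flag[, 2]],
                        r = rmat[flag], n_eff = neff[flag], p = pmat[flag])
  list(r = rmat, n_eff = neff, p = pmat, flagged = flagged,
       threshold = threshold, n = n)
}
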