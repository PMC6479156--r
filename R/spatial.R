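## Spatial statistics: ordinary kriging with bootstrap variogram refits,
## kernel density of sampling effort, beta-diversity matrices, NMDS and
## composition surfaces. Distances are great-circle km; the kriging systems
## themselves treat the study area as planar (adequate at subcontinental
## extents).

# Parametric semivariance models ("range" is the practical range).
.vgModel <- function(h, nugget, psill, range, model) {
  base <- switch(model,
    exponential = 1 - exp(-3 * h / range),
    spherical   = ifelse(h >= range, 1, 1.5 * h / range - 0.5 * (h / range)^3),
    gaussian    = 1 - exp(-3 * (h / range)^2),
    stop("unknown variogram model: ", model))
  out <- nugget + psill * base
  out[h <= 0] <- 0            # semivariance at zero lag is zero by definition
  out
}

# Empirical semivariogram + weighted-least-squares model fit.
fitVariogram <- function(coords, values, model = "exponential",
                         nlags = 12, maxdist = NULL, nugget = NULL) {
  d <- haversineMatrixKm(coords)
  ut <- upper.tri(d)
  dd <- d[ut]
  gg <- 0.5 * (outer(values, values, "-")^2)[ut]
  maxdist <- maxdist %||% (0.6 * max(dd))
  keep <- dd > 0 & dd <= maxdist
  dd <- dd[keep]; gg <- gg[keep]
  br <- seq(0, maxdist, length.out = nlags + 1L)
  bin <- findInterval(dd, br, left.open = TRUE)
  emp <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    c(h = mean(dd[bin == b]), gamma = mean(gg[bin == b]), n = sum(bin == b))
  }))
  v0 <- stats::var(values)
  obj <- function(par) {
    nug <- if (is.null(nugget)) par[3] else nugget
    g <- .vgModel(emp[, "h"], nug, par[1], par[2], model)
    sum(emp[, "n"] * (emp[, "gamma"] - g)^2 / pmax(g, 1e-10)^2)
  }
  init <- c(psill = max(v0, 1e-8), range = maxdist / 2,
            nugget = if (is.null(nugget)) 0.05 * v0 else nugget)
  fit <- stats::optim(init[if (is.null(nugget)) 1:3 else 1:2], obj,
                      method = "L-BFGS-B",
                      lower = c(1e-10, 1e-3, 0)[if (is.null(nugget)) 1:3 else 1:2],
                      upper = c(10 * max(v0, 1e-8), 10 * maxdist,
                                max(v0, 1e-8))[if (is.null(nugget)) 1:3 else 1:2])
  par <- fit$par
  list(model = model, psill = unname(par[1]), range = unname(par[2]),
       nugget = if (is.null(nugget)) unname(par[3]) else nugget,
       empirical = as.data.frame(emp))
}

# Solve the ordinary-kriging system once and predict at target coords.
.krigePredict <- function(coords, values, vg, targets) {
  n <- nrow(coords)
  G <- .vgModel(haversineMatrixKm(coords), vg$nugget, vg$psill, vg$range, vg$model)
  K <- rbind(cbind(G, 1), c(rep(1, n), 0))
  g0 <- matrix(0, n, nrow(targets))
  for (i in seq_len(n))
    g0[i, ] <- .vgModel(haversineKm(coords[i, ], targets),
                        vg$nugget, vg$psill, vg$range, vg$model)
  rhs <- rbind(g0, 1)
  W <- tryCatch(solve(K, rhs), error = function(e) {
    solve(K + diag(1e-8, n + 1L), rhs)
  })
  as.numeric(crossprod(W[seq_len(n), , drop = FALSE], values))
}

#' Kriging configuration
#'
#' @param model variogram model: `"exponential"`, `"spherical"` or
#'   `"gaussian"`.
#' @param nlags distance classes for the empirical semivariogram.
#' @param nugget fixed nugget, or `NULL` to estimate it (`nugget = 0` makes
#'   the interpolator exact at sample locations).
#' @param nSubsets bootstrap variogram refits used to propagate variogram
#'   uncertainty (the empirical-Bayesian idea: parameters are re-estimated on
#'   random subsets and predictions averaged).
#' @param subsetFraction fraction of samples per refit.
#' @param seed RNG seed for the subsets.
#' @export
krigeConfig <- function(model = "exponential", nlags = 12, nugget = NULL,
                        nSubsets = 20, subsetFraction = 0.8, seed = 1) {
  structure(list(model = model, nlags = nlags, nugget = nugget,
                 nSubsets = as.integer(nSubsets),
                 subsetFraction = subsetFraction, seed = as.integer(seed)),
            class = "krige_config")
}

#' Ordinary kriging onto the grid with bootstrap variogram uncertainty
#'
#' Fits an empirical semivariogram by weighted least squares, then
#' re-estimates the variogram on `nSubsets` random subsets of the samples
#' and kriges the full data under each refit; the returned prediction is the
#' mean across refits and the spread their standard deviation, so variogram
#' parameter uncertainty propagates into the surface.
#'
#' @param samples data.frame with `lon`, `lat`, `value` (a [Surface-class]
#'   is also accepted; its unmasked cells become the samples).
#' @param grid target [HexGrid-class].
#' @param cfg a [krigeConfig()].
#' @param name label for the output surface.
#' @return list with `prediction` and `spread` ([Surface-class]) and the
#'   full-data `variogram` fit.
#' @export
krige <- function(samples, grid, cfg = krigeConfig(), name = "kriged") {
  if (is(samples, "Surface")) {
    ok <- !is.na(surfaceValues(samples))
    name <- surfaceName(samples)
    samples <- data.frame(lon = cellCenters(samples@grid)[ok, 1],
                          lat = cellCenters(samples@grid)[ok, 2],
                          value = surfaceValues(samples)[ok])
  }
  coords <- as.matrix(samples[, c("lon", "lat")])
  z <- samples$value
  n <- nrow(coords)
  if (n < 5L) stop("kriging needs at least 5 sample points")
  if (qr(cbind(1, coords))$rank < 3L) stop("sample locations are collinear")
  dup <- duplicated(round(coords, 9))
  if (any(dup)) {
    message(sprintf("%d duplicate sample locations jittered", sum(dup)))
    coords[dup, ] <- coords[dup, ] + stats::runif(2 * sum(dup), -1e-6, 1e-6)
  }
  targets <- cellCenters(grid)
  if (stats::var(z) < 1e-14) {      # constant field: kriging weights are moot
    pred <- newSurface(grid, rep(z[1], nCells(grid)), name)
    return(list(prediction = pred,
                spread = newSurface(grid, rep(0, nCells(grid)),
                                    paste0(name, "_spread")),
                variogram = NULL))
  }
  vg <- fitVariogram(coords, z, model = cfg$model, nlags = cfg$nlags,
                     nugget = cfg$nugget)
  set.seed(cfg$seed)
  m <- max(5L, floor(cfg$subsetFraction * n))
  preds <- matrix(NA_real_, nCells(grid), cfg$nSubsets)
  for (b in seq_len(cfg$nSubsets)) {
    sub <- sample.int(n, m)
    vgb <- tryCatch(
      fitVariogram(coords[sub, , drop = FALSE], z[sub], model = cfg$model,
                   nlags = cfg$nlags, nugget = cfg$nugget),
      error = function(e) vg)
    preds[, b] <- .krigePredict(coords, z, vgb, targets)
  }
  list(prediction = newSurface(grid, rowMeans(preds), name),
       spread = newSurface(grid, apply(preds, 1, stats::sd),
                           paste0(name, "_spread")),
       variogram = vg)
}

## ---- sampling effort -----------------------------------------------------

#' Kernel density of occurrence records (sampling effort)
#'
#' Quartic (biweight) kernel density evaluated at cell centers and reported
#' as the expected record count per cell, so the surface sums to about the
#' number of records when the grid covers the point cloud. The default
#' bandwidth is the spatial variant of Silverman's rule of thumb:
#' `0.9 * min(SD, sqrt(1/ln 2) * Dm) * n^(-0.2)`, with `SD` the standard
#' distance of the points from their mean center and `Dm` the median
#' distance to it.
#'
#' @param points data.frame or matrix with lon/lat columns.
#' @param grid a [HexGrid-class].
#' @param bandwidthKm optional fixed bandwidth; when all points coincide the
#'   fallback is one cell width (with a warning).
#' @return a [Surface-class]; the bandwidth (km) is attached as attribute
#'   `"bandwidth_km"`.
#' @export
kernelDensity <- function(points, grid, bandwidthKm = NULL) {
  pts <- as.matrix(points[, 1:2])
  n <- nrow(pts)
  if (!n) stop("at least one point is required")
  if (is.null(bandwidthKm)) {
    ctr <- colMeans(pts)
    d <- haversineKm(ctr, pts)
    sdist <- sqrt(mean(d^2))
    dm <- stats::median(d)
    bandwidthKm <- 0.9 * min(sdist, sqrt(1 / log(2)) * dm) * n^(-0.2)
  }
  if (!is.finite(bandwidthKm) || bandwidthKm <= 0) {
    warning("zero bandwidth (coincident points); falling back to one cell width")
    bandwidthKm <- cellSize(grid) * KM_PER_DEG
  }
  h <- bandwidthKm
  centers <- cellCenters(grid)
  dens <- rep(0, nCells(grid))
  for (i in seq_len(n)) {
    d <- haversineKm(pts[i, ], centers)
    w <- d < h
    if (any(w)) dens[w] <- dens[w] + 3 / (pi * h^2) * (1 - (d[w] / h)^2)^2
  }
  out <- newSurface(grid, dens * cellAreaKm2(grid), "sampling_effort")
  attr(out, "bandwidth_km") <- h
  out
}

## ---- beta diversity ------------------------------------------------------

.assertDissim <- function(m) {
  stopifnot(isTRUE(all.equal(m, t(m), tolerance = 1e-10)),
            all(abs(diag(m)) < 1e-10),
            all(m >= -1e-10 & m <= 1 + 1e-10))
  m[m < 0] <- 0; m[m > 1] <- 1
  diag(m) <- 0
  m
}

#' Sorensen beta-diversity matrix between cells
#'
#' Pairwise `1 - 2a / (2a + b + c)` over the presence matrix rows; cells
#' with zero species are excluded (with a message).
#'
#' @param presence logical presence matrix from [assignCells()].
#' @return symmetric dissimilarity matrix in `[0, 1]` labeled by cell id.
#' @export
betaSorensen <- function(presence) {
  keep <- rowSums(presence) > 0
  if (any(!keep)) message(sprintf("%d empty cells excluded from beta diversity",
                                  sum(!keep)))
  x <- presence[keep, , drop = FALSE] * 1
  if (nrow(x) < 2L) stop("need at least two non-empty cells")
  d <- as.matrix(vegan::vegdist(x, method = "bray", binary = TRUE))
  dimnames(d) <- list(rownames(x), rownames(x))
  .assertDissim(d)
}

#' PhyloSor beta-diversity matrix between cells
#'
#' Pairwise `1 - PhyloSor` similarity computed from the shared branch length
#' of the cells' minimal root-inclusive subtrees; on a star tree this equals
#' [betaSorensen()] exactly.
#'
#' @inheritParams betaSorensen
#' @param tree an `ape::phylo`.
#' @return symmetric dissimilarity matrix in `[0, 1]` labeled by cell id.
#' @export
betaPhylosor <- function(presence, tree) {
  ce <- cellEdgeIncidence(presence, tree)
  len <- attr(ce, "edge.length")
  keep <- rowSums(ce) > 0
  if (any(!keep)) message(sprintf("%d cells without tree species excluded", sum(!keep)))
  ce <- ce[keep, , drop = FALSE]
  if (nrow(ce) < 2L) stop("need at least two cells with tree species")
  x <- ce * 1
  shared <- (x * rep(len, each = nrow(x))) %*% t(x)
  pd <- as.numeric(x %*% len)
  sim <- shared / (0.5 * outer(pd, pd, "+"))
  .assertDissim(1 - sim)
}

## ---- ordination ----------------------------------------------------------

#' Non-metric multidimensional scaling with random restarts
#'
#' Kruskal stress-1 minimization (isotonic regression inside iterative
#' majorization) from `nRounds` starting configurations: the first start is
#' the metric (principal-coordinates) solution, the rest are random; the
#' lowest-stress solution is returned with centered coordinates. Labels at
#' zero dissimilarity are collapsed before fitting and share coordinates in
#' the result.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param ndim number of ordination axes.
#' @param nRounds number of starts.
#' @param seed RNG seed.
#' @return list of class `oceub_ordination`: `points` (labels x ndim),
#'   `stress` (fraction, best across rounds), `n_rounds_used`, `seed`.
#' @export
nmdsOrdination <- function(d, ndim = 3, nRounds = 100, seed = 1) {
  m <- as.matrix(d)
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (all(m < 1e-12)) stop("degenerate input: all dissimilarities are zero")
  if (nrow(m) < ndim + 2L) stop("need at least ndim + 2 labels")
  # collapse zero-dissimilarity duplicates
  groups <- rep(NA_integer_, nrow(m))
  gid <- 0L
  for (i in seq_len(nrow(m))) {
    if (!is.na(groups[i])) next
    gid <- gid + 1L
    groups[i] <- gid
    dup <- which(is.na(groups) & m[i, ] < 1e-12)
    groups[dup] <- gid
  }
  reps <- match(seq_len(gid), groups)
  mr <- m[reps, reps, drop = FALSE]
  if (nrow(mr) < ndim + 2L)
    stop("too few distinct configurations for ", ndim, " dimensions")
  dr <- stats::as.dist(mr)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRounds)) {
    init <- if (r == 1L) {
      y <- suppressWarnings(stats::cmdscale(dr, k = ndim))
      if (ncol(y) < ndim) y <- cbind(y, matrix(stats::rnorm(nrow(mr) * (ndim - ncol(y)),
                                                            sd = 1e-4), nrow(mr)))
      y
    } else {
      matrix(stats::runif(nrow(mr) * ndim, -1, 1) * max(mr), nrow(mr))
    }
    fit <- tryCatch(MASS::isoMDS(dr, y = init, k = ndim, maxit = 100, trace = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("all NMDS rounds failed")
  pts <- best$points[groups, , drop = FALSE]
  pts <- sweep(pts, 2, colMeans(pts))
  rownames(pts) <- labels
  colnames(pts) <- paste0("axis", seq_len(ndim))
  structure(list(points = pts, stress = best$stress / 100,
                 n_rounds_used = nRounds, seed = seed),
            class = "oceub_ordination")
}

#' @export
print.oceub_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d labels x %d axes, stress %.4f (best of %d rounds)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_rounds_used))
  invisible(x)
}

#' Continuous composition surfaces from an ordination
#'
#' Kriges each NMDS axis from the sampled cells (ordination labels, taken as
#' cell ids) to every grid cell, yielding the continuous species- or
#' phylogenetic-composition surfaces used for regionalization.
#'
#' @param ordination an `oceub_ordination` whose labels are cell ids.
#' @param grid a [HexGrid-class].
#' @param cfg a [krigeConfig()].
#' @param prefix name prefix for the output surfaces.
#' @return list of [Surface-class], one per axis.
#' @export
compositionSurfaces <- function(ordination, grid, cfg = krigeConfig(),
                                prefix = "composition") {
  ids <- as.integer(rownames(ordination$points))
  ctr <- cellCenters(grid)[ids + 1L, , drop = FALSE]
  lapply(seq_len(ncol(ordination$points)), function(j) {
    samples <- data.frame(lon = ctr[, 1], lat = ctr[, 2],
                          value = ordination$points[, j])
    krige(samples, grid, cfg, name = paste0(prefix, "_axis", j))$prediction
  })
}
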