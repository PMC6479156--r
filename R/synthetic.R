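## Synthetic landscape generator: planted biogeographic regions, a compact
## endemism hotspot, regionally clustered phylogenetic structure and a
## spatially biased sampling-effort field. Every stage of the pipeline, and
## the pipeline end to end, is testable against this planted truth without
## any external data. All generators are pure functions of (cfg, seed).

#' Configuration of the synthetic landscape
#'
#' Defaults describe the study conditions the package is validated under: a
#' subcontinental 18 x 10 degree extent gridded at 1 degree, three
#' vertical-band regions with fully distinct species pools (each species'
#' disc range is clipped to its region, so each region holds a unique
#' biota), 50 species per region of which a 0.3 fraction are narrow-ranged
#' endemics co-centered in a single compact hotspot while the rest are
#' widespread across most of their region (keeping each region internally
#' homogeneous in composition), and a smooth south-to-north
#' sampling-accessibility gradient orthogonal to the east-west regional
#' structure.
#'
#' @param nRegions number of vertical-band regions.
#' @param nSpeciesPerRegion species per regional pool.
#' @param hotspotFraction fraction of all species that are narrow-ranged
#'   hotspot endemics (placed in region 1's pool).
#' @param extent geographic bounding box `c(xmin, ymin, xmax, ymax)`.
#' @param cellSizeDeg hexagon width in degrees.
#' @param narrowRadiusDeg range-disc radius bounds for hotspot endemics
#'   (degrees; the defaults put them in the two smallest range-size classes).
#' @param wideRadiusDeg radius bounds for ordinary species.
#' @param groupAssignment `"random"` (taxon groups spatially congruent) or
#'   `"by_region"` (each group confined to one region, spatially discordant).
#' @param seed RNG seed.
#' @export
landscapeConfig <- function(nRegions = 3, nSpeciesPerRegion = 50,
                            hotspotFraction = 0.3,
                            extent = c(-58, -20, -40, -10), cellSizeDeg = 1,
                            narrowRadiusDeg = c(0.3, 0.9),
                            wideRadiusDeg = c(4, 8),
                            groupAssignment = c("random", "by_region"),
                            seed = 1) {
  if (hotspotFraction < 0 || hotspotFraction > 1)
    stop("hotspotFraction must lie in [0, 1]")
  structure(list(nRegions = as.integer(nRegions),
                 nSpeciesPerRegion = as.integer(nSpeciesPerRegion),
                 hotspotFraction = hotspotFraction, extent = as.numeric(extent),
                 cellSizeDeg = cellSizeDeg,
                 narrowRadiusDeg = narrowRadiusDeg,
                 wideRadiusDeg = wideRadiusDeg,
                 groupAssignment = match.arg(groupAssignment),
                 seed = as.integer(seed)), class = "landscape_config")
}

GROUP_LEVELS <- c("angiosperm", "arthropod", "vertebrate")

#' Simulate a landscape with planted regions, hotspot and phylogeny
#'
#' Regions are contiguous vertical bands of cells; each species has a disc
#' range around a region-interior center, clipped to its own region's cells.
#' Hotspot endemics are co-centered on one planted hotspot inside region 1
#' with radii in the two smallest range-size classes. The simulated
#' phylogeny has unit branch lengths and one clade per regional pool, giving
#' the phylogenetic composition surfaces a regional signal to find.
#'
#' @param cfg a [landscapeConfig()].
#' @return list of class `landscape_truth`: `grid`, `regionLabels` (per
#'   cell), `hotspotCells` (0-based ids), `species` (data.frame),
#'   `occupancy` (list of 0-based occupied cell ids per species), `tree`,
#'   `effortField` ([Surface-class]), `cfg`.
#' @export
simulateLandscape <- function(cfg = landscapeConfig()) {
  set.seed(cfg$seed)
  grid <- buildHexGrid(cfg$extent, cfg$cellSizeDeg)
  ctr <- cellCenters(grid)
  e <- cfg$extent
  breaks <- seq(e[1], e[3], length.out = cfg$nRegions + 1L)
  regionLabels <- pmin(pmax(findInterval(ctr[, 1], breaks,
                                         rightmost.closed = TRUE), 1L),
                       cfg$nRegions)

  nTotal <- cfg$nRegions * cfg$nSpeciesPerRegion
  nHot <- min(round(cfg$hotspotFraction * nTotal), cfg$nSpeciesPerRegion - 1L)
  hotCenter <- c(mean(breaks[1:2]), mean(e[c(2, 4)]))

  sp <- list(); occupancy <- list()
  sid <- 0L
  for (r in seq_len(cfg$nRegions)) {
    nNarrow <- if (r == 1L) nHot else 0L
    for (i in seq_len(cfg$nSpeciesPerRegion)) {
      sid <- sid + 1L
      narrow <- i <= nNarrow
      if (narrow) {
        center <- hotCenter + stats::rnorm(2, sd = 0.25)
        radius <- stats::runif(1, cfg$narrowRadiusDeg[1], cfg$narrowRadiusDeg[2])
      } else {
        center <- c(stats::runif(1, breaks[r], breaks[r + 1L]),
                    stats::runif(1, e[2], e[4]))
        radius <- stats::runif(1, cfg$wideRadiusDeg[1], cfg$wideRadiusDeg[2])
      }
      d <- sqrt((ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2)
      occ <- which(d <= radius & regionLabels == r)
      if (!length(occ)) occ <- which(regionLabels == r)[
        which.min(d[regionLabels == r])]
      occupancy[[sid]] <- occ - 1L
      sp[[sid]] <- data.frame(species = sprintf("sp%03d", sid), region = r,
                              lon = center[1], lat = center[2],
                              radius_deg = radius, narrow = narrow)
    }
  }
  species <- do.call(rbind, sp)
  species$group <- if (cfg$groupAssignment == "random") {
    sample(GROUP_LEVELS, nTotal, replace = TRUE)
  } else {
    GROUP_LEVELS[((species$region - 1L) %% length(GROUP_LEVELS)) + 1L]
  }
  names(occupancy) <- species$species

  # the planted hotspot: the high-endemism core, i.e. cells shared by at
  # least half of the narrow-ranged endemics
  hotspotCells <- if (any(species$narrow)) {
    narrowOcc <- unlist(occupancy[species$narrow], use.names = FALSE)
    cov <- table(factor(narrowOcc, levels = seq_len(nCells(grid)) - 1L))
    as.integer(names(cov))[cov >= sum(species$narrow) / 2]
  } else integer(0)

  # regional clades joined on a ladder backbone, unit branch lengths
  cladeNewick <- vapply(seq_len(cfg$nRegions), function(r) {
    pool <- species$species[species$region == r]
    tr <- ape::rtree(length(pool), tip.label = sample(pool))
    sub("\\;$", "", ape::write.tree(tr))
  }, character(1))
  nwk <- Reduce(function(a, b) paste0("(", a, ",", b, ")"), cladeNewick)
  tree <- setUnitBranchLengths(ape::read.tree(text = paste0(nwk, ";")))

  # accessibility gradient orthogonal to the (east-west) regional structure,
  # so effort artifacts are identifiable against the planted biodiversity
  v <- (ctr[, 2] - e[2]) / (e[4] - e[2])
  effort <- 0.25 + 1.5 * pmin(pmax(v, 0), 1)
  structure(list(grid = grid, regionLabels = regionLabels,
                 hotspotCells = hotspotCells, species = species,
                 occupancy = occupancy, tree = tree,
                 effortField = newSurface(grid, effort, "planted_effort"),
                 cfg = cfg), class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat(sprintf(paste0("landscape_truth: %d cells, %d regions, %d species ",
                     "(%d hotspot endemics), hotspot of %d cells\n"),
              nCells(x$grid), x$cfg$nRegions, nrow(x$species),
              sum(x$species$narrow), length(x$hotspotCells)))
  invisible(x)
}

# Uniform point inside the hexagon of a given cell (vectorized rejection).
.randomPointInCells <- function(grid, cellIds) {
  ctr <- cellCenters(grid)[cellIds + 1L, , drop = FALSE]
  cs <- cellSize(grid)
  s <- cs / sqrt(3)
  n <- length(cellIds)
  lon <- lat <- rep(NA_real_, n)
  pending <- seq_len(n)
  while (length(pending)) {
    dx <- stats::runif(length(pending), -s, s)
    dy <- stats::runif(length(pending), -cs / 2, cs / 2)
    ok <- .inHex(dx, dy, cs, tol = 0)
    hit <- pending[ok]
    lon[hit] <- ctr[hit, 1] + dx[ok]
    lat[hit] <- ctr[hit, 2] + dy[ok]
    pending <- pending[!ok]
  }
  cbind(lon = lon, lat = lat)
}

#' Sample occurrence records from a landscape truth
#'
#' Records are drawn species-first (species weighted by range area, i.e.
#' occupied-cell count), then a cell uniformly within the species' range and
#' a point uniformly within that cell; with `bias > 0` candidate records are
#' accepted with probability proportional to `effortField^bias`, emulating
#' collection bias towards accessible areas (`bias = 0` is uniform effort).
#'
#' @param truth a [simulateLandscape()] result.
#' @param nRecords number of accepted records.
#' @param bias nonnegative effort-bias exponent.
#' @param seed RNG seed.
#' @return an `occurrence_table` (all records valid).
#' @export
sampleOccurrences <- function(truth, nRecords = 20000, bias = 0, seed = 1) {
  if (nRecords < 1) stop("nRecords must be >= 1")
  set.seed(seed)
  w <- vapply(truth$occupancy, length, 1L)
  pSpecies <- w / sum(w)
  eff <- surfaceValues(truth$effortField)
  effMax <- max(eff)
  spIdx <- integer(0); cellIdx <- integer(0)
  while (length(spIdx) < nRecords) {
    nDraw <- max(1000L, ceiling((nRecords - length(spIdx)) * 1.5))
    s <- sample.int(nrow(truth$species), nDraw, replace = TRUE, prob = pSpecies)
    cells <- vapply(s, function(si) {
      occ <- truth$occupancy[[si]]
      occ[sample.int(length(occ), 1L)]
    }, 1L)
    keep <- if (bias > 0)
      stats::runif(nDraw) < (eff[cells + 1L] / effMax)^bias else rep(TRUE, nDraw)
    spIdx <- c(spIdx, s[keep]); cellIdx <- c(cellIdx, cells[keep])
  }
  spIdx <- spIdx[seq_len(nRecords)]; cellIdx <- cellIdx[seq_len(nRecords)]
  pts <- .randomPointInCells(truth$grid, cellIdx)
  makeOccurrenceTable(truth$species$species[spIdx], pts[, 1], pts[, 2],
                      group = truth$species$group[spIdx],
                      provenance = "synthetic landscape")
}

#' Run the full pipeline against a planted truth and score recovery
#'
#' Executes the whole modelling chain on sampled occurrences and reports how
#' well the planted structure is recovered: the adjusted Rand index between
#' inferred and planted regions, the fraction of planted hotspot cells
#' inside the optimized high-relevance selection, the optimized coverage
#' fractions, the agreement between the kernel effort surface and the
#' planted effort field, and the effort-sensitivity of the resampled vs the
#' naive richness estimate.
#'
#' @param truth a [simulateLandscape()] result.
#' @param occurrences an `occurrence_table` (default: freshly sampled, with
#'   `bias` and `seed` from `opts`).
#' @param opts pipeline options, see [oceubOptions()].
#' @return list of class `recovery_report`.
#' @export
endToEndRecovery <- function(truth, occurrences = NULL, opts = oceubOptions()) {
  if (is.null(occurrences))
    occurrences <- sampleOccurrences(truth, nRecords = opts$nRecords,
                                     bias = opts$bias, seed = opts$seed + 101L)
  run <- runOceub(occurrences, truth$tree, truth$grid, opts)
  lab <- regionLabels(run$regions)
  both <- !is.na(lab)
  ari <- mclust::adjustedRandIndex(lab[both], truth$regionLabels[both])
  hot <- truth$hotspotCells
  hotRecovery <- mean(hot %in% run$best$selected_cells)
  effAgree <- stats::cor(surfaceValues(run$effort),
                         surfaceValues(truth$effortField),
                         use = "complete.obs")
  effTruth <- surfaceValues(truth$effortField)
  rres <- surfaceValues(run$richnessRaw)
  rnaive <- surfaceValues(richnessNaive(occurrences, truth$grid))
  okR <- !is.na(rres) & !is.na(rnaive)
  corResampled <- stats::cor(rres[okR], effTruth[okR])
  corNaive <- stats::cor(rnaive[okR], effTruth[okR])
  structure(list(region_ari = ari, hotspot_recovery = hotRecovery,
                 fitness = run$best, effort_agreement = effAgree,
                 cor_richness_resampled_effort = corResampled,
                 cor_richness_naive_effort = corNaive,
                 run = run), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery: region ARI %.3f, hotspot recovery %.2f\n",
              x$region_ari, x$hotspot_recovery))
  print(x$fitness)
  cat(sprintf("effort field agreement r = %.3f\n", x$effort_agreement))
  cat(sprintf("richness vs planted effort: resampled r = %.3f, naive r = %.3f\n",
              x$cor_richness_resampled_effort, x$cor_richness_naive_effort))
  invisible(x)
}
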