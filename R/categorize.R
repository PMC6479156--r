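#' Sampling sufficiency from an effort surface
#'
#' Cells whose kernel-density sampling effort falls below a cutoff are
#' flagged as insufficiently sampled. The default cutoff is a quantile of
#' the positive-effort distribution (half of it by default); an absolute
#' density override is available. Cells with zero or no-data effort are
#' always insufficient.
#'
#' @param effort a [Surface-class] from [kernelDensity()].
#' @param rule list with `quantile` (default 0.5) and optional `absolute`
#'   cutoff (same units as the effort surface, overrides the quantile).
#' @return logical per cell: `TRUE` = sufficiently sampled.
#' @export
effortClasses <- function(effort, rule = list(quantile = 0.5, absolute = NULL)) {
  v <- surfaceValues(effort)
  pos <- v[!is.na(v) & v > 0]
  if (!length(pos)) {
    warning("no positive sampling effort anywhere; all cells insufficient")
    return(rep(FALSE, length(v)))
  }
  cutoff <- rule$absolute %||%
    stats::quantile(pos, rule$quantile %||% 0.5, names = FALSE)
  if (max(pos) - min(pos) < 1e-12)
    warning("constant sampling effort; all sampled cells classed sufficient")
  !is.na(v) & v >= cutoff & v > 0
}

#' Combine relevance, sampling sufficiency and vegetation into categories
#'
#' Sufficiency has precedence: a cell with too little sampling is
#' `insufficient_information` regardless of its modelled relevance, because
#' no relevance statement is trustworthy there. An optional vegetation mask
#' is stamped as a sub-flag and never changes the main category.
#'
#' @param relevance logical per cell (selected by the optimized model).
#' @param sufficiency logical per cell from [effortClasses()].
#' @param grid the [HexGrid-class].
#' @param vegetation optional character/factor per cell with values
#'   `remnant`, `cleared` or `unknown`.
#' @return a [CategoryMap-class].
#' @export
categorizeCells <- function(relevance, sufficiency, grid, vegetation = NULL) {
  n <- nCells(grid)
  if (length(relevance) != n || length(sufficiency) != n)
    stop("relevance and sufficiency must align with the grid")
  cat_ <- ifelse(!sufficiency, "insufficient_information",
                 ifelse(relevance, "high_relevance_sampled",
                        "low_relevance_sampled"))
  veg <- if (is.null(vegetation)) factor(character(0), levels = VEGETATION_LEVELS)
         else {
           if (length(vegetation) != n) stop("vegetation mask must align with the grid")
           factor(as.character(vegetation), levels = VEGETATION_LEVELS)
         }
  new("CategoryMap", grid = grid,
      category = factor(cat_, levels = CATEGORY_LEVELS), vegetation = veg)
}

#' Summarize categories, optionally per zone
#'
#' @param categories a [CategoryMap-class].
#' @param zones optional per-cell zone labels (character), or a named list
#'   of boundary polygons (cells are zoned by their center; cells matching
#'   no polygon report as `"unzoned"`).
#' @return data.frame with one row per zone: percent of cells in each
#'   category (rows sum to 100), plus the high-relevance and insufficient
#'   percentages repeated for convenience.
#' @export
summarizeCategories <- function(categories, zones = NULL) {
  grid <- categories@grid
  cat_ <- categories@category
  if (is.null(zones)) {
    zone <- rep("all", nCells(grid))
  } else if (is.list(zones) && !is.data.frame(zones)) {
    ctr <- cellCenters(grid)
    zone <- rep("unzoned", nCells(grid))
    for (nm in names(zones)) {
      b <- zones[[nm]]
      if (is.matrix(b)) b <- list(b)
      hit <- pointInRings(ctr, b)
      zone[hit & zone == "unzoned"] <- nm
    }
  } else {
    zone <- as.character(zones)
    zone[is.na(zone)] <- "unzoned"
  }
  out <- lapply(sort(unique(zone)), function(z) {
    sel <- zone == z & !is.na(cat_)
    n <- sum(sel)
    pct <- 100 * as.numeric(table(cat_[sel])[CATEGORY_LEVELS]) / max(n, 1L)
    pct[is.na(pct)] <- 0
    data.frame(zone = z, n_cells = n,
               pct_high_relevance = pct[1], pct_low_relevance = pct[2],
               pct_insufficient = pct[3])
  })
  do.call(rbind, out)
}
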