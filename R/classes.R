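#' @import methods
NULL

#' Hexagonal analysis grid
#'
#' A flat-topped hexagonal tessellation in geographic (lon/lat) coordinates.
#' Cells are identified by contiguous integer ids starting at 0, ordered
#' row-major from the south-west corner. The across-flats width of every
#' hexagon equals `cellSize` degrees, so a 1 degree grid matches the common
#' "one-degree hexagonal cell" analysis unit of biodiversity mapping.
#'
#' @slot centers numeric matrix (n x 2, columns `lon`, `lat`) of cell centers,
#'   ordered by cell id.
#' @slot cellSize across-flats hexagon width in decimal degrees.
#' @slot extent numeric length-4 bounding box `c(xmin, ymin, xmax, ymax)` the
#'   grid was built to cover (the outermost ring may overhang it).
#' @exportClass HexGrid
setClass("HexGrid",
  representation(centers = "matrix", cellSize = "numeric", extent = "numeric"))

setValidity("HexGrid", function(object) {
  if (ncol(object@centers) != 2L) return("centers must have two columns (lon, lat)")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    return("cellSize must be a single positive number")
  if (length(object@extent) != 4L) return("extent must be c(xmin, ymin, xmax, ymax)")
  if (object@extent[3] <= object@extent[1] || object@extent[4] <= object@extent[2])
    return("extent has zero area")
  TRUE
})

#' Per-cell scalar surface on a hexagonal grid
#'
#' One value per grid cell; `NA` is the no-data marker for masked or
#' unsampled cells (never silently zero).
#'
#' @slot grid the [HexGrid-class] the values refer to.
#' @slot values numeric vector, one entry per cell in cell-id order.
#' @slot name short label for the variable the surface carries.
#' @exportClass Surface
setClass("Surface",
  representation(grid = "HexGrid", values = "numeric", name = "character"))

setValidity("Surface", function(object) {
  if (length(object@values) != nrow(object@grid@centers))
    return("values must have one entry per grid cell")
  TRUE
})

#' Biogeographic region map
#'
#' Per-cell integer region labels (1..k) from unsupervised classification of
#' composition surfaces; `NA` marks masked cells. Labels are canonicalized by
#' descending region size.
#'
#' @slot grid the [HexGrid-class].
#' @slot labels integer vector of region ids per cell (NA = masked).
#' @slot k number of regions.
#' @slot modelParams list of per-region parameter summaries (mean vector and
#'   covariance over the composition axes used for classification).
#' @exportClass RegionMap
setClass("RegionMap",
  representation(grid = "HexGrid", labels = "integer", k = "integer",
                 modelParams = "list"))

setValidity("RegionMap", function(object) {
  if (length(object@labels) != nrow(object@grid@centers))
    return("labels must have one entry per grid cell")
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > object@k))
    return("labels must lie in 1..k")
  if (object@k < 1L) return("k must be >= 1")
  TRUE
})

#' Matrix representation (with parsimony) of a set of source trees
#'
#' Binary character matrix encoding every informative clade of every source
#' tree: `"1"` inside the clade, `"0"` outside but present in that tree,
#' `"?"` absent from that tree. Input to [buildSupertree()].
#'
#' @slot matrix character matrix, rows = union of tip labels, one column per
#'   informative clade.
#' @slot provenance data.frame with columns `tree` (source tree index) and
#'   `node` (clade-defining node id in that tree), one row per column.
#' @exportClass MRPMatrix
setClass("MRPMatrix",
  representation(matrix = "matrix", provenance = "data.frame"))

setValidity("MRPMatrix", function(object) {
  if (ncol(object@matrix) != nrow(object@provenance))
    return("provenance must have one row per matrix column")
  if (!all(object@matrix %in% c("0", "1", "?")))
    return("matrix entries must be '0', '1' or '?'")
  TRUE
})

#' Final priority categories per cell
#'
#' Combines modelled biological relevance with sampling sufficiency: a cell
#' with too little sampling is reported as `insufficient_information`
#' regardless of its modelled relevance. An optional vegetation sub-flag
#' (`remnant`/`cleared`/`unknown`) is stamped on top without changing the
#' main category.
#'
#' @slot grid the [HexGrid-class].
#' @slot category factor per cell with levels `high_relevance_sampled`,
#'   `low_relevance_sampled`, `insufficient_information` (NA = masked).
#' @slot vegetation factor per cell (levels `remnant`, `cleared`, `unknown`)
#'   or length 0 when no vegetation mask was supplied.
#' @exportClass CategoryMap
setClass("CategoryMap",
  representation(grid = "HexGrid", category = "factor", vegetation = "factor"))

CATEGORY_LEVELS <- c("high_relevance_sampled", "low_relevance_sampled",
                     "insufficient_information")
VEGETATION_LEVELS <- c("remnant", "cleared", "unknown")

setValidity("CategoryMap", function(object) {
  if (length(object@category) != nrow(object@grid@centers))
    return("category must have one entry per grid cell")
  if (!identical(levels(object@category), CATEGORY_LEVELS))
    return("category levels must be the three canonical classes")
  if (length(object@vegetation) &&
      length(object@vegetation) != nrow(object@grid@centers))
    return("vegetation flag must be empty or one entry per cell")
  TRUE
})

## ---- accessors -----------------------------------------------------------

#' @describeIn HexGrid-class number of cells.
#' @param grid a `HexGrid`.
#' @export
nCells <- function(grid) nrow(grid@centers)

#' @describeIn HexGrid-class n x 2 matrix of cell centers (lon, lat).
#' @export
cellCenters <- function(grid) grid@centers

#' @describeIn HexGrid-class across-flats cell width in degrees.
#' @export
cellSize <- function(grid) grid@cellSize

#' @describeIn HexGrid-class the covered bounding box.
#' @export
gridExtent <- function(grid) grid@extent

#' @describeIn Surface-class per-cell values (NA = no data).
#' @param x a `Surface`.
#' @export
surfaceValues <- function(x) x@values

#' @describeIn Surface-class the variable label.
#' @export
surfaceName <- function(x) x@name

#' @describeIn Surface-class the underlying grid.
#' @export
surfaceGrid <- function(x) x@grid

#' Construct a Surface
#'
#' @param grid a [HexGrid-class].
#' @param values numeric per-cell values (NA = no data); recycled scalars are
#'   not allowed, length must equal `nCells(grid)`.
#' @param name variable label.
#' @return a [Surface-class].
#' @export
newSurface <- function(grid, values, name = "surface") {
  new("Surface", grid = grid, values = as.numeric(values), name = name)
}

#' @describeIn RegionMap-class per-cell region labels (NA = masked).
#' @param map a `RegionMap`.
#' @export
regionLabels <- function(map) map@labels

#' @describeIn RegionMap-class number of regions.
#' @export
nRegions <- function(map) map@k

#' @describeIn CategoryMap-class per-cell category factor.
#' @param x a `CategoryMap`.
#' @export
cellCategories <- function(x) x@category

#' @describeIn MRPMatrix-class the character matrix itself.
#' @param x an `MRPMatrix`.
#' @export
mrpMatrix <- function(x) x@matrix

## ---- show methods --------------------------------------------------------

setMethod("show", "HexGrid", function(object) {
  e <- object@extent
  cat(sprintf("HexGrid: %d flat-top hexagonal cells of %.3g deg (across flats)\n",
              nCells(object), object@cellSize))
  cat(sprintf("  extent: lon [%.3f, %.3f], lat [%.3f, %.3f]\n", e[1], e[3], e[2], e[4]))
})

setMethod("show", "Surface", function(object) {
  v <- object@values
  cat(sprintf("Surface '%s' on %d cells (%d with data)\n",
              object@name, length(v), sum(!is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range: [%.4g, %.4g]\n", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "RegionMap", function(object) {
  cat(sprintf("RegionMap: %d regions over %d labeled cells\n",
              object@k, sum(!is.na(object@labels))))
  print(table(region = object@labels))
})

setMethod("show", "MRPMatrix", function(object) {
  cat(sprintf("MRPMatrix: %d taxa x %d informative clade characters (%d source trees)\n",
              nrow(object@matrix), ncol(object@matrix),
              length(unique(object@provenance$tree))))
})

setMethod("show", "CategoryMap", function(object) {
  cat("CategoryMap:\n")
  print(table(category = object@category))
  if (length(object@vegetation)) {
    cat("vegetation sub-flag:\n")
    print(table(vegetation = object@vegetation))
  }
})
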