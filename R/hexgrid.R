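#' Build a hexagonal analysis grid
#'
#' Lays out flat-topped hexagons with across-flats width `cellSizeDeg` in
#' geographic coordinates so that the grid fully covers `extent` (the
#' outermost ring overhangs it). Cell ids are contiguous integers from 0,
#' ordered row-major from the south-west corner.
#'
#' The lattice is regular in degree space: across-flats spacing `c` in the
#' north-south direction, column spacing `1.5 * c / sqrt(3)` east-west with
#' alternate columns shifted by `c / 2`. Because the hexagons are the Voronoi
#' cells of their centers, point-to-cell assignment reduces to
#' nearest-center search (ties broken towards the lower cell id).
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in decimal degrees.
#' @param cellSizeDeg across-flats hexagon width in degrees (default 1).
#' @return a [HexGrid-class].
#' @export
buildHexGrid <- function(extent, cellSizeDeg = 1) {
  extent <- as.numeric(extent)
  if (length(extent) != 4L)
    stop("extent must be c(xmin, ymin, xmax, ymax)")
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("zero-area extent")
  if (cellSizeDeg <= 0) stop("cellSizeDeg must be > 0")

  cs <- cellSizeDeg
  s <- cs / sqrt(3)          # side length = circumradius
  dx <- 1.5 * s              # column spacing
  ncol_ <- ceiling((extent[3] - extent[1]) / dx) + 1L
  nrow_ <- ceiling((extent[4] - extent[2]) / cs) + 1L
  cols <- -1L:ncol_
  rows <- -1L:nrow_
  centers <- do.call(rbind, lapply(cols, function(j) {
    x <- extent[1] + j * dx
    yoff <- if (abs(j) %% 2L == 1L) cs / 2 else 0
    cbind(lon = x, lat = extent[2] + rows * cs + yoff)
  }))
  ord <- order(round(centers[, 2], 9), round(centers[, 1], 9))
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- NULL
  new("HexGrid", centers = centers, cellSize = cs, extent = extent)
}

#' Cell polygons of a hexagonal grid
#'
#' @param grid a [HexGrid-class].
#' @return list (by cell id order) of closed 7 x 2 lon/lat rings.
#' @export
cellPolygons <- function(grid) {
  s <- grid@cellSize / sqrt(3)
  ang <- seq(0, 300, by = 60) * pi / 180
  vx <- s * cos(ang)
  vy <- s * sin(ang)
  ctr <- grid@centers
  lapply(seq_len(nrow(ctr)), function(i) {
    ring <- cbind(lon = ctr[i, 1] + c(vx, vx[1]), lat = ctr[i, 2] + c(vy, vy[1]))
    ring
  })
}

# TRUE where (dxy) lies inside the flat-top hexagon centered at origin,
# across-flats width cs; boundary points count as inside (tol).
.inHex <- function(dx, dy, cs, tol = 1e-9) {
  h <- cs / 2 + tol
  a1 <- abs(dy)
  a2 <- abs(dy / 2 + dx * sqrt(3) / 2)
  a3 <- abs(dy / 2 - dx * sqrt(3) / 2)
  a1 <= h & a2 <= h & a3 <= h
}

#' Assign lon/lat points to grid cells
#'
#' Nearest-center assignment (exact for a hexagonal Voronoi tessellation);
#' points on a shared edge go to the lower cell id; points outside the
#' tiled area get `NA`.
#'
#' @param grid a [HexGrid-class].
#' @param lon,lat numeric vectors of coordinates.
#' @return integer vector of 0-based cell ids (NA = outside the grid).
#' @export
cellOf <- function(grid, lon, lat) {
  ctr <- grid@centers
  n <- length(lon)
  out <- rep(NA_integer_, n)
  if (!n) return(out)
  for (i in seq_len(n)) {
    if (!is.finite(lon[i]) || !is.finite(lat[i])) next
    d2 <- (ctr[, 1] - lon[i])^2 + (ctr[, 2] - lat[i])^2
    m <- min(d2)
    cand <- which(d2 <= m + 1e-12)[1L]   # ties -> lowest id
    if (.inHex(lon[i] - ctr[cand, 1], lat[i] - ctr[cand, 2], grid@cellSize))
      out[i] <- cand - 1L
  }
  out
}

#' Hexagonal adjacency pairs
#'
#' @param grid a [HexGrid-class].
#' @return two-column integer matrix of adjacent 0-based cell id pairs.
#' @export
hexAdjacency <- function(grid) {
  ctr <- grid@centers
  cs <- grid@cellSize
  n <- nrow(ctr)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- (ctr[, 1] - ctr[i, 1])^2 + (ctr[, 2] - ctr[i, 2])^2
    nb <- which(d2 > 1e-12 & d2 < (1.1 * cs)^2)
    nb <- nb[nb > i]
    if (length(nb)) pairs[[i]] <- cbind(i - 1L, nb - 1L)
  }
  out <- do.call(rbind, pairs)
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  colnames(out) <- c("a", "b")
  out
}

#' Export a grid or surface as a cell table
#'
#' @param x a [HexGrid-class] or [Surface-class].
#' @return data.frame with `cell_id`, `center_lon`, `center_lat` (and `value`
#'   for surfaces).
#' @export
cellTable <- function(x) {
  if (is(x, "Surface")) {
    g <- x@grid
    data.frame(cell_id = seq_len(nCells(g)) - 1L,
               center_lon = g@centers[, 1], center_lat = g@centers[, 2],
               value = x@values)
  } else {
    data.frame(cell_id = seq_len(nCells(x)) - 1L,
               center_lon = x@centers[, 1], center_lat = x@centers[, 2])
  }
}

# Approximate area of one hexagonal cell in km^2 at each cell's latitude.
cellAreaKm2 <- function(grid) {
  aDeg2 <- sqrt(3) / 2 * grid@cellSize^2
  aDeg2 * KM_PER_DEG^2 * cos(grid@centers[, 2] * pi / 180)
}
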