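#' Read species occurrence records
#'
#' Reads a CSV/TSV of point records into a validated occurrence table. Rows
#' whose coordinates cannot be parsed, or fall outside valid lon/lat ranges,
#' are retained with `valid_geo = FALSE` so that record funnels stay
#' auditable; nothing is silently dropped. A parse report is attached as the
#' `"report"` attribute (see [occurrenceReport()]).
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything else
#'   comma-separated.
#' @param dialect named character vector mapping the canonical fields
#'   `species`, `lon`, `lat` (and optionally `group`, `valid_taxon`) to the
#'   file's column names.
#' @param provenance free-text source tag stored on the table.
#' @return a data.frame of class `occurrence_table` with columns `species`,
#'   `lon`, `lat`, `group`, `valid_geo`, `valid_taxon`.
#' @export
readOccurrences <- function(path,
                            dialect = c(species = "species", lon = "lon", lat = "lat"),
                            provenance = path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (nrow(raw) == 0L) stop("empty occurrence file: ", path)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(dialect)))
    stop("dialect must name the species, lon and lat columns")
  missing <- setdiff(unname(dialect[need]), names(raw))
  if (length(missing))
    stop("columns not found in header: ", paste(missing, collapse = ", "))

  species <- as.character(raw[[dialect[["species"]]]])
  lon <- suppressWarnings(as.numeric(as.character(raw[[dialect[["lon"]]]])))
  lat <- suppressWarnings(as.numeric(as.character(raw[[dialect[["lat"]]]])))
  group <- if ("group" %in% names(dialect) && dialect[["group"]] %in% names(raw))
    as.character(raw[[dialect[["group"]]]]) else rep(NA_character_, nrow(raw))
  vt <- if ("valid_taxon" %in% names(dialect) && dialect[["valid_taxon"]] %in% names(raw))
    as.logical(raw[[dialect[["valid_taxon"]]]]) else rep(TRUE, nrow(raw))
  if (any(!nzchar(species) | is.na(species)))
    stop("species_id must be non-empty for every row")

  validGeo <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  tab <- makeOccurrenceTable(species, lon, lat, group = group,
                             valid_geo = validGeo, valid_taxon = vt,
                             provenance = provenance)
  attr(tab, "report") <- list(n_read = nrow(raw),
                              n_coord_invalid = sum(!validGeo))
  message(sprintf("read %d records (%d with unparseable or out-of-range coordinates)",
                  nrow(raw), sum(!validGeo)))
  tab
}

# Internal constructor shared by the reader and the synthetic generator.
makeOccurrenceTable <- function(species, lon, lat, group = NA_character_,
                                valid_geo = TRUE, valid_taxon = TRUE,
                                provenance = "in-memory") {
  tab <- data.frame(species = as.character(species),
                    lon = as.numeric(lon), lat = as.numeric(lat),
                    group = rep_len(as.character(group), length(species)),
                    valid_geo = rep_len(valid_geo, length(species)),
                    valid_taxon = rep_len(valid_taxon, length(species)),
                    stringsAsFactors = FALSE)
  class(tab) <- c("occurrence_table", "data.frame")
  attr(tab, "provenance") <- provenance
  tab
}

#' Parse report of an occurrence table
#' @param table an `occurrence_table`.
#' @return list with `n_read` and `n_coord_invalid` (NULL for in-memory tables).
#' @export
occurrenceReport <- function(table) attr(table, "report")

#' Write an occurrence table to CSV
#' @param table an `occurrence_table`.
#' @param path output file.
#' @export
writeOccurrences <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

## ---- boundary polygons ---------------------------------------------------

# Even-odd ray-casting point-in-polygon over a set of rings; a point on any
# edge counts as inside. pts: n x 2; rings: list of m x 2 matrices.
pointInRings <- function(pts, rings, tol = 1e-12) {
  n <- nrow(pts)
  inside <- rep(FALSE, n)
  onEdge <- rep(FALSE, n)
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    m <- length(x)
    if (abs(x[1] - x[m]) > tol || abs(y[1] - y[m]) > tol) {  # close ring
      x <- c(x, x[1]); y <- c(y, y[1]); m <- m + 1L
    }
    for (p in seq_len(n)) {
      px <- pts[p, 1]; py <- pts[p, 2]
      crossings <- 0L
      for (i in seq_len(m - 1L)) {
        x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
        # on-segment check
        d <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
        if (d <= tol * max(1, abs(x2 - x1) + abs(y2 - y1)) &&
            px >= min(x1, x2) - tol && px <= max(x1, x2) + tol &&
            py >= min(y1, y2) - tol && py <= max(y1, y2) + tol) {
          onEdge[p] <- TRUE
        }
        if ((y1 > py) != (y2 > py)) {
          xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
          if (px < xint) crossings <- crossings + 1L
        }
      }
      if (crossings %% 2L == 1L) inside[p] <- !inside[p]
    }
  }
  inside | onEdge
}

# Reject degenerate or self-intersecting rings with a named fault.
checkRing <- function(ring, label = "boundary ring") {
  if (nrow(ring) < 3L) stop(label, ": fewer than 3 vertices")
  x <- ring[, 1]; y <- ring[, 2]
  m <- nrow(ring)
  if (abs(x[1] - x[m]) < 1e-12 && abs(y[1] - y[m]) < 1e-12) {
    x <- x[-m]; y <- y[-m]; m <- m - 1L
  }
  if (m < 3L) stop(label, ": fewer than 3 distinct vertices")
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (abs(area2) < 1e-12) stop(label, ": zero area")
  segInt <- function(ax, ay, bx, by, cx, cy, dx, dy) {
    ccw <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
    d1 <- ccw(cx, cy, dx, dy, ax, ay); d2 <- ccw(cx, cy, dx, dy, bx, by)
    d3 <- ccw(ax, ay, bx, by, cx, cy); d4 <- ccw(ax, ay, bx, by, dx, dy)
    (d1 * d2 < 0) && (d3 * d4 < 0)    # proper crossings only
  }
  xs <- c(x, x[1]); ys <- c(y, y[1])
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (abs(i - j) <= 1L || (i == 1L && j == m) || (i == m && j == 1L)) next
      if (segInt(xs[i], ys[i], xs[i + 1], ys[i + 1],
                 xs[j], ys[j], xs[j + 1], ys[j + 1]))
        stop(label, ": self-intersecting")
    }
  }
  invisible(TRUE)
}

#' Read boundary polygons from GeoJSON
#'
#' Supports Polygon and MultiPolygon geometries (plain, Feature, or
#' FeatureCollection). Holes are handled by the even-odd rule.
#'
#' @param path a `.json`/`.geojson` file.
#' @return list of lon/lat ring matrices usable as `boundary` in
#'   [validateGeography()].
#' @export
readBoundary <- function(path) {
  if (!file.exists(path)) stop("boundary file not found: ", path)
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  rings <- list()
  harvest <- function(geom) {
    if (is.null(geom$type)) return()
    ringMat <- function(r) do.call(rbind, lapply(r, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    if (geom$type == "Polygon") {
      for (r in geom$coordinates) rings[[length(rings) + 1L]] <<- ringMat(r)
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) for (r in poly)
        rings[[length(rings) + 1L]] <<- ringMat(r)
    } else if (geom$type == "Feature") {
      harvest(geom$geometry)
    } else if (geom$type == "FeatureCollection") {
      for (f in geom$features) harvest(f)
    }
  }
  harvest(g)
  if (!length(rings)) stop("no Polygon/MultiPolygon geometry in ", path)
  rings
}

#' Validate records against a boundary
#'
#' Records whose point falls outside the boundary get `valid_geo = FALSE`
#' (a point exactly on an edge counts as inside). Previously invalid
#' records stay invalid; the table is never mutated beyond flags.
#'
#' @param table an `occurrence_table`.
#' @param boundary a lon/lat ring matrix, a list of such matrices
#'   (even-odd rule across rings, so holes work), or a length-4 numeric
#'   bounding box `c(xmin, ymin, xmax, ymax)`.
#' @return the table with updated `valid_geo`.
#' @export
validateGeography <- function(table, boundary) {
  if (is.numeric(boundary) && length(boundary) == 4L) {
    b <- boundary
    boundary <- list(cbind(c(b[1], b[3], b[3], b[1], b[1]),
                           c(b[2], b[2], b[4], b[4], b[2])))
  }
  if (is.matrix(boundary)) boundary <- list(boundary)
  for (i in seq_along(boundary)) checkRing(boundary[[i]], paste0("boundary ring ", i))
  idx <- which(table$valid_geo)
  if (length(idx)) {
    ok <- pointInRings(cbind(table$lon[idx], table$lat[idx]), boundary)
    table$valid_geo[idx[!ok]] <- FALSE
    message(sprintf("geographic validation: %d passed, %d failed",
                    sum(ok), sum(!ok)))
  }
  table
}

#' Build a presence matrix from valid records
#'
#' Only records with `valid_geo` and `valid_taxon` contribute. Rows are the
#' occupied cell ids (sorted), columns the species present in the grid
#' (sorted); an entry is `TRUE` iff at least one valid record of that species
#' falls in that cell. Records outside the tiled grid are ignored.
#'
#' @param table an `occurrence_table`.
#' @param grid a [HexGrid-class].
#' @return logical matrix with cell-id rownames and species colnames; the
#'   per-record cell assignment is attached as attribute `"cells"`.
#' @export
assignCells <- function(table, grid) {
  keep <- table$valid_geo & table$valid_taxon
  if (!any(keep)) stop("empty presence matrix: no valid records")
  cells <- cellOf(grid, table$lon[keep], table$lat[keep])
  inGrid <- !is.na(cells)
  sp <- table$species[keep][inGrid]
  cid <- cells[inGrid]
  if (!length(cid)) stop("empty presence matrix: no records inside the grid")
  rows <- sort(unique(cid))
  cols <- sort(unique(sp))
  mat <- matrix(FALSE, length(rows), length(cols),
                dimnames = list(as.character(rows), cols))
  mat[cbind(match(cid, rows), match(sp, cols))] <- TRUE
  attr(mat, "cells") <- cid
  mat
}

# Per-cell record counts for valid records (used by resampling and masking).
recordsPerCell <- function(table, grid) {
  keep <- table$valid_geo & table$valid_taxon
  cells <- cellOf(grid, table$lon[keep], table$lat[keep])
  ok <- !is.na(cells)
  split(which(keep)[ok], cells[ok])
}
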