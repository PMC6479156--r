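#' @importFrom geosphere distHaversine
NULL

# Great-circle distance in km between points given as lon/lat matrices or
# length-2 vectors. Thin wrapper so every module uses one distance arithmetic.
haversineKm <- function(p1, p2) {
  geosphere::distHaversine(p1, p2) / 1000
}

# Pairwise great-circle distance matrix (km) for an n x 2 lon/lat matrix.
haversineMatrixKm <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    dij <- haversineKm(coords[i, , drop = FALSE], coords[j, , drop = FALSE])
    d[i, j] <- dij
    d[j, i] <- dij
  }
  d
}

# Kilometres per degree of longitude/latitude (spherical approximation).
KM_PER_DEG <- 111.32

# Min-max rescale to [0, 1]; constant input collapses to 0 (callers warn).
rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1])) return(x)
  if (r[2] - r[1] <= 0) {
    x[!is.na(x)] <- 0
    return(x)
  }
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of an R object via its deparsed text rendering (manifests only).
paramsDigest <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(deparse(x, control = c("exact")), tf)
  unname(tools::md5sum(tf))
}
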