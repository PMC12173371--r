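# Internal helpers shared across modules.

# Abort with a classed condition so tests can assert on error types.
stop_landrace <- function(msg, class = "landrace_error", call. = FALSE) {
  cnd <- structure(
    class = c(class, "landrace_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cnd)
}

# Derive a stage seed from a global seed. Keeps derived seeds inside the
# 32-bit integer range so set.seed() never overflows.
derive_seed <- function(seed, stage) {
  offsets <- c(
    landscape = 11L, genotypes = 23L, design = 37L, phenotypes = 41L,
    transfer = 53L, gpoe = 67L, gwas = 71L, clump = 83L, bench = 97L,
    pca = 101L, folds = 103L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

# Great-circle distance in km (haversine, Earth radius 6371 km) between
# rows of lon/lat matrices. Returns an n x m matrix.
haversine_km <- function(a, b) {
  rad <- pi / 180
  lon1 <- a[, 1] * rad; lat1 <- a[, 2] * rad
  lon2 <- b[, 1] * rad; lat2 <- b[, 2] * rad
  dlat <- outer(lat1, lat2, function(x, y) y - x)
  dlon <- outer(lon1, lon2, function(x, y) y - x)
  h <- sin(dlat / 2)^2 +
    outer(cos(lat1), cos(lat2)) * sin(dlon / 2)^2
  h <- pmin(h, 1)
  2 * 6371 * asin(sqrt(h))
}

# Equirectangular projection to km around the centroid; adequate for
# clustering points at a regional scale.
project_km <- function(lon, lat) {
  lat0 <- mean(lat)
  cbind(
    x = (lon - mean(lon)) * 111.32 * cos(lat0 * pi / 180),
    y = (lat - lat0) * 110.57
  )
}

# Symmetrize and clip eigenvalues of a covariance matrix to >= 0.
clip_psd <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  lo <- -tol * sum(diag(m))
  if (any(e$values < lo) || any(e$values < 0)) {
    v <- pmax(e$values, 0)
    m <- e$vectors %*% (v * t(e$vectors))
    m <- (m + t(m)) / 2
  }
  m
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
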