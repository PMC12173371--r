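# Cross-validation fold constructors: random k-fold, spatially buffered
# k-fold, and tester folds for the prediction benchmark.

new_fold_assignment <- function(tbl, scheme, seed = NA_integer_,
                                excluded = NULL, buffer_km = NA_real_) {
  structure(tbl,
            scheme = scheme, seed = seed, excluded = excluded,
            buffer_km = buffer_km,
            class = c("fold_assignment", class(tbl)))
}

#' Random k-fold assignment
#'
#' Partitions samples into `k` folds of near-equal size (sizes differ by at
#' most one), deterministically for a given seed.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `fold_assignment` tibble with columns `sample_id` and `fold`.
#' @export
make_random_folds <- function(sample_ids, k = 10, seed = 1) {
  n <- length(sample_ids)
  if (k > n) {
    stop_landrace("k cannot exceed the number of samples",
                  "landrace_value_error")
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  new_fold_assignment(
    tibble::tibble(sample_id = sample_ids, fold = fold),
    scheme = "random", seed = seed
  )
}

#' Spatially separated k-fold assignment with a buffer
#'
#' Clusters sample coordinates (projected to km) with k-means to form `k`
#' geographically contiguous folds. For each fold, training samples within
#' `buffer_km` great-circle distance (haversine, Earth radius 6371 km) of
#' any test sample are marked as excluded, so spatially adjacent samples
#' never inform predictions for that fold.
#'
#' @param coords Data frame with columns `sample_id`, `lon`, `lat`.
#' @param k Number of folds.
#' @param buffer_km Exclusion buffer distance in km.
#' @param seed Integer seed for the k-means initialization.
#' @return A `fold_assignment` tibble; the per-fold excluded sample sets are
#'   stored in `attr(, "excluded")` (a named list).
#' @export
make_spatial_folds <- function(coords, k = 10, buffer_km = 400, seed = 1) {
  stopifnot(all(c("sample_id", "lon", "lat") %in% names(coords)))
  if (!all(is.finite(coords$lon)) || !all(is.finite(coords$lat))) {
    stop_landrace("coordinates must be finite", "landrace_value_error")
  }
  xy <- project_km(coords$lon, coords$lat)
  km_fit <- NULL
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    km_fit <- tryCatch(
      kmeans(xy, centers = k, nstart = 5, iter.max = 50),
      error = function(e) NULL
    )
    if (!is.null(km_fit) && all(tabulate(km_fit$cluster, k) > 0)) break
    km_fit <- NULL
  }
  if (is.null(km_fit)) {
    stop_landrace("k-means failed to produce k non-empty spatial folds",
                  "landrace_value_error")
  }
  fold <- km_fit$cluster
  ll <- cbind(coords$lon, coords$lat)
  excluded <- lapply(seq_len(k), function(f) {
    test <- fold == f
    if (buffer_km <= 0) return(character(0))
    d <- haversine_km(ll[!test, , drop = FALSE], ll[test, , drop = FALSE])
    near <- apply(d, 1, min) <= buffer_km
    coords$sample_id[!test][near]
  })
  names(excluded) <- as.character(seq_len(k))
  new_fold_assignment(
    tibble::tibble(sample_id = coords$sample_id, fold = fold),
    scheme = "spatial", seed = seed, excluded = excluded,
    buffer_km = buffer_km
  )
}

#' Tester folds within a trial
#'
#' Assigns all testcross families made with the same tester to the same
#' fold, the cross-validation unit of the prediction benchmark.
#'
#' @param design Testcross design tibble (`trial`, `tester`, `accession`).
#' @param trial Trial identifier.
#' @return A `fold_assignment` tibble with columns `sample_id` (accession),
#'   `tester` and `fold`.
#' @export
make_tester_folds <- function(design, trial) {
  d <- design[design$trial == trial, , drop = FALSE]
  testers <- sort(unique(d$tester))
  if (length(testers) < 2) {
    stop_landrace(paste0("trial has a single tester, cannot form folds: ",
                         trial),
                  "landrace_value_error")
  }
  new_fold_assignment(
    tibble::tibble(sample_id = d$accession, tester = d$tester,
                   fold = match(d$tester, testers)),
    scheme = "tester"
  )
}
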