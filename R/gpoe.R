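# Genomic prediction of environment: cross-validated evaluation and the
# random-vs-spatial scheme comparison.

#' Cross-validated genomic prediction of environment
#'
#' For each fold, re-estimates the genetic and residual covariance on the
#' training samples (minus any buffer-excluded samples for spatial folds),
#' predicts the held-out samples with [predict_environment()], and records
#' Pearson's r and RMSE per environmental variable on the INT scale. A
#' leakage assertion verifies that no test or excluded sample ever enters a
#' training set.
#'
#' @param Y Samples-by-variables matrix (or data frame with `sample_id`) of
#'   INT-transformed environmental values.
#' @param K Full-sample `kinship_matrix`.
#' @param folds A `fold_assignment` from [make_random_folds()] or
#'   [make_spatial_folds()].
#' @param tol,max_iter Passed to [estimate_multitrait_components()].
#' @return Tibble of class `gpoe_scores` with columns `fold`, `variable`,
#'   `r`, `rmse`, `n_test` and a `scheme` column.
#' @export
evaluate_gpoe_cv <- function(Y, K, folds, tol = 1e-4, max_iter = 200) {
  Y <- as_numeric_matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("V", seq_len(ncol(Y)))
  ids <- rownames(Y)
  if (is.null(ids)) stop_landrace("Y must carry sample ids", "landrace_value_error")
  excl <- attr(folds, "excluded")
  scheme <- attr(folds, "scheme")
  out <- list()
  for (f in sort(unique(folds$fold))) {
    test_ids <- folds$sample_id[folds$fold == f]
    drop_ids <- if (!is.null(excl)) excl[[as.character(f)]] else character(0)
    train_ids <- setdiff(ids, c(test_ids, drop_ids))
    stopifnot(!any(train_ids %in% test_ids), !any(train_ids %in% drop_ids))
    Ytr <- Y[train_ids, , drop = FALSE]
    Ktr <- kinship_values(K)[train_ids, train_ids, drop = FALSE]
    vc <- estimate_multitrait_components(Ytr, Ktr, tol = tol,
                                         max_iter = max_iter)
    pred <- predict_environment(Ytr, K, vc, test_ids)
    obs <- Y[test_ids, , drop = FALSE]
    small <- length(test_ids) < 3
    if (small) {
      warning(sprintf("fold %s has fewer than 3 test samples; r undefined", f),
              call. = FALSE)
    }
    out[[length(out) + 1]] <- tibble::tibble(
      fold = f,
      variable = colnames(Y),
      r = if (small) NA_real_ else
        vapply(seq_len(ncol(Y)),
               function(j) suppressWarnings(cor(pred[, j], obs[, j])),
               numeric(1)),
      rmse = vapply(seq_len(ncol(Y)),
                    function(j) sqrt(mean((pred[, j] - obs[, j])^2)),
                    numeric(1)),
      n_test = length(test_ids)
    )
  }
  res <- dplyr::bind_rows(out)
  res$scheme <- scheme %||% NA_character_
  class(res) <- c("gpoe_scores", class(res))
  res
}

#' Compare random and spatial cross-validation schemes
#'
#' Per environmental variable, runs a two-sided paired t-test over folds for
#' both the correlation and the RMSE, plus one-sample t-tests that each
#' scheme's correlations exceed zero. Folds with undefined r are dropped
#' pairwise with a logged count. A zero-variance difference with a non-zero
#' mean is reported as p = 0 with a warning (p = 1 when the score vectors
#' are identical).
#'
#' @param random_scores,spatial_scores `gpoe_scores` tibbles from
#'   [evaluate_gpoe_cv()] computed with the same `k`.
#' @return Tibble with one row per variable and metric: fold means for both
#'   schemes, paired t statistic and p-value, and per-scheme p-values for
#'   r > 0.
#' @export
compare_cv_schemes <- function(random_scores, spatial_scores) {
  ks <- length(unique(random_scores$fold))
  if (ks != length(unique(spatial_scores$fold))) {
    stop_landrace("schemes must use the same number of folds",
                  "landrace_value_error")
  }
  if (ks < 3) stop_landrace("need k >= 3 folds", "landrace_value_error")
  vars <- unique(random_scores$variable)
  purrr::map_dfr(vars, function(v) {
    purrr::map_dfr(c("r", "rmse"), function(metric) {
      a <- random_scores[[metric]][random_scores$variable == v][
        order(random_scores$fold[random_scores$variable == v])]
      b <- spatial_scores[[metric]][spatial_scores$variable == v][
        order(spatial_scores$fold[spatial_scores$variable == v])]
      ok <- is.finite(a) & is.finite(b)
      if (sum(!ok)) {
        message(sprintf("dropping %d fold(s) with undefined %s for %s",
                        sum(!ok), metric, v))
      }
      a <- a[ok]; b <- b[ok]
      pt_ <- paired_t(a, b)
      tibble::tibble(
        variable = v, metric = metric,
        mean_random = mean(a), mean_spatial = mean(b),
        statistic = pt_$t, p_value = pt_$p,
        p_random_gt0 = if (metric == "r") one_sided_gt0(a) else NA_real_,
        p_spatial_gt0 = if (metric == "r") one_sided_gt0(b) else NA_real_
      )
    })
  })
}

paired_t <- function(a, b) {
  d <- a - b
  if (length(d) < 3) return(list(t = NA_real_, p = NA_real_))
  if (sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) return(list(t = 0, p = 1))
    warning("zero variance of paired differences; p -> 0", call. = FALSE)
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

one_sided_gt0 <- function(x) {
  if (length(x) < 3 || sd(x) < 1e-12) return(NA_real_)
  tt <- t.test(x, mu = 0, alternative = "greater")
  tt$p.value
}
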