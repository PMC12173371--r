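# Weighted mixed-model comparison of prediction-model accuracies.

#' Compare prediction models across trials and folds
#'
#' Fits the weighted linear mixed model
#' `r ~ trial + model + (1 | trial:model) + (1 | trial:fold)` to the
#' per-fold accuracies, with residuals weighted by the fold sample size
#' (the sampling variance of a correlation shrinks with n), and evaluates
#' all pairwise model contrasts with Tukey's studentized-range adjustment
#' (Satterthwaite degrees of freedom).
#'
#' @param scores A `prediction_scores` tibble from [run_model_suite()];
#'   rows with missing r are dropped with a logged count.
#' @return Object of class `model_comparison`: list with `emmeans`
#'   (model-adjusted means), `contrasts` (estimate, SE, df, t, Tukey p per
#'   model pair), `fit` (the `lmerModLmerTest` object) and `n_dropped`.
#' @export
compare_models <- function(scores) {
  d <- scores[!is.na(scores$r), , drop = FALSE]
  n_dropped <- nrow(scores) - nrow(d)
  if (n_dropped > 0) {
    message(sprintf("dropped %d fold score(s) with undefined r", n_dropped))
  }
  if (length(unique(d$model)) < 2) {
    stop_landrace("need at least 2 models to compare", "landrace_value_error")
  }
  if (length(unique(d$trial)) < 2) {
    stop_landrace("need at least 2 trials to compare", "landrace_value_error")
  }
  d$trial <- factor(d$trial)
  d$model <- factor(d$model)
  d$fold <- factor(paste(d$trial, d$fold, sep = ":"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(r ~ trial + model + (1 | trial:model) + (1 | trial:fold),
                   data = d, weights = n,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  emm <- suppressMessages(emmeans::emmeans(fit, "model",
                                           lmer.df = "satterthwaite"))
  ctr <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "tukey"))
  structure(
    list(
      emmeans = tibble::as_tibble(summary(emm)),
      contrasts = tibble::as_tibble(ctr),
      fit = fit,
      n_dropped = n_dropped
    ),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$emmeans)
  print(x$contrasts)
  invisible(x)
}

#' @rdname compare_models
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  ctr <- x$contrasts
  tibble::tibble(
    contrast = as.character(ctr$contrast),
    estimate = ctr$estimate,
    std.error = ctr$SE,
    df = ctr$df,
    statistic = ctr$t.ratio,
    adj.p.value = ctr$p.value
  )
}

#' @rdname compare_models
#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    n_models = nrow(x$emmeans),
    n_contrasts = nrow(x$contrasts),
    var_trial_model = vc$vcov[vc$grp == "trial:model"][1],
    var_trial_fold = vc$vcov[vc$grp == "trial:fold"][1],
    var_residual = vc$vcov[vc$grp == "Residual"][1],
    n_dropped = x$n_dropped
  )
}
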