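# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot estimated optima against trial environments
#'
#' Transfer-model diagnostic: per-trial posterior mean and interval of the
#' optimal environment-of-origin against the trial's environment, with the
#' 1:1 line indicating perfect home-site matching.
#'
#' @param object A `transfer_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transfer_summary
#' @export
autoplot.transfer_summary <- function(object, ...) {
  ggplot2::ggplot(object$optima,
                  ggplot2::aes(x = .data$trial_env, y = .data$optimum_mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$optimum_lo,
                                          ymax = .data$optimum_hi)) +
    ggplot2::labs(
      x = "trial environment", y = "estimated optimal environment-of-origin",
      title = sprintf("Transfer-distance optima (%s)", object$trait),
      subtitle = sprintf("beta_h = %.2f [%.2f, %.2f]", object$beta$mean,
                         object$beta$lo, object$beta$hi)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated prediction of environment
#'
#' Per-variable fold accuracies for one or more cross-validation schemes.
#'
#' @param object A `gpoe_scores` tibble (rows from several schemes can be
#'   combined with `dplyr::bind_rows()`).
#' @param metric `"r"` or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gpoe_scores
#' @export
autoplot.gpoe_scores <- function(object, metric = c("r", "rmse"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$variable, y = .data[[metric]],
                               fill = .data$scheme)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = metric,
                  title = "Genomic prediction of environment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Manhattan plot of a GWAS table
#'
#' @param object A `gwas_table`.
#' @param p_threshold Significance line; defaults to the stored threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwas_table
#' @export
autoplot.gwas_table <- function(object, p_threshold = NULL, ...) {
  thr <- p_threshold %||% attr(object, "p_threshold") %||% 1e-5
  d <- tibble::as_tibble(object)
  d$chrom <- factor(d$chrom, levels = unique(d$chrom))
  d <- dplyr::arrange(d, .data$chrom, .data$pos)
  offsets <- c(0, cumsum(tapply(d$pos, d$chrom, max)))
  d$x <- d$pos + offsets[as.integer(d$chrom)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = -log10(.data$p),
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed",
                        colour = "blue") +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p)),
                  title = "Joint multivariate association scan") +
    ggplot2::theme_minimal()
}

#' Plot benchmark predictive abilities
#'
#' Mean within-tester-fold predictive ability per model, averaged across
#' trials, with per-fold points.
#'
#' @param object A `prediction_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prediction_scores
#' @export
autoplot.prediction_scores <- function(object, ...) {
  d <- object[!is.na(object$r), , drop = FALSE]
  means <- dplyr::summarise(dplyr::group_by(d, .data$model),
                            r = mean(.data$r), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$r)) +
    ggplot2::geom_col(data = means, fill = "grey70") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "predictive ability (Pearson r)",
                  title = "Prediction model benchmark") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
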