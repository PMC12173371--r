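# Hierarchical Bayesian quadratic transfer-distance model.
#
# Family value y_ijk in trial i with tester j is modelled as
#   y_ijk = c_ij + a_i (x_ijk - h_i)^2 + e_ijk
# with per-trial curvature a_i (non-positive under the local-adaptation
# constraint), per-trial optimum h_i regressed on the trial environment
# (h_i = mu_h + beta_h X_i + N(0, sigma_h^2)) and trial-specific residual
# variance. Priors: c_ij ~ N(mu_c, sigma_c^2), mu_c ~ N(0,1),
# a_i ~ N-(0,1) (negative half-normal), mu_h ~ N(0,1), beta_h ~ N(0,3),
# sigma_c/sigma_h/sigma_e,i ~ half-t(3, 0, 2.5). The sampler is an adaptive
# Metropolis-within-Gibbs scheme: c, mu_c, a, (mu_h, beta_h) have conjugate
# updates; h and the scale parameters use adaptive random-walk steps tuned
# during warm-up.

#' Fit the hierarchical quadratic transfer-distance model
#'
#' Fits, for one trait and one environmental variable, the Bayesian model of
#' family phenotype against environment-of-origin described above.
#' Environmental covariates (accession values and trial values) are
#' standardized jointly before fitting; [summarize_transfer_posterior()]
#' back-transforms optima to the raw scale.
#'
#' @param blups BLUP table: tibble with columns `trial`, `tester`,
#'   `accession`, `trait`, `value` (z-scaled within trial).
#' @param env_of_origin Per-accession environment values: a two-column data
#'   frame (`accession`, `value`) or a named vector.
#' @param trial_env Per-trial environment values: a two-column data frame
#'   (`trial`, `value`) or a named vector.
#' @param trait Trait name to fit.
#' @param constrain_negative Constrain curvatures `a_i` to be non-positive
#'   (the local-adaptation prior); set `FALSE` for the unconstrained
#'   variant.
#' @param chains Number of MCMC chains.
#' @param iterations Iterations per chain, warm-up included; the first half
#'   is discarded as warm-up.
#' @param seed Integer seed.
#' @param rhat_max Convergence contract: the fit errors if any parameter's
#'   split-Rhat exceeds this bound.
#' @return An object of class `transfer_fit` with posterior draws,
#'   per-parameter diagnostics and the standardization metadata.
#' @export
fit_transfer_model <- function(blups, env_of_origin, trial_env, trait,
                               constrain_negative = TRUE,
                               chains = 4, iterations = 2000, seed = 1,
                               rhat_max = 1.1) {
  env_of_origin <- as_named_values(env_of_origin, "accession")
  trial_env <- as_named_values(trial_env, "trial")
  d <- blups[blups$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) {
    stop_landrace(paste0("trait not present in blups: ", trait),
                  "landrace_value_error")
  }
  d <- d[d$trial %in% names(trial_env) &
           d$accession %in% names(env_of_origin), , drop = FALSE]
  trials <- sort(unique(d$trial))
  if (length(unique(round(trial_env[trials], 10))) < 3) {
    stop_landrace("need >= 3 distinct trial environment values to identify beta_h",
                  "landrace_value_error")
  }
  std <- pooled_standardization(env_of_origin[unique(d$accession)],
                                trial_env[trials])
  x <- (env_of_origin[d$accession] - std$mean) / std$sd
  X <- (trial_env[trials] - std$mean) / std$sd
  ti <- match(d$trial, trials)
  groups <- paste(d$trial, d$tester, sep = ":")
  glev <- sort(unique(groups))
  gi <- match(groups, glev)
  g_trial <- match(sub(":.*$", "", glev), trials)
  y <- d$value

  n_i <- tabulate(ti, length(trials))
  n_g <- tabulate(gi, length(glev))

  warmup <- floor(iterations / 2)
  keep <- iterations - warmup
  par_names <- c("mu_c", "mu_h", "beta_h", "sigma_c", "sigma_h",
                 paste0("a[", trials, "]"), paste0("h[", trials, "]"),
                 paste0("sigma_e[", trials, "]"), paste0("c[", glev, "]"))
  draws <- vector("list", chains)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    draws[[ch]] <- run_transfer_chain(
      y = y, x = x, X = X, ti = ti, gi = gi, g_trial = g_trial,
      n_i = n_i, n_g = n_g, iterations = iterations, warmup = warmup,
      constrain_negative = constrain_negative, par_names = par_names
    )
  }

  diag_tbl <- tibble::tibble(
    parameter = par_names,
    rhat = vapply(seq_along(par_names), function(j) {
      split_rhat(sapply(draws, function(m) m[, j]))
    }, numeric(1)),
    ess = vapply(seq_along(par_names), function(j) {
      ess_basic(sapply(draws, function(m) m[, j]))
    }, numeric(1))
  )
  fit <- structure(
    list(draws = draws, parameters = par_names, diagnostics = diag_tbl,
         trials = trials, groups = glev, trait = trait,
         standardization = std, trial_env = trial_env[trials],
         constrain_negative = constrain_negative,
         chains = chains, iterations = iterations, warmup = warmup,
         n_obs = length(y), seed = seed),
    class = "transfer_fit"
  )
  bad <- diag_tbl$parameter[!is.na(diag_tbl$rhat) & diag_tbl$rhat > rhat_max]
  if (length(bad)) {
    stop_landrace(
      sprintf("transfer model did not converge (split-Rhat > %.2f): %s",
              rhat_max, paste(utils::head(bad, 5), collapse = ", ")),
      "landrace_convergence_error"
    )
  }
  fit
}

as_named_values <- function(x, key) {
  if (is.data.frame(x)) {
    val_col <- setdiff(names(x), key)
    if (!key %in% names(x) || length(val_col) < 1) {
      stop_landrace(sprintf("expected columns `%s` and a value column", key),
                    "landrace_value_error")
    }
    setNames(x[[val_col[1]]], x[[key]])
  } else if (!is.null(names(x))) {
    x
  } else {
    stop_landrace("environment values must be a data frame or named vector",
                  "landrace_value_error")
  }
}

run_transfer_chain <- function(y, x, X, ti, gi, g_trial, n_i, n_g,
                               iterations, warmup, constrain_negative,
                               par_names) {
  I <- length(X)
  Gn <- length(n_g)

  # initial values, jittered per chain; the compiled core runs the updates
  cg <- as.numeric(tapply(y, factor(gi, levels = seq_len(Gn)), mean)) +
    rnorm(Gn, 0, 0.1)
  cg[is.na(cg)] <- 0
  h <- X + rnorm(I, 0, 0.2)
  a <- if (constrain_negative) -abs(rnorm(I, 0.5, 0.2)) else rnorm(I, 0, 0.5)
  mu_c <- mean(cg)
  fit0 <- lm.fit(cbind(1, X), h)
  mu_h <- fit0$coefficients[1] + rnorm(1, 0, 0.1)
  beta_h <- fit0$coefficients[2] + rnorm(1, 0, 0.1)
  if (!is.finite(beta_h)) beta_h <- rnorm(1)
  sigma_c <- max(sd(cg), 0.1)
  sigma_h <- 0.3
  sigma_e <- vapply(split(y - cg[gi], factor(ti, levels = seq_len(I))),
                    function(r) max(sd(r), 0.05, na.rm = TRUE), numeric(1))
  sigma_e[!is.finite(sigma_e)] <- 0.5

  out <- .transfer_chain_cpp(
    y, x, unname(X), as.integer(ti), as.integer(gi), as.integer(g_trial),
    as.numeric(n_i), as.numeric(n_g), as.integer(iterations),
    as.integer(warmup), isTRUE(constrain_negative),
    cg, a, unname(h), mu_c, unname(mu_h), unname(beta_h),
    sigma_c, sigma_h, sigma_e
  )
  colnames(out) <- par_names
  if (anyNA(out) || any(!is.finite(out))) {
    bad <- par_names[apply(out, 2, function(v) any(!is.finite(v)))]
    stop_landrace(paste0("sampler produced non-finite draws for: ",
                         paste(utils::head(bad, 5), collapse = ", ")),
                  "landrace_divergence_error")
  }
  out
}

adapt_step <- function(step, accepted, it) {
  gamma <- 1 / sqrt(it)
  pmin(pmax(step * exp(gamma * (as.numeric(accepted) - 0.44)), 1e-4), 10)
}

#' @export
print.transfer_fit <- function(x, ...) {
  b <- extract_param(x, "beta_h")
  cat(sprintf(
    "<transfer_fit> trait %s: %d trials, %d obs, %d chains x %d kept draws\n",
    x$trait, length(x$trials), x$n_obs, x$chains, x$iterations - x$warmup))
  cat(sprintf("  beta_h: mean %.3f, 95%% CI [%.3f, %.3f], max Rhat %.3f\n",
              mean(b), quantile(b, 0.025), quantile(b, 0.975),
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

# Pooled posterior draws (all chains) for one parameter name.
extract_param <- function(fit, name) {
  j <- match(name, fit$parameters)
  if (is.na(j)) {
    stop_landrace(paste0("unknown parameter: ", name), "landrace_value_error")
  }
  unlist(lapply(fit$draws, function(m) m[, j]), use.names = FALSE)
}

#' Summarize the transfer-model posterior
#'
#' Reports per-trial optimum summaries on the raw environmental scale
#' (posterior mean and central 95% interval of `h_i`, back-transformed by
#' inverting the joint standardization) and the `beta_h` posterior: mean,
#' central interval, posterior probability of a positive slope, and whether
#' the interval contains 1 (perfect home-site matching).
#'
#' @param fit A `transfer_fit`.
#' @param level Credible-interval level.
#' @return List of class `transfer_summary` with tibbles `optima` and
#'   `beta`.
#' @export
summarize_transfer_posterior <- function(fit, level = 0.95) {
  alpha <- (1 - level) / 2
  std <- fit$standardization
  optima <- purrr::map_dfr(seq_along(fit$trials), function(i) {
    hstd <- extract_param(fit, paste0("h[", fit$trials[i], "]"))
    hraw <- std$mean + std$sd * hstd
    tibble::tibble(
      trial = fit$trials[i],
      trial_env = unname(fit$trial_env[i]),
      optimum_mean = mean(hraw),
      optimum_lo = unname(quantile(hraw, alpha)),
      optimum_hi = unname(quantile(hraw, 1 - alpha))
    )
  })
  b <- extract_param(fit, "beta_h")
  beta <- tibble::tibble(
    mean = mean(b),
    lo = unname(quantile(b, alpha)),
    hi = unname(quantile(b, 1 - alpha)),
    p_positive = mean(b > 0),
    contains_one = unname(quantile(b, alpha) <= 1 & quantile(b, 1 - alpha) >= 1)
  )
  structure(list(optima = optima, beta = beta, trait = fit$trait,
                 level = level),
            class = "transfer_summary")
}

#' @export
print.transfer_summary <- function(x, ...) {
  cat(sprintf("<transfer_summary> trait %s\n", x$trait))
  cat(sprintf("  beta_h: %.3f [%.3f, %.3f], P(beta_h > 0) = %.3f, contains 1: %s\n",
              x$beta$mean, x$beta$lo, x$beta$hi, x$beta$p_positive,
              x$beta$contains_one))
  print(x$optima)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_transfer_model
#' @param x A `transfer_fit`.
#' @param ... Unused.
#' @method tidy transfer_fit
#' @export
tidy.transfer_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$parameters), function(j) {
    v <- unlist(lapply(x$draws, function(m) m[, j]), use.names = FALSE)
    tibble::tibble(
      term = x$parameters[j],
      estimate = mean(v),
      std.error = sd(v),
      conf.low = unname(quantile(v, 0.025)),
      conf.high = unname(quantile(v, 0.975)),
      rhat = x$diagnostics$rhat[j],
      ess = x$diagnostics$ess[j]
    )
  })
}

#' @rdname fit_transfer_model
#' @method glance transfer_fit
#' @export
glance.transfer_fit <- function(x, ...) {
  b <- extract_param(x, "beta_h")
  tibble::tibble(
    trait = x$trait,
    n_obs = x$n_obs,
    n_trials = length(x$trials),
    beta_h = mean(b),
    beta_h_lo = unname(quantile(b, 0.025)),
    beta_h_hi = unname(quantile(b, 0.975)),
    p_positive = mean(b > 0),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}
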