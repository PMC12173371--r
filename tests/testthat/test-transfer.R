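# Hierarchical Bayesian quadratic transfer-distance model.

# Build a dataset directly from the model equation (no generator), so the
# fit is an exact-model recovery problem.
make_exact_transfer_data <- function(n_trials = 6, n_fam = 120, a = -1,
                                     noise = 0.05, seed = 1) {
  set.seed(seed)
  trials <- sprintf("T%02d", seq_len(n_trials))
  X <- seq(-1.2, 1.2, length.out = n_trials)
  rows <- lapply(seq_len(n_trials), function(i) {
    x <- runif(n_fam, -1.8, 1.8)
    y <- a * (x - X[i])^2 + rnorm(n_fam, 0, noise)
    tibble::tibble(
      trial = trials[i],
      tester = rep(c("tA", "tB"), length.out = n_fam),
      accession = sprintf("%s_f%03d", trials[i], seq_len(n_fam)),
      trait = "FW", value = y, x = x
    )
  })
  d <- dplyr::bind_rows(rows)
  list(
    blups = d[, c("trial", "tester", "accession", "trait", "value")],
    env_of_origin = setNames(d$x, d$accession),
    trial_env = setNames(X, trials)
  )
}

test_that("exact-model data recover the optima and a unit slope", {
  td <- make_exact_transfer_data(seed = 3)
  fit <- fit_transfer_model(td$blups, td$env_of_origin, td$trial_env, "FW",
                            chains = 2, iterations = 5000, seed = 7)
  s <- summarize_transfer_posterior(fit)
  # x and X enter the fit jointly standardized; optima are reported back on
  # the input scale, so they should match the trial environments
  expect_lt(max(abs(s$optima$optimum_mean - s$optima$trial_env)), 0.1)
  expect_true(s$beta$lo <= 1 && s$beta$hi >= 1)
  expect_true(s$beta$contains_one)
  expect_gt(s$beta$p_positive, 0.99)
  # posterior curvature is close to truth on the standardized scale
  a_means <- sapply(fit$trials, function(tr) {
    mean(landrace:::extract_param(fit, paste0("a[", tr, "]")))
  })
  expect_true(all(a_means < 0))
})

test_that("interval summaries equal direct quantile computations", {
  td <- make_exact_transfer_data(n_trials = 4, n_fam = 50, seed = 5)
  fit <- fit_transfer_model(td$blups, td$env_of_origin, td$trial_env, "FW",
                            chains = 2, iterations = 4000, seed = 2)
  s <- summarize_transfer_posterior(fit)
  b <- landrace:::extract_param(fit, "beta_h")
  expect_equal(s$beta$lo, unname(quantile(b, 0.025)))
  expect_equal(s$beta$hi, unname(quantile(b, 0.975)))
  expect_equal(s$beta$mean, mean(b))
  h1 <- landrace:::extract_param(fit, paste0("h[", fit$trials[1], "]"))
  raw <- fit$standardization$mean + fit$standardization$sd * h1
  expect_equal(s$optima$optimum_lo[1], unname(quantile(raw, 0.025)))
  # degenerate posterior: all draws equal one
  fit2 <- fit
  j <- match("beta_h", fit2$parameters)
  for (ch in seq_along(fit2$draws)) fit2$draws[[ch]][, j] <- 1
  s2 <- summarize_transfer_posterior(fit2)
  expect_equal(c(s2$beta$lo, s2$beta$hi), c(1, 1))
  expect_true(s2$beta$contains_one)
})

test_that("shifting one trial's values moves only that trial's intercepts", {
  td <- make_exact_transfer_data(n_trials = 4, n_fam = 100, seed = 11)
  fit1 <- fit_transfer_model(td$blups, td$env_of_origin, td$trial_env, "FW",
                             chains = 2, iterations = 5000, seed = 9)
  shifted <- td$blups
  shifted$value[shifted$trial == "T02"] <-
    shifted$value[shifted$trial == "T02"] + 0.7
  fit2 <- fit_transfer_model(shifted, td$env_of_origin, td$trial_env, "FW",
                             chains = 2, iterations = 5000, seed = 9)
  t1 <- tidy(fit1)
  t2 <- tidy(fit2)
  pick <- function(tt, pat) tt$estimate[grepl(pat, tt$term)]
  # shifted trial's tester intercepts move by ~0.7
  expect_equal(pick(t2, "^c\\[T02"), pick(t1, "^c\\[T02") + 0.7,
               tolerance = 0.1)
  # curvature and optima essentially unchanged (MCMC tolerance)
  expect_equal(pick(t2, "^h\\["), pick(t1, "^h\\["), tolerance = 0.1)
  expect_equal(pick(t2, "^a\\["), pick(t1, "^a\\["), tolerance = 0.15)
})

test_that("the unconstrained variant recovers convex truth", {
  td <- make_exact_transfer_data(a = +0.8, noise = 0.1, seed = 13)
  fit <- fit_transfer_model(td$blups, td$env_of_origin, td$trial_env, "FW",
                            constrain_negative = FALSE,
                            chains = 2, iterations = 4000, seed = 3)
  a_means <- sapply(fit$trials, function(tr) {
    mean(landrace:::extract_param(fit, paste0("a[", tr, "]")))
  })
  expect_true(all(a_means > 0))
  # constrained fit on the same data keeps every curvature draw <= 0
  fitc <- fit_transfer_model(td$blups, td$env_of_origin, td$trial_env, "FW",
                             constrain_negative = TRUE,
                             chains = 2, iterations = 1000, seed = 3,
                             rhat_max = Inf)
  a_draws <- unlist(lapply(fitc$trials, function(tr) {
    landrace:::extract_param(fitc, paste0("a[", tr, "]"))
  }))
  expect_true(all(a_draws <= 0))
})

test_that("the sampler agrees with an independent JAGS implementation", {
  skip_if_not_installed("rjags")
  ds <- generate_dataset(synth_config(
    n_accessions = 150, n_snps = 100, n_trials = 5,
    families_per_trial = 60, a_true = -1, seed = 77
  ))
  ev <- setNames(ds$env$elevation, ds$env$sample_id)
  te <- setNames(ds$trials$elevation, ds$trials$trial)
  fit <- fit_transfer_model(ds$blups, ev, te, "FW",
                            chains = 4, iterations = 6000, seed = 5)
  g <- glance(fit)

  d <- ds$blups
  trials <- sort(unique(d$trial))
  std <- landrace:::pooled_standardization(ev[unique(d$accession)],
                                           te[trials])
  x <- (ev[d$accession] - std$mean) / std$sd
  X <- (te[trials] - std$mean) / std$sd
  ti <- match(d$trial, trials)
  glev <- sort(unique(paste(d$trial, d$tester, sep = ":")))
  gi <- match(paste(d$trial, d$tester, sep = ":"), glev)
  model_str <- "model{
    for (k in 1:N) {
      y[k] ~ dnorm(c[g[k]] + a[t[k]] * pow(x[k] - h[t[k]], 2), tau_e[t[k]])
    }
    for (j in 1:G) { c[j] ~ dnorm(mu_c, pow(sigma_c, -2)) }
    for (i in 1:I) {
      a[i] ~ dnorm(0, 1) T(, 0)
      h[i] ~ dnorm(mu_h + beta_h * X[i], pow(sigma_h, -2))
      sigma_e[i] ~ dt(0, pow(2.5, -2), 3) T(0, )
      tau_e[i] <- pow(sigma_e[i], -2)
    }
    mu_c ~ dnorm(0, 1)
    mu_h ~ dnorm(0, 1)
    beta_h ~ dnorm(0, pow(3, -2))
    sigma_c ~ dt(0, pow(2.5, -2), 3) T(0, )
    sigma_h ~ dt(0, pow(2.5, -2), 3) T(0, )
  }"
  set.seed(1)
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = d$value, x = unname(x),
                                      X = unname(X), t = ti, g = gi,
                                      N = nrow(d), G = length(glev),
                                      I = length(trials)),
                          n.chains = 2, quiet = TRUE)
  update(jm, 3000, progress.bar = "none")
  sam <- rjags::coda.samples(jm, "beta_h", 4000, progress.bar = "none")
  jb <- unlist(lapply(sam, as.numeric))
  expect_lt(abs(g$beta_h - mean(jb)), 0.1)
  expect_lt(abs(g$beta_h_lo - quantile(jb, 0.025)), 0.15)
  expect_lt(abs(g$beta_h_hi - quantile(jb, 0.975)), 0.15)
})

test_that("degenerate inputs are refused with informative errors", {
  td <- make_exact_transfer_data(n_trials = 2, n_fam = 30, seed = 17)
  expect_error(
    fit_transfer_model(td$blups, td$env_of_origin, td$trial_env, "FW"),
    "3 distinct", class = "landrace_value_error"
  )
  td3 <- make_exact_transfer_data(n_trials = 4, n_fam = 30, seed = 17)
  expect_error(
    fit_transfer_model(td3$blups, td3$env_of_origin, td3$trial_env, "ZZZ"),
    class = "landrace_value_error"
  )
})

test_that("prior-predictive simulation yields uniform posterior ranks for the slope", {
  # simulation-based calibration at reduced scale: draw parameters from the
  # model priors, simulate data, fit, and rank the true slope among thinned
  # posterior draws; ranks should be uniform
  L <- 24
  ranks <- c()
  for (rep in 1:50) {
    set.seed(9500 + rep)
    I <- 4
    nf <- 25
    X <- seq(-1, 1, length.out = I)
    mu_c <- rnorm(1)
    sigma_c <- abs(rt(1, 3)) * 2.5
    mu_h <- rnorm(1)
    beta_h <- rnorm(1, 0, 3)
    sigma_h <- abs(rt(1, 3)) * 2.5
    a <- -abs(rnorm(I))
    h <- mu_h + beta_h * X + sigma_h * rnorm(I)
    sigma_e <- abs(rt(I, 3)) * 2.5
    trials <- sprintf("T%d", seq_len(I))
    rows <- lapply(seq_len(I), function(i) {
      x <- runif(nf, -1.5, 1.5)
      cg <- rnorm(2, mu_c, sigma_c)
      tester <- rep(c("a", "b"), length.out = nf)
      y <- cg[match(tester, c("a", "b"))] + a[i] * (x - h[i])^2 +
        rnorm(nf, 0, sigma_e[i])
      tibble::tibble(trial = trials[i], tester = tester,
                     accession = sprintf("%s_%d", trials[i], seq_len(nf)),
                     trait = "FW", value = y, x = x)
    })
    d <- dplyr::bind_rows(rows)
    fit <- tryCatch(
      fit_transfer_model(d[, 1:5], setNames(d$x, d$accession),
                         setNames(X, trials), "FW", chains = 1,
                         iterations = 1200, seed = rep, rhat_max = Inf),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    b <- landrace:::extract_param(fit, "beta_h")
    thin <- b[round(seq(1, length(b), length.out = L - 1))]
    ranks <- c(ranks, sum(thin < beta_h))
  }
  counts <- table(cut(ranks, breaks = seq(-0.5, L - 0.5, length.out = 7)))
  expect_gt(chisq.test(as.integer(counts))$p.value, 0.01)
})
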