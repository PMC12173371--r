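# Phenotype preparation, the prediction model suite, and single-component
# mixed-model machinery (REML by eigendecomposition).

#' Prepare family BLUPs for prediction
#'
#' Applies the phenotype quality filters: for each trait, trials with
#' heritability at or below `h2_min` are dropped; trial-trait-tester groups
#' with fewer than `min_unique` unique values are dropped; optionally BLUPs
#' are deregressed by dividing by their reliability
#' \eqn{1 - PEV/\sigma^2_g} (requires `pev` and `sigma2_g` columns); and
#' values are z-scaled within trial and trait.
#'
#' @param blups Tibble with `trial`, `tester`, `accession`, `trait`,
#'   `value`, and `h2` (per trial-trait) when `h2_min > 0`.
#' @param h2_min Heritability threshold (trials kept when `h2 > h2_min`).
#' @param min_unique Minimum unique values per trial:trait:tester group.
#' @param deregress Divide by reliability before scaling.
#' @return Filtered, z-scaled BLUP tibble.
#' @export
prepare_blups <- function(blups, h2_min = 0.1, min_unique = 10,
                          deregress = FALSE) {
  d <- tibble::as_tibble(blups)
  if (h2_min > 0) {
    if (!"h2" %in% names(d)) {
      stop_landrace("h2 metadata column required when h2_min > 0",
                    "landrace_value_error")
    }
    d <- d[d$h2 > h2_min, , drop = FALSE]
  }
  if (deregress) {
    if (!all(c("pev", "sigma2_g") %in% names(d))) {
      stop_landrace("deregression requires `pev` and `sigma2_g` columns",
                    "landrace_value_error")
    }
    rel <- 1 - d$pev / d$sigma2_g
    if (any(rel <= 0)) {
      stop_landrace("non-positive reliability; cannot deregress",
                    "landrace_value_error")
    }
    d$value <- d$value / rel
  }
  d <- dplyr::group_by(d, .data$trial, .data$trait, .data$tester)
  d <- dplyr::filter(d, dplyr::n_distinct(.data$value) >= min_unique)
  d <- dplyr::ungroup(d)
  if (nrow(d) == 0) {
    stop_landrace("no data remain after phenotype filters",
                  "landrace_empty_error")
  }
  d <- dplyr::group_by(d, .data$trial, .data$trait)
  d <- dplyr::mutate(d, value = as.numeric(scale(.data$value)))
  dplyr::ungroup(d)
}

#' Single-variance-component mixed model with test-set prediction
#'
#' Solves \eqn{y = X\beta + Zu + e} by REML profiled over
#' \eqn{\lambda = \sigma^2_u/\sigma^2_e} on the eigendecomposition of the
#' random-effect covariance. Exactly one of `K` (genomic relationship:
#' GBLUP) or `Z_markers` (shared-variance marker effects, the ridge
#' equivalent) may be supplied; with neither, the model is the
#' fixed-effects-only least-squares fit. Collinear fixed-effect columns are
#' dropped with a message.
#'
#' @param y Numeric response.
#' @param fixed Fixed-effect design matrix (including intercept), rows
#'   aligned with `y`.
#' @param K Optional covariance matrix of the random effect over all rows.
#' @param Z_markers Optional marker dosage matrix over all rows.
#' @param train,test Row indices (or logicals) for training and test sets.
#' @return List of class `gblup_fit`: `predictions` (test rows), `beta`,
#'   `lambda`, `sigma2_e`, `sigma2_u`, `h2`.
#' @export
fit_gblup_model <- function(y, fixed, K = NULL, Z_markers = NULL,
                            train, test) {
  if (!is.null(K) && !is.null(Z_markers)) {
    stop_landrace("supply at most one of K / Z_markers",
                  "landrace_value_error")
  }
  train <- to_indices(train, length(y))
  test <- to_indices(test, length(y))
  if (length(intersect(train, test))) {
    stop_landrace("train and test overlap", "landrace_leakage_error")
  }
  X <- as.matrix(fixed)
  Xt <- X[train, , drop = FALSE]
  qx <- qr(Xt)
  if (qx$rank < ncol(Xt)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    message(sprintf("dropping %d collinear fixed-effect column(s)",
                    ncol(Xt) - qx$rank))
    X <- X[, keep, drop = FALSE]
    Xt <- X[train, , drop = FALSE]
  }
  yt <- y[train]

  if (is.null(K) && is.null(Z_markers)) {
    fit <- lm.fit(Xt, yt)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- as.numeric(X[test, , drop = FALSE] %*% beta)
    return(structure(list(predictions = pred, beta = beta, lambda = 0,
                          sigma2_e = mean(fit$residuals^2), sigma2_u = 0,
                          h2 = 0),
                     class = "gblup_fit"))
  }

  marker_mode <- !is.null(Z_markers)
  if (marker_mode) {
    Z <- as.matrix(Z_markers)
    Ktt <- tcrossprod(Z[train, , drop = FALSE])
  } else {
    Kv <- kinship_values(K)
    Ktt <- Kv[train, train, drop = FALSE]
  }
  eK <- eigen((Ktt + t(Ktt)) / 2, symmetric = TRUE)
  dv <- pmax(eK$values, 0)
  Q <- eK$vectors
  ys <- as.numeric(crossprod(Q, yt))
  Xs <- crossprod(Q, Xt)
  n <- length(ys)
  p <- ncol(Xs)

  reml <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * dv + 1)
    XtWX <- crossprod(Xs, w * Xs)
    b <- tryCatch(solve(XtWX, crossprod(Xs, w * ys)),
                  error = function(e) NULL)
    if (is.null(b)) return(list(ll = -Inf))
    r <- ys - Xs %*% b
    s2 <- sum(w * r^2) / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) - sum(log(w)) +
                    determinant(XtWX, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), b = b, s2 = s2, w = w, r = r, lam = lam)
  }
  opt <- optimize(function(l) reml(l)$ll, interval = c(-12, 12),
                  maximum = TRUE, tol = 1e-6)
  sol <- reml(opt$maximum)
  beta <- as.numeric(sol$b)
  # BLUP of random effects: u_hat = lambda * C' Q (w * r_rotated)
  core <- sol$lam * (sol$w * as.numeric(sol$r))
  if (marker_mode) {
    alpha <- as.numeric(crossprod(Z[train, , drop = FALSE],
                                  Q %*% core))
    u_test <- as.numeric(Z[test, , drop = FALSE] %*% alpha)
  } else {
    u_test <- as.numeric(Kv[test, train, drop = FALSE] %*% (Q %*% core))
  }
  pred <- as.numeric(X[test, , drop = FALSE] %*% beta) + u_test
  structure(
    list(predictions = pred, beta = beta, lambda = sol$lam,
         sigma2_e = sol$s2, sigma2_u = sol$lam * sol$s2,
         h2 = sol$lam / (sol$lam + 1)),
    class = "gblup_fit"
  )
}

to_indices <- function(x, n) {
  if (is.logical(x)) which(x) else as.integer(x)
}

#' Random-forest prediction from environmental features
#'
#' Regression forest (default regression feature-subsampling rule,
#' `mtry = max(1, p/3)`), deterministic given the seed.
#'
#' @param y Numeric response.
#' @param features Data frame or matrix of predictor variables.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @param train,test Row indices or logicals.
#' @return Numeric predictions for the test rows.
#' @export
fit_rf_model <- function(y, features, n_trees = 1000, seed = 1, train, test) {
  train <- to_indices(train, length(y))
  test <- to_indices(test, length(y))
  if (length(train) < 5) {
    stop_landrace("fewer than 5 training rows for the forest",
                  "landrace_value_error")
  }
  df <- as.data.frame(features)
  colnames(df) <- make.names(colnames(df), unique = TRUE)
  dtr <- df[train, , drop = FALSE]
  dtr$.y <- y[train]
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dtr,
    num.trees = n_trees, mtry = max(1, floor(ncol(df) / 3)),
    seed = seed, num.threads = 1
  )
  as.numeric(predict(fit, df[test, , drop = FALSE],
                     num.threads = 1)$predictions)
}

MODEL_NAMES <- c("pc_only", "pc_envgwas_snps", "pc_random_snps", "all_snps",
                 "all_snps_env", "env_linear", "env_rf", "env_pc_rf")

#' Run the prediction-model benchmark
#'
#' For every trial and every tester fold within it, trains each requested
#' model on the families of all other testers in that trial (responses
#' corrected for tester via training-estimated tester means) and predicts
#' the held-out tester's families, recording within-fold Pearson r. Models:
#' principal components only (`pc_only`), PCs plus envGWAS lead SNPs or
#' MAF-matched random SNPs as shared-variance marker effects
#' (`pc_envgwas_snps`, `pc_random_snps`), the all-SNPs GBLUP with and
#' without environmental fixed effects (`all_snps`, `all_snps_env`), a
#' linear environment-of-origin model (`env_linear`), and random forests on
#' environment data without and with PCs (`env_rf`, `env_pc_rf`).
#' Principal components are recomputed from the kinship of the accessions
#' present in each trial.
#'
#' @param blups Prepared BLUP tibble (see [prepare_blups()]).
#' @param geno A [geno_matrix()].
#' @param env Accession environment tibble with `*_int` columns.
#' @param design Testcross design tibble.
#' @param models Subset of the eight model names.
#' @param envgwas_leads Lead SNP ids (required for `pc_envgwas_snps`;
#'   `pc_random_snps` MAF-matches against these).
#' @param trait Trait to benchmark.
#' @param n_pcs Number of kinship eigenvectors used as features.
#' @param n_trees Trees for the forest models.
#' @param seed Integer seed (forest and random-SNP draws).
#' @return Tibble of class `prediction_scores`: `trial`, `model`, `fold`
#'   (tester), `r`, `n`.
#' @export
run_model_suite <- function(blups, geno, env, design,
                            models = c("pc_only", "all_snps", "env_linear"),
                            envgwas_leads = NULL, trait, n_pcs = 5,
                            n_trees = 1000, seed = 1) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  if ("pc_envgwas_snps" %in% models && is.null(envgwas_leads)) {
    stop_landrace("pc_envgwas_snps requires envgwas_leads",
                  "landrace_value_error")
  }
  d_all <- blups[blups$trait == trait, , drop = FALSE]
  if (nrow(d_all) == 0) {
    stop_landrace(paste0("trait not present: ", trait),
                  "landrace_value_error")
  }
  Kfull <- compute_grm(geno)
  env_cols <- paste0(ENV_VARS, "_int")
  env_cols <- env_cols[env_cols %in% names(env)]
  env_mat <- as.matrix(env[, env_cols])
  rownames(env_mat) <- env$sample_id

  random_snps <- NULL
  if ("pc_random_snps" %in% models) {
    if (is.null(envgwas_leads)) {
      stop_landrace("pc_random_snps requires envgwas_leads for MAF matching",
                    "landrace_value_error")
    }
    random_snps <- sample_maf_matched(geno, envgwas_leads, n_sets = 1,
                                      seed = derive_seed(seed, "clump"))[[1]]
  }

  out <- list()
  for (tr in sort(unique(d_all$trial))) {
    d <- d_all[d_all$trial == tr, , drop = FALSE]
    testers <- sort(unique(d$tester))
    if (length(testers) < 2) {
      message(sprintf("trial %s has a single tester; skipped", tr))
      next
    }
    acc <- d$accession
    Ksub <- Kfull$values[acc, acc, drop = FALSE]
    eK <- eigen((Ksub + t(Ksub)) / 2, symmetric = TRUE)
    pcs <- eK$vectors[, seq_len(min(n_pcs, ncol(eK$vectors))), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    ev <- env_mat[acc, , drop = FALSE]
    y <- d$value

    for (f in seq_along(testers)) {
      test <- which(d$tester == testers[f])
      train <- which(d$tester != testers[f])
      stopifnot(length(intersect(train, test)) == 0)
      if (length(test) < 3) {
        for (mod in models) {
          out[[length(out) + 1]] <- tibble::tibble(
            trial = tr, model = mod, fold = testers[f],
            r = NA_real_, n = length(test))
        }
        next
      }
      # tester correction from training rows only
      tm <- tapply(y[train], d$tester[train], mean)
      yc <- y
      yc[train] <- y[train] - tm[d$tester[train]]

      base_pc <- cbind(1, pcs)
      for (mod in models) {
        r <- tryCatch({
          pred <- switch(
            mod,
            pc_only = fit_gblup_model(yc, base_pc, train = train,
                                      test = test)$predictions,
            pc_envgwas_snps = fit_gblup_model(
              yc, base_pc,
              Z_markers = geno$dosages[acc, envgwas_leads, drop = FALSE],
              train = train, test = test)$predictions,
            pc_random_snps = fit_gblup_model(
              yc, base_pc,
              Z_markers = geno$dosages[acc, random_snps, drop = FALSE],
              train = train, test = test)$predictions,
            all_snps = fit_gblup_model(yc, base_pc, K = Ksub, train = train,
                                       test = test)$predictions,
            all_snps_env = fit_gblup_model(yc, cbind(base_pc, ev), K = Ksub,
                                           train = train,
                                           test = test)$predictions,
            env_linear = fit_gblup_model(yc, cbind(1, ev), train = train,
                                         test = test)$predictions,
            env_rf = fit_rf_model(yc, ev, n_trees = n_trees,
                                  seed = derive_seed(seed, "bench"),
                                  train = train, test = test),
            env_pc_rf = fit_rf_model(yc, cbind(ev, pcs), n_trees = n_trees,
                                     seed = derive_seed(seed, "bench"),
                                     train = train, test = test)
          )
          suppressWarnings(cor(pred, y[test]))
        }, error = function(e) NA_real_)
        out[[length(out) + 1]] <- tibble::tibble(
          trial = tr, model = mod, fold = testers[f],
          r = r, n = length(test))
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("prediction_scores", class(res))
  res
}

#' Analytic accuracy expected from variance explained
#'
#' Under the standard argument that predictive accuracy approximates the
#' square root of the fraction of (genetic) variance captured by the
#' features, returns \eqn{\sqrt{v}}; e.g. features explaining 5% of
#' variance support an accuracy of about 0.22.
#'
#' @param variance_explained Fraction in \[0, 1\].
#' @return Expected predictive accuracy (Pearson r scale).
#' @export
#' @examples
#' expected_accuracy_from_variance(0.05)
expected_accuracy_from_variance <- function(variance_explained) {
  if (any(variance_explained < 0 | variance_explained > 1)) {
    stop_landrace("variance_explained must lie in [0, 1]",
                  "landrace_value_error")
  }
  sqrt(variance_explained)
}
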