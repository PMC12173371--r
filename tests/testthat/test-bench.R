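# Phenotype filters, the mixed-model/forest predictors, the model suite
# and the accuracy comparison.

test_that("prepare_blups applies heritability and uniqueness filters", {
  b <- tidyr::expand_grid(trial = c("T1", "T2"), tester = c("a", "b"),
                          accession = sprintf("f%02d", 1:12))
  b$trait <- "FW"
  set.seed(81)
  b$value <- rnorm(nrow(b))
  b$h2 <- ifelse(b$trial == "T1", 0.09, 0.5)
  out <- prepare_blups(b, h2_min = 0.1, min_unique = 10)
  expect_false("T1" %in% out$trial)   # h2 = 0.09 dropped
  expect_true("T2" %in% out$trial)
  # the same low-h2 trial is retained for a different trait above threshold
  b2 <- b
  b2$trait <- "PH"
  b2$h2 <- 0.4
  out2 <- prepare_blups(dplyr::bind_rows(b, b2), h2_min = 0.1,
                        min_unique = 10)
  expect_true("T1" %in% out2$trial[out2$trait == "PH"])
  expect_false("T1" %in% out2$trial[out2$trait == "FW"])
  # unique-value threshold: 9 unique dropped (empty result errors), 10 kept
  mk <- function(nuniq) {
    tibble::tibble(trial = "T3", tester = "a",
                   accession = sprintf("g%02d", 1:12), trait = "FW",
                   value = c(seq_len(nuniq), rep(1, 12 - nuniq)), h2 = 0.5)
  }
  expect_equal(nrow(prepare_blups(mk(10))), 12)
  expect_error(prepare_blups(mk(9)), class = "landrace_empty_error")
})

test_that("deregression divides by reliability and errors without PEV", {
  b <- tibble::tibble(trial = "T1", tester = "a",
                      accession = sprintf("f%02d", 1:12), trait = "FW",
                      value = rnorm(12), h2 = 0.5)
  expect_error(prepare_blups(b, deregress = TRUE),
               class = "landrace_value_error")
  b$pev <- 0
  b$sigma2_g <- 1
  # reliability 1: deregression is the identity (up to the common z-scale)
  out1 <- prepare_blups(b, deregress = TRUE)
  out0 <- prepare_blups(b, deregress = FALSE)
  expect_equal(out1$value, out0$value)
  b2 <- b
  b2$pev <- 0.5
  out2 <- prepare_blups(b2, deregress = TRUE)
  # halving reliability doubles raw values; z-scaling makes them equal again
  expect_equal(out2$value, out0$value, tolerance = 1e-12)
})

test_that("tester folds partition families by tester", {
  des <- tibble::tibble(
    trial = "T1",
    tester = rep(c("a", "b", "c"), times = c(5, 4, 6)),
    accession = sprintf("f%02d", 1:15)
  )
  f <- make_tester_folds(des, "T1")
  expect_equal(length(unique(f$fold)), 3)
  expect_equal(as.integer(table(f$fold)), c(5, 4, 6))
  expect_equal(anyDuplicated(f$sample_id), 0)
  one <- des[des$tester == "a", ]
  expect_error(make_tester_folds(one, "T1"), class = "landrace_value_error")
})

test_that("GBLUP equals an explicit mixed-model-equation solve", {
  set.seed(83)
  n <- 30
  dos <- sapply(runif(120, 0.2, 0.8), function(p) rbinom(n, 2, p))
  K <- compute_grm(toy_geno(dos))$values
  u <- t(chol(K + diag(1e-6, n))) %*% rnorm(n) * 0.8
  y <- as.numeric(2 + u + rnorm(n, 0, 0.5))
  X <- cbind(1, rnorm(n))
  train <- 1:22
  test <- 23:30
  fit <- fit_gblup_model(y, X, K = K, train = train, test = test)
  # dense oracle at the fitted lambda: V = lam*K + I (residual scale out)
  lam <- fit$lambda
  V <- lam * K[train, train] + diag(length(train))
  Vi <- solve(V)
  Xt <- X[train, ]
  b <- solve(t(Xt) %*% Vi %*% Xt, t(Xt) %*% Vi %*% y[train])
  u_test <- lam * K[test, train] %*% Vi %*% (y[train] - Xt %*% b)
  oracle <- X[test, ] %*% b + u_test
  expect_equal(fit$predictions, as.numeric(oracle), tolerance = 1e-6)
})

test_that("marker random effects equal the kinship route built from them", {
  set.seed(84)
  n <- 40
  Z <- sapply(runif(15, 0.2, 0.8), function(p) rbinom(n, 2, p))
  y <- as.numeric(Z %*% rnorm(15, 0, 0.3) + rnorm(n, 0, 0.6))
  X <- matrix(1, n, 1)
  train <- 1:30
  test <- 31:40
  fm <- fit_gblup_model(y, X, Z_markers = Z, train = train, test = test)
  fk <- fit_gblup_model(y, X, K = tcrossprod(Z), train = train, test = test)
  expect_equal(fm$predictions, fk$predictions, tolerance = 1e-5)
  expect_error(fit_gblup_model(y, X, K = diag(n), Z_markers = Z,
                               train = train, test = test),
               class = "landrace_value_error")
  expect_error(fit_gblup_model(y, X, train = 1:20, test = 15:25),
               class = "landrace_leakage_error")
})

test_that("zero heritability collapses GBLUP to the fixed-effect fit", {
  set.seed(85)
  n <- 60
  X <- cbind(1, rnorm(n))
  y <- as.numeric(X %*% c(1, 2) + rnorm(n))
  K <- diag(n)
  train <- 1:45
  test <- 46:60
  fit_k <- fit_gblup_model(y, X, K = K, train = train, test = test)
  fit_0 <- fit_gblup_model(y, X, train = train, test = test)
  # with an identity K the off-diagonal cross-block is zero, so the random
  # part contributes nothing to held-out predictions
  expect_equal(fit_k$predictions, fit_0$predictions, tolerance = 0.05)
})

test_that("forest predictions are deterministic and track smooth signal", {
  set.seed(86)
  n <- 500
  f1 <- runif(n)
  feats <- data.frame(f1 = f1, f2 = runif(n), f3 = runif(n))
  y <- sin(2 * pi * f1) + rnorm(n, 0, 0.1)
  train <- 1:400
  test <- 401:500
  p1 <- fit_rf_model(y, feats, n_trees = 300, seed = 3, train = train,
                     test = test)
  p2 <- fit_rf_model(y, feats, n_trees = 300, seed = 3, train = train,
                     test = test)
  expect_identical(p1, p2)
  expect_gt(cor(p1, y[test]), 0.8)
  pc <- fit_rf_model(rep(1, n), feats, n_trees = 50, seed = 1,
                     train = train, test = test)
  expect_true(all(abs(pc - 1) < 1e-8))
  expect_error(fit_rf_model(y, feats, train = 1:3, test = 4:10),
               class = "landrace_value_error")
})

test_that("the model suite scores every trial-model-fold cell and repeats exactly", {
  ds <- small_dataset()
  geno <- filter_variants(ds$geno)
  blups <- prepare_blups(ds$blups, min_unique = 5)
  sc <- suppressMessages(run_model_suite(
    blups, geno, ds$env, ds$design,
    models = c("pc_only", "all_snps", "env_linear"), trait = "FW", seed = 5))
  expect_s3_class(sc, "prediction_scores")
  expect_equal(sort(unique(sc$model)),
               c("all_snps", "env_linear", "pc_only"))
  expect_true(all(sc$n >= 3 | is.na(sc$r)))
  sc2 <- suppressMessages(run_model_suite(
    blups, geno, ds$env, ds$design,
    models = c("pc_only", "all_snps", "env_linear"), trait = "FW", seed = 5))
  expect_identical(sc, sc2)
})

test_that("a tester-plus-noise phenotype gives near-zero predictive ability", {
  ds <- generate_dataset(synth_config(
    n_accessions = 250, n_snps = 300, n_trials = 4,
    families_per_trial = 150, h2_per_trait = 0, a_true = 0, seed = 87
  ))
  geno <- filter_variants(ds$geno)
  blups <- prepare_blups(ds$blups, h2_min = 0, min_unique = 5)
  sc <- suppressMessages(run_model_suite(
    blups, geno, ds$env, ds$design,
    models = c("pc_only", "all_snps", "env_linear"), trait = "FW", seed = 6))
  means <- tapply(sc$r, sc$model, mean, na.rm = TRUE)
  expect_true(all(abs(means) < 0.1))
})

test_that("model comparison flags planted gaps and ignores phantom ones", {
  set.seed(88)
  trials <- paste0("T", 1:6)
  folds <- paste0("f", 1:4)
  base <- tidyr::expand_grid(trial = trials, fold = folds)
  mk <- function(model, mu) {
    d <- base
    d$model <- model
    d$r <- mu + rnorm(nrow(d), 0, 0.02)
    d$n <- 30
    d
  }
  sc <- dplyr::bind_rows(mk("A", 0.5), mk("B", 0.3))
  class(sc) <- c("prediction_scores", class(sc))
  cmp <- suppressMessages(compare_models(sc))
  expect_lt(tidy(cmp)$adj.p.value[1], 0.01)
  expect_equal(tidy(cmp)$estimate[1], 0.2, tolerance = 0.05)
  # identical score vectors: adjusted p ~ 1
  a <- mk("A", 0.4)
  b <- a
  b$model <- "B"
  same2 <- dplyr::bind_rows(a, b)
  class(same2) <- c("prediction_scores", class(same2))
  cmp2 <- suppressMessages(compare_models(same2))
  expect_gt(tidy(cmp2)$adj.p.value[1], 0.95)
  expect_error(compare_models(mk("A", 0.5)), class = "landrace_value_error")
})

test_that("residual weighting treats a split fold like the whole", {
  set.seed(89)
  trials <- paste0("T", 1:5)
  folds <- paste0("f", 1:3)
  d <- tidyr::expand_grid(trial = trials, fold = folds,
                          model = c("A", "B"))
  d$r <- 0.3 + 0.1 * (d$model == "A") + rnorm(nrow(d), 0, 0.05)
  d$n <- 40
  cmp1 <- suppressMessages(compare_models(d))
  # duplicate one row with n halved: weighted estimates unchanged
  extra <- d[1, ]
  extra$n <- 20
  d2 <- dplyr::bind_rows(d, extra)
  d2$n[1] <- 20
  cmp2 <- suppressMessages(compare_models(d2))
  expect_equal(cmp1$emmeans$emmean, cmp2$emmeans$emmean, tolerance = 1e-6)
})

test_that("the analytic accuracy bound follows the square root law", {
  expect_equal(expected_accuracy_from_variance(0.05), sqrt(0.05))
  expect_equal(round(expected_accuracy_from_variance(0.05), 2), 0.22)
  expect_equal(expected_accuracy_from_variance(c(0, 1)), c(0, 1))
  expect_error(expected_accuracy_from_variance(1.5),
               class = "landrace_value_error")
})
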