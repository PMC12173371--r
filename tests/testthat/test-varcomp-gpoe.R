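# Multivariate variance components, genomic prediction of environment and
# the cross-validation machinery.

# Simulate Y with known (G, R) given a kinship matrix.
simulate_kron <- function(K, G, R, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  t_ <- nrow(G)
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eK$values, 0)
  U <- eK$vectors %*% (sqrt(d) * matrix(rnorm(n * t_), n, t_)) %*%
    chol(G + diag(1e-10, t_))
  E <- matrix(rnorm(n * t_), n, t_) %*% chol(R + diag(1e-10, t_))
  Y <- U + E
  rownames(Y) <- rownames(K) %||% paste0("s", seq_len(n))
  list(Y = Y, U = U)
}

structured_K <- function(n = 300, m = 800, seed = 2) {
  set.seed(seed)
  ds <- generate_dataset(synth_config(
    n_accessions = n, n_snps = m, n_trials = 3,
    families_per_trial = min(n, 50), seed = seed
  ))
  compute_grm(filter_variants(ds$geno))
}

test_that("identity kinship: G + R recovers the sample covariance", {
  set.seed(21)
  n <- 300
  G <- matrix(c(0.5, 0.2, 0.2, 0.4), 2, 2)
  R <- matrix(c(0.5, -0.1, -0.1, 0.6), 2, 2)
  sim <- simulate_kron(diag(n), G, R, seed = 3)
  vc <- suppressWarnings(
    estimate_multitrait_components(sim$Y, diag(n), resid_prior_df = 0))
  S <- cov(sim$Y)
  expect_lt(norm(vc$G + vc$R - S, "F") / norm(S, "F"), 0.05)
})

test_that("univariate heritability is recovered from structured kinship", {
  K <- structured_K(n = 300, m = 800, seed = 31)
  h2_hat <- c()
  for (rep in 1:5) {
    sim <- simulate_kron(K$values, matrix(0.5), matrix(0.5), seed = 100 + rep)
    vc <- suppressWarnings(
      estimate_multitrait_components(sim$Y, K, resid_prior_df = 0))
    h2_hat <- c(h2_hat, vc$G[1, 1] / (vc$G[1, 1] + vc$R[1, 1]))
  }
  expect_lt(abs(mean(h2_hat) - 0.5), 0.1)
})

test_that("genetic correlation is recovered at moderate n", {
  K <- structured_K(n = 300, m = 800, seed = 32)
  G <- matrix(c(1, 0.8 * sqrt(1 * 0.6), 0.8 * sqrt(1 * 0.6), 0.6), 2, 2)
  R <- diag(c(0.5, 0.5))
  rg <- c()
  for (rep in 1:3) {
    sim <- simulate_kron(K$values, G, R, seed = 200 + rep)
    vc <- suppressWarnings(
      estimate_multitrait_components(sim$Y, K, resid_prior_df = 0))
    rg <- c(rg, vc$G[1, 2] / sqrt(vc$G[1, 1] * vc$G[2, 2]))
  }
  expect_lt(abs(mean(rg) - 0.8), 0.15)
})

test_that("prediction reduces to column means when G = 0", {
  set.seed(41)
  n <- 40
  Y <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(paste0("s", 1:n), c("a", "b", "c")))
  K <- diag(n + 10)
  rownames(K) <- colnames(K) <- paste0("s", 1:(n + 10))
  vc <- structure(list(G = diag(0, 3), R = diag(3)), class = "varcomp")
  pred <- predict_environment(Y, K, vc, paste0("s", (n + 1):(n + 5)))
  for (j in 1:3) expect_equal(unname(pred[, j]), rep(mean(Y[, j]), 5))
})

test_that("t = 1 prediction equals the direct mixed-model-equation solve", {
  K <- structured_K(n = 50, m = 300, seed = 42)
  Kv <- K$values
  sim <- simulate_kron(Kv, matrix(0.7), matrix(0.3), seed = 5)
  train <- 1:40
  test <- 41:50
  ids <- rownames(Kv) <- colnames(Kv) <- rownames(sim$Y)
  vc <- structure(list(G = matrix(0.7), R = matrix(0.3)), class = "varcomp")
  Ytr <- sim$Y[train, , drop = FALSE]
  pred <- predict_environment(Ytr, Kv, vc, ids[test])
  # oracle: direct dense solve of the BLUP system
  mu <- mean(Ytr)
  V <- 0.7 * Kv[train, train] + 0.3 * diag(40)
  u_test <- 0.7 * Kv[test, train] %*% solve(V, Ytr - mu)
  expect_equal(unname(pred[, 1]), unname(u_test[, 1] + mu), tolerance = 1e-8)
})

test_that("a noise-free duplicate of a test sample is interpolated", {
  K <- structured_K(n = 40, m = 300, seed = 44)
  Kv <- K$values
  # duplicate sample 1 into the training set: rows/cols identical
  Kv <- rbind(cbind(Kv, Kv[, 1]), c(Kv[1, ], Kv[1, 1]))
  ids <- c(rownames(K$values), "dup")
  rownames(Kv) <- colnames(Kv) <- ids
  sim <- simulate_kron(K$values, matrix(1), matrix(1e-8), seed = 6)
  Y <- rbind(sim$Y, sim$Y[1, , drop = FALSE])
  rownames(Y) <- ids
  vc <- structure(list(G = matrix(1), R = matrix(1e-6)), class = "varcomp")
  train_ids <- ids[-1]  # everyone else plus "dup" (identical to sample 1)
  pred <- predict_environment(Y[train_ids, , drop = FALSE], Kv, vc, ids[1])
  expect_equal(unname(pred[1, 1]), unname(Y[1, 1]), tolerance = 1e-3)
  expect_error(predict_environment(Y, Kv, vc, ids[1]),
               class = "landrace_leakage_error")
})

test_that("prediction is equivariant to constant column shifts", {
  K <- structured_K(n = 60, m = 300, seed = 45)
  sim <- simulate_kron(K$values, matrix(0.6), matrix(0.4), seed = 7)
  ids <- rownames(sim$Y)
  Kv <- K$values
  rownames(Kv) <- colnames(Kv) <- ids
  vc <- structure(list(G = matrix(0.6), R = matrix(0.4)), class = "varcomp")
  p1 <- predict_environment(sim$Y[1:50, , drop = FALSE], Kv, vc, ids[51:60])
  Y2 <- sim$Y + 5
  p2 <- predict_environment(Y2[1:50, , drop = FALSE], Kv, vc, ids[51:60])
  expect_equal(p2, p1 + 5, tolerance = 1e-8)
})

test_that("random folds are near-equal partitions, deterministic by seed", {
  ids <- paste0("s", 1:35)
  f <- make_random_folds(ids, k = 10, seed = 3)
  sizes <- as.integer(table(f$fold))
  expect_equal(sort(sizes), c(rep(3L, 5), rep(4L, 5)))
  expect_setequal(f$sample_id, ids)
  f2 <- make_random_folds(ids, k = 10, seed = 3)
  expect_identical(f$fold, f2$fold)
  loo <- make_random_folds(paste0("s", 1:10), k = 10, seed = 1)
  expect_equal(sort(as.integer(table(loo$fold))), rep(1L, 10))
  expect_error(make_random_folds(ids, k = 100), class = "landrace_value_error")
})

test_that("spatial folds exclude training points inside the buffer", {
  # two clusters of points ~400 km apart along a meridian; a third point
  # pair straddles the buffer threshold
  base <- tibble::tibble(
    sample_id = paste0("p", 1:40),
    lon = c(rnorm(20, -100, 0.05), rnorm(20, -100, 0.05)),
    lat = c(rnorm(20, 18, 0.05), rnorm(20, 21.65, 0.05))
  )
  f <- make_spatial_folds(base, k = 2, buffer_km = 400, seed = 2)
  expect_setequal(unique(f$fold), 1:2)
  # haversine oracle: distances between the cluster centroids
  d_clusters <- landrace:::haversine_km(cbind(-100, 18), cbind(-100, 21.65))
  expect_equal(as.numeric(d_clusters), 405.8, tolerance = 0.5)
  # with buffer 0 nothing is excluded
  f0 <- make_spatial_folds(base, k = 2, buffer_km = 0, seed = 2)
  expect_true(all(lengths(attr(f0, "excluded")) == 0))
  # points 399 km apart are excluded from each other's training set,
  # 401 km apart are not: compare buffers around the true distance
  f_in <- make_spatial_folds(base, k = 2, buffer_km = 406, seed = 2)
  f_out <- make_spatial_folds(base, k = 2, buffer_km = 200, seed = 2)
  expect_gt(sum(lengths(attr(f_in, "excluded"))), 0)
  expect_equal(sum(lengths(attr(f_out, "excluded"))), 0)
  # degenerate: all points identical
  same <- tibble::tibble(sample_id = paste0("q", 1:8), lon = -100, lat = 20)
  expect_error(make_spatial_folds(same, k = 3, seed = 1),
               class = "landrace_value_error")
})

test_that("cross-validated evaluation scores and never leaks", {
  ds <- small_dataset()
  geno <- filter_variants(ds$geno)
  K <- compute_grm(geno)
  Y <- env_int_matrix(ds, geno)
  rf <- make_random_folds(rownames(Y), k = 5, seed = 8)
  sc <- suppressWarnings(evaluate_gpoe_cv(Y, K, rf, max_iter = 150))
  expect_equal(nrow(sc), 5 * ncol(Y))
  expect_true(all(is.finite(sc$r)))
  expect_true(all(sc$rmse >= 0))
  # structured environments are predictable from kinship
  expect_gt(mean(sc$r[sc$variable == "elevation"]), 0.3)
})

test_that("null (unstructured) data give fold correlations near zero", {
  set.seed(51)
  n <- 120
  ids <- paste0("s", 1:n)
  Y <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, c("a", "b", "c")))
  K <- diag(n)
  rownames(K) <- colnames(K) <- ids
  rf <- make_random_folds(ids, k = 5, seed = 9)
  sc <- suppressWarnings(evaluate_gpoe_cv(Y, K, rf, max_iter = 100))
  # a fold may score NA when the estimated genetic covariance is exactly
  # zero (constant predictions); finite scores must hover around zero
  finite <- sc$r[is.finite(sc$r)]
  if (length(finite) > 0) expect_lt(abs(mean(finite)), 0.12)
  expect_true(all(is.na(sc$r) | abs(sc$r) < 0.5))
})

test_that("scheme comparison reproduces the paired t-test", {
  a <- c(0.8, 0.75, 0.82, 0.78, 0.81)
  b <- c(0.6, 0.62, 0.65, 0.58, 0.61)
  mk <- function(r, scheme) {
    s <- tibble::tibble(fold = seq_along(r), variable = "elevation",
                        r = r, rmse = 1 - r, n_test = 30)
    s$scheme <- scheme
    s
  }
  cmp <- compare_cv_schemes(mk(a, "random"), mk(b, "spatial"))
  row <- cmp[cmp$metric == "r", ]
  # textbook paired t computed longhand
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(row$statistic, t_hand, tolerance = 1e-10)
  expect_equal(row$p_value, 2 * pt(-abs(t_hand), length(d) - 1),
               tolerance = 1e-10)
  # identical scores: t = 0, p = 1
  cmp0 <- compare_cv_schemes(mk(a, "random"), mk(a, "spatial"))
  expect_equal(cmp0$p_value[cmp0$metric == "r"], 1)
  # constant shift with zero difference variance: p -> 0 with warning
  w <- testthat::capture_warnings(
    cmp1 <- compare_cv_schemes(mk(a, "random"), mk(a - 0.1, "spatial"))
  )
  expect_match(w, "zero variance", all = TRUE)
  expect_equal(cmp1$p_value[cmp1$metric == "r"], 0)
  expect_error(compare_cv_schemes(mk(a[1:2], "random"), mk(b[1:2], "spatial")),
               class = "landrace_value_error")
})
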