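# Multivariate genetic/residual covariance estimation and multivariate
# genomic BLUP of environment-of-origin.
#
# Model: columns of the n x t matrix Y (typically INT-transformed
# environmental variables) follow vec-covariance G (x) K + R (x) I.
# Rotating rows by the eigenvectors of K makes rows independent with
# covariance d_m G + R, so the likelihood factors and both EM updates and
# predictions are cheap; the row-wise kernels live in compiled code.

#' Estimate genetic and residual covariance among variables
#'
#' Maximizes the multivariate normal likelihood of column-centered `Y` with
#' covariance \eqn{G \otimes K + R \otimes I} by expectation-maximization in
#' the eigen-rotated coordinates of `K`, stopping when the log-likelihood
#' improves by less than `tol` or after `max_iter` iterations.
#'
#' @param Y Numeric matrix (samples x variables), or a data frame whose
#'   numeric columns are used; complete cases required.
#' @param K A `kinship_matrix` (or bare symmetric matrix) matching the rows
#'   of `Y` in order.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param resid_prior_frac Mode of the weak inverse-Wishart prior on the
#'   residual covariance, as a fraction of each variable's total variance.
#'   Keeps R away from the zero boundary, where whitening-based tests
#'   degenerate; mirrors the regularization Bayesian multivariate mixed
#'   models apply.
#' @param resid_prior_df Prior degrees of freedom; 0 disables the penalty
#'   (plain maximum likelihood).
#' @return Object of class `varcomp`: list with `G`, `R` (t x t PSD
#'   matrices), `logLik` trace, `converged` flag and `n`.
#' @export
estimate_multitrait_components <- function(Y, K, tol = 1e-6, max_iter = 500,
                                           resid_prior_frac = 0.2,
                                           resid_prior_df = NULL) {
  Y <- as_numeric_matrix(Y)
  Kv <- kinship_values(K, nrow(Y))
  if (anyNA(Y)) {
    stop_landrace("Y must be complete for variance-component estimation",
                  "landrace_value_error")
  }
  eK <- eigen((Kv + t(Kv)) / 2, symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(sum(diag(Kv)), 1e-12)) {
    stop_landrace("kinship matrix is not positive semidefinite",
                  "landrace_value_error")
  }
  d <- pmax(eK$values, 0)
  Yc <- sweep(Y, 2, colMeans(Y))
  Yt <- crossprod(eK$vectors, Yc)
  t_ <- ncol(Y)
  n <- nrow(Y)

  S0 <- crossprod(Yc) / (n - 1)
  G0 <- S0 / 2 + diag(1e-6, t_)
  R0 <- S0 / 2 + diag(1e-6, t_)
  # EM warm start, then direct maximization over Cholesky factors with the
  # analytic gradient (EM alone crawls near the optimum).
  fit <- .em_kron_cpp(Yt, d, G0, R0, tol, as.integer(min(max_iter, 100L)))
  nu <- resid_prior_df %||% (t_ + 2)
  Sp <- if (nu > 0) {
    resid_prior_frac * (nu + t_ + 1) * diag(diag(S0), t_)
  } else diag(0, t_)
  par0 <- c(chol_lower_vec(fit$G), chol_lower_vec(fit$R))
  obj <- function(p) -.kron_ml_obj_cpp(p, Yt, d, Sp, nu)$ll
  grd <- function(p) -.kron_ml_obj_cpp(p, Yt, d, Sp, nu)$grad
  opt <- NULL
  ml_converged <- FALSE
  par_cur <- par0
  for (restart in 1:5) {
    o <- tryCatch(
      optim(par_cur, obj, grd, method = "L-BFGS-B",
            control = list(maxit = max_iter, factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(o)) break
    if (!is.null(opt) && o$value > opt$value - 1e-4) {
      # restart no longer improves: accept as stationary
      if (o$value < opt$value) opt <- o
      ml_converged <- TRUE
      break
    }
    opt <- o
    par_cur <- o$par
    if (o$convergence == 0) {
      ml_converged <- TRUE
      break
    }
  }
  converged <- FALSE
  base_obj <- -obj(par0)
  if (!is.null(opt) && is.finite(opt$value) &&
      -opt$value >= base_obj - 1e-6) {
    ntri <- t_ * (t_ + 1) / 2
    Lg <- vec_to_lower(opt$par[seq_len(ntri)], t_)
    Lr <- vec_to_lower(opt$par[ntri + seq_len(ntri)], t_)
    G <- tcrossprod(Lg)
    R <- tcrossprod(Lr)
    ll <- c(as.numeric(fit$logLik), -opt$value)
    converged <- ml_converged
  } else {
    G <- fit$G
    R <- fit$R
    ll <- as.numeric(fit$logLik)
    converged <- isTRUE(fit$converged)
  }
  fit <- list(G = G, R = R, logLik = ll, converged = converged)
  if (!fit$converged) {
    warning("variance-component estimation did not reach tolerance; result flagged",
            call. = FALSE)
  }
  G <- clip_psd(fit$G)
  R <- clip_psd(fit$R)
  dimnames(G) <- dimnames(R) <- list(colnames(Y), colnames(Y))
  structure(
    list(G = G, R = R, logLik = as.numeric(fit$logLik),
         converged = fit$converged, n = n, variables = colnames(Y)),
    class = "varcomp"
  )
}

as_numeric_matrix <- function(Y) {
  if (is.data.frame(Y)) {
    ids <- if ("sample_id" %in% names(Y)) Y$sample_id else NULL
    num <- vapply(Y, is.numeric, logical(1))
    Y <- as.matrix(Y[, num, drop = FALSE])
    if (!is.null(ids)) rownames(Y) <- ids
  }
  Y
}

chol_lower_vec <- function(S) {
  S <- (S + t(S)) / 2 + diag(1e-8 * max(mean(diag(S)), 1e-8), nrow(S))
  L <- t(chol(S))
  L[lower.tri(L, diag = TRUE)]
}

vec_to_lower <- function(v, t_) {
  L <- matrix(0, t_, t_)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

kinship_values <- function(K, n_expected = NULL) {
  v <- if (inherits(K, "kinship_matrix")) K$values else as.matrix(K)
  if (!is.null(n_expected) && nrow(v) != n_expected) {
    stop_landrace("kinship dimension does not match data rows",
                  "landrace_dim_error")
  }
  v
}

#' @export
print.varcomp <- function(x, ...) {
  h2 <- diag(x$G) / pmax(diag(x$G) + diag(x$R), 1e-12)
  cat(sprintf("<varcomp> %d variables, n = %d, converged: %s\n",
              ncol(x$G), x$n, x$converged))
  cat("  per-variable genetic fraction:",
      paste(sprintf("%.2f", h2), collapse = " "), "\n")
  invisible(x)
}

#' @rdname estimate_multitrait_components
#' @param x A `varcomp`.
#' @param ... Unused.
#' @method glance varcomp
#' @export
glance.varcomp <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_variables = ncol(x$G),
    logLik = x$logLik[length(x$logLik)],
    iterations = length(x$logLik),
    converged = x$converged,
    mean_h2 = mean(diag(x$G) / pmax(diag(x$G) + diag(x$R), 1e-12))
  )
}

#' Multivariate genomic prediction of environment for held-out samples
#'
#' Computes the multivariate best linear unbiased prediction
#' \eqn{\hat U_{test} = (G \otimes K_{test,train})(G \otimes K_{train,train}
#' + R \otimes I)^{-1} \mathrm{vec}(Y_{train} - \bar Y)} plus training
#' column means, using the eigendecomposition of the training kinship block.
#'
#' @param Y_train Training matrix (samples x variables) with row names, or
#'   a data frame carrying a `sample_id` column.
#' @param K Full-sample `kinship_matrix` covering training and test samples.
#' @param vc A `varcomp` estimated on the training rows.
#' @param test_ids Sample ids to predict (must not appear in training).
#' @return Matrix of predictions (length(test_ids) x t) with row names.
#' @export
predict_environment <- function(Y_train, K, vc, test_ids) {
  Y_train <- as_numeric_matrix(Y_train)
  Kv <- kinship_values(K)
  train_ids <- rownames(Y_train)
  if (is.null(train_ids)) {
    stop_landrace("Y_train must carry sample ids as row names",
                  "landrace_value_error")
  }
  if (any(test_ids %in% train_ids)) {
    stop_landrace("test samples overlap the training set",
                  "landrace_leakage_error")
  }
  missing_ids <- setdiff(c(train_ids, test_ids), rownames(Kv))
  if (length(missing_ids)) {
    stop_landrace(paste0("samples absent from kinship: ",
                         paste(utils::head(missing_ids, 3), collapse = ", ")),
                  "landrace_value_error")
  }
  Ktt <- Kv[train_ids, train_ids, drop = FALSE]
  Kct <- Kv[test_ids, train_ids, drop = FALSE]
  mu <- colMeans(Y_train)
  Yc <- sweep(Y_train, 2, mu)
  eK <- eigen((Ktt + t(Ktt)) / 2, symmetric = TRUE)
  d <- pmax(eK$values, 0)
  Yt <- crossprod(eK$vectors, Yc)
  A <- .kron_rowsolve_cpp(Yt, d, vc$G, vc$R)
  pred <- Kct %*% eK$vectors %*% A %*% vc$G
  pred <- sweep(pred, 2, mu, "+")
  rownames(pred) <- test_ids
  colnames(pred) <- colnames(Y_train)
  pred
}
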