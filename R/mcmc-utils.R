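# Convergence diagnostics for the in-package Gibbs sampler.

# Split-Rhat (potential scale reduction on half-chains).
# draws: iterations x chains matrix for one parameter.
split_rhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w < 1e-300) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective sample size via Geyer's initial monotone positive sequence,
# averaged chain autocorrelations.
ess_basic <- function(draws) {
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4) return(NA_real_)
  centered <- sweep(draws, 2, colMeans(draws))
  v <- mean(apply(draws, 2, var))
  if (v < 1e-300) return(n * m)
  max_lag <- min(n - 1, 500)
  rho <- vapply(seq_len(max_lag), function(l) {
    num <- mean(colSums(centered[1:(n - l), , drop = FALSE] *
                          centered[(1 + l):n, , drop = FALSE]) / (n - 1))
    num / v
  }, numeric(1))
  # pair sums; stop at first negative pair
  tau <- 1
  k <- 1
  prev <- Inf
  while (k + 1 <= max_lag) {
    p <- rho[k] + rho[k + 1]
    if (p < 0) break
    p <- min(p, prev)  # enforce monotonicity
    tau <- tau + 2 * p
    prev <- p
    k <- k + 2
  }
  max(n * m / tau, 1)
}

# One-sided truncated normal sampler, X ~ N(mean, sd) constrained to
# (-Inf, 0]. Uses log-scale inverse CDF so far-tail truncation stays
# numerically stable.
rtnorm_upper0 <- function(k, mean, sd) {
  alpha <- (0 - mean) / sd
  u <- runif(k)
  lp <- log(u) + pnorm(alpha, log.p = TRUE)
  mean + sd * qnorm(lp, log.p = TRUE)
}

# log density (up to a constant) of a half-Student-t(df, 0, scale) prior
# evaluated at sigma > 0.
log_half_t <- function(sigma, df = 3, scale = 2.5) {
  -(df + 1) / 2 * log1p((sigma / scale)^2 / df)
}

# Inverse-gamma draws, IG(shape, rate) with density rate^shape *
# x^(-shape-1) * exp(-rate/x) / Gamma(shape).
rinvgamma <- function(shape, rate) {
  rate / stats::rgamma(length(rate), shape = shape, rate = 1)
}

rinvgamma1 <- function(shape, rate) {
  rate / stats::rgamma(1, shape = shape, rate = 1)
}

# Scalar slice sampler (Neal 2003, stepping-out and shrinkage). Extra
# arguments are forwarded to the log-density.
slice_sample1 <- function(x0, logf, w = 0.3, max_steps = 50, ...) {
  f0 <- logf(x0, ...)
  if (!is.finite(f0)) return(x0)
  y <- f0 - stats::rexp(1)
  L <- x0 - w * runif(1)
  R <- L + w
  k <- max_steps
  while (k > 0) {
    fl <- logf(L, ...)
    if (!is.finite(fl) || fl <= y) break
    L <- L - w
    k <- k - 1
  }
  k <- max_steps
  while (k > 0) {
    fr <- logf(R, ...)
    if (!is.finite(fr) || fr <= y) break
    R <- R + w
    k <- k - 1
  }
  for (rep in seq_len(200)) {
    x1 <- runif(1, L, R)
    f1 <- logf(x1, ...)
    if (is.finite(f1) && f1 > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}
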