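# Synthetic georeferenced panel generator: landscape, genotypes, trial
# design and phenotypes, plus a ground-truth record for recovery tests.

#' Configuration for the synthetic-data generator
#'
#' Defines the conditions emulated by the generator: a spatially
#' autocorrelated environmental landscape, a structured landrace panel with
#' planted clinal loci, common-garden trials spanning the elevation
#' gradient, testcross families preferentially assigned to trials of similar
#' elevation, and family phenotypes built from a quadratic transfer-distance
#' function plus polygenic, tester and noise terms.
#'
#' @param n_accessions Number of georeferenced accessions.
#' @param n_snps Number of biallelic SNPs.
#' @param n_chroms Number of chromosomes (contiguous SNP blocks).
#' @param n_clinal_snps Number of planted loci whose allele frequency is
#'   logistic in the designated environmental variable.
#' @param clinal_effect_scale Logistic slope of the planted clinal loci.
#' @param fst Differentiation parameter of the spatial Balding-Nichols-style
#'   allele-frequency fields, in (0, 1); 0 switches structure off.
#' @param n_trials Number of common-garden trials.
#' @param n_testers_per_trial Testers used within each trial.
#' @param families_per_trial Testcross families evaluated per trial.
#' @param traits Trait names to simulate.
#' @param h2_per_trait Target within-trial polygenic variance fraction for
#'   each trait (recycled if length 1).
#' @param structure_align Fraction of the polygenic variance carried by the
#'   top five kinship eigenvectors, emulating trait differentiation along
#'   population structure; the remainder comes from a random causal-SNP
#'   subset.
#' @param a_true Quadratic transfer-distance curvature (non-positive for the
#'   local-adaptation scenario; the sign is not enforced so convex-truth
#'   scenarios can be generated).
#' @param beta_h_true Slope of the per-trial optimum on the trial
#'   environment (1 = perfect home-site advantage).
#' @param mu_h_true Intercept of the optimum regression.
#' @param sigma_h_true Residual scatter of per-trial optima.
#' @param tester_effect_sd Standard deviation of tester effects (added
#'   before within-trial scaling).
#' @param spatial_range_km Range of the Gaussian-random-field kernels.
#' @param noise_sd Residual standard deviation of family phenotypes.
#' @param assignment_bias Strength of the preference for assigning
#'   accessions to trials of similar elevation (0 = unbiased).
#' @param clinal_env Environmental variable driving the clinal loci and the
#'   transfer-distance function.
#' @param seed Integer seed; every stage derives its own stream from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_accessions = 500,
                         n_snps = 2000,
                         n_chroms = 10,
                         n_clinal_snps = 5,
                         clinal_effect_scale = 3,
                         fst = 0.1,
                         n_trials = 10,
                         n_testers_per_trial = 3,
                         families_per_trial = 300,
                         traits = "FW",
                         h2_per_trait = 0.4,
                         structure_align = 0.5,
                         a_true = -0.3,
                         beta_h_true = 0.8,
                         mu_h_true = 0,
                         sigma_h_true = 0.05,
                         tester_effect_sd = 0.5,
                         spatial_range_km = 300,
                         noise_sd = 0.5,
                         assignment_bias = 1,
                         clinal_env = "elevation",
                         seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_accessions", "n_snps", "n_chroms", "n_clinal_snps",
              "n_trials", "n_testers_per_trial", "families_per_trial")
  for (nm in counts) {
    if (!is_scalar_number(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop_landrace(paste0(nm, " must be a positive count"),
                    "landrace_config_error")
    }
  }
  cfg$h2_per_trait <- rep_len(h2_per_trait, length(traits))
  names(cfg$h2_per_trait) <- traits
  if (any(cfg$h2_per_trait < 0 | cfg$h2_per_trait > 1)) {
    stop_landrace("h2_per_trait must lie in [0, 1]", "landrace_config_error")
  }
  if (fst < 0 || fst >= 1) {
    stop_landrace("fst must lie in [0, 1)", "landrace_config_error")
  }
  if (spatial_range_km <= 0) {
    stop_landrace("spatial_range_km must be positive", "landrace_config_error")
  }
  if (n_clinal_snps > n_snps) {
    stop_landrace("n_clinal_snps cannot exceed n_snps", "landrace_config_error")
  }
  if (!clinal_env %in% ENV_VARS) {
    stop_landrace("clinal_env must be one of env_variables()",
                  "landrace_config_error")
  }
  structure(cfg, class = "synth_config")
}

# Smooth spatial field from kernel-weighted mixing of random nodes; unit
# marginal variance by construction.
make_field_basis <- function(coords_km, n_nodes, range_km) {
  lo <- apply(coords_km, 2, min)
  hi <- apply(coords_km, 2, max)
  nodes <- cbind(runif(n_nodes, lo[1], hi[1]), runif(n_nodes, lo[2], hi[2]))
  d2 <- outer(coords_km[, 1], nodes[, 1], "-")^2 +
    outer(coords_km[, 2], nodes[, 2], "-")^2
  w <- exp(-d2 / (2 * range_km^2))
  w / sqrt(rowSums(w^2))
}

#' Generate the environmental landscape and trial locations
#'
#' Accession coordinates are drawn in a bounded region; each raw
#' environmental variable is a smooth Gaussian-random-field function of the
#' coordinates plus independent noise. Elevation drives both temperature
#' variables negatively, `trange` is `tmax - tmin` by construction, and
#' trials are placed at locations spanning the elevation range of the
#' accessions. INT-transformed columns (`*_int`) are appended for all seven
#' variables.
#'
#' @param config A [synth_config()].
#' @return List with `env` (accession environment tibble) and `trials`
#'   (trial location/environment tibble).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "landscape"))
  n <- config$n_accessions
  lon <- runif(n, -106, -96)
  lat <- runif(n, 16, 24)

  n_cand <- max(200, 20 * config$n_trials)
  lon_c <- runif(n_cand, -105.5, -96.5)
  lat_c <- runif(n_cand, 16.5, 23.5)
  all_lon <- c(lon, lon_c)
  all_lat <- c(lat, lat_c)
  km <- project_km(all_lon, all_lat)
  basis <- make_field_basis(km, n_nodes = 50, range_km = config$spatial_range_km)
  field <- function() as.numeric(basis %*% rnorm(ncol(basis)))

  # f_cont is a continentality field: it enters tmin and tmax with opposite
  # signs so the diurnal/seasonal range keeps its own strong spatial
  # pattern instead of cancelling out of tmax - tmin.
  f_elev <- field(); f_t <- field(); f_cont <- field()
  f_p <- field(); f_a <- field(); f_h <- field()
  m <- length(all_lon)
  elevation <- pmin(pmax(1500 + 800 * f_elev + 350 * rnorm(m), 0), 3500)
  tmin <- 16 - 0.005 * elevation + 0.8 * f_t + 1.8 * f_cont + 1.2 * rnorm(m)
  tmax <- 34 - 0.0045 * elevation + 0.8 * f_t - 1.8 * f_cont + 1.6 * rnorm(m)
  trange <- tmax - tmin
  precipTot <- pmax(900 + 250 * f_p - 0.05 * elevation + 150 * rnorm(m), 30)
  aridityMean <- pmax(0.9 + 0.3 * f_p + 0.15 * f_a + 0.16 * rnorm(m), 0.05)
  rhMean <- pmin(pmax(62 + 8 * f_h + 5 * f_p + 5 * rnorm(m), 5), 100)

  raw <- tibble::tibble(tmin, tmax, trange, precipTot, aridityMean,
                        rhMean, elevation)
  acc <- raw[seq_len(n), ]
  env <- tibble::tibble(
    sample_id = sprintf("acc%04d", seq_len(n)),
    lon = lon, lat = lat
  )
  env <- dplyr::bind_cols(env, acc)
  for (v in ENV_VARS) env[[paste0(v, "_int")]] <- int_transform(acc[[v]])

  cand <- raw[-seq_len(n), ]
  targets <- quantile(acc$elevation,
                      probs = seq(0.05, 0.95, length.out = config$n_trials))
  chosen <- integer(0)
  for (tg in targets) {
    ord <- order(abs(cand$elevation - tg))
    pick <- ord[!(ord %in% chosen)][1]
    chosen <- c(chosen, pick)
  }
  trials <- tibble::tibble(
    trial = sprintf("T%02d", seq_len(config$n_trials)),
    lon = lon_c[chosen], lat = lat_c[chosen], year = 2012L
  )
  trials <- dplyr::bind_cols(trials, cand[chosen, ])
  list(env = env, trials = trials)
}

#' Generate structured SNP dosages with planted clinal loci
#'
#' Neutral SNPs follow a spatial Balding-Nichols-style scheme: per-SNP local
#' allele frequencies are logistic perturbations of an ancestral frequency
#' along a smooth spatial field, with perturbation scale set so the expected
#' differentiation matches `fst`. Planted clinal SNPs additionally have
#' allele frequency logistic in the designated environmental variable.
#' Dosages are binomial(2, p_local) and chromosomes are contiguous blocks.
#'
#' @param config A [synth_config()].
#' @param env_table Accession environment tibble from [generate_landscape()].
#' @return List with `geno` (a [geno_matrix()]) and `truth` (partial ground
#'   truth: clinal SNP ids, indices and slopes).
#' @export
generate_genotypes <- function(config, env_table) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- nrow(env_table)
  m <- config$n_snps

  p0 <- runif(m, 0.1, 0.9)
  km <- project_km(env_table$lon, env_table$lat)
  logit_local <- matrix(qlogis(p0), n, m, byrow = TRUE)
  if (config$fst > 0) {
    basis <- make_field_basis(km, n_nodes = 50,
                              range_km = config$spatial_range_km)
    u <- basis %*% matrix(rnorm(ncol(basis) * m), ncol(basis), m)
    sigma <- pmin(sqrt(config$fst / (p0 * (1 - p0))), 3)
    logit_local <- logit_local + sweep(u, 2, sigma, "*")
  }
  clinal_idx <- sort(sample.int(m, config$n_clinal_snps))
  zenv <- as.numeric(scale(env_table[[config$clinal_env]]))
  slopes <- config$clinal_effect_scale *
    sample(c(-1, 1), config$n_clinal_snps, replace = TRUE)
  logit_local[, clinal_idx] <- logit_local[, clinal_idx] +
    outer(zenv, slopes)

  p_local <- plogis(logit_local)
  dos <- matrix(rbinom(n * m, 2, p_local), n, m)
  rownames(dos) <- env_table$sample_id

  chrom <- as.character(rep(seq_len(config$n_chroms),
                            each = ceiling(m / config$n_chroms))[seq_len(m)])
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i) {
    cumsum(sample(1000:50000, length(i), replace = TRUE))
  })[unique(chrom)], use.names = FALSE)
  variants <- tibble::tibble(
    snp_id = paste0("S", chrom, "_", pos),
    chrom = chrom, pos = pos, ref = "A", alt = "T"
  )
  geno <- geno_matrix(dos, variants)
  truth <- list(
    clinal = tibble::tibble(
      snp_id = variants$snp_id[clinal_idx],
      index = clinal_idx,
      env = config$clinal_env,
      slope = slopes
    )
  )
  list(geno = geno, truth = truth)
}

#' Generate the testcross trial design
#'
#' Builds a shared tester pool with elevation affinities, gives each trial
#' the `n_testers_per_trial` testers closest to its elevation, and assigns
#' accessions to trials with a soft preference for trials of similar
#' elevation-of-origin (strength `assignment_bias`; 0 is unbiased). Testers
#' are rotated over the sampled accessions so every trial-tester group has a
#' near-equal family count.
#'
#' @param config A [synth_config()].
#' @param trial_table Trial tibble from [generate_landscape()].
#' @param env_table Accession environment tibble.
#' @return Tibble with columns `trial`, `tester`, `accession`; one row per
#'   testcross family.
#' @export
generate_design <- function(config, trial_table, env_table) {
  stopifnot(inherits(config, "synth_config"))
  if (config$families_per_trial > nrow(env_table)) {
    stop_landrace("families_per_trial cannot exceed n_accessions",
                  "landrace_config_error")
  }
  set.seed(derive_seed(config$seed, "design"))
  n_pool <- max(config$n_testers_per_trial + 1, 2 * config$n_testers_per_trial)
  pool <- tibble::tibble(
    tester = sprintf("tester%02d", seq_len(n_pool)),
    elev = seq(min(trial_table$elevation), max(trial_table$elevation),
               length.out = n_pool)
  )
  sd_e <- sd(env_table$elevation)
  rows <- lapply(seq_len(nrow(trial_table)), function(i) {
    tr <- trial_table[i, ]
    testers <- pool$tester[order(abs(pool$elev - tr$elevation))][
      seq_len(config$n_testers_per_trial)]
    d <- (env_table$elevation - tr$elevation) / sd_e
    w <- exp(-config$assignment_bias * d^2)
    acc <- sample(env_table$sample_id, config$families_per_trial,
                  prob = w / sum(w))
    tibble::tibble(
      trial = tr$trial,
      tester = rep_len(testers, length(acc)),
      accession = acc
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate family phenotypes from the transfer-distance model
#'
#' Each family value is a tester effect plus the quadratic transfer-distance
#' term \eqn{a (x - h_i)^2} (with per-trial optimum
#' \eqn{h_i = \mu_h + \beta_h X_i + \epsilon}), a polygenic term scaled to
#' the target within-trial heritability, and Gaussian noise, then z-scaled
#' within trial and trait to emulate deregressed family BLUPs. The
#' environmental covariate and trial environments are standardized jointly,
#' exactly as the fitting routine standardizes them.
#'
#' @param config A [synth_config()].
#' @param geno [geno_matrix()] from [generate_genotypes()].
#' @param env_table,trial_table Tibbles from [generate_landscape()].
#' @param design Design tibble from [generate_design()].
#' @return List with `blups` (tibble: trial, tester, accession, trait,
#'   value, h2) and `truth` (a `synthetic_truth` list with the generative
#'   parameters).
#' @export
generate_phenotypes <- function(config, geno, env_table, trial_table, design) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "phenotypes"))
  ev <- config$clinal_env
  std <- pooled_standardization(env_table[[ev]], trial_table[[ev]])
  x_acc <- (env_table[[ev]] - std$mean) / std$sd
  names(x_acc) <- env_table$sample_id
  x_trial <- (trial_table[[ev]] - std$mean) / std$sd
  names(x_trial) <- trial_table$trial

  h_true <- config$mu_h_true + config$beta_h_true * x_trial +
    config$sigma_h_true * rnorm(length(x_trial))
  names(h_true) <- trial_table$trial

  groups <- dplyr::distinct(design, .data$trial, .data$tester)
  groups$c_true <- rnorm(nrow(groups), 0, config$tester_effect_sd)

  xc <- sweep(geno$dosages, 2, colMeans(geno$dosages))
  n_causal <- max(1, round(0.05 * ncol(xc)))
  # top kinship eigenvectors for the structure-aligned genetic component
  w_struct <- min(max(config$structure_align, 0), 1)
  pcs <- NULL
  if (w_struct > 0) {
    eK <- eigen(tcrossprod(xc), symmetric = TRUE)
    pcs <- eK$vectors[, seq_len(min(5, ncol(eK$vectors))), drop = FALSE]
  }
  blup_list <- list()
  poly_truth <- list()
  h2_realized <- list()
  for (trait in config$traits) {
    causal <- sort(sample.int(ncol(xc), n_causal))
    b <- rnorm(n_causal)
    g_poly <- as.numeric(xc[, causal, drop = FALSE] %*% b)
    g_raw <- if (w_struct > 0) {
      g_pc <- as.numeric(pcs %*% rnorm(ncol(pcs)))
      sqrt(1 - w_struct) * g_poly / max(sd(g_poly), 1e-12) +
        sqrt(w_struct) * g_pc / max(sd(g_pc), 1e-12)
    } else {
      g_poly
    }
    names(g_raw) <- rownames(xc)
    h2 <- config$h2_per_trait[[trait]]

    df <- dplyr::left_join(design, groups, by = c("trial", "tester"))
    df$x <- x_acc[df$accession]
    df$h <- h_true[df$trial]
    df$g_raw <- g_raw[df$accession]
    out <- lapply(split(df, df$trial), function(d) {
      sg <- sd(d$g_raw)
      alpha <- if (h2 > 0 && sg > 0) {
        config$noise_sd * sqrt(h2 / max(1 - h2, 1e-8)) / sg
      } else 0
      d$value_raw <- d$c_true + config$a_true * (d$x - d$h)^2 +
        alpha * d$g_raw + config$noise_sd * rnorm(nrow(d))
      d$alpha <- alpha
      d
    })
    df <- dplyr::bind_rows(out)
    df <- dplyr::group_by(df, .data$trial)
    df <- dplyr::mutate(
      df,
      value = as.numeric(scale(.data$value_raw)),
      scale_mean = mean(.data$value_raw),
      scale_sd = sd(.data$value_raw)
    )
    df <- dplyr::ungroup(df)
    blup_list[[trait]] <- tibble::tibble(
      trial = df$trial, tester = df$tester, accession = df$accession,
      trait = trait, value = df$value, h2 = h2
    )
    poly_truth[[trait]] <- list(
      causal_snps = geno$variants$snp_id[causal],
      effects = b,
      alpha_per_trial = vapply(split(df$alpha, df$trial), `[`, numeric(1), 1),
      scale_per_trial = dplyr::distinct(df, .data$trial, .data$scale_mean,
                                        .data$scale_sd)
    )
    h2_realized[[trait]] <- vapply(split(df, df$trial), function(d) {
      va <- var(d$alpha[1] * d$g_raw)
      va / max(var(d$value_raw), 1e-12)
    }, numeric(1))
  }

  truth <- structure(
    list(
      h_true = h_true,
      a_true = config$a_true,
      beta_h_true = config$beta_h_true,
      mu_h_true = config$mu_h_true,
      c_true = groups,
      polygenic = poly_truth,
      h2_realized = h2_realized,
      env_standardization = std,
      clinal_env = ev,
      x_acc = x_acc,
      x_trial = x_trial
    ),
    class = "synthetic_truth"
  )
  list(blups = dplyr::bind_rows(blup_list), truth = truth)
}

# Joint standardization of accession and trial environment values; shared
# by the generator and the transfer-model fitting routine.
pooled_standardization <- function(acc_values, trial_values) {
  pooled <- c(acc_values, trial_values)
  list(mean = mean(pooled), sd = sd(pooled))
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_landscape()], [generate_genotypes()], [generate_design()]
#' and [generate_phenotypes()] in sequence, each on its own seed stream
#' derived from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_dataset` with elements `env`,
#'   `trials`, `geno`, `design`, `blups`, `truth` and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  land <- generate_landscape(config)
  gg <- generate_genotypes(config, land$env)
  design <- generate_design(config, land$trials, land$env)
  ph <- generate_phenotypes(config, gg$geno, land$env, land$trials, design)
  truth <- ph$truth
  truth$clinal <- gg$truth$clinal
  structure(
    list(env = land$env, trials = land$trials, geno = gg$geno,
         design = design, blups = ph$blups, truth = truth, config = config),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d accessions, %d SNPs, %d trials, %d families, %d trait(s)\n",
    nrow(x$env), ncol(x$geno$dosages), nrow(x$trials), nrow(x$design),
    length(unique(x$blups$trait))
  ))
  invisible(x)
}
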