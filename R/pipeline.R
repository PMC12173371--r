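# End-to-end orchestration: generator -> QC -> transfer model -> GPoE ->
# envGWAS -> clumping/enrichment -> prediction benchmark, from a single
# declarative configuration.

pipeline_defaults <- function() {
  list(
    synthetic = TRUE,
    synth = list(),
    geno_path = NULL, variants_path = NULL, geno_format = "dosage_tsv",
    env_path = NULL, trials_path = NULL, design_path = NULL,
    blups_path = NULL,
    trait = NULL,
    filters = list(maf_min = 0.01, max_sample_missing = 0.25,
                   h2_min = 0.1, min_unique = 10),
    transfer = list(env = "elevation", chains = 2, iterations = 1000,
                    constrain_negative = TRUE),
    gpoe = list(run = TRUE, k = 10, buffer_km = 400),
    gwas = list(p_threshold = 1e-5, structure_correction = TRUE),
    clump = list(r2_threshold = 0.3, n_sets = 1000, maf_bin_width = 0.02),
    bench = list(run = TRUE, models = c("pc_only", "all_snps", "env_linear"),
                 n_trees = 1000, n_pcs = 5),
    pca = list(n_snps = 5000, n_components = 5),
    seed = 1,
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Merges user settings over the stage defaults; unknown keys (top-level or
#' within a stage block) are rejected before any computation.
#'
#' @param config A named list, or path to a YAML file.
#' @return Validated configuration list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown)) {
    stop_landrace(paste0("unknown config key(s): ",
                         paste(unknown, collapse = ", ")),
                  "landrace_config_error")
  }
  for (blk in c("filters", "transfer", "gpoe", "gwas", "clump", "bench",
                "pca")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(defs[[blk]]))
      if (length(bad)) {
        stop_landrace(paste0("unknown key(s) in `", blk, "`: ",
                             paste(bad, collapse = ", ")),
                      "landrace_config_error")
      }
      defs[[blk]][names(config[[blk]])] <- config[[blk]]
    }
  }
  scalar <- setdiff(names(config),
                    c("filters", "transfer", "gpoe", "gwas", "clump",
                      "bench", "pca"))
  defs[scalar] <- config[scalar]
  if (!defs$synthetic && is.null(defs$geno_path)) {
    stop_landrace("non-synthetic runs require `geno_path`",
                  "landrace_config_error")
  }
  structure(defs, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on either a synthetic dataset
#' (generated from `config$synth` and the global seed) or user-supplied
#' files. Every stage writes its tabular outputs under `out_dir`, a
#' manifest of MD5 checksums is recorded, failed stages stop their
#' dependents but independent branches continue, and per-stage seeds are
#' derived deterministically from the global seed so identical
#' configurations reproduce byte-identical outputs.
#'
#' @param config A configuration list or YAML path (see
#'   [validate_config()]).
#' @return Object of class `pipeline_run`: list with `stages` (status and
#'   results), `manifest`, `report`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir %||% tempfile("landrace_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  files <- character(0)
  emit <- function(name, tbl) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1]] <<- path
    path
  }
  run_stage <- function(name, deps, expr) {
    failed_dep <- deps[!vapply(deps, function(d)
      identical(stages[[d]]$status, "ok"), logical(1))]
    if (length(failed_dep)) {
      stages[[name]] <<- list(status = "skipped",
                              reason = paste0("dependency failed: ",
                                              paste(failed_dep,
                                                    collapse = ", ")))
      return(invisible(NULL))
    }
    res <- tryCatch(list(status = "ok", value = expr()),
                    error = function(e) list(status = "failed",
                                             reason = conditionMessage(e)))
    stages[[name]] <<- res
    invisible(NULL)
  }

  run_stage("data", character(0), function() {
    if (cfg$synthetic) {
      sc <- do.call(synth_config, c(cfg$synth, list(seed = cfg$seed)))
      ds <- generate_dataset(sc)
    } else {
      geno <- read_genotypes(cfg$geno_path, cfg$geno_format,
                             cfg$variants_path)
      env <- tibble::as_tibble(read.delim(cfg$env_path))
      trials <- tibble::as_tibble(read.delim(cfg$trials_path))
      design <- tibble::as_tibble(read.delim(cfg$design_path))
      blups <- tibble::as_tibble(read.delim(cfg$blups_path))
      ds <- list(geno = geno, env = env, trials = trials, design = design,
                 blups = blups, truth = NULL)
    }
    emit("env", ds$env)
    emit("trials", ds$trials)
    emit("design", ds$design)
    emit("blups", ds$blups)
    ds
  })

  run_stage("qc", "data", function() {
    ds <- stages$data$value
    geno <- filter_variants(ds$geno, maf_min = cfg$filters$maf_min,
                            max_sample_missing = cfg$filters$max_sample_missing)
    emit("variants_filtered", geno$variants)
    geno
  })

  run_stage("kinship", "qc", function() {
    K <- compute_grm(stages$qc$value)
    pca <- genotype_pca(stages$qc$value, n_snps = cfg$pca$n_snps,
                        n_components = cfg$pca$n_components,
                        seed = derive_seed(cfg$seed, "pca"))
    emit("pca_scores", pca$scores)
    list(K = K, pca = pca)
  })

  trait <- function() cfg$trait %||% stages$data$value$blups$trait[1]

  run_stage("blup_prep", "data", function() {
    prepare_blups(stages$data$value$blups, h2_min = cfg$filters$h2_min,
                  min_unique = cfg$filters$min_unique)
  })

  run_stage("transfer", "blup_prep", function() {
    ds <- stages$data$value
    ev <- cfg$transfer$env
    fit_once <- function(iters, seed) {
      fit_transfer_model(
        stages$blup_prep$value,
        env_of_origin = setNames(ds$env[[ev]], ds$env$sample_id),
        trial_env = setNames(ds$trials[[ev]], ds$trials$trial),
        trait = trait(),
        constrain_negative = cfg$transfer$constrain_negative,
        chains = cfg$transfer$chains,
        iterations = iters,
        seed = seed
      )
    }
    # a non-converged fit is retried once with doubled chain length
    fit <- tryCatch(
      fit_once(cfg$transfer$iterations, derive_seed(cfg$seed, "transfer")),
      landrace_convergence_error = function(e) {
        fit_once(2L * cfg$transfer$iterations,
                 derive_seed(cfg$seed, "transfer") + 1L)
      }
    )
    summ <- summarize_transfer_posterior(fit)
    emit("transfer_optima", summ$optima)
    emit("transfer_beta", summ$beta)
    list(fit = fit, summary = summ)
  })

  run_stage("gpoe", "kinship", function() {
    if (!isTRUE(cfg$gpoe$run)) return(NULL)
    ds <- stages$data$value
    geno <- stages$qc$value
    K <- stages$kinship$value$K
    ids <- geno$sample_ids
    Y <- as.matrix(ds$env[match(ids, ds$env$sample_id),
                          paste0(ENV_VARS, "_int")])
    rownames(Y) <- ids
    colnames(Y) <- ENV_VARS
    k <- min(cfg$gpoe$k, nrow(Y))
    rf <- make_random_folds(ids, k = k, seed = derive_seed(cfg$seed, "folds"))
    sf <- make_spatial_folds(
      ds$env[match(ids, ds$env$sample_id), c("sample_id", "lon", "lat")],
      k = k, buffer_km = cfg$gpoe$buffer_km,
      seed = derive_seed(cfg$seed, "folds")
    )
    sc_r <- evaluate_gpoe_cv(Y, K, rf)
    sc_s <- evaluate_gpoe_cv(Y, K, sf)
    cmp <- compare_cv_schemes(sc_r, sc_s)
    emit("gpoe_random", sc_r)
    emit("gpoe_spatial", sc_s)
    emit("gpoe_comparison", cmp)
    list(random = sc_r, spatial = sc_s, comparison = cmp)
  })

  run_stage("envgwas", "kinship", function() {
    ds <- stages$data$value
    geno <- stages$qc$value
    ids <- geno$sample_ids
    Y <- as.matrix(ds$env[match(ids, ds$env$sample_id),
                          paste0(ENV_VARS, "_int")])
    rownames(Y) <- ids
    colnames(Y) <- ENV_VARS
    vc <- estimate_multitrait_components(Y, stages$kinship$value$K,
                                         tol = 1e-4, max_iter = 200)
    gw <- env_gwas(geno, Y, vc,
                   structure_correction = cfg$gwas$structure_correction,
                   p_threshold = cfg$gwas$p_threshold)
    emit("envgwas", gw[, c("snp_id", "chrom", "pos", "Fstat", "df1",
                           "df2", "p")])
    list(vc = vc, gwas = gw)
  })

  run_stage("clump", "envgwas", function() {
    geno <- stages$qc$value
    cl <- greedy_clump(stages$envgwas$value$gwas, geno,
                       p_threshold = cfg$gwas$p_threshold,
                       r2_threshold = cfg$clump$r2_threshold)
    flat <- tibble::tibble(
      lead_snp = cl$lead_snp, chrom = cl$chrom, pos = cl$pos,
      lead_p = cl$lead_p,
      members = vapply(cl$members, paste, character(1), collapse = ",")
    )
    emit("clumps", flat)
    cl
  })

  run_stage("phenogwas", c("qc", "blup_prep"), function() {
    gw <- pheno_gwas(stages$qc$value, stages$blup_prep$value,
                     trait = trait())
    emit("phenogwas", gw[, c("snp_id", "chrom", "pos", "F_main", "F_int",
                             "p_main", "p_interaction", "p")])
    gw
  })

  run_stage("enrichment", c("clump", "phenogwas"), function() {
    cl <- stages$clump$value
    if (nrow(cl) == 0) return(NULL)
    geno <- stages$qc$value
    sets <- sample_maf_matched(geno, cl$lead_snp,
                               n_sets = cfg$clump$n_sets,
                               maf_bin_width = cfg$clump$maf_bin_width,
                               seed = derive_seed(cfg$seed, "clump"))
    en <- enrichment_test(cl$lead_snp, stages$phenogwas$value, sets,
                          trait = trait())
    emit("enrichment", en)
    en
  })

  run_stage("bench", c("qc", "blup_prep"), function() {
    if (!isTRUE(cfg$bench$run)) return(NULL)
    ds <- stages$data$value
    leads <- if (identical(stages$clump$status, "ok") &&
                 nrow(stages$clump$value) > 0) {
      stages$clump$value$lead_snp
    } else NULL
    models <- cfg$bench$models
    if (is.null(leads)) {
      models <- setdiff(models, c("pc_envgwas_snps", "pc_random_snps"))
    }
    scores <- run_model_suite(
      stages$blup_prep$value, stages$qc$value, ds$env, ds$design,
      models = models, envgwas_leads = leads, trait = trait(),
      n_pcs = cfg$bench$n_pcs, n_trees = cfg$bench$n_trees,
      seed = derive_seed(cfg$seed, "bench")
    )
    emit("bench_scores", scores)
    cmp <- tryCatch(compare_models(scores), error = function(e) NULL)
    if (!is.null(cmp)) emit("bench_contrasts", tidy(cmp))
    list(scores = scores, comparison = cmp)
  })

  manifest <- tibble::tibble(
    file = basename(unlist(files)),
    md5 = unname(tools::md5sum(unlist(files)))
  )
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  run <- structure(
    list(stages = stages, manifest = manifest, out_dir = out_dir,
         config = cfg),
    class = "pipeline_run"
  )
  run$report <- write_report(run)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-10s %s\n", nm, x$stages[[nm]]$status))
  }
  cat(sprintf("  outputs: %d file(s) in %s\n", nrow(x$manifest), x$out_dir))
  invisible(x)
}

#' Write the run report
#'
#' Produces a machine-readable JSON report and a plain-text twin
#' summarizing each completed stage: the `beta_h` posterior interval, GPoE
#' mean correlations for random and spatial folds, the lead-SNP count,
#' enrichment p-values, and the benchmark contrast table.
#'
#' @param run A `pipeline_run`.
#' @return Invisibly, the report list. Files `report.json` and
#'   `report.txt` are written to the run's output directory.
#' @export
write_report <- function(run) {
  stages <- run$stages
  rep <- list(
    package = "landrace",
    seed = run$config$seed,
    stages = lapply(stages, function(s) {
      list(status = s$status, reason = s$reason %||% NA)
    })
  )
  if (identical(stages$transfer$status, "ok")) {
    b <- stages$transfer$value$summary$beta
    rep$transfer <- list(beta_h_mean = b$mean, beta_h_lo = b$lo,
                         beta_h_hi = b$hi, p_positive = b$p_positive,
                         contains_one = b$contains_one)
  }
  if (identical(stages$gpoe$status, "ok") && !is.null(stages$gpoe$value)) {
    g <- stages$gpoe$value
    rep$gpoe <- list(
      mean_r_random = mean(g$random$r, na.rm = TRUE),
      mean_r_spatial = mean(g$spatial$r, na.rm = TRUE)
    )
  }
  if (identical(stages$envgwas$status, "ok")) {
    gw <- stages$envgwas$value$gwas
    rep$envgwas <- list(
      n_tested = nrow(gw),
      n_significant = nrow(significant_snps(gw))
    )
  }
  if (identical(stages$clump$status, "ok")) {
    rep$clump <- list(n_leads = nrow(stages$clump$value))
  }
  if (identical(stages$enrichment$status, "ok") &&
      !is.null(stages$enrichment$value)) {
    en <- stages$enrichment$value
    rep$enrichment <- list(trait = en$trait, p_enrich = en$p_enrich,
                           observed_mean_neglog10p = en$observed_mean_neglog10p)
  }
  if (identical(stages$bench$status, "ok") && !is.null(stages$bench$value)) {
    sc <- stages$bench$value$scores
    means <- tapply(sc$r, sc$model, mean, na.rm = TRUE)
    rep$bench <- list(mean_r_by_model = as.list(means))
    if (!is.null(stages$bench$value$comparison)) {
      rep$bench$contrasts <- tidy(stages$bench$value$comparison)
    }
  }
  json_path <- file.path(run$out_dir, "report.json")
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  txt <- c(
    "landrace pipeline report",
    paste0("seed: ", run$config$seed),
    "",
    vapply(names(stages), function(nm) {
      sprintf("%-10s %s", nm, stages[[nm]]$status)
    }, character(1))
  )
  if (!is.null(rep$transfer)) {
    txt <- c(txt, "", sprintf(
      "beta_h: %.3f [%.3f, %.3f], P(>0) = %.3f",
      rep$transfer$beta_h_mean, rep$transfer$beta_h_lo,
      rep$transfer$beta_h_hi, rep$transfer$p_positive))
  }
  if (!is.null(rep$gpoe)) {
    txt <- c(txt, sprintf("GPoE mean r: random %.3f, spatial %.3f",
                          rep$gpoe$mean_r_random, rep$gpoe$mean_r_spatial))
  }
  if (!is.null(rep$clump)) {
    txt <- c(txt, sprintf("lead SNPs: %d", rep$clump$n_leads))
  }
  if (!is.null(rep$enrichment)) {
    txt <- c(txt, sprintf("enrichment p (%s): %.3f", rep$enrichment$trait,
                          rep$enrichment$p_enrich))
  }
  if (!is.null(rep$bench)) {
    m <- unlist(rep$bench$mean_r_by_model)
    txt <- c(txt, paste0("benchmark mean r: ",
                         paste(sprintf("%s=%.3f", names(m), m),
                               collapse = ", ")))
  }
  writeLines(txt, file.path(run$out_dir, "report.txt"))
  invisible(rep)
}

#' Validate a report JSON against the packaged schema
#'
#' Structural check of the machine-readable run report: required top-level
#' fields, required per-stage fields and value types, as declared in the
#' schema shipped under `inst/extdata/report_schema.json`.
#'
#' @param path Path to a `report.json`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report_schema.json", package = "landrace"))
  rep <- jsonlite::read_json(path)
  for (k in unlist(schema$required)) {
    if (is.null(rep[[k]])) {
      stop_landrace(paste0("report missing required field: ", k),
                    "landrace_schema_error")
    }
  }
  if (!is.character(rep$package) && !is.null(rep$package)) {
    stop_landrace("report `package` must be a string", "landrace_schema_error")
  }
  for (nm in names(rep$stages)) {
    st <- rep$stages[[nm]]$status
    if (is.null(st) || !st %in% unlist(schema$stage_status)) {
      stop_landrace(paste0("invalid stage status for ", nm),
                    "landrace_schema_error")
    }
  }
  invisible(TRUE)
}
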