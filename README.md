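# landrace

Tools for asking a practical question in crop pre-breeding and
conservation genomics: **how much do environment-of-origin data add to
genomic data when prioritizing traditional varieties (landraces) for new
climates?** The package implements, end to end, the analysis pipeline used
to answer that question in large georeferenced maize landrace panels
evaluated in common-garden testcross trials — together with a synthetic-data
generator with known ground truth, so every stage can be validated against
planted signals.

## What the package computes

* **Genotype QC and kinship** — dosage I/O (VCF or TSV), MAF/missingness
  filters, the genomic relationship matrix
  `K = X_c X_c' / (2 Σ p(1−p))` with half-sib (1/4) scaling and
  leave-one-chromosome-out (LOCO) variants, genotype PCA, and the
  rank-based inverse normal transform
  `INT(w_i) = Φ⁻¹((rank_i − 3/8)/(N + 1/4))` applied to all environmental
  variables.
* **Hierarchical Bayesian transfer-distance model** — per trial `i`,
  tester `j`, family `k`:

  ```
  y_ijk = c_ij + a_i (x_ijk − h_i)² + e_ijk,   a_i ≤ 0
  h_i   = μ_h + β_h X_i + N(0, σ_h²)
  ```

  where `x` is the family's environment-of-origin and `X_i` the trial's
  environment. `β_h = 1` means trials select accessions from matching
  environments (local adaptation); the posterior of `β_h` is the headline
  adaptation summary. Fitting is by a compiled collapsed Gibbs/slice
  sampler with split-Rhat convergence contracts
  (`fit_transfer_model()`, `summarize_transfer_posterior()`).
* **Genomic prediction of environment (GPoE)** — multivariate BLUP of the
  seven growing-season variables from kinship under the covariance
  `G ⊗ K + R ⊗ I`, with `(G, R)` estimated by EM plus direct
  maximum-penalized-likelihood (`estimate_multitrait_components()`,
  `predict_environment()`), evaluated under random k-fold and spatially
  buffered (k-means + 400 km haversine buffer) cross-validation
  (`evaluate_gpoe_cv()`, `compare_cv_schemes()`).
* **Joint multivariate association scans** — envGWAS: per SNP, an F-test
  with t numerator degrees of freedom that the SNP is associated with *any*
  environmental variable, after exact whitening of the Kronecker error
  covariance with LOCO kinship (`env_gwas()`); phenoGWAS: SNP main and
  SNP-by-trial effects on family BLUPs combined by Fisher's method
  (`pheno_gwas()`, `fisher_combine()`).
* **LD clumping and enrichment** — greedy genome-wide clumping of
  significant SNPs at dosage `r² > 0.3` (`greedy_clump()`), MAF-matched
  random SNP sets (`sample_maf_matched()`), and the fraction-based
  enrichment test of lead SNPs against phenotypic associations
  (`enrichment_test()`).
* **Prediction benchmark** — eight models (PCs only, PCs + envGWAS or
  random SNPs, all-SNPs GBLUP with and without environment, and
  environment-only linear/random-forest models) evaluated within tester
  folds per trial (`run_model_suite()`), compared by a weighted mixed model
  with Tukey-adjusted contrasts (`compare_models()`).
* **Synthetic data** — `generate_dataset()` builds a georeferenced panel
  with spatially autocorrelated environments, Balding–Nichols-style spatial
  population structure, planted clinal loci, a biased testcross trial
  design, and phenotypes generated from the quadratic transfer model plus
  polygenic, tester and noise terms, with a full ground-truth record.
* **Orchestration** — `run_pipeline()` runs everything from one declarative
  config (list or YAML) with derived per-stage seeds, a checksum manifest
  and a JSON + text run report; outputs are byte-identical across reruns
  with the same seed.

## Worked example

```r
library(landrace)

ds   <- generate_dataset(synth_config(n_accessions = 300, n_snps = 1000, seed = 11))
geno <- filter_variants(ds$geno)
K    <- compute_grm(geno)

fit  <- fit_transfer_model(prepare_blups(ds$blups),
                           env_of_origin = setNames(ds$env$elevation, ds$env$sample_id),
                           trial_env     = setNames(ds$trials$elevation, ds$trials$trial),
                           trait = "FW", chains = 2, iterations = 3000, seed = 2)
summarize_transfer_posterior(fit)
#> <transfer_summary> trait FW
#>   beta_h: 0.877 [0.774, 0.971], P(beta_h > 0) = 1.000, contains 1: FALSE
#>    trial trial_env optimum_mean optimum_lo optimum_hi
#>  1 T01        726.         772.       682.       859.
#>  2 T02       1020.        1037.       971.      1101.
#>  ...
#> 10 T10       2230.        2094.      2018.      2171.
```

The generator planted `β_h = 0.8`: the posterior mean is 0.877 with a 95%
interval [0.774, 0.971], and each trial's estimated optimal
elevation-of-origin tracks the trial's elevation. The association scan then
recovers the planted clinal loci and groups them into independent lead
SNPs:

```r
Y  <- as.matrix(ds$env[match(geno$sample_ids, ds$env$sample_id),
                       paste0(env_variables(), "_int")])
rownames(Y) <- geno$sample_ids; colnames(Y) <- env_variables()
vc <- estimate_multitrait_components(Y, K)
gw <- env_gwas(geno, Y, vc)
significant_snps(gw)
#> # A tibble: 5 x 7   (all five planted clinal SNPs, p < 1e-20)
greedy_clump(gw, geno)
#> <clump_result> 2 lead SNP(s) (p < 1e-05, r2 > 0.3), 3 member SNP(s)
```

The five clinal SNPs collapse into two leads because strong parallel
clines are mutually correlated (trans-LD) — exactly why clumping is done
genome-wide. Lead SNPs are then tested for phenotypic enrichment against
MAF-matched null sets, and the prediction benchmark scores genomic vs
environmental models within tester folds (`run_model_suite()`,
`autoplot()` on each result).

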