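---
title: "Models and methods behind landrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind landrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical decisions made where the design was open.
All quantitative statements here are properties that the test suite or
`scripts/acceptance.R` themselves compute.

## 1. The scientific setting

A georeferenced panel of traditional crop varieties (landraces) carries two
kinds of information about adaptation: the environment of the collection
site (seven growing-season variables: tmin, tmax, trange, precipTot,
aridityMean, rhMean, elevation) and genome-wide SNP genotypes. Yield-trait
data come from common-garden trials in which each accession is crossed to
an elite tester and the testcross family's performance is summarized as a
deregressed, within-trial z-scaled BLUP. The package quantifies (i) whether
yield declines with transfer distance (evidence of environmental
adaptation), (ii) how predictable the environment-of-origin is from the
genome, (iii) which loci drive genotype–environment association, and (iv)
whether any of this improves the prediction of breeding values beyond
plain genomic prediction.

## 2. The quadratic transfer-distance model

For family $k$ crossed to tester $j$ and evaluated in trial $i$,

$$y_{ijk} = c_{ij} + a_i\,(x_{ijk} - h_i)^2 + e_{ijk}, \qquad
  e_{ijk} \sim N(0, \sigma^2_{e,i}),$$

$$c_{ij} \sim N(\mu_c, \sigma_c^2),\quad
  a_i \sim N^-(0,1),\quad
  h_i = \mu_h + \beta_h X_i + N(0, \sigma_h^2),$$

with $\mu_c, \mu_h \sim N(0,1)$, $\beta_h \sim N(0,3)$ (standard
deviation 3), and half-Student-t(3, 0, 2.5) priors on $\sigma_c$,
$\sigma_h$ and each $\sigma_{e,i}$. The response is the within-trial
z-scaled BLUP; the environmental covariates $x$ (accession) and $X$
(trial) are standardized **jointly** before fitting — this stabilizes the
quadratic term, and because a common affine map is applied to both axes,
$\beta_h$ is unchanged by it. Reported optima are back-transformed to the
raw environmental scale. The prior for $c_{ij}$ is given its own scale
$\sigma_c$ (this scale is sometimes notationally conflated with the
curvature scale; a dedicated, weakly-informative scale is the coherent
choice). One model is fitted per trait and environmental variable.

$\beta_h = 1$ with $\mu_h = 0$ means each trial's optimal
environment-of-origin equals the trial's own environment; positive
$\beta_h$ indicates adaptation along the gradient; $a_i \le 0$ encodes the
local-adaptation expectation of concave response, and
`constrain_negative = FALSE` fits the unconstrained variant used for
sensitivity analysis.

### Sampler

The posterior is simulated by a compiled Metropolis-within-Gibbs scheme:

* $c_{ij}$, $\mu_c$, $(\mu_h, \beta_h)$ — exact conjugate updates;
* $a_i$ — exact truncated-normal (or normal) conjugate update;
* $h_i$ — scalar slice sampling on the **collapsed** target with $a_i$
  integrated out analytically. The per-trial sum of squares is a quartic
  polynomial in $h_i$, so each evaluation is a handful of scalar
  operations on precomputed moments. Collapsing matters: when the transfer
  signal is weak the joint $(a_i, h_i)$ posterior has a ridge
  ($a_i \to 0$, $h_i \to \pm\infty$) that defeats uncollapsed updates;
* $\sigma_c, \sigma_h, \sigma_{e,i}$ — the half-t priors are represented
  with Huang–Wand auxiliary inverse-gamma variables, giving exact Gibbs
  updates; $\sigma_h$ additionally gets an ancillarity–sufficiency
  interweaving move (a slice update of $\log\sigma_h$ in the non-centered
  parameterization that carries the $h_i$ along), which breaks the funnel
  that otherwise traps $\sigma_h$ near zero when the optima sit exactly on
  the regression line.

Four chains of 2000 iterations (half warm-up) are the defaults; the fit
*errors* if any parameter's split-Rhat exceeds 1.1, so a returned object is
always a converged one. Correctness of the posterior is checked in the test
suite against an independent implementation of the same model in JAGS, and
by simulation-based calibration (rank-uniformity of the true $\beta_h$
among posterior draws over prior-predictive replicates; the joint
standardization makes this only approximately exact, which is why the SBC
test uses a conservative $\alpha = 0.01$).

Two caveats established empirically by the acceptance machinery: the
emulated trial design assigns accessions preferentially to home-like
trials, and under that design a concave fit to pure noise places its apex
near the within-trial centroid of origins — a *design* confound that
produces spuriously positive $\beta_h$ under the null. Null-calibration
checks therefore run with unbiased assignment. And at a fixed generator
point with near-zero true optimum scatter, the frequentist coverage of the
95% interval over 20 replicates fluctuates around the nominal-minus-a-bit
range (roughly 75–95% depending on the seed stream) even though the
posterior itself is exact — the usual fixed-point-versus-prior calibration
gap with only ten trials informing $(\beta_h, \sigma_h)$.

## 3. Multivariate variance components and prediction of environment

The seven INT-transformed variables $Y$ ($n \times t$) are modelled with
covariance $G \otimes K + R \otimes I$. Rotating rows by the
eigenvectors of $K$ makes rows independent with covariance
$d_m G + R$, so likelihood, EM updates and BLUP all cost $O(n t^3)$.
Estimation runs a short EM warm start and then maximizes the penalized
likelihood directly over Cholesky factors of $G$ and $R$ with analytic
gradients (L-BFGS); EM alone crawls near the optimum. The penalty is a weak
inverse-Wishart prior on $R$ (mode 0.2 of each variable's variance,
df $t+2$): without it the maximum sits on the $h^2 \to 1$ boundary for
spatially smooth variables — smooth environmental variance is collinear
with kinship structure at desk scale — and boundary estimates make the
downstream whitened tests degenerate, annihilating exactly the planted
clinal directions. The penalty mirrors the regularization a Bayesian
multivariate mixed model applies and brings the elevation genetic fraction
in line with its cross-validated predictability. `resid_prior_df = 0`
recovers plain maximum likelihood.

Predictions for held-out accessions are the multivariate BLUP
$\hat U = (G \otimes K_{\mathrm{test,train}})\Sigma^{-1}
\mathrm{vec}(Y - \bar Y)$ plus training means. Cross-validation offers
random folds and spatially separated folds (k-means on projected
coordinates) with a great-circle buffer (haversine, Earth radius 6371 km,
default 400 km): any training sample within the buffer of a test sample is
excluded, and the leakage invariant is asserted on every run. Components
are re-estimated inside every training fold. The spatial-vs-random
contrast (paired t-tests per variable) is the package's test of whether
genotype–environment correlation survives the removal of spatial
proximity.

## 4. Joint association scans

**envGWAS.** For each SNP the model $Y = XB + E$ is tested with
$\mathrm{cov}(\mathrm{vec}\,E) = G \otimes K + R \otimes I$, where $K$ is
the LOCO kinship for the SNP's chromosome and $(G, R)$ are estimated once
genome-wide. The covariance is factored once per chromosome; the response
and each SNP's $t$ coefficient columns (plus per-variable intercept
columns) are whitened, and the joint F-test has $t$ numerator and
$nt - 2t$ denominator degrees of freedom. The implementation is verified
against a dense GLS oracle that explicitly builds the full $nt \times nt$
covariance (agreement to $10^{-14}$). Setting
`structure_correction = FALSE` replaces $K$ with the identity — the
uncorrected scan used to explore structure-confounded discovery, with the
p-value threshold exposed as a parameter. Monomorphic SNPs are reported as
untested rather than $p = 1$.

At the package's desk scale (500 accessions, 2000 SNPs, marker-to-sample
ratio 4) the structured-null scan is mildly anti-conservative (type-I
fraction ≈ 0.08–0.09 at $\alpha = 0.05$; QQ slope ≈ 1.1–1.25): the
estimated kinship captures the shared smooth spatial space only partially,
so some spatial confounding leaks past the correction. The uncorrected
scan's type-I fraction on the same data is ≈ 0.76, so the correction
removes the overwhelming share of the confounding; with marker densities
like a real panel's (hundreds of markers per sample) the leak shrinks
accordingly. This behaviour is reported as-is by the acceptance script.

**phenoGWAS.** Family BLUPs across trials are tested per SNP with fixed
trial-by-tester effects, a SNP main effect and SNP-by-trial interactions,
under the selected-rows covariance $Z(G \otimes K/4 + R \otimes I)Z'$
(half-sib kinship scaling). The main (1 df) and interaction ($t-1$ df)
F-tests are combined with Fisher's method on 4 df into a single
any-trial association test.

## 5. Clumping and enrichment

Significant SNPs (default $p < 10^{-5}$) are clumped greedily in ascending
p-value order (ties broken by chromosome, then position): a SNP becomes a
lead unless its dosage $r^2$ with an existing lead exceeds 0.3, in which
case it joins the first such lead in creation order. Clumping is
genome-wide because strong parallel clines are mutually correlated across
chromosomes (trans-LD); the synthetic panel reproduces this — planted
clinal loci on different chromosomes clump together. Enrichment compares
the lead SNPs' mean $-\log_{10} p$ of phenotypic association against 1000
MAF-matched random SNP sets (fixed-width 0.02 MAF bins, sampling without
replacement, each bin requiring at least twice as many non-target SNPs as
targets); the enrichment p-value is the plain fraction of null sets with a
strictly larger mean, with the guarded $(1+b)/(1+n)$ version reported
alongside so a literal zero is never the only output.

## 6. The prediction benchmark

Eight models are evaluated per trial within tester folds (train on all
other testers' families, predict the held-out tester's): PCs-only,
PCs + envGWAS lead SNPs, PCs + MAF-matched random SNPs, all-SNPs GBLUP,
all-SNPs + environment, environment-only linear, environment random
forest, and environment + PCs random forest. Responses are corrected for
tester using training-fold tester means; principal components are
recomputed from the kinship of the accessions present in each trial;
marker sets enter as shared-variance random effects (the ridge
equivalent); the single-variance-component REML solver works on the
eigendecomposition of the training kinship and is verified against a dense
mixed-model-equation oracle. Forests use 1000 trees, the regression
default mtry of one third of the features, INT-transformed environments,
and are deterministic given the seed (single-threaded ranger).

Accuracies are compared with the weighted mixed model
`r ~ trial + model + (1 | trial:model) + (1 | trial:fold)`, residual
precision proportional to fold size, and Tukey-adjusted pairwise contrasts
with Satterthwaite degrees of freedom (the containment alternative is
conservative but not available in the contrast machinery used; Satterthwaite
is the field-standard choice here).

The analytic touchstone `expected_accuracy_from_variance(v)` returns
$\sqrt{v}$ — features explaining 5% of variance support an accuracy of
about 0.22 — and the acceptance machinery verifies on a constructed
1000-accession panel with $h^2 = 1$ and five components holding 25% of the
genetic variance that the PCs-only model's fold accuracy lands within
±0.08 of $\sqrt{0.25}$.

## 7. What the generator emulates — and what it does not

`synth_config()` defaults define the study conditions (desk scale):

| parameter | default | anchor |
|---|---|---|
| `n_accessions`, `n_snps`, `n_chroms` | 500, 2000, 10 | desk-scale panel, maize chromosome count |
| `fst` | 0.1 | top genotype PC explains ≈ 4% of variance (PC2 ≈ 2%), the PC variance shares typical of a continental landrace panel (a few percent on PC1) |
| `spatial_range_km` | 300 | regional climate autocorrelation; fields are kernel mixtures of 50 random nodes |
| env noise levels | fixed in `generate_landscape()` | chosen so 10-fold GPoE accuracy lands in the range seen for such panels (≈ 0.84 for elevation/tmax, 0.63–0.81 elsewhere); a dedicated continentality field keeps trange's own spatial signal from cancelling out of tmax − tmin |
| `n_clinal_snps`, `clinal_effect_scale` | 5, 3 | a few large-effect clines near fixation across the gradient, like the known elevation inversions |
| `n_trials`, `families_per_trial`, `n_testers_per_trial` | 10, 300, 3 | trial counts and family sizes of a multi-location testcross evaluation |
| `a_true` | −0.3 | weak concave transfer response: environment-only prediction lands near r ≈ 0.1–0.25 while the transfer model still recovers β_h |
| `beta_h_true`, `mu_h_true`, `sigma_h_true` | 0.8, 0, 0.05 | adaptation slope below unity with near-linear optima |
| `h2_per_trait` | 0.4 | within-trial polygenic fraction of a yield trait |
| `structure_align` | 0.5 | half of the polygenic variance loads on the top five kinship eigenvectors, reproducing the observation that a handful of PCs predict almost as well as the full kinship; 0 gives the purely random causal-SNP architecture |
| `assignment_bias` | 1 | accessions preferentially evaluated in home-like trials, as in the emulated design |
| `tester_effect_sd`, `noise_sd` | 0.5, 0.5 | tester and residual variation before within-trial z-scaling |

Not emulated: plot-level replication and the BLUP-fitting stage (family
values stand in for deregressed BLUPs, with an optional deregression step
when prediction-error variances are supplied), linkage disequilibrium
within chromosomes (SNPs are exchangeable given the spatial fields, so
physical clumping windows are not meaningful here), missing genotype
patterns of real sequencing, and year/location crossing of trials.
Consequently, passing tests demonstrate correct and well-behaved
*machinery* under a faithful statistical caricature — not performance on
any real panel.

Two generator switches matter for calibration experiments:
`assignment_bias = 0` removes the design confound when testing the
transfer model's null behaviour, and `structure_align = 0` removes
structure–environment confounding when measuring pure slope recovery; both
uses are deliberate and noted where they occur.

## 8. Numerical choices and degenerate inputs

* GRM centering uses $2p$ per SNP with MAF recomputed after sample
  filtering; missing dosages are mean-imputed per SNP after filtering.
* Eigenvalues of kinship and covariance matrices are clipped at zero
  (tolerance $10^{-8}$ of the trace); non-PD whitening blocks receive a
  single $10^{-8}$-scale ridge before failing.
* INT ties use average ranks; a constant vector returns zeros with a
  warning.
* PCA signs are fixed by making each component's largest-magnitude loading
  positive.
* k-means spatial folds re-seed up to ten times before declaring the
  configuration degenerate; identical coordinates error out.
* Equal-p clumping ties break by (chromosome, position); a SNP tagging
  several leads joins the first-created one.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds from one global seed, and two runs with the same
  configuration produce byte-identical outputs (checksums in the
  manifest), forests and MCMC included.

## 9. Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run at deliberately modest sizes
chosen as the package's own validation conditions: transfer-model recovery
and null behaviour on 20 replicates of 10 trials × 300 families;
association-scan calibration and power at 500 accessions × 2000 SNPs;
GPoE contrasts at 300 accessions × 1000 SNPs with ten folds per scheme;
benchmark orderings over 20 default-scale replicates; and the
√(variance-explained) check at 1000 accessions. Each replicate stream is
seeded deterministically from a single integer.

## 10. Known limitations

* The whitened association test treats the estimated $(G, R)$ as known;
  with few markers per sample the estimated kinship under-captures shared
  smooth spatial variation and the structured-null scan inherits mild
  inflation (section 4). The package reports this honestly rather than
  re-tuning thresholds.
* LOCO kinship removes proximal contamination but cannot remove spatial
  confounding that markers never captured.
* The transfer model fits one trait–variable pair at a time; no
  multivariate borrowing across traits.
* `estimate_trial_components()` for phenoGWAS uses complete-case
  accessions across trials and falls back to an equal-split diagonal when
  too few exist; very sparse designs should supply their own trial-level
  covariance.
* The comparison mixed model can be singular when fold counts are small;
  singular fits are accepted (they reduce to the fixed-effect comparison)
  rather than failed.
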