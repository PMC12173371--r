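# Greedy LD clumping of significant SNPs and MAF-matched resampling
# enrichment of lead SNPs against phenotypic association results.

#' Pairwise r-squared between SNP dosage columns
#'
#' Squared Pearson correlations between dosage vectors; the post-imputation
#' dosage analogue of LD.
#'
#' @param geno A [geno_matrix()].
#' @param snp_ids SNPs to correlate (at least two).
#' @return Symmetric matrix of r-squared values with unit diagonal.
#' @export
pairwise_r2 <- function(geno, snp_ids) {
  if (length(snp_ids) < 2) {
    stop_landrace("need at least 2 SNPs for pairwise r2",
                  "landrace_value_error")
  }
  miss <- setdiff(snp_ids, geno$variants$snp_id)
  if (length(miss)) {
    stop_landrace(paste0("unknown SNPs: ",
                         paste(utils::head(miss, 3), collapse = ", ")),
                  "landrace_value_error")
  }
  x <- geno$dosages[, snp_ids, drop = FALSE]
  v <- apply(x, 2, var)
  if (any(v < 1e-12)) {
    stop_landrace(paste0("constant dosage column: ",
                         paste(snp_ids[v < 1e-12], collapse = ", ")),
                  "landrace_value_error")
  }
  r2 <- cor(x)^2
  diag(r2) <- 1
  r2
}

#' Greedy LD clumping of significant SNPs
#'
#' Iterates the SNPs below `p_threshold` in ascending p-value order (ties
#' broken by chromosome then position). Each SNP becomes a new lead unless
#' its dosage r-squared with an existing lead exceeds `r2_threshold`, in
#' which case it joins the first such lead in lead-creation order. Clumping
#' is genome-wide: cross-chromosome LD is allowed to capture trans-LD and
#' mis-mapping.
#'
#' @param gwas A `gwas_table` (columns `snp_id`, `chrom`, `pos`, `p`).
#' @param geno The [geno_matrix()] providing dosages.
#' @param p_threshold Significance threshold for SNPs entering clumping.
#' @param r2_threshold LD threshold above which a SNP joins a lead.
#' @return A tibble of class `clump_result`: one row per lead with
#'   `lead_snp`, `chrom`, `pos`, `lead_p`, `n_members` and a `members`
#'   list-column (member SNPs, lead excluded). Empty (zero rows) when no
#'   SNP passes the threshold.
#' @export
greedy_clump <- function(gwas, geno, p_threshold = 1e-5, r2_threshold = 0.3) {
  sig <- gwas[gwas$p < p_threshold, , drop = FALSE]
  empty <- tibble::tibble(
    lead_snp = character(), chrom = character(), pos = integer(),
    lead_p = numeric(), n_members = integer(), members = list()
  )
  if (nrow(sig) == 0) {
    message("no SNP passes the significance threshold; empty clump result")
    return(new_clump_result(empty, p_threshold, r2_threshold))
  }
  miss <- setdiff(sig$snp_id, geno$variants$snp_id)
  if (length(miss)) {
    stop_landrace("gwas and geno must share SNP ids", "landrace_value_error")
  }
  sig <- sig[order(sig$p, match(sig$chrom, unique(geno$variants$chrom)),
                   sig$pos), , drop = FALSE]
  dos <- geno$dosages[, sig$snp_id, drop = FALSE]
  leads <- integer(0)
  assignment <- integer(nrow(sig))  # 0 = lead
  for (i in seq_len(nrow(sig))) {
    joined <- 0L
    for (l in leads) {
      r2 <- suppressWarnings(cor(dos[, i], dos[, l])^2)
      if (is.finite(r2) && r2 > r2_threshold) {
        joined <- l
        break
      }
    }
    if (joined == 0L) leads <- c(leads, i) else assignment[i] <- joined
  }
  res <- tibble::tibble(
    lead_snp = sig$snp_id[leads],
    chrom = sig$chrom[leads],
    pos = sig$pos[leads],
    lead_p = sig$p[leads],
    n_members = vapply(leads, function(l) sum(assignment == l), integer(1)),
    members = lapply(leads, function(l) sig$snp_id[assignment == l])
  )
  new_clump_result(res, p_threshold, r2_threshold)
}

new_clump_result <- function(tbl, p_threshold, r2_threshold) {
  attr(tbl, "p_threshold") <- p_threshold
  attr(tbl, "r2_threshold") <- r2_threshold
  class(tbl) <- c("clump_result", class(tbl))
  tbl
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("<clump_result> %d lead SNP(s) (p < %g, r2 > %g), %d member SNP(s)\n",
              nrow(x), attr(x, "p_threshold"), attr(x, "r2_threshold"),
              sum(x$n_members)))
  NextMethod()
}

#' MAF-matched random SNP sets
#'
#' Draws `n_sets` random SNP sets, each the size of `target_snps`, matching
#' the targets' minor-allele-frequency distribution bin-for-bin
#' (fixed-width bins). Sampling is without replacement within a set and
#' deterministic given the seed.
#'
#' @param geno A [geno_matrix()].
#' @param target_snps SNP ids to match.
#' @param n_sets Number of matched sets.
#' @param maf_bin_width Width of the MAF bins.
#' @param seed Integer seed.
#' @return List of character vectors of SNP ids.
#' @export
sample_maf_matched <- function(geno, target_snps, n_sets = 1000,
                               maf_bin_width = 0.02, seed = 1) {
  v <- geno$variants
  miss <- setdiff(target_snps, v$snp_id)
  if (length(miss)) {
    stop_landrace("target SNPs absent from genotype matrix",
                  "landrace_value_error")
  }
  bin <- floor(v$maf / maf_bin_width)
  names(bin) <- v$snp_id
  target_bins <- bin[target_snps]
  is_target <- v$snp_id %in% target_snps
  pool <- split(v$snp_id[!is_target], bin[v$snp_id[!is_target]])
  need <- table(target_bins)
  for (b in names(need)) {
    avail <- length(pool[[b]])
    if (avail < 2 * need[[b]]) {
      stop_landrace(sprintf(
        "MAF bin [%0.2f, %0.2f) has %d non-target SNPs for %d target(s); need at least 2x",
        as.numeric(b) * maf_bin_width, (as.numeric(b) + 1) * maf_bin_width,
        avail, need[[b]]), "landrace_value_error")
    }
  }
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    unname(unlist(lapply(names(need), function(b) {
      sample(pool[[b]], need[[b]])
    })))
  })
}

#' Enrichment of lead SNPs for phenotypic association
#'
#' Compares the mean -log10 phenotypic-association p-value of the lead SNPs
#' against the null distribution formed by MAF-matched SNP sets. The
#' enrichment p-value is the fraction of null sets with a strictly larger
#' mean; a guarded version `(1 + b) / (1 + n)` that never reaches exactly
#' zero is reported alongside.
#'
#' @param lead_snps Character vector of lead SNP ids.
#' @param pheno_gwas A `gwas_table` from [pheno_gwas()] (column `p`).
#' @param null_sets List of SNP-id sets from [sample_maf_matched()].
#' @param trait Trait label recorded in the output.
#' @return One-row tibble: `trait`, `observed_mean_neglog10p`, `p_enrich`,
#'   `p_enrich_guarded`, `n_sets`.
#' @export
enrichment_test <- function(lead_snps, pheno_gwas, null_sets, trait = NA) {
  lookup <- setNames(pheno_gwas$p, pheno_gwas$snp_id)
  all_needed <- unique(c(lead_snps, unlist(null_sets)))
  miss <- setdiff(all_needed, names(lookup))
  if (length(miss)) {
    stop_landrace(paste0("SNPs missing from phenotypic GWAS: ",
                         paste(utils::head(miss, 3), collapse = ", ")),
                  "landrace_value_error")
  }
  obs <- mean(-log10(lookup[lead_snps]))
  null_means <- vapply(null_sets, function(s) mean(-log10(lookup[s])),
                       numeric(1))
  b <- sum(null_means > obs)
  n <- length(null_sets)
  tibble::tibble(
    trait = trait,
    observed_mean_neglog10p = obs,
    p_enrich = b / n,
    p_enrich_guarded = (1 + b) / (1 + n),
    n_sets = n
  )
}
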