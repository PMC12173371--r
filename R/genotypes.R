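# Genotype containers, I/O, variant QC, kinship and PCA.

#' Construct a genotype matrix object
#'
#' Bundles a samples-by-SNPs dosage matrix (counts of the alternate allele,
#' 0/1/2, possibly `NA`) with its variant table. Minor allele frequencies are
#' always recomputed from the dosages, never trusted from metadata.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns. Row names
#'   are sample identifiers, column names SNP identifiers.
#' @param variants Data frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per dosage column, in column order.
#' @return An object of class `geno_matrix`: a list with elements `dosages`,
#'   `variants` (tibble including a recomputed `maf` column), `sample_ids`
#'   and `sample_missing` (per-sample missingness fraction).
#' @export
geno_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- tibble::as_tibble(variants)
  if (ncol(dosages) != nrow(variants)) {
    stop_landrace("number of dosage columns must equal number of variants",
                  "landrace_dim_error")
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- variants$snp_id
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop_landrace("dosages must lie in [0, 2]", "landrace_value_error")
  }
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  variants$maf <- compute_maf(dosages)
  structure(
    list(
      dosages = dosages,
      variants = variants,
      sample_ids = rownames(dosages),
      sample_missing = rowMeans(is.na(dosages))
    ),
    class = "geno_matrix"
  )
}

compute_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs on %d chromosome(s); %.2f%% missing\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chrom)),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Read genotypes from VCF or a plain dosage table
#'
#' For VCF input only the GT field is used; dosages are the count of the
#' alternate allele and missing genotypes (`./.`) become `NA`. Multi-allelic
#' records are skipped with a warning reporting how many were dropped. For
#' `dosage_tsv` input, the file is a tab-separated samples-by-SNPs matrix
#' (header row of SNP ids, first column sample id) accompanied by a variant
#' table TSV with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path Path to the genotype file.
#' @param format Either `"vcf"` or `"dosage_tsv"`.
#' @param variants_path Path to the variant table TSV (required for
#'   `dosage_tsv`).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv"),
                           variants_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_landrace(paste0("file not found: ", path), "landrace_io_error")
  }
  if (format == "vcf") {
    read_genotypes_vcf(path)
  } else {
    if (is.null(variants_path)) {
      stop_landrace("dosage_tsv input requires `variants_path`",
                    "landrace_io_error")
    }
    dos <- read.delim(path, check.names = FALSE, row.names = 1)
    variants <- tibble::as_tibble(read.delim(
      variants_path, check.names = FALSE,
      colClasses = c(chrom = "character", ref = "character",
                     alt = "character", snp_id = "character")
    ))
    geno_matrix(as.matrix(dos), variants)
  }
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_landrace("reading VCF requires the vcfR package", "landrace_io_error")
  }
  # Cheap structural pre-scan so malformed records are reported with a line
  # number rather than an opaque downstream failure.
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (length(body) && length(unique(nfield)) > 1) {
    bad <- body[which(nfield != nfield[1])[1]]
    stop_landrace(sprintf("malformed VCF record at line %d: %d fields, expected %d",
                          bad, nfield[which(nfield != nfield[1])[1]], nfield[1]),
                  "landrace_parse_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% character())
  if (any(multi)) {
    warning(sprintf("skipped %d multi-allelic site(s)", sum(multi)),
            call. = FALSE)
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  dosages <- t(dos)
  variants <- tibble::tibble(
    snp_id = fix$ID,
    chrom = as.character(fix$CHROM),
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  no_id <- is.na(variants$snp_id) | variants$snp_id == "."
  variants$snp_id[no_id] <- paste0("S", variants$chrom[no_id], "_",
                                   variants$pos[no_id])
  geno_matrix(dosages, variants)
}

gt_to_dosage <- function(g) {
  if (is.na(g)) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

#' Write genotypes as a dosage table plus variant table
#'
#' @param geno A [geno_matrix()].
#' @param path Output TSV path for the dosage matrix.
#' @param variants_path Output TSV path for the variant table.
#' @return Invisibly, `geno`.
#' @export
write_genotypes <- function(geno, path, variants_path) {
  df <- data.frame(sample_id = rownames(geno$dosages), geno$dosages,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(geno$variants[, c("snp_id", "chrom", "pos", "ref", "alt")],
              variants_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(geno)
}

#' Filter samples and variants, then mean-impute
#'
#' Samples with missingness above `max_sample_missing` are removed first.
#' Monomorphic SNPs and SNPs with minor allele frequency at or below
#' `maf_min` (recomputed after sample removal) are then dropped, and any
#' remaining missing dosages are replaced by the per-SNP mean.
#'
#' @param geno A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency; SNPs are kept when
#'   `maf > maf_min`.
#' @param max_sample_missing Maximum tolerated per-sample missingness.
#' @return A filtered [geno_matrix()] with no missing dosages.
#' @export
filter_variants <- function(geno, maf_min = 0.01, max_sample_missing = 0.25) {
  keep_s <- geno$sample_missing <= max_sample_missing
  dos <- geno$dosages[keep_s, , drop = FALSE]
  maf <- compute_maf(dos)
  keep_v <- !is.na(maf) & maf > maf_min & maf > 0
  if (!any(keep_v)) {
    stop_landrace("no SNPs remain after filtering", "landrace_empty_error")
  }
  dos <- dos[, keep_v, drop = FALSE]
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  geno_matrix(dos, geno$variants[keep_v, setdiff(names(geno$variants), "maf"),
                                 drop = FALSE])
}

#' Genomic relationship matrix
#'
#' Computes the VanRaden-style genomic relationship matrix
#' \eqn{K = X_c X_c^T / (2\sum_m p_m(1-p_m))} from dosages centered by twice
#' the alternate allele frequency, using SNPs with minor allele frequency
#' above `maf_min`. `scale_factor` rescales the whole matrix (use 1/4 for
#' half-sib testcross analyses).
#'
#' @param geno A [geno_matrix()]; missing dosages are mean-imputed.
#' @param maf_min MAF threshold for SNPs entering the kinship estimate.
#' @param scale_factor Positive multiplier applied to the matrix.
#' @return A `kinship_matrix`: list with `values` (n x n symmetric matrix),
#'   `sample_ids` and `scale_factor`.
#' @export
compute_grm <- function(geno, maf_min = 0.05, scale_factor = 1) {
  maf <- geno$variants$maf
  keep <- !is.na(maf) & maf > maf_min
  if (sum(keep) < 2) {
    stop_landrace("fewer than 2 SNPs above `maf_min` for kinship",
                  "landrace_empty_error")
  }
  dos <- geno$dosages[, keep, drop = FALSE]
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(dos) / 2
  xc <- sweep(dos, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  k <- tcrossprod(xc) / denom * scale_factor
  k <- (k + t(k)) / 2
  structure(
    list(values = k, sample_ids = rownames(dos), scale_factor = scale_factor,
         n_snps = sum(keep)),
    class = "kinship_matrix"
  )
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d samples, %d SNPs, scale %.3g, mean diag %.3f\n",
              length(x$sample_ids), x$n_snps %||% NA_integer_,
              x$scale_factor, mean(diag(x$values))))
  invisible(x)
}

#' Leave-one-chromosome-out genomic relationship matrix
#'
#' Identical to [compute_grm()] but restricted to SNPs not on
#' `held_out_chrom`, so association tests on that chromosome do not absorb
#' their own signal through the kinship correction.
#'
#' @inheritParams compute_grm
#' @param held_out_chrom Chromosome to exclude.
#' @return A `kinship_matrix`.
#' @export
compute_loco_grm <- function(geno, held_out_chrom, maf_min = 0.05,
                             scale_factor = 1) {
  chroms <- unique(geno$variants$chrom)
  if (length(chroms) < 2) {
    stop_landrace("LOCO kinship requires at least 2 chromosomes",
                  "landrace_value_error")
  }
  if (!held_out_chrom %in% chroms) {
    stop_landrace(paste0("chromosome not present: ", held_out_chrom),
                  "landrace_value_error")
  }
  keep <- geno$variants$chrom != held_out_chrom
  sub <- geno_matrix(geno$dosages[, keep, drop = FALSE],
                     geno$variants[keep, setdiff(names(geno$variants), "maf"),
                                   drop = FALSE])
  compute_grm(sub, maf_min = maf_min, scale_factor = scale_factor)
}

#' Principal components of the genotype matrix
#'
#' Extracts principal components of a randomly sampled SNP subset
#' (default 5000 SNPs) of the column-centered dosage matrix via singular
#' value decomposition. The sign of each component is fixed so that its
#' largest-magnitude SNP loading is positive, making runs comparable.
#'
#' @param geno A [geno_matrix()] without missing dosages (run
#'   [filter_variants()] first).
#' @param n_snps Number of SNPs to sample; if more than available, all SNPs
#'   are used with a message.
#' @param n_components Number of components to return.
#' @param seed Integer seed controlling the SNP subsample.
#' @return A list of class `genotype_pca` with `scores` (tibble with
#'   `sample_id` and `PC1..PCk`), `var_explained` (fractions of the subset
#'   variance) and `snp_ids` used.
#' @export
genotype_pca <- function(geno, n_snps = 5000, n_components = 5, seed = 1) {
  n <- nrow(geno$dosages)
  if (n_components > n) {
    stop_landrace("n_components exceeds number of samples",
                  "landrace_value_error")
  }
  m <- ncol(geno$dosages)
  if (n_snps > m) {
    message(sprintf("only %d SNPs available; using all of them", m))
    n_snps <- m
  }
  set.seed(seed)
  idx <- sort(sample.int(m, n_snps))
  x <- geno$dosages[, idx, drop = FALSE]
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    nas <- which(is.na(x), arr.ind = TRUE)
    x[nas] <- mu[nas[, 2]]
  }
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = n_components, nv = n_components)
  total_var <- sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (j in seq_len(n_components)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) {
      scores[, j] <- -scores[, j]
      sv$v[, j] <- -load
    }
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(
    list(
      scores = tibble::tibble(sample_id = rownames(geno$dosages),
                              tibble::as_tibble(scores)),
      var_explained = sv$d[seq_len(n_components)]^2 / total_var,
      snp_ids = geno$variants$snp_id[idx],
      seed = seed
    ),
    class = "genotype_pca"
  )
}

#' Rank-based inverse normal transform
#'
#' Maps values through their (average-tie) ranks to standard normal
#' quantiles, \eqn{\Phi^{-1}((r_i - c)/(N + 1 - 2c))}, with Blom's offset
#' `c = 3/8` by default. A constant input vector is returned as all zeros
#' with a warning.
#'
#' @param values Numeric vector without missing values.
#' @param offset_c Rank offset constant.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' int_transform(c(10, 20, 30))
int_transform <- function(values, offset_c = 3 / 8) {
  if (anyNA(values)) {
    stop_landrace("int_transform requires complete values",
                  "landrace_value_error")
  }
  n <- length(values)
  if (n == 0) return(numeric(0))
  if (length(unique(values)) == 1) {
    if (n > 1) {
      warning("constant input: all ranks tied, returning zeros", call. = FALSE)
    }
    return(rep(0, n))
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - offset_c) / (n + 1 - 2 * offset_c))
}
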