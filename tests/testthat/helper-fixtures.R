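# Shared fixtures and small utilities for the test suite. Expensive
# objects are built once per session and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

# Small synthetic dataset shared by several test files.
small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_dataset(synth_config(
      n_accessions = 150, n_snps = 300, n_trials = 5,
      families_per_trial = 60, seed = 4242
    ))
  }
  .fixtures$small
}

# Hand-built genotype matrix from a dosage matrix (one chromosome unless
# chrom given).
toy_geno <- function(dos, chrom = NULL, pos = NULL) {
  m <- ncol(dos)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- ave(seq_len(m), chrom, FUN = seq_along) * 100L
  geno_matrix(dos, tibble::tibble(
    snp_id = paste0("s", seq_len(m)), chrom = chrom, pos = as.integer(pos),
    ref = "A", alt = "T"
  ))
}

# Slope of the observed vs expected -log10 p QQ line, through the origin.
qq_slope <- function(p) {
  ex <- -log10(ppoints(length(p)))
  ob <- sort(-log10(p), decreasing = TRUE)
  sum(ob * ex) / sum(ex^2)
}

# INT env matrix aligned with a filtered genotype matrix.
env_int_matrix <- function(ds, geno) {
  ids <- geno$sample_ids
  Y <- as.matrix(ds$env[match(ids, ds$env$sample_id),
                        paste0(env_variables(), "_int")])
  rownames(Y) <- ids
  colnames(Y) <- env_variables()
  Y
}

# Write a small VCF fixture; returns the path.
write_test_vcf <- function(lines_extra = character()) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\tsnp1\tA\tT\t.\t.\t.\tGT\t0/1\t1/1\t./.",
    "1\t200\tsnp2\tG\tC\t.\t.\t.\tGT\t0|0\t0/1\t1/1",
    "2\t50\tsnp3\tT\tA\t.\t.\t.\tGT\t0/0\t0/0\t0/1",
    lines_extra
  ), path)
  path
}
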