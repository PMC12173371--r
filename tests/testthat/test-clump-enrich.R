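# Greedy LD clumping and MAF-matched enrichment.

# Exhaustive oracle for the greedy clumping rule: walk SNPs in ascending-p
# order, checking r2 against leads in creation order.
clump_oracle <- function(p, r2mat, r2_threshold) {
  ord <- order(p)
  leads <- integer(0)
  assign <- integer(length(p))
  for (i in ord) {
    joined <- 0L
    for (l in leads) {
      if (r2mat[i, l] > r2_threshold) {
        joined <- l
        break
      }
    }
    if (joined == 0L) leads <- c(leads, i) else assign[i] <- joined
  }
  list(leads = leads, assign = assign)
}

make_gwas_tbl <- function(geno, p) {
  tibble::tibble(snp_id = geno$variants$snp_id, chrom = geno$variants$chrom,
                 pos = geno$variants$pos, p = p)
}

test_that("pairwise r2 matches longhand covariance arithmetic", {
  dos <- cbind(c(0, 1, 2, 2, 1, 0), c(0, 1, 2, 1, 1, 0))
  g <- toy_geno(dos)
  r2 <- pairwise_r2(g, c("s1", "s2"))
  hand <- (cov(dos[, 1], dos[, 2])^2) / (var(dos[, 1]) * var(dos[, 2]))
  expect_equal(r2[1, 2], hand, tolerance = 1e-12)
  expect_equal(diag(r2), c(s1 = 1, s2 = 1))
  # duplicated column
  g2 <- toy_geno(cbind(dos, dos[, 1]))
  expect_equal(pairwise_r2(g2, c("s1", "s3"))[1, 2], 1)
  # constant column is named in the error
  g3 <- toy_geno(cbind(dos, 2))
  expect_error(pairwise_r2(g3, c("s1", "s3")), "s3",
               class = "landrace_value_error")
})

test_that("independent SNPs show near-zero background r2", {
  set.seed(71)
  dos <- sapply(runif(30, 0.2, 0.8), function(p) rbinom(500, 2, p))
  g <- toy_geno(dos)
  r2 <- pairwise_r2(g, g$variants$snp_id)
  expect_lt(mean(r2[upper.tri(r2)]), 0.02)
})

test_that("greedy clumping matches the exhaustive oracle on LD fixtures", {
  set.seed(72)
  n <- 120
  base1 <- rbinom(n, 2, 0.5)
  base2 <- rbinom(n, 2, 0.4)
  flip <- function(x, k) {
    i <- sample(n, k)
    x[i] <- 2 - x[i]
    x
  }
  # two LD blocks (columns 1-3 and 4-5) plus an independent SNP
  dos <- cbind(base1, flip(base1, 8), flip(base1, 12),
               base2, flip(base2, 6), rbinom(n, 2, 0.5))
  g <- toy_geno(dos, chrom = c("1", "1", "2", "2", "3", "3"))
  p <- c(1e-9, 1e-7, 1e-8, 1e-10, 1e-6, 1e-12)
  gw <- make_gwas_tbl(g, p)
  cl <- greedy_clump(gw, g, p_threshold = 1e-5, r2_threshold = 0.3)
  r2m <- pairwise_r2(g, g$variants$snp_id)
  orc <- clump_oracle(p, r2m, 0.3)
  expect_setequal(cl$lead_snp, g$variants$snp_id[orc$leads])
  for (k in seq_along(orc$leads)) {
    l <- orc$leads[k]
    got <- cl$members[[match(g$variants$snp_id[l], cl$lead_snp)]]
    expect_setequal(got, g$variants$snp_id[orc$assign == l])
  }
  # invariants: exclusive membership, leads mutually below threshold
  all_members <- unlist(cl$members)
  expect_equal(anyDuplicated(all_members), 0)
  if (nrow(cl) > 1) {
    lr2 <- pairwise_r2(g, cl$lead_snp)
    expect_true(all(lr2[upper.tri(lr2)] <= 0.3))
  }
  # row order of the GWAS table does not matter
  cl2 <- greedy_clump(gw[sample(nrow(gw)), ], g, 1e-5, 0.3)
  expect_equal(cl2$lead_snp, cl$lead_snp)
})

test_that("clumping edge cases: no LD, ties, empty input", {
  set.seed(73)
  dos <- sapply(runif(6, 0.3, 0.7), function(p) rbinom(400, 2, p))
  g <- toy_geno(dos, chrom = rep(c("1", "2"), each = 3))
  p <- c(1e-8, 1e-7, 1e-6, 0.5, 0.9, 1e-9)
  cl <- greedy_clump(make_gwas_tbl(g, p), g, 1e-5, 0.3)
  expect_setequal(cl$lead_snp, c("s1", "s2", "s3", "s6"))  # all leads
  # ties broken by (chrom, pos): duplicate column with equal p
  g2 <- toy_geno(cbind(dos[, 1], dos[, 1]), chrom = c("1", "1"))
  cl2 <- greedy_clump(make_gwas_tbl(g2, c(1e-8, 1e-8)), g2, 1e-5, 0.3)
  expect_equal(cl2$lead_snp, "s1")   # earlier coordinate wins
  expect_equal(cl2$members[[1]], "s2")
  expect_message(
    cl0 <- greedy_clump(make_gwas_tbl(g, rep(0.5, 6)), g, 1e-5, 0.3),
    "no SNP"
  )
  expect_equal(nrow(cl0), 0)
})

test_that("MAF-matched sets reproduce the target histogram bin-for-bin", {
  set.seed(74)
  dos <- sapply(runif(300, 0.05, 0.95), function(p) rbinom(200, 2, p))
  g <- toy_geno(dos)
  targets <- g$variants$snp_id[c(5, 50, 120, 200)]
  sets <- sample_maf_matched(g, targets, n_sets = 50, seed = 5)
  expect_length(sets, 50)
  maf <- setNames(g$variants$maf, g$variants$snp_id)
  bin <- function(ids) sort(table(floor(maf[ids] / 0.02)))
  tb <- bin(targets)
  for (s in sets[1:10]) {
    expect_length(s, length(targets))
    expect_false(any(s %in% targets))
    expect_equal(bin(s), tb)
  }
  # pooled matched MAF distribution is compatible with the targets
  pooled <- table(floor(maf[unlist(sets)] / 0.02))
  expected <- tb[names(pooled)] / sum(tb) * sum(pooled)
  chi <- sum((pooled - expected)^2 / expected)
  expect_lt(chi, qchisq(0.99, length(pooled) - 1))
  # determinism
  sets2 <- sample_maf_matched(g, targets, n_sets = 50, seed = 5)
  expect_identical(sets, sets2)
  # under-populated bin
  g_small <- toy_geno(dos[, 1:6])
  expect_error(
    sample_maf_matched(g_small, g_small$variants$snp_id[1:5], n_sets = 2),
    "MAF bin", class = "landrace_value_error"
  )
})

test_that("enrichment p-values are calibrated and hit the extremes", {
  set.seed(75)
  m <- 400
  dos <- sapply(rep(0.5, m), function(p) rbinom(60, 2, p))
  g <- toy_geno(dos)
  pg <- make_gwas_tbl(g, runif(m))
  # all SNPs share one MAF bin: matched sets are simple random draws; leads
  # drawn from the same pool give a uniform enrichment p
  ids <- g$variants$snp_id
  p_en <- replicate(200, {
    leads <- sample(ids, 10)
    nulls <- lapply(1:40, function(i) sample(setdiff(ids, leads), 10))
    enrichment_test(leads, pg, nulls)$p_enrich
  })
  expect_lt(abs(mean(p_en) - 0.5), 0.06)
  # leads holding the smallest p-values are maximally enriched
  best <- ids[order(pg$p)][1:10]
  nulls <- sample_maf_matched(g, best, n_sets = 100, seed = 2)
  en <- enrichment_test(best, pg, nulls, trait = "FW")
  expect_equal(en$p_enrich, 0)
  expect_gt(en$p_enrich_guarded, 0)
  expect_error(enrichment_test(c("nope"), pg, nulls),
               class = "landrace_value_error")
})

test_that("a planted clinal region in LD collapses to a single lead", {
  set.seed(76)
  ds <- generate_dataset(synth_config(
    n_accessions = 250, n_snps = 400, n_clinal_snps = 1,
    clinal_effect_scale = 3, n_trials = 3, families_per_trial = 80,
    seed = 77
  ))
  geno0 <- ds$geno
  # surround the clinal SNP with high-LD neighbours
  j <- ds$truth$clinal$index
  snp <- geno0$dosages[, j]
  neigh <- sapply(1:3, function(k) {
    x <- snp
    i <- sample(length(x), 10)
    x[i] <- rbinom(10, 2, mean(x) / 2)
    x
  })
  dos <- cbind(geno0$dosages, neigh)
  v <- geno0$variants[, c("snp_id", "chrom", "pos", "ref", "alt")]
  vn <- tibble::tibble(
    snp_id = paste0("ld", 1:3), chrom = v$chrom[j],
    pos = v$pos[j] + 1:3, ref = "A", alt = "T"
  )
  g <- geno_matrix(dos, dplyr::bind_rows(v, vn))
  K <- compute_grm(filter_variants(g))
  geno_f <- filter_variants(g)
  Y <- env_int_matrix(ds, geno_f)
  vc <- suppressWarnings(estimate_multitrait_components(Y, K))
  gw <- env_gwas(geno_f, Y, vc)
  cl <- greedy_clump(gw, geno_f)
  sig <- significant_snps(gw)
  ld_block <- c(ds$truth$clinal$snp_id, paste0("ld", 1:3))
  if (sum(sig$snp_id %in% ld_block) >= 2) {
    expect_equal(sum(cl$lead_snp %in% ld_block), 1)
  }
})
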