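# QC filters: hand-enumerated toy fixtures, boundary behaviour, idempotence,
# and the pi-hat relatedness estimator against a likelihood oracle.

toy_gm <- function() {
  # v_mono: no alternate alleles (MAF 0); v_miss: 40% missing calls;
  # v_ok: common and complete
  geno <- cbind(
    v_mono = rep(0, 10),
    v_miss = c(NA, NA, NA, NA, 1, 1, 0, 2, 1, 0),
    v_ok   = c(0, 1, 2, 1, 0, 1, 2, 1, 0, 1)
  )
  genotype_matrix(geno,
                  variants = data.frame(id = colnames(geno), chrom = "1",
                                        pos = c(100L, 200L, 300L),
                                        ref = "A", alt = "G",
                                        stringsAsFactors = FALSE))
}

test_that("variant filters reproduce the hand-enumerated toy fixture", {
  res <- filter_variants(toy_gm())
  expect_identical(res$genotypes$variants$id, "v_ok")
  rep <- res$report$removed
  expect_setequal(rep$item, c("v_mono", "v_miss"))
  expect_identical(rep$reason[rep$item == "v_mono"], "maf")
  expect_identical(rep$reason[rep$item == "v_miss"], "call_rate")
})

test_that("variant filter boundaries are strict and zero thresholds are identity", {
  g <- toy_gm()
  res0 <- filter_variants(g, maf_min = 0, call_rate_min = 0)
  expect_identical(res0$genotypes$variants$id, g$variants$id)
  expect_identical(nrow(res0$report$removed), 0L)
  # MAF exactly at the threshold is kept (strict '<'): 1 alt in 100 alleles
  geno <- matrix(0, 50, 1); geno[1, 1] <- 1
  gm <- genotype_matrix(geno)
  expect_identical(ncol(filter_variants(gm, maf_min = 0.01)$genotypes$geno), 1L)
  expect_identical(ncol(filter_variants(gm, maf_min = 0.0100001)$genotypes$geno), 0L)
})

test_that("per-group MAF removes variants rare in any one group", {
  geno <- rbind(matrix(1, 30, 1), matrix(0, 30, 1))  # common overall
  samples <- data.frame(id = sprintf("s%02d", 1:60),
                        group = rep(c("EU", "AA"), each = 30))
  gm <- genotype_matrix(geno, samples = samples)
  expect_identical(ncol(filter_variants(gm)$genotypes$geno), 0L)
  expect_identical(ncol(filter_variants(gm, per_group = FALSE)$genotypes$geno), 1L)
})

test_that("filters are idempotent and the report partitions the input", {
  g <- toy_gm()
  r1 <- filter_variants(g)
  r2 <- filter_variants(r1$genotypes)
  expect_identical(r1$genotypes$geno, r2$genotypes$geno)
  expect_identical(nrow(r2$report$removed), 0L)
  expect_setequal(c(r1$genotypes$variants$id, r1$report$removed$item),
                  g$variants$id)
})

test_that("sample call-rate filter removes low-call-rate samples only", {
  geno <- matrix(1, 4, 20)
  geno[1, 1:2] <- NA   # 90% call rate -> removed at 0.95
  gm <- genotype_matrix(geno)
  res <- filter_samples(gm)
  expect_identical(res$report$removed$item, gm$samples$id[1])
  expect_identical(nrow(res$genotypes$geno), 3L)
  full <- filter_samples(genotype_matrix(matrix(1, 4, 5)))
  expect_identical(nrow(full$report$removed), 0L)
  expect_identical(nrow(filter_samples(gm, 0)$report$removed), 0L)
  all_bad <- genotype_matrix(matrix(NA_real_, 3, 10))
  expect_error(filter_samples(all_bad), "every sample")
})

test_that("pi-hat: self, duplicate and unrelated pairs behave as expected", {
  set.seed(61)
  freqs <- runif(5000, 0.1, 0.9)
  # background cohort keeps the study allele-frequency estimates stable
  geno <- sim_hwe_geno(60, freqs)
  # duplicate of sample 1 with 5% independent missingness
  dup <- geno[1, ]
  both <- rbind(geno, dup)
  rownames(both) <- NULL
  gm <- genotype_matrix(both)
  gm$geno[61, runif(5000) < 0.05] <- NA
  gm$geno[1, runif(5000) < 0.05] <- NA
  expect_gt(estimate_pihat(gm, 1, 1), 0.99)
  expect_gt(estimate_pihat(gm, 1, 61), 0.9)
  expect_lt(abs(estimate_pihat(gm, 2, 3)), 0.05)
  # unreliable flag below the overlap floor
  small <- genotype_matrix(sim_hwe_geno(3, freqs[1:20]))
  expect_true(attr(estimate_pihat(small, 1, 2), "unreliable"))
})

test_that("pi-hat agrees with the likelihood IBD oracle on simulated pairs", {
  set.seed(62)
  freqs <- runif(25000, 0.2, 0.8)
  background <- sim_hwe_geno(60, freqs)
  n_pairs <- 20
  for (k in seq_len(n_pairs)) {
    kind <- c("unrelated", "duplicate", "parent_child")[(k %% 3) + 1]
    g1 <- drop(sim_hwe_geno(1, freqs))
    g2 <- switch(kind,
      unrelated = drop(sim_hwe_geno(1, freqs)),
      duplicate = g1,
      # child shares exactly one allele IBD per site
      parent_child = rbinom(25000, 1, g1 / 2) + rbinom(25000, 1, freqs)
    )
    geno <- rbind(background, g1, g2)
    rownames(geno) <- NULL
    gm <- genotype_matrix(geno)
    ph <- estimate_pihat(gm, 61, 62)
    orc <- oracle_pihat(g1, g2, est_freq(gm$geno))
    expect_lt(abs(as.numeric(ph) - orc), 0.02)
  }
})

test_that("relatedness pruning keeps the higher-call-rate member, greedily", {
  set.seed(63)
  freqs <- runif(3000, 0.2, 0.8)
  base <- sim_hwe_geno(4, freqs)
  geno <- rbind(base, base[1, ], base[1, ])  # samples 5,6 duplicate sample 1
  rownames(geno) <- NULL
  gm <- genotype_matrix(geno)
  gm$geno[5, sample(3000, 300)] <- NA  # worst call rate
  gm$geno[6, sample(3000, 150)] <- NA
  res <- remove_related(gm)
  # trio of mutual duplicates: two removed, best-called member retained
  expect_setequal(res$report$removed$item, gm$samples$id[c(5, 6)])
  expect_true(gm$samples$id[1] %in% res$genotypes$samples$id)
  expect_true(all(res$report$removed$reason == "relatedness"))
  # unrelated cohort: nothing removed
  clean <- remove_related(genotype_matrix(base))
  expect_identical(nrow(clean$report$removed), 0L)
  # single duplicated pair: exactly the more-missing member removed
  pair_geno <- rbind(base[2, ], base[2, ], base[3, ])
  rownames(pair_geno) <- NULL
  pair <- genotype_matrix(pair_geno)
  pair$geno[1, sample(3000, 200)] <- NA
  rp <- remove_related(pair)
  expect_identical(rp$report$removed$item, pair$samples$id[1])
})

test_that("info-score filter removes poorly imputed variants only", {
  geno <- matrix(rbinom(10 * 7, 2, 0.5), 10, 7)
  variants <- data.frame(
    id = sprintf("v%d", 1:7), chrom = "1", pos = 1:7 * 100L,
    ref = "A", alt = "G",
    imputed = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    info_r2 = c(NA, NA, 0.2, 0.5, 0.8, 0.9, 1.0),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(geno, variants)
  res <- filter_info(gm)
  expect_identical(sum(res$genotypes$variants$imputed), 3L)  # 0.8, 0.9, 1.0
  expect_setequal(res$report$removed$item, c("v3", "v4"))
  # boundary: 0.79 removed, 0.80 kept (strict '<'); no imputed -> identity
  expect_identical(
    filter_info(gm, r2_min = 0.801)$genotypes$variants$id,
    c("v1", "v2", "v6", "v7")
  )
  plain <- filter_info(genotype_matrix(geno[, 1:2]))
  expect_identical(ncol(plain$genotypes$geno), 2L)
})
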