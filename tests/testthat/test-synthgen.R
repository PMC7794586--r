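# Generators: shape contracts, seed determinism, frequency/LD behaviour,
# and recovery of planted effects by the downstream estimators.

test_that("haplotype panel honours shape, values and seed determinism", {
  spec <- ancestry_spec("EU", 12, 0.3, ld_rho = 0.4)
  p1 <- simulate_haplotype_panel(spec, 200, seed = 11)
  p2 <- simulate_haplotype_panel(spec, 200, seed = 11)
  p3 <- simulate_haplotype_panel(spec, 200, seed = 12)
  expect_identical(dim(p1$haplotypes), c(200L, 12L))
  expect_true(all(p1$haplotypes %in% c(0L, 1L)))
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_false(identical(p1$haplotypes, p3$haplotypes))
  expect_error(simulate_haplotype_panel(spec, 201, seed = 1), "even")
  expect_error(ancestry_spec("X", 3, c(0, 0.5, 0.5)), "inside")
})

test_that("per-site allele frequencies converge to the spec", {
  spec <- ancestry_spec("EU", 6, 0.5, ld_rho = 0)
  p <- simulate_haplotype_panel(spec, 10000, seed = 3)
  f <- colMeans(p$haplotypes)
  se3 <- 3 * sqrt(0.5 * 0.5 / 10000)
  expect_true(all(abs(f - 0.5) < se3))
})

test_that("LD is near zero at ld_rho = 0 and non-decreasing in ld_rho", {
  adj_r2 <- function(rho, n_hap, seed) {
    spec <- ancestry_spec("EU", 8, 0.5, ld_rho = rho)
    h <- simulate_haplotype_panel(spec, n_hap, seed)$haplotypes
    mean(sapply(1:7, function(j) stats::cor(h[, j], h[, j + 1])^2))
  }
  r2_zero <- {
    spec <- ancestry_spec("EU", 8, 0.5, ld_rho = 0)
    h <- simulate_haplotype_panel(spec, 10000, seed = 5)$haplotypes
    cm <- stats::cor(h)
    mean(cm[upper.tri(cm)]^2)
  }
  expect_lt(r2_zero, 0.01)
  lev <- sapply(c(0, 0.3, 0.6, 0.9), adj_r2, n_hap = 6000, seed = 7)
  expect_true(all(diff(lev) >= 0))
})

test_that("case-control simulator recovers null and non-null odds ratios", {
  spec <- ancestry_spec("EU", 5, 0.3, ld_rho = 0.5,
                        n_cases = 2000, n_controls = 2000)
  panel <- simulate_haplotype_panel(spec, 4000, seed = 21)
  null_coh <- simulate_case_control(panel, 3, 1.0, seed = 22)
  r0 <- logistic_scan(null_coh, variants = 3)$records
  expect_lt(abs(r0$BETA), 3 * r0$SE)
  coh <- simulate_case_control(panel, 3, 1.5, seed = 23)
  r <- logistic_scan(coh, variants = 3)$records
  expect_lt(abs(r$BETA - log(1.5)), 3 * r$SE)
  # quotas and status coding
  expect_identical(sum(coh$status == 1), 2000L)
  expect_identical(sum(coh$status == 0), 2000L)
  expect_true(all(coh$admixture >= 0) && all(rowSums(coh$admixture) <= 1))
  expect_error(simulate_case_control(panel, 3, 1.5, base_rate = 0),
               "unattainable")
  expect_error(simulate_case_control(panel, 99, 1.5), "out of range")
})

test_that("a mid-range planted effect ranks in the top p-values of the scan", {
  hits <- 0L
  for (r in 1:100) {
    spec <- ancestry_spec("EU", 12, 0.3, ld_rho = 0.5,
                          n_cases = 1000, n_controls = 1000)
    panel <- simulate_haplotype_panel(spec, 3000, seed = 3000 + r)
    coh <- simulate_case_control(panel, 6, 1.35, seed = 4000 + r)
    p <- logistic_scan(coh)$records$P
    hits <- hits + (rank(p, ties.method = "min")[6] <= 5)
  }
  expect_gte(hits, 90)
})

test_that("eQTL expression generator: noiseless limit, null calibration, recovery", {
  spec <- ancestry_spec("YRI", 3, 0.4, ld_rho = 0)
  panel <- simulate_haplotype_panel(spec, 116, seed = 31)
  coh <- simulate_case_control(panel, NA, 1.0, n_cases = 29, n_controls = 29,
                               missing_rate = 0, seed = 32)
  g <- coh$genotypes
  # noiseless limit: slope -> beta, residual variance -> 0
  e0 <- simulate_eqtl_expression(g, beta = 2, noise_sd = 1e-9,
                                 n_null_genes = 0, variant = 1, seed = 33)
  r0 <- eqtl_scan(g, e0, gene = "MIR146A")$records
  r0 <- r0[r0$ID == g$variants$id[1], ]
  expect_equal(r0$SLOPE, 2, tolerance = 1e-6)
  # null: slope p-values approximately uniform over replicates
  pvals <- sapply(1:200, function(r) {
    e <- simulate_eqtl_expression(g, beta = 0, noise_sd = 1,
                                  n_null_genes = 0, variant = 1,
                                  seed = 5000 + r)
    rec <- eqtl_scan(g, e, gene = "MIR146A")$records
    rec$P[rec$ID == g$variants$id[1]]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  # recovery at n = 58
  e1 <- simulate_eqtl_expression(g, beta = 1, noise_sd = 1,
                                 n_null_genes = 0, variant = 1, seed = 34)
  r1 <- eqtl_scan(g, e1, gene = "MIR146A")$records
  r1 <- r1[r1$ID == g$variants$id[1], ]
  expect_identical(r1$N, 58L)
  expect_lt(abs(r1$SLOPE - 1), 3 * r1$SE)
  expect_error(simulate_eqtl_expression(g, beta = 1, noise_sd = 0), "positive")
})

test_that("IFN panel generator matches its generative law", {
  p <- simulate_ifn_panel(20, 20, seed = 41)
  expect_identical(dim(p$values), c(40L, 4L))
  expect_identical(colnames(p$values), c("IFI27", "IFIT3", "OAS1", "LY6E"))
  # no treated shift: score location shift within Monte-Carlo noise
  big <- simulate_ifn_panel(200, 200, seed = 42)
  s <- ifn_score(big)
  d <- mean(s$score[!s$nc_mask]) - mean(s$score[s$nc_mask])
  se <- stats::sd(s$score) * sqrt(2 / 200)
  expect_lt(abs(d), 3 * se)
  # shift of -1 SD in each of the four genes forces a mean score near -4
  sh <- simulate_ifn_panel(200, 200, treated_shift = -1 * c(2, 2, 1, 1),
                           seed = 43)
  ssh <- ifn_score(sh)
  expect_lt(abs(mean(ssh$score[!ssh$nc_mask]) - (-4)), 0.45)
  expect_error(simulate_ifn_panel(1, 5), "NC")
})

test_that("T7 band generator hits the exact boundary cases", {
  b0 <- simulate_t7_bands(0, noise_cv = 0)
  expect_identical(c(b0$b, b0$c), c(0, 0))
  b1 <- simulate_t7_bands(1, noise_cv = 0)
  expect_identical(b1$a, 0)
  expect_equal(t7_efficiency(simulate_t7_bands(0.5, noise_cv = 0)),
               100 * (1 - sqrt(0.5)), tolerance = 1e-12)
  expect_error(simulate_t7_bands(1.2), "0, 1")
})
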