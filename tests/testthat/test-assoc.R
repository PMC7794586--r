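# Logistic and linear association scans: closed-form fixtures, the
# brute-force likelihood oracle, calibration, and conditional analysis.

carrier_gm <- function(case_carriers, case_non, ctrl_carriers, ctrl_non) {
  g <- c(rep(1, case_carriers), rep(0, case_non),
         rep(1, ctrl_carriers), rep(0, ctrl_non))
  y <- rep(c(1, 0), c(case_carriers + case_non, ctrl_carriers + ctrl_non))
  list(gm = genotype_matrix(matrix(g, ncol = 1)), y = y)
}

test_that("single-binary-predictor beta equals the 2x2 log odds ratio", {
  d <- carrier_gm(60, 40, 40, 60)
  r <- logistic_scan(d$gm, d$y)$records
  expect_equal(r$BETA, log((60 * 60) / (40 * 40)), tolerance = 1e-8)
  expect_true(r$CONVERGED)
  expect_equal(r$P, 2 * pnorm(-abs(r$Z)), tolerance = 1e-12)
  balanced <- carrier_gm(50, 50, 50, 50)
  expect_equal(logistic_scan(balanced$gm, balanced$y)$records$BETA, 0,
               tolerance = 1e-10)
})

test_that("scan beta matches brute-force likelihood maximisation with a covariate", {
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(20:30, 1)
    g <- rbinom(n, 2, 0.4)
    cv <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.2 + 0.5 * g + 0.3 * cv))
    if (length(unique(y)) < 2 || length(unique(g)) < 2) next
    r <- logistic_scan(genotype_matrix(matrix(g, ncol = 1)), y,
                       covariates = matrix(cv, ncol = 1))$records
    if (!r$CONVERGED) next
    ref <- oracle_logistic(y, cbind(cv, g))
    expect_lt(abs(r$BETA - ref[3]), 1e-4)
  }
})

test_that("an orthogonal covariate leaves beta unchanged on a symmetric fixture", {
  # duplicate every observation with covariate +c and -c: by symmetry the
  # covariate coefficient is 0 and beta reduces to the covariate-free MLE
  d <- carrier_gm(60, 40, 40, 60)
  g2 <- rbind(d$gm$geno, d$gm$geno)
  rownames(g2) <- NULL
  y2 <- c(d$y, d$y)
  cv <- c(rep(1, 200), rep(-1, 200))
  gm2 <- genotype_matrix(g2)
  b_with <- logistic_scan(gm2, y2, covariates = matrix(cv))$records$BETA
  b_without <- logistic_scan(gm2, y2)$records$BETA
  expect_lt(abs(b_with - b_without), 1e-6)
})

test_that("missing genotypes are dropped per variant (complete-case)", {
  set.seed(72)
  g <- rbinom(80, 2, 0.4)
  y <- rbinom(80, 1, plogis(0.4 * g))
  g_na <- g; g_na[1:10] <- NA
  r_na <- logistic_scan(genotype_matrix(matrix(g_na, ncol = 1)), y)$records
  r_sub <- logistic_scan(genotype_matrix(matrix(g[-(1:10)], ncol = 1)),
                         y[-(1:10)])$records
  expect_identical(r_na$N, 70L)
  expect_equal(r_na$BETA, r_sub$BETA, tolerance = 1e-12)
})

test_that("separation and monomorphic variants are flagged, never silent numbers", {
  y <- rep(c(1, 0), each = 20)
  sep <- genotype_matrix(matrix(c(rep(2, 20), rep(0, 20)), ncol = 1))
  r <- logistic_scan(sep, y)$records
  expect_false(r$CONVERGED)
  expect_true(is.na(r$P))
  mono <- genotype_matrix(matrix(1, 40, 1))
  rm <- logistic_scan(mono, y)$records
  expect_false(rm$CONVERGED)
})

test_that("null scan p-values are uniform", {
  set.seed(73)
  n <- 300
  geno <- sim_hwe_geno(n, runif(1000, 0.1, 0.9))
  y <- rbinom(n, 1, 0.5)
  p <- logistic_scan(genotype_matrix(geno), y)$records$P
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("conditioning a variant on itself exercises the aliased path", {
  set.seed(74)
  g <- rbinom(100, 2, 0.5)
  y <- rbinom(100, 1, plogis(0.3 * g))
  gm <- genotype_matrix(matrix(g, ncol = 1))
  r <- logistic_scan(gm, y, variants = 1, condition_on = 1)$records
  expect_false(r$CONVERGED)
  expect_true(is.na(r$P))
})

test_that("stepwise conditioning finds two unlinked planted effects", {
  two_step <- 0L
  for (r in 1:10) {
    set.seed(8000 + r)
    # two causal variants on unlinked blocks: independent genotypes, both
    # feeding a single logistic disease model
    n <- 2500
    geno <- sim_hwe_geno(n, rep(0.4, 10))
    y <- rbinom(n, 1, plogis(-1 + log(2) * geno[, 3] + log(2) * geno[, 8]))
    tr <- conditional_stepwise(genotype_matrix(geno), y)
    if (length(tr$steps) == 2 &&
        setequal(tr$conditioned, c("v00003", "v00008"))) {
      two_step <- two_step + 1L
    }
  }
  expect_gte(two_step, 7L)
})

test_that("eQTL slope matches the closed form and the noiseless limit", {
  set.seed(75)
  g <- rbinom(40, 2, 0.5)
  gm <- genotype_matrix(matrix(g, ncol = 1))
  expr <- matrix(2 * g, ncol = 1,
                 dimnames = list(gm$samples$id, "MIR146A"))
  r <- eqtl_scan(gm, expr)$records
  expect_equal(r$SLOPE, 2, tolerance = 1e-10)
  expect_lt(r$P, 1e-12)
  y <- 0.7 * g + rnorm(40)
  expr2 <- matrix(y, ncol = 1, dimnames = list(gm$samples$id, "MIR146A"))
  r2 <- eqtl_scan(gm, expr2)$records
  expect_equal(r2$SLOPE, stats::cov(g, y) / stats::var(g), tolerance = 1e-10)
  # cross-check SE/t against lm()
  lf <- summary(stats::lm(y ~ g))$coefficients
  expect_equal(r2$SE, lf["g", "Std. Error"], tolerance = 1e-10)
  expect_equal(r2$P, lf["g", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("conditioning on the causal variant abrogates proxy eQTL signals", {
  abrogated <- 0L
  n_rep <- 30
  for (r in 1:n_rep) {
    spec <- ancestry_spec("YRI", 6, 0.4, ld_rho = 0.8)
    panel <- simulate_haplotype_panel(spec, 120, seed = 9000 + r)
    coh <- simulate_case_control(panel, NA, 1.0, n_cases = 29,
                                 n_controls = 29, missing_rate = 0,
                                 seed = 9100 + r)
    g <- coh$genotypes
    e <- simulate_eqtl_expression(g, beta = 1.5, noise_sd = 1,
                                  n_null_genes = 0, variant = 3,
                                  seed = 9200 + r)
    causal_id <- g$variants$id[3]
    cond <- eqtl_scan(g, e, gene = "MIR146A", condition_on = causal_id)
    rec <- cond$records[cond$records$ID != causal_id, ]
    ok <- rec$CONVERGED & !is.na(rec$P)
    if (all(rec$P[ok] > 1e-4)) abrogated <- abrogated + 1L
  }
  expect_gte(abrogated, 0.9 * n_rep)
})

test_that("constant genotypes in the eQTL scan are flagged without estimates", {
  gm <- genotype_matrix(matrix(1, 30, 1))
  expr <- matrix(rnorm(30), ncol = 1,
                 dimnames = list(gm$samples$id, "MIR146A"))
  r <- eqtl_scan(gm, expr)$records
  expect_false(r$CONVERGED)
  expect_true(is.na(r$SLOPE))
})
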