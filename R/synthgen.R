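#' Ancestry specification for the synthetic cohort generator
#'
#' Describes one ancestral cohort: the regional variants (alternate-allele
#' frequencies, positions) and the latent linkage-disequilibrium strength used
#' when simulating haplotypes, plus the case/control quotas.
#'
#' @param name cohort label, e.g. `"EU"`, `"AA"`, `"AS"`, `"AI"`.
#' @param n_variants number of variants in the region.
#' @param alt_freqs alternate-allele frequency per variant, each in (0, 1).
#' @param ld_rho adjacent-site latent correlation in [0, 1). Larger values
#'   produce stronger local LD and hence stronger shadow associations at
#'   non-causal sites.
#' @param positions strictly increasing 1-based positions (default 1000 bp
#'   spacing).
#' @param n_cases,n_controls case/control quotas for [simulate_case_control()].
#' @return an object of class `ancestry_spec`.
#' @export
ancestry_spec <- function(name, n_variants, alt_freqs, ld_rho = 0.5,
                          positions = NULL, n_cases = 1000, n_controls = 1000) {
  if (length(alt_freqs) == 1L) alt_freqs <- rep(alt_freqs, n_variants)
  if (length(alt_freqs) != n_variants) {
    stop("alt_freqs must have one frequency per variant")
  }
  if (any(alt_freqs <= 0 | alt_freqs >= 1)) {
    stop("alt_freqs must lie strictly inside (0, 1)")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (is.null(positions)) positions <- seq_len(n_variants) * 1000L
  if (length(positions) != n_variants || any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing with one entry per variant")
  }
  structure(
    list(name = name, n_variants = as.integer(n_variants),
         alt_freqs = alt_freqs, ld_rho = ld_rho,
         positions = as.integer(positions),
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls)),
    class = "ancestry_spec"
  )
}

#' Simulate a haplotype panel with tunable local LD
#'
#' Haplotypes are drawn from a latent AR(1) Gaussian process along the region:
#' each haplotype carries latent values \eqn{z_j = \rho z_{j-1} +
#' \sqrt{1-\rho^2}\,\epsilon_j} and the alternate allele is called where
#' \eqn{z_j > \Phi^{-1}(1 - f_j)}, so marginal allele frequencies hit the
#' specified `alt_freqs` while adjacent-site allelic correlation grows with
#' `ld_rho`. This is deliberately simple: it produces the multi-variant shadow
#' associations that fine-mapping must resolve without any demographic realism.
#'
#' @param spec an [ancestry_spec()].
#' @param n_hap number of haplotypes (even; pairs form diploid individuals).
#' @param seed integer seed; all randomness flows from it.
#' @return a `hap_panel`: list with binary `haplotypes` (n_hap x n_variants)
#'   and the `spec`.
#' @export
simulate_haplotype_panel <- function(spec, n_hap, seed) {
  stopifnot(inherits(spec, "ancestry_spec"))
  if (n_hap < 2 || n_hap %% 2 != 0) stop("n_hap must be even and >= 2")
  set.seed(as.integer(seed))
  m <- spec$n_variants
  rho <- spec$ld_rho
  z <- matrix(stats::rnorm(n_hap * m), n_hap, m)
  if (rho > 0 && m > 1) {
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  thr <- stats::qnorm(1 - spec$alt_freqs)
  h <- matrix(0L, n_hap, m)
  h[sweep(z, 2, thr, ">")] <- 1L
  structure(list(haplotypes = h, spec = spec), class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel (%s): %d haplotypes x %d variants, ld_rho=%.2f\n",
              x$spec$name, nrow(x$haplotypes), ncol(x$haplotypes),
              x$spec$ld_rho))
  invisible(x)
}

# internal: Dirichlet(1,1,1,1) admixture proportions, first three retained
r_admixture <- function(n) {
  g <- matrix(stats::rgamma(n * 4, shape = 1), n, 4)
  (g / rowSums(g))[, 1:3, drop = FALSE]
}

#' Simulate a case-control cohort with one planted causal variant
#'
#' Individuals are formed by pairing random haplotypes from the panel; disease
#' status is drawn from the additive logistic model
#' \deqn{\mathrm{logit}\,P(\mathrm{case}) = \mathrm{logit}(p_0) +
#'   \ln(\mathrm{OR})\, g_{\mathrm{causal}} + \gamma' a}
#' where \eqn{a} are three admixture proportions (Dirichlet over four
#' components, first three retained). Because the disease model is logistic,
#' the simulated per-allele odds ratio is exactly the logistic-regression
#' estimand recovered by [logistic_scan()]. Sampling continues until the case
#' and control quotas are met; genotypes are then masked missing completely at
#' random at `missing_rate`.
#'
#' @param panel a `hap_panel` from [simulate_haplotype_panel()].
#' @param causal_index column index of the causal variant (or `NA` for a null
#'   region).
#' @param or_per_allele per-allele odds ratio (> 0); disease-relevant values
#'   for a common-variant association are around 1.2-1.5.
#' @param base_rate baseline case probability at genotype 0 and zero admixture
#'   effect, strictly inside (0, 1).
#' @param admixture_effect length-3 log-odds coefficients on the admixture
#'   proportions (population-stratification confounding when non-zero).
#' @param n_cases,n_controls quotas; defaults from the panel's spec.
#' @param missing_rate per-call missing probability (MCAR).
#' @param seed integer seed.
#' @return a `cohort`: list with `genotypes` (a [genotype_matrix()]), `status`
#'   (0 control / 1 case), `admixture` (n x 3), `causal_index`, `true_or`.
#' @export
simulate_case_control <- function(panel, causal_index, or_per_allele,
                                  base_rate = 0.1,
                                  admixture_effect = c(0, 0, 0),
                                  n_cases = panel$spec$n_cases,
                                  n_controls = panel$spec$n_controls,
                                  missing_rate = 0.02, seed = 1) {
  stopifnot(inherits(panel, "hap_panel"))
  h <- panel$haplotypes
  m <- ncol(h)
  if (!is.na(causal_index) && (causal_index < 1 || causal_index > m)) {
    stop("causal_index out of range")
  }
  if (or_per_allele <= 0) stop("or_per_allele must be positive")
  if (base_rate <= 0 || base_rate >= 1) {
    stop("base_rate must lie strictly inside (0, 1): quotas unattainable")
  }
  if (length(admixture_effect) != 3) stop("admixture_effect must have length 3")
  set.seed(as.integer(seed))
  n_target <- n_cases + n_controls
  geno <- matrix(NA_real_, n_target, m)
  admix <- matrix(NA_real_, n_target, 3)
  status <- integer(n_target)
  got_cases <- 0L; got_controls <- 0L; filled <- 0L
  max_draws <- 2000L * n_target
  drawn <- 0L
  batch <- max(256L, n_target)
  while ((got_cases < n_cases || got_controls < n_controls) &&
         drawn < max_draws) {
    i1 <- sample.int(nrow(h), batch, replace = TRUE)
    i2 <- sample.int(nrow(h), batch, replace = TRUE)
    g <- h[i1, , drop = FALSE] + h[i2, , drop = FALSE]
    a <- r_admixture(batch)
    eta <- stats::qlogis(base_rate) + drop(a %*% admixture_effect)
    if (!is.na(causal_index)) {
      eta <- eta + log(or_per_allele) * g[, causal_index]
    }
    y <- stats::rbinom(batch, 1, stats::plogis(eta))
    drawn <- drawn + batch
    keep <- (y == 1 & got_cases < n_cases) | (y == 0 & got_controls < n_controls)
    # fill quotas in draw order, never exceeding either quota
    for (b in which(keep)) {
      if (y[b] == 1 && got_cases < n_cases) {
        got_cases <- got_cases + 1L
      } else if (y[b] == 0 && got_controls < n_controls) {
        got_controls <- got_controls + 1L
      } else next
      filled <- filled + 1L
      geno[filled, ] <- g[b, ]
      admix[filled, ] <- a[b, ]
      status[filled] <- y[b]
    }
  }
  if (got_cases < n_cases || got_controls < n_controls) {
    stop(sprintf("case/control quota unattainable after %d draws", drawn))
  }
  if (missing_rate > 0) {
    geno[matrix(stats::runif(n_target * m) < missing_rate, n_target, m)] <- NA
  }
  spec <- panel$spec
  variants <- data.frame(
    id = sprintf("v%05d", spec$positions), chrom = "1", pos = spec$positions,
    ref = "A", alt = "G", imputed = FALSE, info_r2 = NA_real_,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    id = sprintf("%s_s%05d", spec$name, seq_len(n_target)),
    group = spec$name, stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(geno, variants, samples)
  structure(
    list(genotypes = gm, status = status, admixture = admix,
         causal_index = causal_index, true_or = or_per_allele),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "cohort (%s): %d cases / %d controls, %d variants, causal=%s (OR %.3f)\n",
    x$genotypes$samples$group[1], sum(x$status == 1), sum(x$status == 0),
    ncol(x$genotypes$geno),
    if (is.na(x$causal_index)) "none"
    else x$genotypes$variants$id[x$causal_index],
    x$true_or
  ))
  invisible(x)
}

#' Simulate genotype-additive gene expression for eQTL scans
#'
#' The target gene's expression is `beta * g + N(0, noise_sd^2)` where `g` is
#' the alternate-allele count at the focal variant; the remaining genes are
#' pure Gaussian noise (no genetic signal), giving a null background for
#' trans-scan calibration.
#'
#' @param genotypes a [genotype_matrix()] (or `cohort`).
#' @param target_gene id for the regulated gene.
#' @param beta per-allele expression shift (expression units per alt allele).
#' @param noise_sd residual SD (> 0).
#' @param n_null_genes number of unregulated noise genes.
#' @param variant focal variant (column index or id); default the first.
#' @param seed integer seed.
#' @return an [expression_matrix()] with the target gene first.
#' @export
simulate_eqtl_expression <- function(genotypes, target_gene = "MIR146A",
                                     beta = 1, noise_sd = 1,
                                     n_null_genes = 9, variant = 1, seed = 1) {
  if (inherits(genotypes, "cohort")) genotypes <- genotypes$genotypes
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (is.character(variant)) {
    variant <- match(variant, genotypes$variants$id)
  }
  g <- genotypes$geno[, variant]
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)  # generator-side fill
  set.seed(as.integer(seed))
  n <- length(g)
  vals <- cbind(
    beta * g + stats::rnorm(n, 0, noise_sd),
    matrix(stats::rnorm(n * n_null_genes, 0, noise_sd), n, n_null_genes)
  )
  colnames(vals) <- c(target_gene,
                      if (n_null_genes > 0) sprintf("NULLG%03d", seq_len(n_null_genes)))
  rownames(vals) <- genotypes$samples$id
  expression_matrix(vals)
}

#' Simulate a negative-control/treated interferon-signature panel
#'
#' Generates relative expression for the four interferon-inducible signature
#' genes (IFI27, IFIT3, OAS1, LY6E). Negative-control (NC) samples are drawn
#' `N(gene_means, gene_sds^2)` per gene; treated samples are shifted by
#' `treated_shift`. Feeds [ifn_score()].
#'
#' @param n_nc number of NC samples (>= 2, so the NC SD is defined).
#' @param n_treated number of treated samples.
#' @param gene_means,gene_sds length-4 NC means and SDs (SDs > 0).
#' @param treated_shift length-4 additive shift for treated samples.
#' @param seed integer seed.
#' @return an [expression_matrix()] with `groups` of `"NC"` / `"treated"`.
#' @export
simulate_ifn_panel <- function(n_nc, n_treated,
                               gene_means = c(10, 8, 6, 4),
                               gene_sds = c(2, 2, 1, 1),
                               treated_shift = c(0, 0, 0, 0), seed = 1) {
  if (n_nc < 2) stop("need at least 2 NC samples to define the NC SD")
  stopifnot(length(gene_means) == 4, length(gene_sds) == 4,
            length(treated_shift) == 4)
  if (any(gene_sds <= 0)) stop("gene_sds must be positive")
  set.seed(as.integer(seed))
  genes <- c("IFI27", "IFIT3", "OAS1", "LY6E")
  n <- n_nc + n_treated
  mu <- rbind(
    matrix(gene_means, n_nc, 4, byrow = TRUE),
    matrix(gene_means + treated_shift, n_treated, 4, byrow = TRUE)
  )
  sd <- matrix(gene_sds, n, 4, byrow = TRUE)
  vals <- matrix(stats::rnorm(n * 4, mu, sd), n, 4)
  colnames(vals) <- genes
  rownames(vals) <- c(sprintf("NC%03d", seq_len(n_nc)),
                      sprintf("TR%03d", seq_len(n_treated)))
  expression_matrix(vals, groups = rep(c("NC", "treated"), c(n_nc, n_treated)))
}

#' Simulate T7 endonuclease I band intensities
#'
#' Splits a total intensity into substrate `a = (1 - f) * scale` and cleavage
#' products `b + c = f * scale` (split equally), then applies multiplicative
#' log-normal noise with coefficient of variation `noise_cv` per band.
#'
#' @param true_cleaved_fraction cleaved fraction f in [0, 1].
#' @param noise_cv per-band multiplicative noise CV (0 for exact bands).
#' @param scale total intensity before noise.
#' @param seed integer seed.
#' @return a [t7_bands()] object.
#' @export
simulate_t7_bands <- function(true_cleaved_fraction, noise_cv = 0,
                              scale = 100, seed = 1) {
  f <- true_cleaved_fraction
  if (f < 0 || f > 1) stop("true_cleaved_fraction must lie in [0, 1]")
  set.seed(as.integer(seed))
  bands <- c(a = (1 - f) * scale, b = f * scale / 2, c = f * scale / 2)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    bands <- bands * stats::rlnorm(3, -sdlog^2 / 2, sdlog)  # mean-1 noise
  }
  t7_bands(bands[["a"]], bands[["b"]], bands[["c"]])
}
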