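#' @title Quality-control filters for genotype data
#' @description Variant- and sample-level filters matching standard
#'   case-control GWAS practice: per-group minor-allele-frequency and
#'   call-rate variant filters, imputation info-score filtering, sample
#'   call-rate filtering, and relatedness pruning on the method-of-moments
#'   IBD estimate pi-hat. Filters are applied in the order
#'   variants -> sample call rate -> relatedness, since the sample filters are
#'   defined over variants that pass the variant filters.
#' @name qc
NULL

new_qc_report <- function(items, thresholds) {
  if (is.null(items) || nrow(items) == 0) {
    items <- data.frame(item = character(), type = character(),
                        reason = character(), value = numeric(),
                        threshold = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(removed = items, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$removed), "items removed\n")
  if (nrow(x$removed)) {
    tab <- table(x$removed$type, x$removed$reason)
    print(tab)
  }
  cat("thresholds:",
      paste(sprintf("%s=%s", names(x$thresholds),
                    unlist(x$thresholds)), collapse = ", "), "\n")
  invisible(x)
}

#' Filter variants on per-group MAF and overall call rate
#'
#' A variant is removed if its minor allele frequency is below `maf_min` in
#' any ancestral group (when `per_group = TRUE`; otherwise overall), or if its
#' overall call rate is below `call_rate_min`. Both comparisons are strict
#' (`<`), so a variant sitting exactly at a threshold is kept. For dosage
#' data the allele frequency is the mean dosage divided by 2 and any
#' non-missing dosage counts as a call. A group in which a variant has no
#' calls at all is treated as MAF 0 for that variant (removed).
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum per-group minor allele frequency (default 0.01).
#' @param call_rate_min minimum overall variant call rate (default 0.90).
#' @param per_group evaluate MAF within each sample group (requires group
#'   labels); default `TRUE`.
#' @return list with elements `genotypes` (filtered) and `report`
#'   (a `qc_report`; each removed variant carries one reason, `maf` taking
#'   precedence over `call_rate`).
#' @export
filter_variants <- function(g, maf_min = 0.01, call_rate_min = 0.90,
                            per_group = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  groups <- if (per_group) unique(g$samples$group) else "all"
  maf_by_group <- sapply(groups, function(grp) {
    rows <- if (identical(grp, "all")) seq_len(nrow(g$geno))
            else which(g$samples$group == grp)
    if (length(rows) == 0) stop("empty sample group: ", grp)
    f <- alt_freq(g$geno[rows, , drop = FALSE])
    f[is.nan(f)] <- 0  # no calls in this group
    pmin(f, 1 - f)
  })
  maf_by_group <- matrix(maf_by_group, ncol = length(groups))
  min_maf <- apply(maf_by_group, 1, min)
  call_rate <- colMeans(!is.na(g$geno))
  fail_maf <- min_maf < maf_min
  fail_cr <- call_rate < call_rate_min
  removed <- fail_maf | fail_cr
  items <- if (any(removed)) data.frame(
    item = g$variants$id[removed], type = "variant",
    reason = ifelse(fail_maf[removed], "maf", "call_rate"),
    value = ifelse(fail_maf[removed], min_maf[removed], call_rate[removed]),
    threshold = ifelse(fail_maf[removed], maf_min, call_rate_min),
    stringsAsFactors = FALSE
  ) else NULL
  list(
    genotypes = subset_gm(g, variants = which(!removed)),
    report = new_qc_report(items, list(maf_min = maf_min,
                                       call_rate_min = call_rate_min,
                                       per_group = per_group))
  )
}

#' Filter samples on genotyping call rate
#'
#' Removes samples whose call rate across the (already variant-filtered)
#' genotypes falls below `sample_call_rate_min`. Note the conventional
#' direction is implemented — samples with *low* call rates are excluded;
#' descriptions of this rule are sometimes printed with the inequality
#' inverted, which would discard the best-genotyped samples.
#'
#' @param g a [genotype_matrix()] (apply [filter_variants()] first).
#' @param sample_call_rate_min minimum sample call rate (default 0.95,
#'   strict `<`).
#' @return list with `genotypes` and `report`.
#' @export
filter_samples <- function(g, sample_call_rate_min = 0.95) {
  stopifnot(inherits(g, "genotype_matrix"))
  cr <- rowMeans(!is.na(g$geno))
  removed <- cr < sample_call_rate_min
  if (all(removed)) stop("sample call-rate filter removed every sample")
  items <- if (any(removed)) data.frame(
    item = g$samples$id[removed], type = "sample", reason = "call_rate",
    value = cr[removed], threshold = sample_call_rate_min,
    stringsAsFactors = FALSE
  ) else NULL
  list(
    genotypes = subset_gm(g, samples = which(!removed)),
    report = new_qc_report(items,
                           list(sample_call_rate_min = sample_call_rate_min))
  )
}

# internal: expected IBS-class probabilities per site given the alt/ref
# allele counts a, b (x = a + b alleles observed). Frequency monomials are
# estimated by their unbiased factorial-moment estimators, e.g.
# p^2 q^2 -> a(a-1)b(b-1)/x^(4), the small-sample correction the standard
# GWAS toolkits apply; with `exact = TRUE` the plain monomials of p = a/x
# are used (appropriate when reference frequencies are supplied).
ibs_expectations <- function(a, b, exact = FALSE) {
  x <- a + b
  if (exact) {
    p <- a / x
    q <- b / x
    m22 <- p^2 * q^2; m31 <- p^3 * q; m13 <- p * q^3
    m40 <- p^4; m04 <- q^4; m11 <- p * q
    m20 <- p^2; m02 <- q^2
  } else {
    x4 <- x * (x - 1) * (x - 2) * (x - 3)
    x2 <- x * (x - 1)
    m22 <- a * (a - 1) * b * (b - 1) / x4
    m31 <- a * (a - 1) * (a - 2) * b / x4
    m13 <- a * b * (b - 1) * (b - 2) / x4
    m40 <- a * (a - 1) * (a - 2) * (a - 3) / x4
    m04 <- b * (b - 1) * (b - 2) * (b - 3) / x4
    m11 <- a * b / x2
    m20 <- a * (a - 1) / x2
    m02 <- b * (b - 1) / x2
  }
  list(
    p0_ibd0 = 2 * m22,
    p1_ibd0 = 4 * m31 + 4 * m13,
    p2_ibd0 = m40 + m04 + 4 * m22,
    p1_ibd1 = 2 * m11,
    p2_ibd1 = m20 + m02
  )
}

#' Method-of-moments IBD estimate pi-hat for a sample pair
#'
#' Estimates the proportion of the genome shared identical-by-descent,
#' \eqn{\hat\pi = P(\mathrm{IBD}{=}1)/2 + P(\mathrm{IBD}{=}2)}, from observed
#' identity-by-state class counts (IBS 0/1/2) and study allele frequencies —
#' the standard GWAS-toolkit moments estimator. Negative moment components
#' are clipped at 0 and the result at [0, 1]. Values above 0.4 flag
#' duplicates or first-degree relatives.
#'
#' @param g a [genotype_matrix()] (dosages are rounded to hard calls).
#' @param i,j sample indices or ids.
#' @param min_overlap minimum overlapping non-missing variants below which
#'   the estimate is flagged unreliable (default 50).
#' @param freqs optional per-variant alternate-allele frequencies from a
#'   reference panel; by default frequencies are estimated from `g` itself
#'   (small cohorts make the estimate noisier).
#' @return numeric pi-hat with attributes `n_overlap` and `unreliable`.
#' @export
estimate_pihat <- function(g, i, j, min_overlap = 50, freqs = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(i)) i <- match(i, g$samples$id)
  if (is.character(j)) j <- match(j, g$samples$id)
  geno <- round(g$geno)
  if (is.null(freqs)) {
    acnt <- colSums(geno, na.rm = TRUE)
    xcnt <- 2 * colSums(!is.na(geno))
    bcnt <- xcnt - acnt
    exact <- FALSE
  } else {
    if (length(freqs) != ncol(geno)) {
      stop("freqs must have one entry per variant")
    }
    acnt <- freqs
    bcnt <- 1 - freqs
    xcnt <- rep(1, length(freqs))
    exact <- TRUE
  }
  ok <- !is.na(geno[i, ]) & !is.na(geno[j, ]) & acnt > 0 & bcnt > 0 &
    xcnt >= ifelse(exact, 0, 4)
  gi <- geno[i, ok]; gj <- geno[j, ok]
  d <- abs(gi - gj)
  ex <- ibs_expectations(acnt[ok], bcnt[ok], exact = exact)
  n <- length(d)
  if (n == 0) {
    return(structure(NA_real_, n_overlap = 0L, unreliable = TRUE))
  }
  e0 <- sum(ex$p0_ibd0); e1_0 <- sum(ex$p1_ibd0); e2_0 <- sum(ex$p2_ibd0)
  e1_1 <- sum(ex$p1_ibd1); e2_1 <- sum(ex$p2_ibd1)
  n0 <- sum(d == 2); n1 <- sum(d == 1); n2 <- sum(d == 0)
  # raw (unclipped) moment solution first: the three components
  # anticorrelate, so clamping mid-solution would bias pi-hat upwards
  k0 <- if (e0 > 0) n0 / e0 else 0
  k1 <- if (e1_1 > 0) (n1 - k0 * e1_0) / e1_1 else 0
  k2 <- (n2 - k0 * e2_0 - k1 * e2_1) / n
  k <- pmin(pmax(c(k0, k1, k2), 0), 1)
  k <- k / sum(k)
  pihat <- min(max(k[2] / 2 + k[3], 0), 1)
  structure(pihat, n_overlap = n, unreliable = n < min_overlap)
}

# internal: all-pairs pi-hat via matrix products (same estimator as
# estimate_pihat, vectorised over pairs; missingness handled per pair)
pihat_matrix <- function(g) {
  geno <- round(g$geno)
  acnt <- colSums(geno, na.rm = TRUE)
  xcnt <- 2 * colSums(!is.na(geno))
  bcnt <- xcnt - acnt
  use <- acnt > 0 & bcnt > 0 & xcnt >= 4
  geno <- geno[, use, drop = FALSE]
  M <- (!is.na(geno)) * 1
  G0 <- (geno == 0 & !is.na(geno)) * 1
  G1 <- (geno == 1 & !is.na(geno)) * 1
  G2 <- (geno == 2 & !is.na(geno)) * 1
  n0 <- G0 %*% t(G2) + G2 %*% t(G0)
  n1 <- G0 %*% t(G1) + G1 %*% t(G0) + G1 %*% t(G2) + G2 %*% t(G1)
  n2 <- G0 %*% t(G0) + G1 %*% t(G1) + G2 %*% t(G2)
  ex <- ibs_expectations(acnt[use], bcnt[use])
  wsum <- function(w) (M * rep(w, each = nrow(M))) %*% t(M)
  e0 <- wsum(ex$p0_ibd0); e1_0 <- wsum(ex$p1_ibd0); e2_0 <- wsum(ex$p2_ibd0)
  e1_1 <- wsum(ex$p1_ibd1); e2_1 <- wsum(ex$p2_ibd1)
  nover <- M %*% t(M)
  k0 <- ifelse(e0 > 0, n0 / e0, 0)
  k1 <- ifelse(e1_1 > 0, (n1 - k0 * e1_0) / e1_1, 0)
  k2 <- ifelse(nover > 0, (n2 - k0 * e2_0 - k1 * e2_1) / nover, 0)
  k0 <- pmin(pmax(k0, 0), 1)
  k1 <- pmin(pmax(k1, 0), 1)
  k2 <- pmin(pmax(k2, 0), 1)
  tot <- k0 + k1 + k2
  tot[tot == 0] <- 1
  ph <- pmin(pmax((k1 / 2 + k2) / tot, 0), 1)
  dimnames(ph) <- list(g$samples$id, g$samples$id)
  ph
}

#' Remove duplicated samples and first-degree relatives
#'
#' Computes pi-hat for every sample pair and, greedily over pairs sorted by
#' descending pi-hat, removes the lower-call-rate member of each pair with
#' pi-hat above `pihat_max` (the higher-call-rate sample is retained). Pairs
#' with an already-removed member are skipped.
#'
#' @param g a [genotype_matrix()].
#' @param pihat_max relatedness threshold (default 0.4, strict `>`).
#' @return list with `genotypes` and `report` (reason `relatedness`, value =
#'   the pair's pi-hat).
#' @export
remove_related <- function(g, pihat_max = 0.4) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$geno)
  if (n < 2) {
    return(list(genotypes = g,
                report = new_qc_report(NULL, list(pihat_max = pihat_max))))
  }
  ph <- pihat_matrix(g)
  cr <- rowMeans(!is.na(g$geno))
  pairs <- which(upper.tri(ph) & ph > pihat_max, arr.ind = TRUE)
  drop <- logical(n)
  items <- list()
  if (nrow(pairs)) {
    pairs <- pairs[order(-ph[pairs]), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (drop[a] || drop[b]) next
      victim <- if (cr[a] < cr[b]) a else b  # keep the higher call rate
      drop[victim] <- TRUE
      items[[length(items) + 1L]] <- data.frame(
        item = g$samples$id[victim], type = "sample", reason = "relatedness",
        value = ph[a, b], threshold = pihat_max, stringsAsFactors = FALSE
      )
    }
  }
  items <- if (length(items)) do.call(rbind, items) else NULL
  list(
    genotypes = subset_gm(g, samples = which(!drop)),
    report = new_qc_report(items, list(pihat_max = pihat_max))
  )
}

#' Filter imputed variants on imputation info score
#'
#' Removes imputed variants whose imputation r2 (info score) is below
#' `r2_min` (strict `<`); directly genotyped variants are untouched. An r2
#' cutoff of 0.8 is commonly used to retain reliably imputed markers.
#'
#' @param g a [genotype_matrix()] whose variant table carries `imputed` and
#'   `info_r2` columns.
#' @param r2_min minimum info score (default 0.8).
#' @return list with `genotypes` and `report` (reason `info`).
#' @export
filter_info <- function(g, r2_min = 0.8) {
  stopifnot(inherits(g, "genotype_matrix"))
  imputed <- g$variants$imputed
  r2 <- g$variants$info_r2
  removed <- imputed & !is.na(r2) & r2 < r2_min
  items <- if (any(removed)) data.frame(
    item = g$variants$id[removed], type = "variant", reason = "info",
    value = r2[removed], threshold = r2_min, stringsAsFactors = FALSE
  ) else NULL
  list(
    genotypes = subset_gm(g, variants = which(!removed)),
    report = new_qc_report(items, list(r2_min = r2_min))
  )
}
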