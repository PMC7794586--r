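#' Genotype matrix container
#'
#' Bundles an individuals-by-variants additive genotype matrix with variant
#' metadata (id, chromosome, 1-based position, ref/alt alleles, optional
#' imputation info r2) and sample metadata (id, ancestral group label).
#' Genotypes are alternate-allele counts in \{0, 1, 2\} with `NA` for missing
#' calls, or real dosages in [0, 2] when `dosage = TRUE`.
#'
#' @param geno numeric matrix, individuals in rows, variants in columns.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   and optionally `imputed` (logical) and `info_r2` (numeric). Defaults are
#'   synthesised when omitted.
#' @param samples data.frame with columns `id` and `group`. Defaults are
#'   synthesised when omitted.
#' @param dosage logical; treat entries as real dosages rather than hard calls.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, variants = NULL, samples = NULL,
                            dosage = FALSE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  n <- nrow(geno)
  m <- ncol(geno)
  vals <- geno[!is.na(geno)]
  if (length(vals)) {
    if (min(vals) < 0 || max(vals) > 2) {
      stop("genotype values must lie in [0, 2]")
    }
    if (!dosage && any(vals != round(vals))) {
      stop("non-integer genotypes found; use dosage = TRUE for dosage data")
    }
  }
  if (is.null(variants)) {
    ids <- colnames(geno)
    if (is.null(ids)) ids <- sprintf("v%05d", seq_len(m))
    variants <- data.frame(
      id = ids, chrom = "1", pos = seq_len(m),
      ref = "A", alt = "G",
      imputed = FALSE, info_r2 = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(variants$imputed)) variants$imputed <- FALSE
  if (is.null(variants$info_r2)) variants$info_r2 <- NA_real_
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (nrow(variants) != m) stop("variant table does not match genotype columns")
  if (is.null(samples)) {
    ids <- rownames(geno)
    if (is.null(ids)) ids <- sprintf("s%05d", seq_len(n))
    samples <- data.frame(id = ids, group = "cohort", stringsAsFactors = FALSE)
  }
  if (anyDuplicated(samples$id)) stop("sample ids must be unique")
  if (nrow(samples) != n) stop("sample table does not match genotype rows")
  dimnames(geno) <- list(samples$id, variants$id)
  structure(
    list(geno = geno, variants = variants, samples = samples, dosage = dosage),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%s)\n",
    nrow(x$geno), ncol(x$geno), if (x$dosage) "dosage" else "hard calls"
  ))
  grp <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness: %.3f; imputed variants: %d\n",
              miss, sum(x$variants$imputed)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# internal: subset a genotype_matrix by sample / variant index
subset_gm <- function(g, samples = NULL, variants = NULL) {
  if (!is.null(samples)) {
    g$geno <- g$geno[samples, , drop = FALSE]
    g$samples <- g$samples[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    g$geno <- g$geno[, variants, drop = FALSE]
    g$variants <- g$variants[variants, , drop = FALSE]
  }
  g
}

# internal: per-variant alternate-allele frequency from genotypes/dosages
alt_freq <- function(geno) colMeans(geno, na.rm = TRUE) / 2

#' Expression matrix container
#'
#' A samples-by-genes matrix of (normalised) expression values with optional
#' per-sample group labels such as `"NC"` (negative control) and `"treated"`.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param groups optional character vector of per-sample group labels.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("g%04d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique")
  if (anyDuplicated(colnames(values))) stop("gene ids must be unique")
  if (!is.null(groups) && length(groups) != nrow(values)) {
    stop("groups must have one label per sample")
  }
  structure(
    list(values = values, gene_ids = colnames(values),
         sample_ids = rownames(values), groups = groups),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups)) {
    grp <- table(x$groups)
    cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  }
  invisible(x)
}

#' T7 endonuclease I band intensities
#'
#' Holds the three band intensities from a T7EI mismatch-cleavage gel:
#' `a` is the uncleaved DNA substrate and `b`, `c` the two cleavage products.
#'
#' @param a,b,c non-negative band intensities; `a + b + c` must be positive.
#' @return an object of class `t7_bands`.
#' @export
t7_bands <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("band intensities must be non-negative")
  if (a + b + c <= 0) stop("total band intensity must be positive")
  structure(list(a = a, b = b, c = c), class = "t7_bands")
}

#' @export
print.t7_bands <- function(x, ...) {
  cat(sprintf("t7_bands: a=%.3f b=%.3f c=%.3f (cleaved fraction %.3f)\n",
              x$a, x$b, x$c, (x$b + x$c) / (x$a + x$b + x$c)))
  invisible(x)
}
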