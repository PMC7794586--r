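#' @title Bench statistics: IFN score, T7EI efficiency, fold enrichment,
#'   allelic imbalance
#' @name scores-module
#' @description Deterministic summary statistics used to quantify bench
#'   experiments: the type I interferon signature score computed from four
#'   interferon-inducible genes standardised against a negative-control
#'   group, genome-editing efficiency from T7 endonuclease I band
#'   intensities, qPCR fold enrichment for ChIP/FAIRE experiments, and a
#'   simple exact-binomial test of allelic read imbalance.
NULL

#' Interferon signature score
#'
#' For each signature gene, the gene's mean expression in the
#' negative-control (NC) group is subtracted from every sample's expression
#' and the remainder divided by the NC group's SD for that gene; the per-gene
#' standardised values are then summed across the four genes to give each
#' sample's IFN score. By construction the mean score of the NC group is 0.
#' Standardisation absorbs each gene's location and scale, so the score is
#' invariant to per-gene affine rescaling of the raw units.
#'
#' @param panel an [expression_matrix()] or samples-by-genes matrix holding
#'   relative expression for the signature genes.
#' @param nc_mask logical vector flagging negative-control samples; defaults
#'   to `panel$groups == "NC"` when the panel carries group labels.
#' @param genes signature genes (default IFI27, IFIT3, OAS1, LY6E); all must
#'   be present.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator) for the NC SD.
#' @return an object of class `ifn_score`: per-sample `score`, the NC
#'   per-gene `nc_mean`/`nc_sd`, `genes`, and `nc_mask`.
#' @export
ifn_score <- function(panel, nc_mask = NULL,
                      genes = c("IFI27", "IFIT3", "OAS1", "LY6E"),
                      sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (inherits(panel, "expression_matrix")) {
    if (is.null(nc_mask) && !is.null(panel$groups)) {
      nc_mask <- panel$groups == "NC"
    }
    panel <- panel$values
  }
  panel <- as.matrix(panel)
  if (is.null(nc_mask)) stop("nc_mask is required")
  missing_genes <- setdiff(genes, colnames(panel))
  if (length(missing_genes)) {
    stop("missing signature gene(s): ", paste(missing_genes, collapse = ", "))
  }
  if (sum(nc_mask) < 2) stop("need at least 2 negative-control samples")
  x <- panel[, genes, drop = FALSE]
  nc <- x[nc_mask, , drop = FALSE]
  mu <- colMeans(nc)
  sdv <- apply(nc, 2, stats::sd)
  if (sd_type == "population") {
    n_nc <- nrow(nc)
    sdv <- sdv * sqrt((n_nc - 1) / n_nc)
  }
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad)) {
    stop("zero negative-control SD for gene(s): ",
         paste(genes[bad], collapse = ", "))
  }
  std <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  score <- rowSums(std)
  structure(
    list(score = score, nc_mean = mu, nc_sd = sdv, genes = genes,
         nc_mask = nc_mask, standardized = std),
    class = "ifn_score"
  )
}

#' @export
print.ifn_score <- function(x, ...) {
  cat(sprintf("ifn_score: %d samples (%d NC), genes %s\n",
              length(x$score), sum(x$nc_mask),
              paste(x$genes, collapse = "/")))
  cat(sprintf("  mean NC score: %.3g", mean(x$score[x$nc_mask])))
  if (any(!x$nc_mask)) {
    cat(sprintf("; mean non-NC score: %.3f", mean(x$score[!x$nc_mask])))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.ifn_score <- function(object, ...) {
  data.frame(
    group = c("NC", "other"),
    n = c(sum(object$nc_mask), sum(!object$nc_mask)),
    mean = c(mean(object$score[object$nc_mask]),
             if (any(!object$nc_mask)) mean(object$score[!object$nc_mask])
             else NA_real_),
    sd = c(stats::sd(object$score[object$nc_mask]),
           if (sum(!object$nc_mask) > 1) stats::sd(object$score[!object$nc_mask])
           else NA_real_)
  )
}

#' T7 endonuclease I editing efficiency
#'
#' From gel band intensities — substrate `a` and cleavage products `b`, `c` —
#' the cleaved fraction is \eqn{f = (b+c)/(a+b+c)} and the editing
#' efficiency, accounting for re-annealed homoduplexes, is
#' \deqn{\mathrm{efficiency} = \left(1 - \sqrt{1 - f}\right) \times 100.}
#' The result is invariant to rescaling all bands by a common factor and
#' strictly increasing in the cleaved fraction.
#'
#' @param a substrate band intensity, or a [t7_bands()] object.
#' @param b,c cleavage-product intensities (vectorised).
#' @return editing efficiency percentage(s) in [0, 100].
#' @seealso [editing_result()] for the tabulated form with the usability flag.
#' @export
t7_efficiency <- function(a, b = NULL, c = NULL) {
  if (inherits(a, "t7_bands")) {
    b <- a$b; c <- a$c; a <- a$a
  }
  if (any(c(a, b, c) < 0)) stop("band intensities must be non-negative")
  tot <- a + b + c
  if (any(tot <= 0)) stop("total band intensity must be positive")
  f <- (b + c) / tot
  (1 - sqrt(1 - f)) * 100
}

#' Tabulated editing results with usability flag
#'
#' Wraps [t7_efficiency()] over vectors of band intensities and flags the
#' samples whose efficiency exceeds the usability cutoff (editing above 40%
#' is conventionally required before downstream expression analysis).
#'
#' @param a,b,c band intensity vectors.
#' @param usable_min minimum efficiency percentage to flag a sample usable
#'   (default 40).
#' @return data.frame with a, b, c, `cleaved_fraction`, `efficiency_pct`,
#'   `usable`.
#' @export
editing_result <- function(a, b, c, usable_min = 40) {
  eff <- t7_efficiency(a, b, c)
  data.frame(
    a = a, b = b, c = c,
    cleaved_fraction = (b + c) / (a + b + c),
    efficiency_pct = eff,
    usable = eff > usable_min
  )
}

#' qPCR fold enrichment
#'
#' Ratio of the signal in a target sample (e.g. ChIP with the target
#' antibody, or FAIRE) to the signal in its control (IgG or input DNA).
#' In `"linear"` mode the two signals are divided directly; in `"ct"` mode
#' the inputs are qPCR cycle-threshold values and the fold is
#' \eqn{E^{(Ct_\mathrm{control} - Ct_\mathrm{target})}} for amplification
#' efficiency `E` (default 2, perfect doubling). The two modes agree on
#' signals \eqn{E^{-Ct}}.
#'
#' @param target_signal,control_signal linear signals or Ct values
#'   (vectorised).
#' @param mode `"linear"` or `"ct"`.
#' @param efficiency per-cycle amplification factor for `"ct"` mode.
#' @return fold enrichment ratio(s).
#' @export
fold_enrichment <- function(target_signal, control_signal,
                            mode = c("linear", "ct"), efficiency = 2) {
  mode <- match.arg(mode)
  if (mode == "linear") {
    if (any(control_signal <= 0)) stop("control signal must be positive")
    target_signal / control_signal
  } else {
    if (any(!is.finite(c(target_signal, control_signal)))) {
      stop("Ct values must be finite")
    }
    efficiency^(control_signal - target_signal)
  }
}

#' Exact binomial test of allelic read imbalance
#'
#' Tests whether reference/alternate read counts at a heterozygous site
#' depart from the 1:1 expectation using the exact two-sided binomial test at
#' null probability 0.5 (two-sidedness by the minimum-likelihood rule: the
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one).
#'
#' @param ref_reads,alt_reads non-negative read counts (vectorised);
#'   `ref + alt >= 1`.
#' @return two-sided p-value(s) in (0, 1].
#' @export
allelic_imbalance <- function(ref_reads, alt_reads) {
  if (any(ref_reads < 0 | alt_reads < 0)) stop("read counts must be non-negative")
  tot <- ref_reads + alt_reads
  if (any(tot < 1)) stop("need at least one read (ref + alt >= 1)")
  mapply(function(r, n) stats::binom.test(r, n, p = 0.5)$p.value,
         ref_reads, tot)
}
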