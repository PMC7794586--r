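#' @title Sample-size-weighted Z-score meta-analysis
#' @description Combines per-study association evidence across ancestral
#'   cohorts with the sample-size weighting scheme: each study contributes a
#'   signed Wald statistic \eqn{z_i = \Phi^{-1}(1 - p_i/2)\,
#'   \mathrm{sign}(\beta_i)} after aligning its effect allele to a common
#'   reference, and the combined statistic is
#'   \eqn{Z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}} with \eqn{w_i =
#'   \sqrt{N_i}}. This is the fixed-weight scheme of the standard GWAS
#'   meta-analysis toolkits when only p-values, directions and sample sizes
#'   are shared.
#' @name meta-module
NULL

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Align study alleles to reference alleles
#'
#' Decides, per variant, whether a study's effect direction must be flipped
#' to refer to the reference effect allele. Handles swapped effect/other
#' alleles and opposite-strand reporting (complemented alleles). Palindromic
#' A/T and C/G variants cannot be strand-resolved without allele frequencies
#' and are flagged ambiguous; allele pairs that match under no
#' swap/complement combination are irreconcilable.
#'
#' @param a1,a2 study effect and other allele (single letters A/C/G/T;
#'   vectorised).
#' @param ref_a1,ref_a2 reference effect and other allele.
#' @return data.frame with logical columns `flip`, `ambiguous`,
#'   `irreconcilable`.
#' @export
align_alleles <- function(a1, a2, ref_a1, ref_a2) {
  up <- function(x) toupper(as.character(x))
  a1 <- up(a1); a2 <- up(a2); ref_a1 <- up(ref_a1); ref_a2 <- up(ref_a2)
  ok <- a1 %in% names(COMPLEMENT) & a2 %in% names(COMPLEMENT) &
    ref_a1 %in% names(COMPLEMENT) & ref_a2 %in% names(COMPLEMENT)
  if (!all(ok)) stop("alleles must be single bases A/C/G/T")
  c1 <- COMPLEMENT[a1]; c2 <- COMPLEMENT[a2]
  ambiguous <- a1 == COMPLEMENT[a2]  # A/T or C/G pair
  same <- a1 == ref_a1 & a2 == ref_a2
  swap <- a1 == ref_a2 & a2 == ref_a1
  strand <- c1 == ref_a1 & c2 == ref_a2
  strand_swap <- c1 == ref_a2 & c2 == ref_a1
  flip <- !same & !strand & (swap | strand_swap)
  irreconcilable <- !(same | swap | strand | strand_swap)
  data.frame(flip = flip & !irreconcilable, ambiguous = ambiguous,
             irreconcilable = irreconcilable)
}

#' Sample-size-weighted Z-score meta-analysis
#'
#' Each study table must contain columns `ID`, `A1` (effect allele), `A2`,
#' `P`, `N`, and either `BETA` (its sign gives the direction) or `DIR`
#' (`"+"`/`"-"`). Effects are aligned to the reference alleles (by default
#' those of the first study carrying each variant); palindromic variants are
#' excluded unless `keep_ambiguous = TRUE`; variants whose alleles cannot be
#' reconciled in some study drop that study's contribution with a logged
#' reason. Studies providing p-values without any direction are rejected —
#' the signed scheme requires a direction.
#'
#' @param studies list of per-study data.frames (optionally named).
#' @param ref_alleles optional data.frame (ID, A1, A2) fixing the reference
#'   effect allele per variant.
#' @param keep_ambiguous keep palindromic A/T and C/G variants assuming same
#'   strand (default FALSE).
#' @return an object of class `meta_scan`: `records` data.frame (ID, Z, P,
#'   N_TOTAL, N_STUDIES, DIRECTIONS with one `+`/`-`/`?` per study) and
#'   `skipped` (variant/study exclusions with reasons).
#' @export
weighted_z_meta <- function(studies, ref_alleles = NULL,
                            keep_ambiguous = FALSE) {
  stopifnot(length(studies) >= 1)
  studies <- lapply(studies, as.data.frame)
  for (s in seq_along(studies)) {
    st <- studies[[s]]
    need <- c("ID", "A1", "A2", "P", "N")
    if (!all(need %in% names(st))) {
      stop("study ", s, " lacks required columns: ",
           paste(setdiff(need, names(st)), collapse = ", "))
    }
    if (is.null(st$BETA) && is.null(st$DIR)) {
      stop("study ", s, " has p-values without effect direction (BETA or DIR)")
    }
  }
  all_ids <- unique(unlist(lapply(studies, `[[`, "ID")))
  if (is.null(ref_alleles)) {
    ref_alleles <- do.call(rbind, lapply(studies, function(st) {
      st[, c("ID", "A1", "A2")]
    }))
    ref_alleles <- ref_alleles[!duplicated(ref_alleles$ID), , drop = FALSE]
  }
  skipped <- list()
  out <- list()
  for (id in all_ids) {
    ra <- ref_alleles[ref_alleles$ID == id, , drop = FALSE]
    if (nrow(ra) == 0) next
    zs <- c(); ws <- c(); ns <- c()
    dirs <- character(length(studies))
    dirs[] <- "?"
    drop_variant <- FALSE
    for (s in seq_along(studies)) {
      st <- studies[[s]]
      row <- st[st$ID == id, , drop = FALSE]
      if (nrow(row) == 0) next
      al <- align_alleles(row$A1, row$A2, ra$A1, ra$A2)
      if (al$irreconcilable) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          ID = id, study = s, reason = "irreconcilable_alleles",
          stringsAsFactors = FALSE
        )
        next
      }
      if (al$ambiguous && !keep_ambiguous) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          ID = id, study = s, reason = "palindromic_ambiguous",
          stringsAsFactors = FALSE
        )
        drop_variant <- TRUE
        next
      }
      sgn <- if (!is.null(row$BETA) && !is.na(row$BETA)) {
        if (row$BETA >= 0) 1 else -1
      } else if (row$DIR %in% c("+", "-")) {
        if (row$DIR == "+") 1 else -1
      } else {
        stop("study ", s, " direction missing for variant ", id)
      }
      if (al$flip) sgn <- -sgn
      z <- stats::qnorm(row$P / 2, lower.tail = FALSE) * sgn
      zs <- c(zs, z); ws <- c(ws, sqrt(row$N)); ns <- c(ns, row$N)
      dirs[s] <- if (z >= 0) "+" else "-"
    }
    if (drop_variant || length(zs) == 0) next
    Z <- sum(ws * zs) / sqrt(sum(ws^2))
    out[[length(out) + 1L]] <- data.frame(
      ID = id, Z = Z, P = 2 * stats::pnorm(-abs(Z)), N_TOTAL = sum(ns),
      N_STUDIES = length(zs), DIRECTIONS = paste(dirs, collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  records <- if (length(out)) do.call(rbind, out) else
    data.frame(ID = character(), Z = numeric(), P = numeric(),
               N_TOTAL = numeric(), N_STUDIES = integer(),
               DIRECTIONS = character(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(
    list(records = records,
         skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
         n_studies = length(studies)),
    class = "meta_scan"
  )
}

#' @export
print.meta_scan <- function(x, ...) {
  r <- x$records
  cat(sprintf("meta_scan: %d variants across %d studies\n",
              nrow(r), x$n_studies))
  if (nrow(r)) {
    top <- r[which.min(r$P), ]
    cat(sprintf("  top: %s Z=%.3f p=%.3g (N=%d, %s)\n",
                top$ID, top$Z, top$P, top$N_TOTAL, top$DIRECTIONS))
  }
  if (!is.null(x$skipped)) {
    cat(sprintf("  %d study-variant contribution(s) skipped\n",
                nrow(x$skipped)))
  }
  invisible(x)
}

#' @export
as.data.frame.meta_scan <- function(x, ...) x$records
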