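#' @title Approximate Bayes factors, posterior probabilities, credible sets
#' @description Single-causal-variant Bayesian fine-mapping of an associated
#'   region. Evidence per variant is the Wakefield approximate Bayes factor
#'   computed from the effect estimate and its standard error (or recovered
#'   from a p-value, sample size and allele frequency); per-variant posterior
#'   probabilities are the Bayes-factor shares
#'   \eqn{PP_i = BF_i / \sum_{j=1}^k BF_j}, and the 95\% credible set is the
#'   minimum number of variants whose summed posterior probability reaches
#'   0.95.
#' @name finemap-module
NULL

#' Wakefield log approximate Bayes factor from an effect estimate
#'
#' With sampling variance \eqn{V = se^2}, Wald statistic \eqn{z = \beta/se}
#' and a Gaussian effect prior \eqn{N(0, W)}, the approximate Bayes factor of
#' the association model against the null is
#' \deqn{\log \mathrm{BF} = \tfrac12 \log\frac{V}{V+W} +
#'   \frac{z^2}{2}\,\frac{W}{V+W}.}
#' Computed and returned in natural-log space so that very strong signals do
#' not overflow. The default prior variance `W = 0.04` (prior SD 0.2 on the
#' log-odds scale) is the de facto standard for binary-trait fine-mapping.
#'
#' @param beta effect estimate (log-odds per allele); vectorised.
#' @param se standard error(s), > 0.
#' @param prior_w prior effect variance W, > 0 (default 0.04).
#' @return natural-log Bayes factor(s).
#' @export
abf_from_summary <- function(beta, se, prior_w = 0.04) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_w <= 0)) stop("prior_w must be positive")
  v <- se^2
  z <- beta / se
  0.5 * log(v / (v + prior_w)) + (z^2 / 2) * (prior_w / (v + prior_w))
}

#' Wakefield log approximate Bayes factor from a p-value
#'
#' Recovers the Wald statistic from a two-sided p-value,
#' \eqn{z = \Phi^{-1}(1 - p/2)\cdot\mathrm{sign}}, approximates the sampling
#' variance of the log-odds estimate as \eqn{V \approx 1/(2\,N\,f(1-f))} for
#' allele frequency f, and proceeds as [abf_from_summary()]. This is the
#' route used when only summary p-values are available, e.g. for
#' meta-analysis results. p-values may be supplied in natural-log space
#' (`log_p = TRUE`) so extreme signals (p < 1e-300) never produce an
#' infinite z.
#'
#' @param p two-sided p-value(s) in (0, 1], or their natural logs.
#' @param n effective sample size(s).
#' @param maf minor/alternate allele frequency in (0, 1).
#' @param prior_w prior effect variance (default 0.04).
#' @param sign effect direction (+1/-1), only affects the (unused) sign of z.
#' @param log_p interpret `p` as log(p).
#' @return natural-log Bayes factor(s).
#' @export
abf_from_pvalue <- function(p, n, maf, prior_w = 0.04, sign = 1,
                            log_p = FALSE) {
  if (!log_p && any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  if (any(n <= 0)) stop("n must be positive")
  if (any(maf <= 0 | maf >= 1)) stop("maf must lie in (0, 1)")
  lp <- if (log_p) p else log(p)
  z <- stats::qnorm(lp - log(2), lower.tail = FALSE, log.p = TRUE) * sign
  v <- 1 / (2 * n * maf * (1 - maf))
  0.5 * log(v / (v + prior_w)) + (z^2 / 2) * (prior_w / (v + prior_w))
}

#' Posterior probabilities from per-variant log Bayes factors
#'
#' Under the assumptions that any variant in the region could be causal and
#' exactly one is, the posterior probability of variant i is its
#' Bayes-factor share of the region,
#' \eqn{PP_i = BF_i / \sum_{j=1}^{k} BF_j}. Evaluated with log-sum-exp so
#' regions with thousands of variants and very large BFs normalise exactly.
#'
#' @param log_bfs vector of natural-log Bayes factors (one region).
#' @return posterior probabilities summing to 1 (names preserved).
#' @export
posterior_probs <- function(log_bfs) {
  if (length(log_bfs) == 0) stop("region is empty")
  m <- max(log_bfs)
  lse <- m + log(sum(exp(log_bfs - m)))
  exp(log_bfs - lse)
}

#' Minimal credible set at a given posterior level
#'
#' Ranks variants by descending posterior probability and accumulates the
#' minimum number whose summed posterior probability reaches `level`
#' (default 0.95), so the set is minimal by construction. Variants tied in
#' posterior probability are taken in input order, making the membership
#' deterministic (any such choice yields the same size and cumulative PP).
#'
#' @param pps posterior probabilities summing to 1 (names used as ids).
#' @param level credible level in (0, 1] (default 0.95).
#' @param ids variant ids (default `names(pps)` or indices).
#' @return an object of class `credible_set`: `members` (ids, descending
#'   PP), `pp` (their posterior probabilities), `cum_pp`, `level`.
#' @export
credible_set <- function(pps, level = 0.95, ids = NULL) {
  if (level <= 0 || level > 1) stop("level must lie in (0, 1]")
  if (abs(sum(pps) - 1) > 1e-6) stop("posterior probabilities must sum to 1")
  if (is.null(ids)) ids <- names(pps)
  if (is.null(ids)) ids <- as.character(seq_along(pps))
  o <- order(pps, decreasing = TRUE)  # stable: ties keep input order
  cum <- cumsum(pps[o])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(pps)
  sel <- o[seq_len(k)]
  structure(
    list(members = ids[sel], pp = unname(pps[sel]),
         cum_pp = unname(sum(pps[sel])), level = level),
    class = "credible_set"
  )
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%.0f%% credible set: %d variant(s), cumulative PP %.4f\n",
              100 * x$level, length(x$members), x$cum_pp))
  show <- utils::head(seq_along(x$members), 10)
  for (i in show) {
    cat(sprintf("  %s  PP=%.4f\n", x$members[i], x$pp[i]))
  }
  if (length(x$members) > 10) cat("  ...\n")
  invisible(x)
}

#' Variants shared by credible sets across ancestries
#'
#' Intersects the member ids of two or more credible sets (one per ancestral
#' cohort) and orders the shared variants by their mean posterior
#' probability, descending. A variant common to every ancestry's credible
#' set is the natural trans-ancestral causal candidate; an empty
#' intersection is a valid outcome.
#'
#' @param sets list of [credible_set()] objects (>= 2).
#' @return character vector of shared variant ids (possibly empty), ordered
#'   by mean PP.
#' @export
shared_credible_variants <- function(sets) {
  if (length(sets) < 2) stop("need at least two credible sets")
  ids <- Reduce(intersect, lapply(sets, `[[`, "members"))
  if (length(ids) == 0) return(character(0))
  mean_pp <- vapply(ids, function(id) {
    mean(vapply(sets, function(s) s$pp[match(id, s$members)], numeric(1)))
  }, numeric(1))
  ids[order(mean_pp, decreasing = TRUE)]
}

#' Fine-map a region to a credible set
#'
#' One-stop fitting function: takes per-variant association evidence —
#' an [logistic_scan()]/[eqtl_scan()] result, or explicit `beta`/`se`
#' vectors, or `p`/`n`/`maf` vectors — computes Wakefield log Bayes factors,
#' normalises them to posterior probabilities under the single-causal-variant
#' assumption, and constructs the credible set.
#'
#' @param x an `assoc_scan` object, or a data.frame with columns
#'   `ID`, `BETA`, `SE` (or `P`, `N`, `MAF`).
#' @param prior_w prior effect variance (default 0.04).
#' @param level credible level (default 0.95).
#' @param from `"beta-se"` (default) or `"pvalue"`.
#' @return an object of class `finemap`: `records` data.frame
#'   (ID, LOG_BF, PP, IN_CS), the `credible_set`, `prior_w`, `level`.
#' @export
finemap <- function(x, prior_w = 0.04, level = 0.95,
                    from = c("beta-se", "pvalue")) {
  from <- match.arg(from)
  if (inherits(x, "assoc_scan")) x <- x$records
  x <- as.data.frame(x)
  if (is.null(x$ID)) x$ID <- as.character(seq_len(nrow(x)))
  if (!is.null(x$CONVERGED)) x <- x[x$CONVERGED %in% TRUE, , drop = FALSE]
  if (nrow(x) == 0) stop("no converged association records to fine-map")
  lbf <- if (from == "beta-se") {
    abf_from_summary(x$BETA, x$SE, prior_w)
  } else {
    sgn <- if (!is.null(x$BETA)) sign(x$BETA) else 1
    abf_from_pvalue(x$P, x$N, x$MAF, prior_w, sign = sgn)
  }
  pp <- posterior_probs(lbf)
  cs <- credible_set(stats::setNames(pp, x$ID), level = level)
  records <- data.frame(
    ID = x$ID, LOG_BF = lbf, PP = pp, IN_CS = x$ID %in% cs$members,
    stringsAsFactors = FALSE
  )
  if (!is.null(x$POS)) records$POS <- x$POS
  rownames(records) <- NULL
  structure(
    list(records = records, credible_set = cs, prior_w = prior_w,
         level = level),
    class = "finemap"
  )
}

#' @export
print.finemap <- function(x, ...) {
  cat(sprintf("finemap: %d variants, prior W=%.3g\n",
              nrow(x$records), x$prior_w))
  print(x$credible_set)
  invisible(x)
}

#' @export
summary.finemap <- function(object, ...) {
  r <- object$records
  r[order(-r$PP), , drop = FALSE]
}

#' @export
plot.finemap <- function(x, ...) {
  r <- x$records
  xs <- if (!is.null(r$POS)) r$POS else seq_len(nrow(r))
  graphics::plot(xs, r$PP, xlab = "position (bp)",
                 ylab = "posterior probability",
                 pch = ifelse(r$IN_CS, 19, 1), ...)
  invisible(x)
}
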