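#' @title Additive-model association scans
#' @description Per-variant logistic regression of case-control status on
#'   alternate-allele count with covariates (typically three admixture
#'   proportions), stepwise conditional analysis, and additive linear-model
#'   eQTL scans. Effects are reported per alternate allele as coded in the
#'   genotype matrix; a positive beta means the alternate allele increases
#'   risk (or expression).
#' @name assoc
NULL

# internal: resolve a genotype matrix plus aligned status/covariates
resolve_geno <- function(g) {
  if (inherits(g, "cohort")) g$genotypes else g
}

# internal: fit one logistic model; returns beta, se for the focal column
# (the last column of X), flagged on non-convergence / separation / aliasing
fit_logistic_variant <- function(y, X) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  k <- ncol(X) + 1L
  beta <- fit$coefficients[k]
  aliased <- is.na(beta)
  # separation: fitted probabilities at the boundary or runaway coefficient
  sep <- !aliased && (abs(beta) > 15 || !fit$converged)
  if (aliased || sep) {
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE,
                aliased = aliased))
  }
  # Wald SE from the unscaled covariance of the IRLS fit
  w <- fit$weights
  XtWX <- crossprod(cbind(1, X) * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov) || cov[k, k] <= 0) {
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE,
                aliased = FALSE))
  }
  list(beta = beta, se = sqrt(cov[k, k]), converged = TRUE, aliased = FALSE)
}

#' Logistic association scan under the additive genetic model
#'
#' For each variant, fits by maximum likelihood (binomial IRLS)
#' \deqn{\mathrm{logit}\,P(\mathrm{case}) = \alpha + \beta g + \gamma' c}
#' on the samples with a non-missing genotype at that variant (complete-case
#' per variant, no mean imputation), where `g` is the alternate-allele count
#' and `c` the covariate row. Reports the per-allele log-odds beta, its Wald
#' standard error, z = beta/se, and the two-sided normal p-value. Variants
#' whose fit separates, fails to converge, or is aliased against the
#' conditioning genotypes are flagged `converged = FALSE` with `p = NA` —
#' never a silent number.
#'
#' @param g a [genotype_matrix()] or `cohort` (whose status/admixture are used
#'   as defaults).
#' @param status binary 0/1 case-control vector.
#' @param covariates optional numeric matrix of covariates (rows = samples),
#'   e.g. three admixture proportions.
#' @param variants subset of variant ids or indices to scan (default all).
#' @param condition_on variant ids/indices whose genotypes are added as model
#'   covariates (conditional analysis). Missing genotypes in conditioning
#'   variants are mean-filled so the conditional scan keeps the per-variant
#'   complete-case sample.
#' @return an object of class `assoc_scan` with a `records` data.frame
#'   (ID, CHR, POS, A1 = ref, A2 = alt/effect allele, N, BETA, SE, Z, P,
#'   CONVERGED).
#' @seealso [conditional_stepwise()], [finemap()]
#' @export
logistic_scan <- function(g, status = NULL, covariates = NULL,
                          variants = NULL, condition_on = NULL) {
  if (inherits(g, "cohort")) {
    if (is.null(status)) status <- g$status
    if (is.null(covariates)) covariates <- g$admixture
    g <- g$genotypes
  }
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(status)) stop("status is required")
  if (!all(status %in% c(0, 1))) stop("status must be binary 0/1")
  geno <- g$geno
  if (length(status) != nrow(geno)) stop("status length mismatch")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(geno)) stop("covariate rows mismatch")
  }
  idx <- seq_len(ncol(geno))
  if (!is.null(variants)) {
    idx <- if (is.character(variants)) match(variants, g$variants$id)
           else variants
  }
  cond_idx <- integer(0)
  if (!is.null(condition_on)) {
    cond_idx <- if (is.character(condition_on)) {
      match(condition_on, g$variants$id)
    } else as.integer(condition_on)
    if (anyNA(cond_idx)) stop("unknown conditioning variant id")
  }
  cond_mat <- NULL
  if (length(cond_idx)) {
    cond_mat <- geno[, cond_idx, drop = FALSE]
    for (k in seq_len(ncol(cond_mat))) {
      ck <- cond_mat[, k]
      if (anyNA(ck)) ck[is.na(ck)] <- mean(ck, na.rm = TRUE)
      cond_mat[, k] <- ck
    }
  }
  rec <- lapply(idx, function(v) {
    gv <- geno[, v]
    ok <- !is.na(gv)
    n <- sum(ok)
    base <- cbind(covariates, cond_mat)[ok, , drop = FALSE]
    if (n < 2 || length(unique(gv[ok])) < 2 ||
        length(unique(status[ok])) < 2) {
      return(list(n = n, beta = NA_real_, se = NA_real_, converged = FALSE))
    }
    # conditioning columns precede the focal genotype so that aliasing
    # (e.g. conditioning a variant on itself) lands on the focal term
    X <- cbind(base, gv[ok])
    f <- fit_logistic_variant(status[ok], X)
    list(n = n, beta = f$beta, se = f$se, converged = f$converged)
  })
  beta <- vapply(rec, `[[`, numeric(1), "beta")
  se <- vapply(rec, `[[`, numeric(1), "se")
  z <- beta / se
  records <- data.frame(
    ID = g$variants$id[idx], CHR = g$variants$chrom[idx],
    POS = g$variants$pos[idx], A1 = g$variants$ref[idx],
    A2 = g$variants$alt[idx],
    N = as.integer(vapply(rec, `[[`, numeric(1), "n")),
    BETA = beta, SE = se, Z = z, P = 2 * stats::pnorm(-abs(z)),
    CONVERGED = vapply(rec, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  structure(
    list(records = records,
         conditioned = if (length(cond_idx)) g$variants$id[cond_idx]
                       else character(0),
         n_covariates = if (is.null(covariates)) 0L else ncol(covariates)),
    class = "assoc_scan"
  )
}

#' @export
print.assoc_scan <- function(x, ...) {
  r <- x$records
  cat(sprintf("assoc_scan: %d variants, %d covariates", nrow(r),
              x$n_covariates))
  if (length(x$conditioned)) {
    cat(", conditioned on", paste(x$conditioned, collapse = ", "))
  }
  cat("\n")
  ok <- r[r$CONVERGED & !is.na(r$P), , drop = FALSE]
  if (nrow(ok)) {
    top <- ok[which.min(ok$P), ]
    cat(sprintf("  top hit: %s  beta=%.4f se=%.4f p=%.3g (n=%d)\n",
                top$ID, top$BETA, top$SE, top$P, top$N))
  }
  invisible(x)
}

#' @export
summary.assoc_scan <- function(object, n_top = 10, ...) {
  r <- object$records
  r <- r[order(r$P), , drop = FALSE]
  utils::head(r, n_top)
}

#' @export
coef.assoc_scan <- function(object, ...) {
  stats::setNames(object$records$BETA, object$records$ID)
}

#' @export
plot.assoc_scan <- function(x, ...) {
  r <- x$records
  graphics::plot(r$POS, -log10(r$P), xlab = "position (bp)",
                 ylab = expression(-log[10](p)), pch = 19, ...)
  invisible(x)
}

#' @export
as.data.frame.assoc_scan <- function(x, ...) x$records

#' Stepwise conditional association analysis
#'
#' Identifies the number of independent genetic effects in a region. The top
#' variant of the unconditional scan (lowest p; ties broken by lowest genomic
#' position) is added as a model covariate, the region is re-scanned, and the
#' process repeats while any remaining variant stays below `p_stop`. Each
#' step records the variants with residual evidence of association in the
#' window `p_stop < p < p_report_hi`. Variants collinear with the
#' conditioning set are reported as aliased (flagged, skipped).
#'
#' @inheritParams logistic_scan
#' @param p_stop conditioning continues while some variant has p below this
#'   (default 1e-4).
#' @param p_report_hi upper bound of the residual-association window
#'   (default 1e-2).
#' @param max_steps safety cap on conditioning rounds.
#' @return an object of class `conditional_trace`: per-step top variant, its
#'   pre-conditioning p, the residual-window records, and the final scan.
#' @export
conditional_stepwise <- function(g, status = NULL, covariates = NULL,
                                 p_stop = 1e-4, p_report_hi = 1e-2,
                                 max_steps = 10) {
  if (inherits(g, "cohort")) {
    if (is.null(status)) status <- g$status
    if (is.null(covariates)) covariates <- g$admixture
    g <- g$genotypes
  }
  conditioned <- character(0)
  steps <- list()
  scan <- logistic_scan(g, status, covariates)
  repeat {
    r <- scan$records
    r <- r[r$CONVERGED & !is.na(r$P) & !(r$ID %in% conditioned), , drop = FALSE]
    if (nrow(r) == 0) break
    r <- r[order(r$P, r$POS), , drop = FALSE]
    if (r$P[1] >= p_stop || length(steps) >= max_steps) break
    top <- r$ID[1]
    conditioned <- c(conditioned, top)
    scan <- logistic_scan(g, status, covariates, condition_on = conditioned)
    res <- scan$records
    residual <- res[res$CONVERGED & !is.na(res$P) &
                      res$P > p_stop & res$P < p_report_hi, , drop = FALSE]
    steps[[length(steps) + 1L]] <- list(
      conditioned_on = top, p_before = r$P[1], residual_window = residual
    )
  }
  structure(
    list(steps = steps, conditioned = conditioned, final_scan = scan,
         p_stop = p_stop, p_report_hi = p_report_hi),
    class = "conditional_trace"
  )
}

#' @export
print.conditional_trace <- function(x, ...) {
  cat(sprintf("conditional_trace: %d independent effect(s) (p_stop=%g)\n",
              length(x$steps), x$p_stop))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  step %d: conditioned on %s (p=%.3g), %d variant(s) in the residual window\n",
                i, s$conditioned_on, s$p_before, nrow(s$residual_window)))
  }
  invisible(x)
}

#' Additive linear-model eQTL scan
#'
#' For each variant x gene pair, fits by ordinary least squares
#' `expression ~ genotype (+ conditioning genotypes)` on the samples shared
#' between the genotype and expression matrices, and reports the per-allele
#' slope, its SE, the t statistic, and the two-sided Student-t p-value.
#' Constant (monomorphic) genotypes are flagged with no estimate.
#'
#' @param g a [genotype_matrix()] or `cohort`.
#' @param expr an [expression_matrix()] (or plain samples-by-genes matrix).
#' @param gene gene id(s) to scan, or `"all"`.
#' @param condition_on variant ids/indices added as covariates; conditioning
#'   on the association lead variant tests whether it explains the signal.
#' @param p_report reporting threshold stored on the object and used by
#'   `summary()` (default 1e-4).
#' @return an object of class `eqtl_scan` with a `records` data.frame
#'   (ID, GENE, N, SLOPE, SE, T, P, CONVERGED).
#' @export
eqtl_scan <- function(g, expr, gene = "all", condition_on = NULL,
                      p_report = 1e-4) {
  g <- resolve_geno(g)
  stopifnot(inherits(g, "genotype_matrix"))
  if (inherits(expr, "expression_matrix")) expr <- expr$values
  expr <- as.matrix(expr)
  shared <- intersect(g$samples$id, rownames(expr))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  geno <- g$geno[match(shared, g$samples$id), , drop = FALSE]
  expr <- expr[shared, , drop = FALSE]
  genes <- if (identical(gene, "all")) colnames(expr) else gene
  if (!all(genes %in% colnames(expr))) stop("gene not found in expression matrix")
  cond_mat <- NULL
  if (!is.null(condition_on)) {
    ci <- if (is.character(condition_on)) match(condition_on, g$variants$id)
          else as.integer(condition_on)
    if (anyNA(ci)) stop("unknown conditioning variant id")
    cond_mat <- geno[, ci, drop = FALSE]
    for (k in seq_len(ncol(cond_mat))) {
      ck <- cond_mat[, k]
      if (anyNA(ck)) ck[is.na(ck)] <- mean(ck, na.rm = TRUE)
      cond_mat[, k] <- ck
    }
  }
  out <- list()
  for (gn in genes) {
    y_all <- expr[, gn]
    for (v in seq_len(ncol(geno))) {
      gv <- geno[, v]
      ok <- !is.na(gv) & !is.na(y_all)
      n <- sum(ok)
      if (n < 3 || length(unique(gv[ok])) < 2) {
        out[[length(out) + 1L]] <- data.frame(
          ID = g$variants$id[v], GENE = gn, N = n, SLOPE = NA_real_,
          SE = NA_real_, T = NA_real_, P = NA_real_, CONVERGED = FALSE,
          stringsAsFactors = FALSE
        )
        next
      }
    # conditioning columns first; focal genotype last (as in logistic_scan)
      X <- cbind(1, cond_mat[ok, , drop = FALSE], gv[ok])
      fit <- stats::lm.fit(X, y_all[ok])
      k <- ncol(X)
      slope <- fit$coefficients[k]
      df <- n - fit$rank
      if (is.na(slope) || df <= 0) {
        out[[length(out) + 1L]] <- data.frame(
          ID = g$variants$id[v], GENE = gn, N = n, SLOPE = NA_real_,
          SE = NA_real_, T = NA_real_, P = NA_real_, CONVERGED = FALSE,
          stringsAsFactors = FALSE
        )
        next
      }
      rss <- sum(fit$residuals^2)
      sigma2 <- rss / df
      XtXi <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
      if (is.null(XtXi)) {
        out[[length(out) + 1L]] <- data.frame(
          ID = g$variants$id[v], GENE = gn, N = n, SLOPE = NA_real_,
          SE = NA_real_, T = NA_real_, P = NA_real_, CONVERGED = FALSE,
          stringsAsFactors = FALSE
        )
        next
      }
      se <- sqrt(sigma2 * XtXi[k, k])
      tt <- slope / se
      out[[length(out) + 1L]] <- data.frame(
        ID = g$variants$id[v], GENE = gn, N = n, SLOPE = slope, SE = se,
        T = tt, P = 2 * stats::pt(-abs(tt), df), CONVERGED = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  structure(
    list(records = records, p_report = p_report,
         conditioned = if (is.null(condition_on)) character(0)
                       else as.character(condition_on)),
    class = "eqtl_scan"
  )
}

#' @export
print.eqtl_scan <- function(x, ...) {
  r <- x$records
  cat(sprintf("eqtl_scan: %d variant-gene pairs", nrow(r)))
  if (length(x$conditioned)) {
    cat(", conditioned on", paste(x$conditioned, collapse = ", "))
  }
  cat("\n")
  hits <- r[r$CONVERGED & !is.na(r$P) & r$P < x$p_report, , drop = FALSE]
  cat(sprintf("  %d pair(s) below p_report=%g\n", nrow(hits), x$p_report))
  if (nrow(hits)) {
    top <- hits[which.min(hits$P), ]
    cat(sprintf("  top: %s x %s slope=%.4f p=%.3g\n",
                top$ID, top$GENE, top$SLOPE, top$P))
  }
  invisible(x)
}

#' @export
summary.eqtl_scan <- function(object, ...) {
  r <- object$records
  r <- r[r$CONVERGED & !is.na(r$P) & r$P < object$p_report, , drop = FALSE]
  r[order(r$P), , drop = FALSE]
}

#' @export
as.data.frame.eqtl_scan <- function(x, ...) x$records
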