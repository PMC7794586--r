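#' @title End-to-end synthetic replay pipeline
#' @description Orchestrates the full analysis chain on synthetic cohorts:
#'   simulate per-ancestry case-control data around one shared causal
#'   variant, apply QC, run the covariate-adjusted logistic scan and
#'   (optionally) stepwise conditional analysis per ancestry, fine-map each
#'   ancestry to a 95\% credible set, intersect the sets across ancestries,
#'   meta-analyse the per-ancestry results with sample-size weights, and
#'   fine-map the meta-analysis from its p-values. All stage tables are
#'   written as TSV and the run is deterministic given the seed.
#' @name pipeline
NULL

#' Build a pipeline run configuration
#'
#' Defaults describe four ancestral cohorts (EU, AA, AS, AI) genotyped over
#' the same 30-variant region with ancestry-specific allele frequencies and
#' LD strength, one shared causal variant of per-allele odds ratio 1.35 (the
#' middle of the 1.18-1.51 range typical of common autoimmune risk alleles),
#' and a 1:1 control:case ratio per cohort (an assumption; ratios are
#' configurable).
#'
#' @param seed master seed; every stage's randomness derives from it.
#' @param ancestries list of [ancestry_spec()] objects sharing positions.
#' @param causal_index index of the causal variant (shared across
#'   ancestries).
#' @param or_per_allele per-allele odds ratio at the causal variant.
#' @param base_rate baseline case probability.
#' @param missing_rate MCAR genotype missingness.
#' @param qc list: `maf_min`, `call_rate_min`, `sample_call_rate_min`,
#'   `pihat_max`, `r2_min`. Relatedness pruning is off by default
#'   (`pihat_max = NA`): pi-hat needs thousands of genome-wide markers, and
#'   a single fine-mapping region cannot estimate IBD reliably. Set
#'   `pihat_max` (e.g. 0.4) when the input carries genome-wide genotypes.
#' @param finemap list: `prior_w`, `level`.
#' @param assoc list: `p_stop`, `p_report_hi`, `conditional` (logical).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       ancestries = NULL,
                       causal_index = 15,
                       or_per_allele = 1.35,
                       base_rate = 0.1,
                       missing_rate = 0.02,
                       qc = list(),
                       finemap = list(),
                       assoc = list()) {
  if (is.null(ancestries)) {
    pos <- seq_len(30) * 1000L
    mk <- function(name, base_f, rho) {
      set.seed(seed + match(name, c("EU", "AA", "AS", "AI")))
      f <- pmin(pmax(base_f + stats::runif(30, -0.1, 0.1), 0.05), 0.95)
      ancestry_spec(name, 30, f, ld_rho = rho, positions = pos,
                    n_cases = 500, n_controls = 500)
    }
    ancestries <- list(mk("EU", 0.30, 0.6), mk("AA", 0.40, 0.4),
                       mk("AS", 0.25, 0.6), mk("AI", 0.35, 0.5))
  }
  qc <- utils::modifyList(
    list(maf_min = 0.01, call_rate_min = 0.90, sample_call_rate_min = 0.95,
         pihat_max = NA_real_, r2_min = 0.8), qc)
  qc$pihat_max <- as.numeric(qc$pihat_max)
  finemap <- utils::modifyList(list(prior_w = 0.04, level = 0.95), finemap)
  assoc <- utils::modifyList(
    list(p_stop = 1e-4, p_report_hi = 1e-2, conditional = FALSE), assoc)
  stopifnot(qc$maf_min >= 0, qc$maf_min < 0.5,
            qc$call_rate_min >= 0, qc$call_rate_min <= 1,
            qc$sample_call_rate_min >= 0, qc$sample_call_rate_min <= 1,
            finemap$prior_w > 0, finemap$level > 0, finemap$level <= 1,
            assoc$p_stop > 0, assoc$p_report_hi > assoc$p_stop)
  structure(
    list(seed = as.integer(seed), ancestries = ancestries,
         causal_index = causal_index, or_per_allele = or_per_allele,
         base_rate = base_rate, missing_rate = missing_rate,
         qc = qc, finemap = finemap, assoc = assoc),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; `ancestries` is a list
#' of mappings with the [ancestry_spec()] fields. The configuration
#' round-trips losslessly through [write_run_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  anc <- NULL
  if (!is.null(y$ancestries)) {
    anc <- lapply(y$ancestries, function(a) {
      ancestry_spec(a$name, a$n_variants, unlist(a$alt_freqs), a$ld_rho,
                    unlist(a$positions), a$n_cases, a$n_controls)
    })
  }
  run_config(
    seed = y$seed %||% 1, ancestries = anc,
    causal_index = y$causal_index %||% 15,
    or_per_allele = y$or_per_allele %||% 1.35,
    base_rate = y$base_rate %||% 0.1,
    missing_rate = y$missing_rate %||% 0.02,
    qc = y$qc %||% list(), finemap = y$finemap %||% list(),
    assoc = y$assoc %||% list()
  )
}

#' Write a pipeline configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  y <- list(
    seed = config$seed,
    causal_index = config$causal_index,
    or_per_allele = config$or_per_allele,
    base_rate = config$base_rate,
    missing_rate = config$missing_rate,
    qc = config$qc, finemap = config$finemap, assoc = config$assoc,
    ancestries = lapply(config$ancestries, function(a) {
      list(name = a$name, n_variants = a$n_variants,
           alt_freqs = a$alt_freqs, ld_rho = a$ld_rho,
           positions = a$positions, n_cases = a$n_cases,
           n_controls = a$n_controls)
    })
  )
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic fine-mapping pipeline
#'
#' Executes simulate -> QC -> logistic scan (three admixture covariates) ->
#' optional stepwise conditional analysis -> per-ancestry fine-mapping ->
#' cross-ancestry credible-set intersection -> sample-size-weighted
#' meta-analysis -> fine-mapping of the meta-analysis from its p-values
#' (combined N, cross-ancestry mean MAF). Per-ancestry randomness uses
#' `seed + k` for the k-th ancestry, so reruns with the same configuration
#' are byte-identical. Stage failures abort with the stage name; any stage
#' tables already written are retained.
#'
#' @param config a [run_config()].
#' @param out_dir directory for stage TSVs (created; default a fresh temp
#'   directory).
#' @return an object of class `run_report`: per-ancestry cohorts (post-QC),
#'   scans, fine-maps, the shared credible variants, the meta-analysis, its
#'   fine-map, QC reports, conditional traces (if run), and output paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("crediblemap_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  scans <- list(); finemaps <- list(); sets <- list(); studies <- list()
  qc_reports <- list(); traces <- list(); cohorts <- list()
  files <- character(0)
  for (k in seq_along(config$ancestries)) {
    spec <- config$ancestries[[k]]
    seed_k <- config$seed + k
    cohort <- stage(paste0("simulate:", spec$name), {
      panel <- simulate_haplotype_panel(spec, n_hap = 2000, seed = seed_k)
      simulate_case_control(panel, config$causal_index,
                            config$or_per_allele, config$base_rate,
                            missing_rate = config$missing_rate,
                            seed = seed_k + 1000L)
    })
    qcres <- stage(paste0("qc:", spec$name), {
      v <- filter_variants(cohort$genotypes, config$qc$maf_min,
                           config$qc$call_rate_min)
      s <- filter_samples(v$genotypes, config$qc$sample_call_rate_min)
      keep_samples <- match(s$genotypes$samples$id,
                            cohort$genotypes$samples$id)
      rel_report <- NULL
      g <- s$genotypes
      if (!is.na(config$qc$pihat_max)) {
        r <- remove_related(g, config$qc$pihat_max)
        g <- r$genotypes
        rel_report <- r$report
        keep_samples <- match(g$samples$id, cohort$genotypes$samples$id)
      }
      i <- filter_info(g, config$qc$r2_min)
      list(genotypes = i$genotypes, keep = keep_samples,
           reports = list(variants = v$report, samples = s$report,
                          related = rel_report, info = i$report))
    })
    g <- qcres$genotypes
    status <- cohort$status[qcres$keep]
    admix <- cohort$admixture[qcres$keep, , drop = FALSE]
    cohorts[[spec$name]] <- cohort
    qc_reports[[spec$name]] <- qcres$reports
    scan <- stage(paste0("assoc:", spec$name),
                  logistic_scan(g, status, admix))
    scans[[spec$name]] <- scan
    if (isTRUE(config$assoc$conditional)) {
      traces[[spec$name]] <- stage(
        paste0("conditional:", spec$name),
        conditional_stepwise(g, status, admix, config$assoc$p_stop,
                             config$assoc$p_report_hi)
      )
    }
    fm <- stage(paste0("finemap:", spec$name),
                finemap(scan, config$finemap$prior_w, config$finemap$level))
    finemaps[[spec$name]] <- fm
    sets[[spec$name]] <- fm$credible_set
    studies[[spec$name]] <- scan_to_study(scan, g)
    f_assoc <- file.path(out_dir, sprintf("assoc_%s.tsv", spec$name))
    write_stage_tsv(scan$records, f_assoc,
                    list(stage = "assoc", ancestry = spec$name,
                         seed = seed_k, covariates = "admixture3"))
    f_fm <- file.path(out_dir, sprintf("finemap_%s.tsv", spec$name))
    write_stage_tsv(fm$records, f_fm,
                    list(stage = "finemap", ancestry = spec$name,
                         prior_w = config$finemap$prior_w,
                         level = config$finemap$level))
    files <- c(files, f_assoc, f_fm)
  }
  shared <- stage("shared_credible_variants", shared_credible_variants(sets))
  meta <- stage("meta", {
    st <- lapply(studies, function(s) s[s$CONVERGED, , drop = FALSE])
    weighted_z_meta(st)
  })
  meta_fm <- stage("finemap_meta", {
    maf_tab <- do.call(rbind, studies)
    maf_mean <- tapply(maf_tab$MAF, maf_tab$ID, mean, na.rm = TRUE)
    mr <- meta$records
    finemap(data.frame(ID = mr$ID, P = mr$P, N = mr$N_TOTAL,
                       MAF = as.numeric(maf_mean[mr$ID]),
                       BETA = mr$Z, stringsAsFactors = FALSE),
            config$finemap$prior_w, config$finemap$level, from = "pvalue")
  })
  f_meta <- file.path(out_dir, "meta.tsv")
  write_stage_tsv(meta$records, f_meta,
                  list(stage = "meta", scheme = "samplesize",
                       seed = config$seed))
  f_meta_fm <- file.path(out_dir, "finemap_meta.tsv")
  write_stage_tsv(meta_fm$records, f_meta_fm,
                  list(stage = "finemap_meta",
                       prior_w = config$finemap$prior_w,
                       level = config$finemap$level))
  f_shared <- file.path(out_dir, "shared_credible_variants.tsv")
  write_stage_tsv(data.frame(ID = shared, stringsAsFactors = FALSE),
                  f_shared, list(stage = "shared", seed = config$seed))
  files <- c(files, f_meta, f_meta_fm, f_shared)
  structure(
    list(config = config, cohorts = cohorts, qc_reports = qc_reports,
         scans = scans, conditional = traces, finemaps = finemaps,
         shared_credible = shared, meta = meta, meta_finemap = meta_fm,
         out_dir = out_dir, files = files),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$config$seed, ")\n")
  for (nm in names(x$finemaps)) {
    cs <- x$finemaps[[nm]]$credible_set
    cat(sprintf("  %s: credible set of %d variant(s), cum PP %.3f\n",
                nm, length(cs$members), cs$cum_pp))
  }
  cat("  shared credible variants:",
      if (length(x$shared_credible)) paste(x$shared_credible, collapse = ", ")
      else "(none)", "\n")
  mr <- x$meta$records
  if (nrow(mr)) {
    top <- mr[which.min(mr$P), ]
    cat(sprintf("  meta top hit: %s Z=%.2f p=%.3g\n", top$ID, top$Z, top$P))
  }
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}
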