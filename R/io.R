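#' @title VCF and TSV input/output
#' @description Readers and writers connecting the pipeline to standard
#'   formats: biallelic-SNV VCF v4.2 (GT hard calls or DS dosages) for
#'   genotypes, and tab-separated tables with `# key=value` header comments
#'   for stage outputs. Positions are 1-based as in VCF.
#' @name io
NULL

#' Write genotypes as VCF v4.2
#'
#' Writes a plain-text VCF v4.2 with one biallelic SNV per row. Hard calls
#' are written as unphased GT (`0/0`, `0/1`, `1/1`, `./.`); dosage matrices
#' are written with a `DS` FORMAT field instead. Imputation info scores, when
#' present, are carried in the INFO column (`IMPUTED;R2=`).
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  info <- ifelse(v$imputed,
                 sprintf("IMPUTED;R2=%.4g", v$info_r2), ".")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crediblemap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternate allele dosage">',
    '##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description="Imputed variant">',
    '##INFO=<ID=R2,Number=1,Type=Float,Description="Imputation info score">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$id), collapse = "\t")
  )
  if (g$dosage) {
    fmt <- "DS"
    calls <- apply(g$geno, 2, function(col) {
      ifelse(is.na(col), ".", formatC(col, format = "g", digits = 6))
    })
  } else {
    fmt <- "GT"
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    calls <- apply(g$geno, 2, function(col) {
      ifelse(is.na(col), "./.", code[as.character(col)])
    })
  }
  # calls is samples x variants; VCF rows are variants
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            info[i], fmt, calls[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses a VCF (via `vcfR`) into a [genotype_matrix()]. GT fields are mapped
#' to alternate-allele counts \{0, 1, 2\} with `./.` as missing (phased
#' separators accepted); with `dosage = TRUE` the DS field is read instead.
#' Only biallelic SNVs are supported: multiallelic records are rejected with
#' the offending record named (`strict = TRUE`, default) or dropped with a
#' warning.
#'
#' @param path VCF file path.
#' @param dosage read the DS field as real dosages.
#' @param strict error on multiallelic records instead of dropping them.
#' @param group optional group label applied to all samples.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dosage = FALSE, strict = TRUE,
                           group = "cohort") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (strict) {
      stop("multiallelic record(s) not supported: ",
           paste(fix$ID[multi], collapse = ", "))
    }
    warning(sum(multi), " multiallelic record(s) dropped")
  }
  keep <- !multi
  if (dosage) {
    ds <- vcfR::extract.gt(vcf, element = "DS")
    geno <- suppressWarnings(apply(ds, 2, as.numeric))
    if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(ds))
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
    geno <- matrix(unname(map[gt]), nrow = nrow(gt))
  }
  geno <- t(geno)[, keep, drop = FALSE]  # samples x variants
  fix <- fix[keep, , drop = FALSE]
  info <- fix$INFO
  imputed <- grepl("IMPUTED", info)
  r2 <- suppressWarnings(
    as.numeric(sub(".*R2=([0-9.eE+-]+).*", "\\1", info))
  )
  r2[!grepl("R2=", info)] <- NA_real_
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, imputed = imputed, info_r2 = r2,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(id = colnames(vcf@gt)[-1], group = group,
                        stringsAsFactors = FALSE)
  genotype_matrix(geno, variants, samples, dosage = dosage)
}

#' Write a stage table as TSV with metadata header
#'
#' Writes a data.frame as a tab-separated table preceded by `# key=value`
#' comment lines recording, e.g., the seed and thresholds the stage applied.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list of key=value metadata.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, format(meta[[k]])), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage TSV written by [write_stage_tsv()]
#'
#' @param path file path.
#' @return data.frame; the `# key=value` header lines are attached as the
#'   `meta` attribute.
#' @export
read_stage_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^# ", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "# ")],
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

# internal: per-ancestry summary-statistics table from an assoc_scan,
# in the study-table layout weighted_z_meta() consumes
scan_to_study <- function(scan, g, maf = NULL) {
  r <- scan$records
  if (is.null(maf)) {
    f <- alt_freq(g$geno)[match(r$ID, g$variants$id)]
    maf <- pmin(f, 1 - f)
  }
  data.frame(
    ID = r$ID, A1 = r$A2, A2 = r$A1,  # effect allele = alt
    BETA = r$BETA, SE = r$SE, P = r$P, N = r$N, MAF = maf,
    CONVERGED = r$CONVERGED, stringsAsFactors = FALSE
  )
}
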