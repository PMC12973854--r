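.SS_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

#' Write GWAS summary statistics
#'
#' Canonical tab-separated dialect: header `SNP CHR POS EA OA EAF BETA SE
#' P N`, `.` for missing values.  [read_summary_stats()] of a written
#' file is the identity.
#'
#' @param stats a `summary_stats` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  df <- data.frame(SNP = stats$snp_id, CHR = stats$chrom,
                   POS = stats$pos_bp, EA = stats$effect_allele,
                   OA = stats$other_allele, EAF = stats$eaf,
                   BETA = stats$beta, SE = stats$se, P = stats$pval,
                   N = stats$n, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- vapply(x, function(v)
      if (is.na(v)) "." else format(v, digits = 17, scientific = NA),
      character(1))
    out
  })
  df[!num] <- lapply(df[!num], function(x) ifelse(is.na(x), ".", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Reads the tab-separated dialect written by [write_summary_stats()].
#' Header matching is case-insensitive; `.` is missing; scientific
#' notation in any numeric column (including P) is parsed.  Rows failing
#' validation (non-positive SE, p outside (0, 1]) are rejected and
#' collected, with line numbers and reasons, in the `"rejected"`
#' attribute.
#'
#' @param path input path.
#' @return a `summary_stats` data.frame.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  hdr <- toupper(names(raw))
  missing <- setdiff(.SS_COLS, hdr)
  if (length(missing))
    stop("missing required column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  names(raw) <- hdr
  raw <- raw[.SS_COLS]
  raw[raw == "."] <- NA
  num <- function(x) as.numeric(x)
  out <- data.frame(snp_id = raw$SNP, chrom = raw$CHR,
                    pos_bp = as.integer(num(raw$POS)),
                    effect_allele = raw$EA, other_allele = raw$OA,
                    eaf = num(raw$EAF), beta = num(raw$BETA),
                    se = num(raw$SE), pval = num(raw$P),
                    n = as.integer(num(raw$N)),
                    stringsAsFactors = FALSE)
  bad_se <- !is.na(out$se) & out$se <= 0
  bad_p <- !is.na(out$pval) & (out$pval <= 0 | out$pval > 1)
  bad <- bad_se | bad_p
  rejected <- data.frame(line = which(bad) + 1L,
                         snp_id = out$snp_id[bad],
                         reason = ifelse(bad_se[bad], "nonpositive_se",
                                         "pval_out_of_range"),
                         stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "rejected") <- rejected
  out
}

#' Write a genotype dosage matrix as TSV
#'
#' First column `SAMPLE_ID`, one integer column per SNP (header = snp
#' id), `.` for missing calls.
#'
#' @param G a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(G, path) {
  df <- as.data.frame(G$dosages)
  df[] <- lapply(df, function(x) ifelse(is.na(x), ".",
                                        as.character(as.integer(x))))
  df <- cbind(SAMPLE_ID = G$sample_ids, df, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write genotypes as a minimal VCF v4.2
#'
#' GT-only, unphased; the panel's effect allele is written as ALT so that
#' the ALT-allele count equals the stored dosage.
#'
#' @param G a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", G$sample_ids),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  p <- G$panel
  for (j in seq_len(nrow(p))) {
    d <- G$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(p$chrom[j], p$pos_bp[j], p$snp_id[j],
                       p$other_allele[j], p$effect_allele[j], ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype matrix
#'
#' `format = "tsv_dosage"` reads the dialect of [write_genotype_tsv()]
#' (non-integer dosages are an error).  `format = "vcf"` reads a VCF v4.2
#' with GT: `0/0`, `0/1`, `1/1` map to dosages 0, 1, 2 counting ALT as
#' the effect allele; `./.` is missing; phased separators are accepted;
#' multi-allelic records are skipped with a warning reporting the count.
#'
#' @param path input path.
#' @param format `"tsv_dosage"` or `"vcf"`.
#' @return a `genotype_matrix` (panel holds whatever metadata the format
#'   carries; TSV gives ids only, VCF adds chrom/pos/alleles).
#' @export
read_genotype_matrix <- function(path, format = c("tsv_dosage", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv_dosage") {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE, check.names = FALSE)
    ids <- raw[[1]]
    mat <- as.matrix(raw[, -1, drop = FALSE])
    mat[mat == "."] <- NA
    suppressWarnings(num <- as.numeric(mat))
    if (any(!is.na(mat) & (is.na(num) | num != as.integer(num))))
      stop("non-integer dosage value(s) in ", path)
    dos <- matrix(as.integer(num), nrow(mat), ncol(mat))
    snp <- colnames(raw)[-1]
    panel <- .bare_panel(snp)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      warning("skipped ", sum(multi), " multi-allelic VCF record(s)")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    code <- function(x) {
      x <- gsub("|", "/", x, fixed = TRUE)
      out <- rep(NA_integer_, length(x))
      out[x == "0/0"] <- 0L
      out[x %in% c("0/1", "1/0")] <- 1L
      out[x == "1/1"] <- 2L
      out
    }
    dos <- t(matrix(code(as.vector(gt)), nrow(gt), ncol(gt)))
    ids <- colnames(gt)
    snp <- unname(fix[, "ID"])
    panel <- .bare_panel(snp, chrom = unname(fix[, "CHROM"]),
                         pos_bp = as.integer(fix[, "POS"]),
                         effect_allele = unname(fix[, "ALT"]),
                         other_allele = unname(fix[, "REF"]))
  }
  af <- colMeans(dos, na.rm = TRUE) / 2
  panel$maf <- pmin(pmax(af, 1e-6), 0.5)
  new_genotype_matrix(dos, panel, ids)
}

.bare_panel <- function(snp_id, chrom = NA_character_, pos_bp = 1L,
                        effect_allele = "A", other_allele = "C") {
  structure(data.frame(snp_id = snp_id, chrom = chrom,
                       pos_bp = pos_bp,
                       effect_allele = effect_allele,
                       other_allele = other_allele,
                       maf = 0.25, ld_block = seq_along(snp_id),
                       gamma_true = 0, alpha_true = 0,
                       stringsAsFactors = FALSE),
            class = c("snp_panel", "data.frame"))
}

#' Write / read a phenotype table as CSV
#'
#' Columns `SAMPLE_ID, EXPOSURE, OUTCOME, AGE, SEX, EDU`.
#'
#' @param ph a `phenotype_table` (or compatible data.frame).
#' @param path file path.
#' @return `path` invisibly (write); a `phenotype_table` (read).
#' @export
write_phenotypes <- function(ph, path) {
  df <- data.frame(SAMPLE_ID = ph$sample_id,
                   EXPOSURE = ph$exposure_binary, OUTCOME = ph$outcome,
                   AGE = ph$age, SEX = ph$sex, EDU = ph$education)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("SAMPLE_ID", "EXPOSURE", "OUTCOME", "AGE", "SEX", "EDU")
  missing <- setdiff(need, toupper(names(df)))
  if (length(missing))
    stop("missing required column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  names(df) <- toupper(names(df))
  structure(data.frame(sample_id = as.character(df$SAMPLE_ID),
                       exposure_binary = df$EXPOSURE,
                       outcome = df$OUTCOME, age = df$AGE, sex = df$SEX,
                       education = df$EDU, stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

#' Write the tables of a summary-MR report
#'
#' Emits the report as machine-readable artifacts under `dir`:
#' `estimates.jsonl` (one JSON record per estimator, beta and OR scales),
#' `forest.tsv` (per-SNP associations and ratios), `funnel.tsv`,
#' `leave_one_out.tsv`, and `harmonisation_audit.tsv`.
#'
#' @param report an `mr_report`.
#' @param iset the `instrument_set` it was computed from.
#' @param dir output directory (created if needed).
#' @param stamp named list of provenance fields added to every JSON
#'   record (e.g. seed, package version, config hash).
#' @return character vector of written paths, invisibly.
#' @export
write_mr_report <- function(report, iset, dir, stamp = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  jl <- file.path(dir, "estimates.jsonl")
  con <- file(jl, "w")
  emit <- function(df, extra = list()) {
    for (i in seq_len(nrow(df))) {
      rec <- c(as.list(df[i, ]), extra, stamp)
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  }
  emit(report$headline, list(set = "all", k = report$k))
  if (!is.null(report$excluding_outliers))
    emit(report$excluding_outliers$headline,
         list(set = "excluding_outliers",
              k = report$excluding_outliers$k))
  close(con)
  paths <- c(paths, jl)

  forest <- merge(iset[, c("snp_id", "gamma", "se_gamma", "big_gamma",
                           "se_big_gamma")],
                  report$ratios, by = "snp_id")
  forest$ci_low <- forest$ratio_beta - 1.96 * forest$ratio_se
  forest$ci_high <- forest$ratio_beta + 1.96 * forest$ratio_se
  for (nm in c("forest", "funnel", "leave_one_out")) {
    obj <- switch(nm, forest = forest, funnel = report$funnel,
                  leave_one_out = report$leave_one_out)
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(obj, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  aud <- report$audit$harmonisation
  if (!is.null(aud)) {
    p <- file.path(dir, "harmonisation_audit.tsv")
    utils::write.table(aud, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
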