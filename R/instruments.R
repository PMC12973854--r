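#' LD-clumping parameters
#'
#' Defaults mirror common practice for instrument selection from GWAS
#' summary statistics: a 10,000 kb window, an r-squared threshold of
#' 0.001, index/secondary p-value thresholds of 1e-5 and a genome-wide
#' significance filter of 5e-8 applied before clumping.
#'
#' @param window_kb clumping window in kilobases (inclusive both ends).
#' @param r2_threshold SNPs with r-squared at or above this value to an
#'   index SNP are pruned.
#' @param p_index,p_secondary p-value thresholds for index and secondary
#'   SNPs.
#' @param gwas_threshold genome-wide significance threshold applied
#'   upstream of clumping (strict `<`).
#' @return list of class `clump_params`.
#' @export
clump_params <- function(window_kb = 10000, r2_threshold = 0.001,
                         p_index = 1e-5, p_secondary = 1e-5,
                         gwas_threshold = 5e-8) {
  thr <- c(r2_threshold, p_index, p_secondary, gwas_threshold)
  if (any(thr <= 0 | thr > 1)) stop("thresholds must lie in (0, 1]")
  if (window_kb <= 0) stop("window_kb must be > 0")
  structure(list(window_kb = window_kb, r2_threshold = r2_threshold,
                 p_index = p_index, p_secondary = p_secondary,
                 gwas_threshold = gwas_threshold),
            class = "clump_params")
}

#' Filter summary statistics by p-value
#'
#' Retains records with `pval` strictly below the threshold, preserving
#' input order.  A record with p exactly equal to the threshold is
#' excluded.
#'
#' @param stats a `summary_stats` data.frame.
#' @param threshold p-value threshold in (0, 1].
#' @return the filtered `summary_stats`.
#' @export
filter_by_pvalue <- function(stats, threshold = 5e-8) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  keep <- !is.na(stats$pval) & stats$pval < threshold
  stats[keep, , drop = FALSE]
}

#' Pairwise r-squared between two SNPs
#'
#' Squared Pearson correlation of the dosage columns over
#' pairwise-complete individuals.  A constant dosage at either SNP leaves
#' r-squared undefined; it is returned as `NA` (clumping treats it as 0)
#' with a message.
#'
#' @param G a `genotype_matrix` reference panel.
#' @param snp_a,snp_b SNP identifiers present in `G`.
#' @return r-squared in \[0, 1\], or `NA` when undefined.
#' @export
pairwise_r2 <- function(G, snp_a, snp_b) {
  for (s in c(snp_a, snp_b))
    if (!s %in% colnames(G$dosages))
      stop("SNP not present in reference panel: ", s)
  a <- G$dosages[, snp_a]
  b <- G$dosages[, snp_b]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete individuals")
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
    message("r2 undefined (constant dosage) for ", snp_a, " / ", snp_b)
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])^2
}

#' Greedy LD clumping of summary statistics
#'
#' PLINK-style greedy algorithm.  Candidates are the SNPs with
#' `pval < p_index`, sorted by ascending p (ties broken by ascending
#' position, then SNP id).  The best remaining SNP becomes an index; every
#' other candidate with `pval < p_secondary` on the same chromosome within
#' the window (inclusive both ends) whose r-squared with the index is at
#' or above `r2_threshold` is pruned.  The retained index SNPs are
#' returned in genomic order.  The output is independent of input record
#' order.
#'
#' @param stats a `summary_stats` data.frame with `chrom`/`pos_bp` filled.
#' @param ref a `genotype_matrix` reference panel supplying dosages for
#'   r-squared.
#' @param params a [clump_params()].
#' @param missing_ref `"error"` (default) or `"drop"` for SNPs absent from
#'   the reference panel.
#' @return character vector of retained SNP ids, in genomic order.
#' @export
greedy_ld_clump <- function(stats, ref, params = clump_params(),
                            missing_ref = c("error", "drop")) {
  missing_ref <- match.arg(missing_ref)
  present <- stats$snp_id %in% colnames(ref$dosages)
  if (!all(present)) {
    if (missing_ref == "error")
      stop("SNP(s) absent from reference panel: ",
           paste(stats$snp_id[!present], collapse = ", "))
    stats <- stats[present, , drop = FALSE]
  }
  cand <- stats[!is.na(stats$pval) & stats$pval < params$p_index, ,
                drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  ord <- order(cand$pval, cand$pos_bp, cand$snp_id)
  cand <- cand[ord, , drop = FALSE]
  win_bp <- params$window_kb * 1000
  alive <- rep(TRUE, nrow(cand))
  retained <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    retained <- c(retained, i)
    alive[i] <- FALSE
    rest <- which(alive)
    if (!length(rest)) break
    near <- rest[cand$chrom[rest] == cand$chrom[i] &
                 abs(cand$pos_bp[rest] - cand$pos_bp[i]) <= win_bp &
                 cand$pval[rest] < params$p_secondary]
    for (j in near) {
      r2 <- suppressMessages(pairwise_r2(ref, cand$snp_id[i],
                                         cand$snp_id[j]))
      if (is.na(r2)) r2 <- 0
      if (r2 >= params$r2_threshold) alive[j] <- FALSE
    }
  }
  kept <- cand[retained, , drop = FALSE]
  kept$snp_id[order(kept$chrom, kept$pos_bp, kept$snp_id)]
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Matches records by SNP id and aligns the outcome association to the
#' exposure's effect allele.  Swapped alleles flip the sign of the outcome
#' beta and complement its frequency; alleles matching only after strand
#' complementation (A-T, C-G) are complemented first.  Palindromic SNPs
#' (A/T or G/C pairs) are strand-ambiguous: under the default
#' `"drop_intermediate"` policy they are dropped when the outcome
#' effect-allele frequency lies in the ambiguity band \[0.42, 0.58\] and
#' aligned by frequency otherwise; `"drop_all"` drops every palindromic
#' SNP, `"keep"` takes the allele letters at face value.  Every dropped
#' SNP carries a reason code in the audit table.
#'
#' @param exposure_stats,outcome_stats `summary_stats` data.frames; SNP
#'   ids must be unique within each.
#' @param palindrome_policy `"drop_intermediate"` (default), `"drop_all"`,
#'   or `"keep"`.
#' @param ambiguity_band outcome-EAF band treated as unresolvable for
#'   palindromic SNPs.
#' @return A data.frame of class `instrument_set` with one row per
#'   retained SNP: `snp_id`, shared `effect_allele`/`other_allele`,
#'   exposure association `gamma`/`se_gamma`, outcome association
#'   `big_gamma`/`se_big_gamma`, both EAFs and provenance flags.  The
#'   audit trail (snp_id, action, reason) is in attribute `"audit"`.
#' @export
harmonize_instruments <- function(exposure_stats, outcome_stats,
                                  palindrome_policy = c("drop_intermediate",
                                                        "drop_all", "keep"),
                                  ambiguity_band = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  for (nm in c("exposure", "outcome")) {
    st <- if (nm == "exposure") exposure_stats else outcome_stats
    if (anyDuplicated(st$snp_id))
      stop("duplicate snp_id in ", nm, " statistics: ",
           paste(unique(st$snp_id[duplicated(st$snp_id)]), collapse = ", "))
  }
  oidx <- match(exposure_stats$snp_id, outcome_stats$snp_id)
  audit <- data.frame(snp_id = character(0), action = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  note <- function(id, action, reason = "") {
    audit[nrow(audit) + 1L, ] <<- list(id, action, reason)
  }
  rows <- vector("list", nrow(exposure_stats))
  for (i in seq_len(nrow(exposure_stats))) {
    e <- exposure_stats[i, ]
    j <- oidx[i]
    if (is.na(j)) { note(e$snp_id, "dropped", "not_in_outcome"); next }
    o <- outcome_stats[j, ]
    ea <- e$effect_allele; oa <- e$other_allele
    b <- o$beta; f <- o$eaf
    flipped <- FALSE; strand <- FALSE
    pal <- .is_palindromic(ea, oa)
    if (pal) {
      if (palindrome_policy == "drop_all") {
        note(e$snp_id, "dropped", "palindromic"); next
      }
      if (palindrome_policy == "drop_intermediate") {
        if (is.na(f) || (f >= ambiguity_band[1] && f <= ambiguity_band[2])) {
          note(e$snp_id, "dropped", "palindromic_ambiguous"); next
        }
        # align by frequency: same side of 0.5 means same allele coded
        same_side <- sign(e$eaf - 0.5) == sign(f - 0.5)
        if (!same_side) { b <- -b; f <- 1 - f; flipped <- TRUE }
      } else {
        # keep: fall through to literal allele matching below
        pal <- FALSE
      }
    }
    if (!pal) {
      if (o$effect_allele == ea && o$other_allele == oa) {
        # aligned as is
      } else if (o$effect_allele == oa && o$other_allele == ea) {
        b <- -b; f <- 1 - f; flipped <- TRUE
      } else {
        cea <- unname(.complement[o$effect_allele])
        coa <- unname(.complement[o$other_allele])
        if (identical(cea, ea) && identical(coa, oa)) {
          strand <- TRUE
        } else if (identical(cea, oa) && identical(coa, ea)) {
          strand <- TRUE; b <- -b; f <- 1 - f; flipped <- TRUE
        } else {
          note(e$snp_id, "dropped", "allele_mismatch"); next
        }
      }
    }
    note(e$snp_id, "retained",
         if (flipped && strand) "strand_and_flip"
         else if (flipped) "flipped"
         else if (strand) "strand" else "aligned")
    rows[[i]] <- data.frame(snp_id = e$snp_id, chrom = e$chrom,
                            pos_bp = e$pos_bp,
                            effect_allele = ea, other_allele = oa,
                            gamma = e$beta, se_gamma = e$se,
                            big_gamma = b, se_big_gamma = o$se,
                            eaf_exposure = e$eaf, eaf_outcome = f,
                            flipped = flipped, strand_swapped = strand,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no SNPs could be harmonized")
  iset <- do.call(rbind, rows)
  rownames(iset) <- NULL
  bad <- iset$se_gamma <= 0 | iset$se_big_gamma <= 0
  if (any(bad)) {
    for (id in iset$snp_id[bad]) note(id, "dropped", "nonpositive_se")
    iset <- iset[!bad, , drop = FALSE]
  }
  class(iset) <- c("instrument_set", "data.frame")
  attr(iset, "audit") <- audit
  iset
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d harmonized SNPs (%d flipped, %d strand-swapped)\n",
              nrow(x), sum(x$flipped), sum(x$strand_swapped)))
  print(as.data.frame(x), ...)
  invisible(x)
}
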