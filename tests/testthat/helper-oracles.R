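# Independent oracles, written against the definitions rather than the
# package internals, for equivalence tests.

# brute-force greedy clumping: recomputes the candidate list from scratch
# on every step instead of maintaining an alive mask
brute_clump <- function(stats, r2fun, window_kb, r2_thr, p_index, p_sec) {
  cand <- stats[stats$pval < p_index, , drop = FALSE]
  kept <- character(0)
  repeat {
    if (nrow(cand) == 0) break
    o <- order(cand$pval, cand$pos_bp, cand$snp_id)
    idx <- cand[o[1], ]
    kept <- c(kept, idx$snp_id)
    drop <- vapply(seq_len(nrow(cand)), function(i) {
      if (cand$snp_id[i] == idx$snp_id) return(TRUE)
      if (cand$chrom[i] != idx$chrom) return(FALSE)
      if (abs(cand$pos_bp[i] - idx$pos_bp) > window_kb * 1000) return(FALSE)
      if (!(cand$pval[i] < p_sec)) return(FALSE)
      r2 <- r2fun(idx$snp_id, cand$snp_id[i])
      if (is.na(r2)) r2 <- 0
      r2 >= r2_thr
    }, logical(1))
    cand <- cand[!drop, , drop = FALSE]
  }
  sort(kept)
}

# closed-form simple OLS slope
ols_slope <- function(g, y) sum((g - mean(g)) * (y - mean(y))) /
  sum((g - mean(g))^2)

# instrument set built directly from numbers, for estimator fixtures
make_iset <- function(gamma, se_gamma, big_gamma, se_big_gamma,
                      snp_id = sprintf("rs%03d", seq_along(gamma))) {
  df <- data.frame(snp_id = snp_id, chrom = "1",
                   pos_bp = seq_along(gamma) * 1000L,
                   effect_allele = "A", other_allele = "G",
                   gamma = gamma, se_gamma = se_gamma,
                   big_gamma = big_gamma, se_big_gamma = se_big_gamma,
                   eaf_exposure = 0.3, eaf_outcome = 0.3,
                   flipped = FALSE, strand_swapped = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("instrument_set", "data.frame")
  df
}

# summary-stat record builder
make_stats <- function(snp_id, beta, se, pval = NULL, chrom = "1",
                       pos_bp = seq_along(snp_id) * 1000L,
                       ea = "A", oa = "G", eaf = 0.3,
                       n = 1000L, trait_label = "trait") {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  df <- data.frame(snp_id = snp_id, chrom = chrom, pos_bp = pos_bp,
                   effect_allele = rep_len(ea, length(snp_id)),
                   other_allele = rep_len(oa, length(snp_id)),
                   eaf = rep_len(eaf, length(snp_id)),
                   beta = beta, se = se, pval = pval,
                   n = rep_len(n, length(snp_id)),
                   trait_label = trait_label, degenerate = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("summary_stats", "data.frame")
  df
}

# small genotype matrix from an explicit dosage matrix
make_gm <- function(dos, snp_id = sprintf("rs%03d", seq_len(ncol(dos))),
                    chrom = "1", pos_bp = seq_len(ncol(dos)) * 1000L,
                    maf = rep(0.25, ncol(dos))) {
  panel <- snp_panel(snp_id, rep_len(chrom, ncol(dos)), pos_bp,
                     rep("A", ncol(dos)), rep("G", ncol(dos)), maf,
                     ld_block = seq_len(ncol(dos)))
  mrcausal:::new_genotype_matrix(
    matrix(as.integer(dos), nrow(dos), ncol(dos)), panel,
    sprintf("S%03d", seq_len(nrow(dos))))
}

# two-sample replicate: returns the harmonized instrument set and truth
sim_twosample_iset <- function(panel, n, beta, seed_base,
                               noise_sd_y = 2.4) {
  cfgA <- cohort_config(n_individuals = n, causal_beta = beta,
                        noise_sd_y = noise_sd_y, seed = seed_base)
  cfgB <- cohort_config(n_individuals = n, causal_beta = beta,
                        noise_sd_y = noise_sd_y, seed = seed_base + 1L)
  st <- simulate_two_sample_study(panel, cfgA, cfgB)
  suppressMessages(harmonize_instruments(st$exposure_stats,
                                         st$outcome_stats))
}
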