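#' Construct a SNP panel
#'
#' A SNP panel is the variant-level ground truth of a synthetic cohort: one
#' row per biallelic SNP with its genomic location, allele coding, minor
#' allele frequency, linkage-disequilibrium (LD) block membership, the true
#' per-allele effect on the exposure liability (`gamma_true`) and any direct
#' (horizontally pleiotropic) per-allele effect on the outcome
#' (`alpha_true`).
#'
#' @param snp_id character vector of unique variant identifiers.
#' @param chrom chromosome labels (character or integer).
#' @param pos_bp 1-based base-pair positions.
#' @param effect_allele,other_allele single-base allele codes; must differ
#'   within each row.
#' @param maf minor-allele frequency of the effect allele, in (0, 0.5].
#' @param ld_block integer block labels; SNPs sharing a label are simulated
#'   with correlated haplotypes, SNPs in different blocks are independent.
#' @param gamma_true per-allele effect on the exposure liability
#'   (liability-scale units).
#' @param alpha_true direct per-allele effect on the outcome, i.e. the
#'   horizontal-pleiotropy pathway. Zero for a valid instrument.
#' @return A `data.frame` of class `snp_panel`.
#' @export
snp_panel <- function(snp_id, chrom, pos_bp, effect_allele, other_allele,
                      maf, ld_block = seq_along(snp_id),
                      gamma_true = 0, alpha_true = 0) {
  n <- length(snp_id)
  panel <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    maf = as.numeric(maf),
    ld_block = as.integer(ld_block),
    gamma_true = rep_len(as.numeric(gamma_true), n),
    alpha_true = rep_len(as.numeric(alpha_true), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(panel$snp_id))
    stop("duplicate snp_id in panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  if (any(panel$maf <= 0 | panel$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  if (any(panel$effect_allele == panel$other_allele))
    stop("effect_allele must differ from other_allele")
  if (any(panel$pos_bp < 1)) stop("pos_bp must be >= 1")
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Study-like default SNP panel
#'
#' Builds a panel emulating the instrument set of a migraine GWAS: a stated
#' number of independent loci (default 18), each contributing a small
#' per-allele effect on the migraine liability, optionally surrounded by
#' correlated neighbours in the same LD block so that clumping has something
#' to prune.
#'
#' @param n_loci number of independent causal loci (LD blocks).
#' @param snps_per_block SNPs per block; neighbours beyond the first carry
#'   the same block label and no effect of their own (they tag the causal
#'   SNP through LD only).
#' @param gamma_range range from which per-locus liability effects are drawn
#'   uniformly; small effects, as expected for a polygenic trait.
#' @param maf_range range for minor-allele frequencies.
#' @param seed integer seed controlling the drawn effects and frequencies.
#' @return A `snp_panel`.
#' @export
default_panel <- function(n_loci = 18, snps_per_block = 1,
                          gamma_range = c(0.05, 0.15),
                          maf_range = c(0.10, 0.50), seed = 1L) {
  withr::with_seed(seed, {
    m <- n_loci * snps_per_block
    block <- rep(seq_len(n_loci), each = snps_per_block)
    within <- rep(seq_len(snps_per_block), times = n_loci)
    gam <- stats::runif(n_loci, gamma_range[1], gamma_range[2])
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, m, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
    snp_panel(
      snp_id = sprintf("rs%d", 100000L + seq_len(m)),
      chrom = as.character(((block - 1L) %% 22L) + 1L),
      pos_bp = 1000000L * block + 5000L * within,
      effect_allele = ea, other_allele = oa,
      maf = maf, ld_block = block,
      gamma_true = ifelse(within == 1L, gam[block], 0),
      alpha_true = 0
    )
  })
}

#' Add horizontal pleiotropy to a panel
#'
#' Applies one of three named pleiotropy scenarios by drawing direct SNP to
#' outcome effects `alpha_true` for a stated fraction of SNPs: `"none"`
#' leaves the panel untouched; `"balanced"` draws alpha from a zero-mean
#' normal (violates exclusion restriction but not the InSIDE-balanced
#' assumption underlying IVW on average); `"directional"` draws alpha from a
#' normal with non-zero mean, which biases IVW and shifts the MR-Egger
#' intercept.
#'
#' @param panel a `snp_panel`.
#' @param preset one of `"none"`, `"balanced"`, `"directional"`.
#' @param frac_invalid fraction of SNPs receiving a direct effect.
#' @param alpha_mean mean direct effect (directional preset only).
#' @param alpha_sd standard deviation of the direct effects.
#' @param seed integer seed.
#' @return The panel with `alpha_true` filled in; affected SNP ids in
#'   attribute `"invalid_snps"`.
#' @export
apply_pleiotropy <- function(panel,
                             preset = c("none", "balanced", "directional"),
                             frac_invalid = 0.3, alpha_mean = 0.05,
                             alpha_sd = 0.02, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "none") {
    attr(panel, "invalid_snps") <- character(0)
    return(panel)
  }
  mu <- if (preset == "balanced") 0 else alpha_mean
  withr::with_seed(seed, {
    m <- nrow(panel)
    k <- max(1L, round(frac_invalid * m))
    idx <- sample.int(m, k)
    panel$alpha_true[idx] <- stats::rnorm(k, mu, alpha_sd)
  })
  attr(panel, "invalid_snps") <- panel$snp_id[idx]
  panel
}

#' Cohort generation settings
#'
#' Collects every knob of the liability-threshold phenotype model into one
#' validated list.  The exposure is binary (e.g. migraine status), generated
#' by thresholding a standardized latent liability at the quantile implied
#' by `prevalence_k`; the outcome is a bounded continuous score (MMSE-like,
#' 0 to 30 by default, 30 best) affected by the liability with slope
#' `causal_beta`.
#'
#' @param n_individuals cohort size.
#' @param prevalence_k exposure prevalence in (0, 1).
#' @param causal_beta causal effect of one liability unit on the outcome
#'   (outcome units).
#' @param confounder_sd,confounder_effect_x,confounder_effect_y a shared
#'   normal confounder `C` with this SD loading on the liability
#'   (`confounder_effect_x`) and directly on the outcome
#'   (`confounder_effect_y`). All zero by default (no confounding).
#' @param noise_sd_y outcome noise SD (MMSE-like scores scatter by roughly
#'   2.4 points).
#' @param within_block_rho latent haplotype correlation inside an LD block,
#'   in \[0, 1).
#' @param outcome_floor,outcome_ceiling outcome bounds (default 0 and 30).
#' @param outcome_mean target mean of the unclipped outcome (default 27,
#'   MMSE-like).
#' @param clip_outcome clip the outcome to its bounds? Default `FALSE`:
#'   clipping breaks the exact linear identities that estimator tests rely
#'   on; turn on for realism fixtures.
#' @param round_outcome round the outcome to integers? Default `FALSE`.
#' @param miss_rate missing-completely-at-random dosage rate, default 0.
#' @param seed integer seed for all randomness driven by this config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 1386, prevalence_k = 0.15,
                          causal_beta = 0, confounder_sd = 0,
                          confounder_effect_x = 0, confounder_effect_y = 0,
                          noise_sd_y = 2.4, within_block_rho = 0,
                          outcome_floor = 0, outcome_ceiling = 30,
                          outcome_mean = 27, clip_outcome = FALSE,
                          round_outcome = FALSE, miss_rate = 0, seed = 1L) {
  if (outcome_floor >= outcome_ceiling)
    stop("outcome_floor must be < outcome_ceiling")
  if (prevalence_k <= 0 || prevalence_k >= 1)
    stop("prevalence_k must lie in (0, 1)")
  if (within_block_rho < 0 || within_block_rho >= 1)
    stop("within_block_rho must lie in [0, 1)")
  if (noise_sd_y < 0) stop("noise_sd_y must be >= 0")
  cfg <- list(n_individuals = as.integer(n_individuals),
              prevalence_k = prevalence_k, causal_beta = causal_beta,
              confounder_sd = confounder_sd,
              confounder_effect_x = confounder_effect_x,
              confounder_effect_y = confounder_effect_y,
              noise_sd_y = noise_sd_y, within_block_rho = within_block_rho,
              outcome_floor = outcome_floor,
              outcome_ceiling = outcome_ceiling,
              outcome_mean = outcome_mean,
              clip_outcome = isTRUE(clip_outcome),
              round_outcome = isTRUE(round_outcome),
              miss_rate = miss_rate, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}
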