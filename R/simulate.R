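#' @keywords internal
new_genotype_matrix <- function(dosages, panel, sample_ids) {
  stopifnot(ncol(dosages) == nrow(panel))
  dimnames(dosages) <- list(sample_ids, panel$snp_id)
  structure(list(dosages = dosages, panel = panel,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# haplotype draw for one LD block under the latent equicorrelated Gaussian:
# allele = 1 iff z < qnorm(maf), so P(allele) = maf per SNP and pairwise
# correlation is tuned by rho
.block_haplotype <- function(n, maf, rho) {
  b <- length(maf)
  z <- matrix(stats::rnorm(n * b), n, b)
  if (rho > 0 && b > 1) {
    shared <- stats::rnorm(n)
    z <- sqrt(rho) * shared + sqrt(1 - rho) * z
  }
  thr <- stats::qnorm(maf)
  (z < matrix(thr, n, b, byrow = TRUE)) + 0L
}

.sim_geno <- function(panel, n, rho, miss_rate = 0) {
  m <- nrow(panel)
  dos <- matrix(0L, n, m)
  for (blk in split(seq_len(m), panel$ld_block)) {
    maf <- panel$maf[blk]
    dos[, blk] <- .block_haplotype(n, maf, rho) + .block_haplotype(n, maf, rho)
  }
  if (miss_rate > 0 && n > 0) {
    drop <- stats::runif(n * m) < miss_rate
    dos[drop] <- NA_integer_
  }
  dos
}

#' Simulate LD-structured genotypes
#'
#' Each genotype is the sum of two independent haplotypes.  Within an LD
#' block, haplotype alleles come from a latent equicorrelated Gaussian
#' (correlation `rho`) thresholded at the minor-allele-frequency quantile,
#' which yields Hardy-Weinberg proportions per SNP and a tunable pairwise
#' r-squared; SNPs in different blocks are independent.  The construction
#' is deliberately simple: the pipeline only needs LD for clumping to act
#' on, not a realistic human LD map.
#'
#' @param panel a `snp_panel`.
#' @param n number of individuals (0 allowed).
#' @param rho latent within-block haplotype correlation in \[0, 1).
#' @param seed integer seed; identical inputs and seed give identical
#'   output.
#' @param miss_rate missing-completely-at-random dosage rate, default 0.
#' @return A `genotype_matrix` with dosages in \{0, 1, 2, NA\}.
#' @export
simulate_genotypes <- function(panel, n, rho = 0, seed = 1L, miss_rate = 0) {
  stopifnot(inherits(panel, "snp_panel"), n >= 0, rho >= 0, rho < 1)
  if (nrow(panel) == 0) stop("panel must be nonempty")
  dos <- withr::with_seed(seed, .sim_geno(panel, as.integer(n), rho, miss_rate))
  new_genotype_matrix(dos, panel, sprintf("S%05d", seq_len(n)))
}

.sim_pheno <- function(G, cfg) {
  panel <- G$panel
  dos <- G$dosages
  n <- nrow(dos)
  # centre dosages at their expectation 2*maf so the liability has mean ~0
  gc <- sweep(dos, 2, 2 * panel$maf)
  genetic <- as.vector(gc %*% panel$gamma_true)
  C <- stats::rnorm(n, 0, cfg$confounder_sd)
  raw <- genetic + cfg$confounder_effect_x * C
  v_raw <- if (n > 1) stats::var(raw) else 0
  if (v_raw >= 1)
    stop("systematic liability variance >= 1; reduce gamma_true or confounding")
  liab <- raw + stats::rnorm(n, 0, sqrt(1 - v_raw))
  x_bin <- as.integer(liab > stats::qnorm(1 - cfg$prevalence_k))
  direct <- as.vector(dos %*% panel$alpha_true)
  mu0 <- cfg$outcome_mean - sum(panel$alpha_true * 2 * panel$maf)
  y <- mu0 + cfg$causal_beta * liab + direct +
    cfg$confounder_effect_y * C + stats::rnorm(n, 0, cfg$noise_sd_y)
  if (cfg$clip_outcome)
    y <- pmin(pmax(y, cfg$outcome_floor), cfg$outcome_ceiling)
  if (cfg$round_outcome) y <- round(y)
  age <- round(stats::rnorm(n, 55, 10))
  sex <- stats::rbinom(n, 1, 0.5)
  edu <- sample(0:4, n, replace = TRUE,
                prob = c(0.05, 0.15, 0.35, 0.30, 0.15))
  structure(data.frame(sample_id = G$sample_ids,
                       exposure_binary = x_bin,
                       exposure_liability = liab,
                       outcome = y, age = age, sex = sex, education = edu,
                       confounder = C,
                       stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

#' Simulate liability-threshold phenotypes
#'
#' Generates the exposure and outcome of a cohort from its genotypes.  The
#' latent exposure liability is
#' `L = sum_j gamma_j (G_j - 2 maf_j) + c_x C + eps_x`, with the residual
#' scaled so that `Var(L) = 1`; the binary exposure indicates
#' `L > qnorm(1 - prevalence_k)`.  The outcome is
#' `mu0 + causal_beta L + sum_j alpha_j G_j + c_y C + noise`, optionally
#' clipped to its bounds and rounded (both off by default because they
#' break the exact linear identities used by estimator tests).  The latent
#' liability is retained in the output for oracle tests.
#'
#' Note: phenotype randomness is driven by `cfg$seed`.  Use a seed
#' different from the genotype seed (or [simulate_cohort()], which manages
#' one stream for both) to keep the two draws independent.
#'
#' @param G a `genotype_matrix`.
#' @param cfg a [cohort_config()].
#' @return A `phenotype_table` data.frame.
#' @export
simulate_phenotypes <- function(G, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "cohort_config"))
  if (nrow(G$dosages) == 0) stop("genotype matrix has no individuals")
  withr::with_seed(cfg$seed, .sim_pheno(G, cfg))
}

#' Simulate a full cohort (genotypes + phenotypes) from one seed
#'
#' Draws genotypes and phenotypes from a single RNG stream seeded by
#' `cfg$seed`, so one integer reproduces the whole cohort.
#'
#' @param panel a `snp_panel`.
#' @param cfg a [cohort_config()].
#' @return `list(genotypes = genotype_matrix, phenotypes = phenotype_table)`.
#' @export
simulate_cohort <- function(panel, cfg) {
  withr::with_seed(cfg$seed, {
    dos <- .sim_geno(panel, cfg$n_individuals, cfg$within_block_rho,
                     cfg$miss_rate)
    G <- new_genotype_matrix(dos, panel,
                             sprintf("S%05d", seq_len(cfg$n_individuals)))
    ph <- .sim_pheno(G, cfg)
    list(genotypes = G, phenotypes = ph)
  })
}

# fast vectorised per-SNP OLS, complete dosage matrix, no covariates
.ols_scan <- function(dos, y) {
  n <- nrow(dos)
  yc <- y - mean(y)
  cm <- colMeans(dos)
  sxx <- colSums(dos * dos) - n * cm^2
  sxy <- as.vector(crossprod(dos, yc))
  beta <- sxy / sxx
  syy <- sum(yc^2)
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  list(beta = beta, se = se, sxx = sxx)
}

#' Per-SNP GWAS summary statistics
#'
#' Runs one single-SNP regression of the trait on each dosage column
#' (plus covariates if given) and returns one summary record per SNP:
#' effect and other allele, effect-allele frequency from the non-missing
#' dosages, beta, SE, two-sided p under the normal approximation, and the
#' per-SNP sample size after casewise deletion of missing dosages.
#' Monomorphic SNPs and exact fits are flagged `degenerate` and are meant
#' to be excluded downstream.
#'
#' @param G a `genotype_matrix`.
#' @param trait numeric trait vector of length `nrow(G$dosages)`; for
#'   `family = "logistic"` a 0/1 vector.
#' @param covariates optional data.frame of covariate columns.
#' @param family `"linear"` (default; also the linear-probability model for
#'   a binary trait) or `"logistic"`.
#' @param trait_label free-text label stored in each record.
#' @return A data.frame of class `summary_stats` with columns `snp_id`,
#'   `chrom`, `pos_bp`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`, `trait_label`, `degenerate`.
#' @export
gwas_summary <- function(G, trait, covariates = NULL,
                         family = c("linear", "logistic"),
                         trait_label = "trait") {
  family <- match.arg(family)
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  n_all <- nrow(dos)
  if (length(trait) != n_all)
    stop("trait length (", length(trait), ") does not match cohort size (",
         n_all, ")")
  panel <- G$panel
  m <- ncol(dos)
  beta <- se <- pval <- eaf <- rep(NA_real_, m)
  nn <- integer(m)
  degen <- logical(m)

  fast <- family == "linear" && is.null(covariates) && !anyNA(dos)
  if (fast) {
    sc <- .ols_scan(dos, trait)
    beta <- sc$beta; se <- sc$se
    nn <- rep(n_all, m)
    eaf <- colMeans(dos) / 2
    degen <- sc$sxx <= 0 | !is.finite(se) | se == 0
  } else {
    cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
    for (j in seq_len(m)) {
      g <- dos[, j]
      ok <- !is.na(g) & !is.na(trait)
      if (!is.null(cov_df)) ok <- ok & stats::complete.cases(cov_df)
      nj <- sum(ok)
      nn[j] <- nj
      if (nj < 3 || stats::var(g[ok]) == 0) { degen[j] <- TRUE; next }
      eaf[j] <- mean(g[ok]) / 2
      dat <- data.frame(.y = trait[ok], .g = g[ok])
      if (!is.null(cov_df)) dat <- cbind(dat, cov_df[ok, , drop = FALSE])
      if (family == "linear") {
        fit <- stats::lm(.y ~ ., data = dat)
        cf <- summary(fit)$coefficients
      } else {
        fit <- suppressWarnings(
          stats::glm(.y ~ ., data = dat, family = stats::binomial()))
        if (!fit$converged) { degen[j] <- TRUE; next }
        cf <- summary(fit)$coefficients
      }
      beta[j] <- cf[".g", 1]; se[j] <- cf[".g", 2]
      if (!is.finite(se[j]) || se[j] == 0) degen[j] <- TRUE
    }
  }
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  pval[degen] <- ifelse(is.finite(beta[degen]) & se[degen] == 0, 0,
                        NA_real_)
  out <- data.frame(snp_id = panel$snp_id, chrom = panel$chrom,
                    pos_bp = panel$pos_bp,
                    effect_allele = panel$effect_allele,
                    other_allele = panel$other_allele,
                    eaf = eaf, beta = beta, se = se, pval = pval, n = nn,
                    trait_label = trait_label, degenerate = degen,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Simulate a two-sample MR study
#'
#' Generates two independent cohorts from the same SNP panel: exposure
#' associations are estimated in cohort A only, outcome associations in
#' cohort B only, mirroring a two-sample design with the exposure GWAS
#' from an external database and the outcome GWAS from a biobank.  Both
#' configs must share `causal_beta` and must use different seeds (a shared
#' seed would make the two "samples" the same draw and violate two-sample
#' independence).
#'
#' @param panel a `snp_panel`.
#' @param cfg_exposure,cfg_outcome [cohort_config()]s for the two cohorts.
#' @param exposure_scale regress the exposure GWAS on the continuous
#'   liability (default; the scale on which `causal_beta` acts, so the
#'   ratio estimand is exactly `causal_beta`) or on the binary exposure
#'   indicator (attenuated; see the methods vignette).
#' @return list with elements `exposure_stats`, `outcome_stats` (both
#'   `summary_stats`), and `truth` (causal_beta, per-SNP true effects, the
#'   two seeds).
#' @export
simulate_two_sample_study <- function(panel, cfg_exposure, cfg_outcome,
                                      exposure_scale = c("liability",
                                                         "binary")) {
  exposure_scale <- match.arg(exposure_scale)
  if (cfg_exposure$seed == cfg_outcome$seed)
    stop("exposure and outcome cohorts must use different seeds ",
         "(a shared seed violates two-sample independence)")
  if (!isTRUE(all.equal(cfg_exposure$causal_beta, cfg_outcome$causal_beta)))
    stop("both cohort configs must share causal_beta")
  a <- simulate_cohort(panel, cfg_exposure)
  b <- simulate_cohort(panel, cfg_outcome)
  x <- if (exposure_scale == "liability") a$phenotypes$exposure_liability
       else a$phenotypes$exposure_binary
  exp_stats <- gwas_summary(a$genotypes, x, trait_label = "exposure")
  out_stats <- gwas_summary(b$genotypes, b$phenotypes$outcome,
                            trait_label = "outcome")
  list(exposure_stats = exp_stats, outcome_stats = out_stats,
       truth = list(causal_beta = cfg_exposure$causal_beta,
                    gamma_true = stats::setNames(panel$gamma_true,
                                                 panel$snp_id),
                    alpha_true = stats::setNames(panel$alpha_true,
                                                 panel$snp_id),
                    seed_exposure = cfg_exposure$seed,
                    seed_outcome = cfg_outcome$seed))
}
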