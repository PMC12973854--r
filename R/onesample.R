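#' Fit polygenic-score instrument weights
#'
#' One joint multiple regression of the exposure on all SNP dosages; the
#' PRS weights are the joint coefficients.  The default `"linear"` family
#' is the linear-probability model for a binary exposure, which keeps the
#' additive PRS formula and two-stage least squares internally consistent;
#' logistic regression is offered for exploration (its coefficients live
#' on the log-odds scale and the fitted score is no longer a linear
#' instrument).
#'
#' @param G a `genotype_matrix` (missing dosages are mean-imputed per SNP,
#'   with a message).
#' @param exposure numeric exposure vector, no missing values.
#' @param family `"linear"` (default) or `"logistic"`.
#' @return list of class `prs_weights`: named `weights`, `intercept`, fit
#'   metadata (`n`, `r2`, `family`).
#' @export
fit_instrument_weights <- function(G, exposure,
                                   family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (anyNA(exposure)) stop("exposure must have no missing values")
  X <- .impute_dosages(G$dosages)
  if (nrow(X) != length(exposure))
    stop("exposure length does not match cohort size")
  if (ncol(X) >= nrow(X)) stop("need more individuals than SNPs")
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    piv <- qx$pivot[seq_len(qx$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), piv) - 1L
    # report the dropped columns and any column they alias
    cand <- colnames(X)[dropped]
    aliases <- unique(unlist(lapply(dropped, function(d) {
      cors <- suppressWarnings(stats::cor(X[, d], X))
      colnames(X)[which(abs(cors - 1) < 1e-12 | abs(cors + 1) < 1e-12)]
    })))
    stop("exactly collinear dosage columns: ",
         paste(unique(c(cand, aliases)), collapse = ", "))
  }
  if (family == "linear") {
    fit <- stats::lm(exposure ~ X)
    r2 <- summary(fit)$r.squared
  } else {
    fit <- stats::glm(exposure ~ X, family = stats::binomial())
    r2 <- 1 - fit$deviance / fit$null.deviance
  }
  cf <- stats::coef(fit)
  structure(list(weights = stats::setNames(cf[-1], colnames(X)),
                 intercept = unname(cf[1]),
                 n = nrow(X), r2 = r2, family = family),
            class = "prs_weights")
}

.impute_dosages <- function(dos) {
  if (anyNA(dos)) {
    nmiss <- sum(is.na(dos))
    cm <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- cm[idx[, 2]]
    message("mean-imputed ", nmiss, " missing dosage(s)")
  }
  dos
}

#' Compute per-individual polygenic risk scores
#'
#' `PRS_i = sum_j weight_j G_ij` over the weighted SNPs (no intercept, per
#' the standard PRS definition).  Missing dosages are mean-imputed per SNP
#' with a message.  When `rounding_dp` is set, each score is rounded
#' half-even to that many decimals -- an option retained because some
#' workflows carry the fitted score at limited precision (four decimals is
#' customary).
#'
#' @param G a `genotype_matrix`.
#' @param weights a `prs_weights` object or a named numeric vector.
#' @param rounding_dp optional integer number of decimals.
#' @return numeric vector of scores, one per individual.
#' @export
compute_prs <- function(G, weights, rounding_dp = NULL) {
  w <- if (inherits(weights, "prs_weights")) weights$weights else weights
  missing <- setdiff(names(w), colnames(G$dosages))
  if (length(missing))
    stop("weight(s) for SNP(s) absent from genotypes: ",
         paste(missing, collapse = ", "))
  X <- .impute_dosages(G$dosages[, names(w), drop = FALSE])
  prs <- as.vector(X %*% w)
  if (!is.null(rounding_dp)) prs <- round(prs, rounding_dp)
  stats::setNames(prs, G$sample_ids)
}

#' Two-stage least squares with a PRS instrument
#'
#' Stage 1 regresses the exposure jointly on all SNP dosages and forms the
#' fitted PRS; stage 2 regresses the outcome on that single fitted score.
#' The stage-2 slope is the causal estimate.  Two standard errors are
#' computed: `naive` (the stage-2 OLS standard error, mirroring the
#' manual regress-on-the-fitted-score procedure) and `iv_robust` (the
#' conventional just-identified IV sandwich using exposure residuals).
#' Both are stored; `se_mode` picks the headline.  Instrument strength is
#' summarised by the F-statistic of the exposure-on-PRS regression, with
#' `weak_instrument = (F < 10)`.
#'
#' @param G a `genotype_matrix`.
#' @param exposure,outcome numeric vectors; rows with missing values are
#'   dropped casewise (with a message).
#' @param family_stage1 stage-1 family, see [fit_instrument_weights()].
#' @param se_mode `"naive"` (default) or `"iv_robust"`.
#' @param rounding_dp optional decimals at which the fitted PRS is carried
#'   into stage 2.
#' @return list with `estimate` (an [mr_estimate()], method `"prs_2sls"`,
#'   flags holding both SEs) and `stage1` (fitted PRS, F-statistic,
#'   `weak_instrument` flag, the stage-1 weights).
#' @export
two_stage_ls <- function(G, exposure, outcome,
                         family_stage1 = c("linear", "logistic"),
                         se_mode = c("naive", "iv_robust"),
                         rounding_dp = NULL) {
  family_stage1 <- match.arg(family_stage1)
  se_mode <- match.arg(se_mode)
  ok <- !is.na(exposure) & !is.na(outcome)
  if (!all(ok)) {
    message("dropped ", sum(!ok), " incomplete case(s)")
    G <- subset_genotypes(G, rows = which(ok))
    exposure <- exposure[ok]; outcome <- outcome[ok]
  }
  w <- fit_instrument_weights(G, exposure, family = family_stage1)
  prs <- compute_prs(G, w, rounding_dp = rounding_dp)
  if (stats::var(prs) == 0) stop("instrument has no variation")
  n <- length(prs)

  s2 <- stats::lm(outcome ~ prs)
  cf <- summary(s2)$coefficients
  beta <- cf["prs", 1]
  se_naive <- cf["prs", 2]

  # just-identified IV sandwich: residuals from the *structural* equation
  zc <- prs - mean(prs); xc <- exposure - mean(exposure)
  a_iv <- mean(outcome) - beta * mean(exposure)
  u <- outcome - a_iv - beta * exposure
  denom <- sum(zc * xc)
  se_robust <- sqrt(sum(zc^2 * u^2)) / abs(denom)

  s1 <- stats::lm(exposure ~ prs)
  fs <- summary(s1)$fstatistic
  f_stat <- if (is.null(fs)) Inf else unname(fs[1])
  degen <- !is.finite(f_stat) ||
    summary(s1)$sigma < sqrt(.Machine$double.eps)
  if (degen) f_stat <- Inf

  se <- if (se_mode == "naive") se_naive else se_robust
  est <- mr_estimate("prs_2sls", beta, se, k = n,
                     flags = list(se_naive = se_naive,
                                  se_iv_robust = se_robust,
                                  se_mode = se_mode,
                                  weak_instrument = f_stat < 10,
                                  degenerate_stage1 = degen))
  stage1 <- structure(list(fitted_prs = prs, f_statistic = f_stat,
                           weak_instrument = f_stat < 10,
                           rounding_dp = rounding_dp, weights = w),
                      class = "stage1_fit")
  list(estimate = est, stage1 = stage1)
}

#' Subset a genotype matrix
#'
#' @param G a `genotype_matrix`.
#' @param rows individual indices (or logical mask) to keep.
#' @param snps SNP ids to keep.
#' @return the subset `genotype_matrix`.
#' @export
subset_genotypes <- function(G, rows = NULL, snps = NULL) {
  dos <- G$dosages; panel <- G$panel; ids <- G$sample_ids
  if (!is.null(rows)) { dos <- dos[rows, , drop = FALSE]; ids <- ids[rows] }
  if (!is.null(snps)) {
    j <- match(snps, panel$snp_id)
    if (anyNA(j)) stop("unknown SNP id(s): ",
                       paste(snps[is.na(j)], collapse = ", "))
    dos <- dos[, j, drop = FALSE]
    panel <- panel[j, , drop = FALSE]
  }
  new_genotype_matrix(dos, panel, ids)
}

#' Instrument-strength F-statistic
#'
#' F from the regression of the exposure on the single fitted PRS (one
#' numerator degree of freedom); for a single regressor F equals the
#' squared t of the slope.  `F < 10` (strict) is the conventional weak
#' instrument criterion.
#'
#' @param prs fitted per-individual score.
#' @param exposure exposure vector.
#' @return list: `f_statistic`, `weak_instrument`, `pval`.
#' @export
instrument_f <- function(prs, exposure) {
  fit <- stats::lm(exposure ~ prs)
  sm <- summary(fit)
  fs <- sm$fstatistic
  f <- if (is.null(fs)) Inf else unname(fs[1])
  p <- if (is.null(fs)) 0 else
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  list(f_statistic = f, weak_instrument = f < 10, pval = p)
}

.assign_tertiles <- function(prs) {
  n <- length(prs)
  # order-statistic assignment, ties broken by original index: group sizes
  # differ by at most one and the split is deterministic
  ord <- order(prs, seq_len(n))
  sizes <- rep(n %/% 3, 3) + c(n %% 3 >= 1, n %% 3 >= 2, FALSE)
  grp <- integer(n)
  grp[ord] <- rep(1:3, times = sizes)
  grp
}

#' PRS-tertile descriptive table
#'
#' Splits the cohort into PRS tertiles (empirical thirds; ties broken
#' deterministically toward the lower group) and compares variables across
#' groups: one-way ANOVA for continuous variables, Pearson chi-squared for
#' discrete ones, a linear-regression trend test on the tertile index for
#' continuous variables and the Cochran-Armitage trend test for binary
#' ones.  A constant variable is reported with `NA` p-values.
#'
#' @param prs per-individual scores.
#' @param phenotypes a data.frame with the variables.
#' @param continuous_vars,discrete_vars column names to compare.
#' @return list of class `tertile_table`: `tertile` assignment, per-group
#'   `n`, `continuous` and `discrete` summary data.frames.
#' @export
tertile_descriptives <- function(prs, phenotypes,
                                 continuous_vars = character(0),
                                 discrete_vars = character(0)) {
  n <- length(prs)
  if (n < 3) stop("need at least 3 individuals")
  grp <- .assign_tertiles(prs)
  gf <- factor(grp, levels = 1:3)
  cont <- lapply(continuous_vars, function(v) {
    x <- phenotypes[[v]]
    means <- tapply(x, gf, mean)
    sds <- tapply(x, gf, stats::sd)
    if (stats::var(x) == 0) {
      p_an <- NA_real_; p_tr <- NA_real_
    } else {
      p_an <- stats::anova(stats::lm(x ~ gf))[["Pr(>F)"]][1]
      p_tr <- summary(stats::lm(x ~ grp))$coefficients["grp", 4]
    }
    data.frame(variable = v,
               mean_t1 = means[1], sd_t1 = sds[1],
               mean_t2 = means[2], sd_t2 = sds[2],
               mean_t3 = means[3], sd_t3 = sds[3],
               p_anova = p_an, p_trend = p_tr, stringsAsFactors = FALSE)
  })
  disc <- lapply(discrete_vars, function(v) {
    x <- phenotypes[[v]]
    tab <- table(x, gf)
    if (length(unique(x)) < 2) {
      p_chi <- NA_real_; p_tr <- NA_real_
    } else {
      p_chi <- suppressWarnings(stats::chisq.test(tab)$p.value)
      p_tr <- if (length(unique(x)) == 2)
        cochran_armitage(as.matrix(tab))$p.value
      else summary(stats::lm(as.numeric(x) ~ grp))$coefficients["grp", 4]
    }
    counts <- apply(tab, 2, paste, collapse = "/")
    data.frame(variable = v,
               counts_t1 = counts[1], counts_t2 = counts[2],
               counts_t3 = counts[3],
               p_chisq = p_chi, p_trend = p_tr, stringsAsFactors = FALSE)
  })
  bindf <- function(l) if (length(l))
    do.call(rbind, c(l, list(make.row.names = FALSE))) else NULL
  structure(list(tertile = grp, n = as.vector(table(gf)),
                 continuous = bindf(cont), discrete = bindf(disc)),
            class = "tertile_table")
}

#' @export
print.tertile_table <- function(x, ...) {
  cat("<tertile_table> group sizes:", paste(x$n, collapse = ", "), "\n")
  if (!is.null(x$continuous) && nrow(x$continuous)) {
    cat("continuous:\n"); print(x$continuous)
  }
  if (!is.null(x$discrete) && nrow(x$discrete)) {
    cat("discrete:\n"); print(x$discrete)
  }
  invisible(x)
}

#' Cochran-Armitage trend test
#'
#' Trend in binomial proportions across ordered groups.  With cases
#' `r_i`, group totals `n_i`, overall proportion `p`, and scores `s_i`:
#' `T = sum s_i (r_i - n_i p)`,
#' `V = p (1 - p) (sum n_i s_i^2 - (sum n_i s_i)^2 / N)`, and
#' `Z = T / sqrt(V)` with a two-sided normal p-value.  `Z^2` is invariant
#' to affine rescaling of the scores.  Columns with zero total are dropped
#' with a message.
#'
#' @param counts a 2 x k matrix: row 1 cases, row 2 controls.
#' @param scores column scores, default `0:(k-1)`.
#' @return list: `statistic` (Z), `p.value`.
#' @export
cochran_armitage <- function(counts, scores = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2)
    stop("counts must be a 2 x k matrix with k >= 2")
  if (is.null(scores)) scores <- seq_len(ncol(counts)) - 1
  tot <- colSums(counts)
  if (any(tot == 0)) {
    message("dropping ", sum(tot == 0), " zero-total column(s)")
    keep <- tot > 0
    counts <- counts[, keep, drop = FALSE]
    scores <- scores[keep]
    tot <- tot[keep]
  }
  if (any(rowSums(counts) <= 0)) stop("row sums must be > 0")
  r <- counts[1, ]; N <- sum(tot); R <- sum(r); pbar <- R / N
  T_ <- sum(scores * (r - tot * pbar))
  V <- pbar * (1 - pbar) * (sum(tot * scores^2) - sum(tot * scores)^2 / N)
  z <- T_ / sqrt(V)
  list(statistic = z, p.value = 2 * stats::pnorm(-abs(z)))
}
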