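#' Per-SNP Wald ratio estimates
#'
#' For each harmonized instrument the per-SNP causal estimate is the ratio
#' of the outcome to the exposure association, `beta_j = Gamma_j /
#' gamma_j`, with first-order delta-method standard error `se(Gamma_j) /
#' |gamma_j|` and inverse-variance weight `w_j = 1 / se_j^2`.  A
#' second-order delta correction (adding the term in `se(gamma_j)`) is
#' available behind a flag.  SNPs with a zero exposure association are
#' excluded with reason code `"zero exposure association"` rather than
#' silently kept.
#'
#' @param iset an `instrument_set`.
#' @param second_order use the second-order delta SE? Default `FALSE`.
#' @return data.frame of class `ratio_estimates`: `snp_id`, `ratio_beta`,
#'   `ratio_se`, `weight`; excluded SNPs in attribute `"excluded"`.
#' @export
wald_ratios <- function(iset, second_order = FALSE) {
  stopifnot(all(iset$se_gamma > 0), all(iset$se_big_gamma > 0))
  zero <- iset$gamma == 0
  excluded <- data.frame(snp_id = iset$snp_id[zero],
                         reason = rep("zero exposure association",
                                      sum(zero)),
                         stringsAsFactors = FALSE)
  if (any(zero)) {
    message("excluded ", sum(zero), " SNP(s) with zero exposure association")
    iset <- iset[!zero, , drop = FALSE]
  }
  se <- iset$se_big_gamma / abs(iset$gamma)
  if (second_order)
    se <- sqrt(se^2 + iset$big_gamma^2 * iset$se_gamma^2 / iset$gamma^4)
  out <- data.frame(snp_id = iset$snp_id,
                    ratio_beta = iset$big_gamma / iset$gamma,
                    ratio_se = se, weight = 1 / se^2,
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_estimates", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' Inverse-variance weighted estimator
#'
#' `beta = sum(w_j beta_j) / sum(w_j)` over the per-SNP Wald ratios with
#' precision weights.  Fixed-effect SE is `(sum w_j)^(-1/2)`;
#' `"multiplicative_random"` scales it by `max(1, sqrt(Q / (k - 1)))`
#' where `Q = sum w_j (beta_j - beta)^2` is Cochran's heterogeneity
#' statistic (never shrinking below the fixed-effect SE).  The p-value is
#' two-sided normal.
#'
#' @param ratios a `ratio_estimates` data.frame.
#' @param model `"fixed"` (default) or `"multiplicative_random"`.
#' @return an [mr_estimate()] with `Q` in its flags.
#' @export
mr_ivw <- function(ratios, model = c("fixed", "multiplicative_random")) {
  model <- match.arg(model)
  k <- nrow(ratios)
  if (k < 1) stop("need at least 1 SNP")
  if (model == "multiplicative_random" && k < 2)
    stop("multiplicative random effects needs at least 2 SNPs")
  w <- ratios$weight; b <- ratios$ratio_beta
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (b - beta)^2)
  if (model == "multiplicative_random")
    se <- se * max(1, sqrt(Q / (k - 1)))
  mr_estimate(paste0("ivw_", if (model == "fixed") "fixed" else "random"),
              beta, se, k, flags = list(Q = Q))
}

#' I2GX weak-instrument diagnostic for MR-Egger
#'
#' Quantifies regression dilution (violation of the no-measurement-error
#' assumption) in MR-Egger.  With precision `v_j = 1 / se(gamma_j)^2`,
#' weighted mean `gbar`, and `Q_GX = sum v_j (g_j - gbar)^2` computed on
#' the absolute exposure associations (the scale MR-Egger uses after sign
#' orientation): `I2GX = max(0, (Q_GX - (k - 1)) / Q_GX)`.  Values below
#' 0.90 indicate more than ~10% relative bias in the Egger slope, which
#' this package treats as invalidating the estimator.
#'
#' @param iset an `instrument_set` (or any data.frame with `gamma`,
#'   `se_gamma`).
#' @return I2GX in \[0, 1\].
#' @export
i2_gx <- function(iset) {
  k <- nrow(iset)
  if (k < 2) stop("need at least 2 SNPs")
  g <- abs(iset$gamma)
  v <- 1 / iset$se_gamma^2
  gbar <- sum(v * g) / sum(v)
  Q <- sum(v * (g - gbar)^2)
  if (Q == 0) return(0)
  max(0, (Q - (k - 1)) / Q)
}

#' MR-Egger regression
#'
#' Orients every SNP so its exposure association is non-negative (flipping
#' both association signs together leaves the science unchanged), then
#' fits a weighted linear regression of the outcome associations on the
#' exposure associations with a free intercept and weights
#' `1 / se(Gamma_j)^2`.  The slope is the causal estimate; the intercept
#' estimates average directional pleiotropy.  Standard errors use
#' multiplicative random effects with no underdispersion (residual scale
#' bounded below by 1).  The estimate is gated by [i2_gx()]: when
#' `I2GX < 0.90` the result is still returned but flagged invalid and is
#' excluded from headline reporting.
#'
#' @param iset an `instrument_set`.
#' @return list of class `egger_result`: `slope` ([mr_estimate()]),
#'   `intercept` (est/se/p), `i2_gx`, `valid`.
#' @export
mr_egger <- function(iset) {
  k <- nrow(iset)
  if (k < 3) stop("MR-Egger needs at least 3 SNPs")
  s <- ifelse(iset$gamma < 0, -1, 1)
  g <- iset$gamma * s
  G <- iset$big_gamma * s
  if (length(unique(g)) < 2)
    stop("exposure associations are constant after orientation; ",
         "the Egger slope is not identifiable")
  w <- 1 / iset$se_big_gamma^2
  fit <- stats::lm(G ~ g, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  # no-underdispersion multiplicative model; exact fits keep the OLS scale
  scale <- if (sigma < sqrt(.Machine$double.eps)) 1 else max(1, sigma) / sigma
  slope <- sm$coefficients["g", 1]
  se_slope <- sm$coefficients["g", 2] * scale
  int <- sm$coefficients["(Intercept)", 1]
  se_int <- sm$coefficients["(Intercept)", 2] * scale
  i2 <- i2_gx(iset)
  valid <- i2 >= 0.90
  est <- mr_estimate("mr_egger", slope, se_slope, k,
                     flags = list(i2_gx = i2, valid = valid))
  structure(list(slope = est,
                 intercept = list(estimate = int, se = se_int,
                                  pval = 2 * stats::pnorm(-abs(int / se_int))),
                 i2_gx = i2, valid = valid),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4f (SE %.4f, p = %.3g); I2GX = %.3f (%s)\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pval,
              x$i2_gx, if (x$valid) "valid" else "invalid: I2GX < 0.90"))
  invisible(x)
}

# weighted median of beta at cumulative weight 0.5
.weighted_median <- function(beta, w) {
  ord <- order(beta)
  b <- beta[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(b[1])
  k <- length(b)
  if (0.5 >= s[k]) return(b[k])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' The 50% point of the inverse-variance-weight-ordered Wald ratios:
#' consistent as long as valid instruments carry more than half of the
#' total weight, which makes it robust to a minority of pleiotropic SNPs.
#' The standard error is the standard deviation of the estimate over
#' `n_boot` parametric-bootstrap replicates, redrawing each association
#' from a normal centred on its estimate with its own SE.
#'
#' @param ratios a `ratio_estimates` data.frame.
#' @param iset the `instrument_set` the ratios came from (needed to
#'   redraw the underlying associations in the bootstrap).
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed for the bootstrap.
#' @return an [mr_estimate()], method `"weighted_median"`.
#' @export
weighted_median_mr <- function(ratios, iset, n_boot = 1000, seed = 1L) {
  k <- nrow(ratios)
  if (k < 3) stop("weighted median needs at least 3 SNPs")
  est <- .weighted_median(ratios$ratio_beta, ratios$weight)
  ii <- iset[match(ratios$snp_id, iset$snp_id), , drop = FALSE]
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      gs <- stats::rnorm(k, ii$gamma, ii$se_gamma)
      Gs <- stats::rnorm(k, ii$big_gamma, ii$se_big_gamma)
      ok <- gs != 0
      bs <- Gs[ok] / gs[ok]
      ws <- (gs[ok] / ii$se_big_gamma[ok])^2
      .weighted_median(bs, ws)
    }, numeric(1))
  })
  mr_estimate("weighted_median", est, stats::sd(boots), k,
              flags = list(n_boot = n_boot, seed = seed))
}

#' Funnel-plot outlier detection
#'
#' An outlier SNP is one whose Wald ratio lies more than three
#' interquartile ranges below the first or above the third quartile of the
#' per-SNP ratios.  Quartiles use the common interpolation-of-order-
#' statistics sample-quantile definition (R's default, type 7).  With
#' fewer than 5 SNPs the rule is reported as not applicable.
#'
#' @param ratios a `ratio_estimates` data.frame.
#' @return list: `applicable`, `outliers` (snp ids), `fences` (low, high).
#' @export
funnel_outliers <- function(ratios) {
  k <- nrow(ratios)
  if (k < 5)
    return(list(applicable = FALSE, outliers = character(0),
                fences = c(NA_real_, NA_real_)))
  b <- ratios$ratio_beta
  q <- stats::quantile(b, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 3 * iqr, q[2] + 3 * iqr)
  out <- ratios$snp_id[b < fences[1] | b > fences[2]]
  list(applicable = TRUE, outliers = out, fences = fences)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect k times, each excluding one SNP, and
#' flags any exclusion that moves the estimate outside the full-set 95%
#' confidence interval.
#'
#' @param iset an `instrument_set`.
#' @param estimator `"ivw"` (default) or `"weighted_median"`.
#' @param model IVW heterogeneity model passed to [mr_ivw()].
#' @param n_boot,seed weighted-median bootstrap settings.
#' @return data.frame: `excluded_snp`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `outside_full_ci`; the full-set estimate in attribute `"full"`.
#' @export
leave_one_out <- function(iset, estimator = c("ivw", "weighted_median"),
                          model = "fixed", n_boot = 200, seed = 1L) {
  estimator <- match.arg(estimator)
  k <- nrow(iset)
  if (estimator == "ivw" && k < 2) stop("leave-one-out IVW needs k >= 2")
  if (estimator == "weighted_median" && k < 4)
    stop("leave-one-out weighted median needs k >= 4")
  fit1 <- function(ss, sd) {
    r <- wald_ratios(ss)
    if (estimator == "ivw") mr_ivw(r, model = model)
    else weighted_median_mr(r, ss, n_boot = n_boot, seed = sd)
  }
  full <- fit1(iset, seed)
  rows <- lapply(seq_len(k), function(i) {
    e <- fit1(iset[-i, , drop = FALSE], seed)
    data.frame(excluded_snp = iset$snp_id[i], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high,
               outside_full_ci = e$beta < full$ci_low |
                 e$beta > full$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Full summary-MR report
#'
#' Runs the whole Strategy-2/3 analysis over a harmonized instrument set:
#' Wald ratios, IVW (fixed and multiplicative-random), MR-Egger with the
#' I2GX gate, the weighted median, funnel-plot outlier detection with an
#' optional re-run excluding outliers, and leave-one-out IVW.  Estimates
#' are reported on both the beta and the exponentiated (odds-ratio)
#' scale.
#'
#' @param iset an `instrument_set`.
#' @param exclude_outliers re-run the estimators without funnel outliers?
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed integer seed (bootstrap only; everything else is
#'   deterministic).
#' @return list of class `mr_report`; see Details for components.
#' @details Components: `ratios`, `estimates` (named list of
#'   [mr_estimate()] / `egger_result`), `headline` (data.frame of the
#'   three headline estimators with OR columns; Egger carried but flagged
#'   when gated invalid), `outliers`, `excluding_outliers` (same shape,
#'   present when outliers were found and excluded), `leave_one_out`,
#'   `funnel` (per-SNP ratio and precision), `audit` (harmonisation +
#'   ratio exclusions), `k`.
#' @export
mr_report <- function(iset, exclude_outliers = TRUE, n_boot = 1000,
                      seed = 1L) {
  stopifnot(inherits(iset, "instrument_set") || is.data.frame(iset))
  core <- function(ss) {
    r <- wald_ratios(ss)
    est <- list(ivw_fixed = mr_ivw(r, "fixed"),
                ivw_random = mr_ivw(r, "multiplicative_random"),
                egger = mr_egger(ss[ss$snp_id %in% r$snp_id, ,
                                    drop = FALSE]),
                weighted_median = weighted_median_mr(r, ss,
                                                     n_boot = n_boot,
                                                     seed = seed))
    hl <- do.call(rbind, list(
      as.data.frame(est$ivw_fixed),
      {
        e <- as.data.frame(est$egger$slope)
        e
      },
      as.data.frame(est$weighted_median)))
    hl$valid <- c(TRUE, est$egger$valid, TRUE)
    or <- beta_to_or(hl$beta, hl$ci_low, hl$ci_high)
    hl$or <- or$or; hl$or_low <- or$or_low; hl$or_high <- or$or_high
    list(ratios = r, estimates = est, headline = hl)
  }
  base <- core(iset)
  fo <- funnel_outliers(base$ratios)
  excl <- NULL
  if (exclude_outliers && fo$applicable && length(fo$outliers)) {
    sub <- iset[!iset$snp_id %in% fo$outliers, , drop = FALSE]
    excl <- core(sub)
    excl$k <- nrow(sub)
  }
  loo <- leave_one_out(iset, "ivw", seed = seed)
  funnel <- data.frame(snp_id = base$ratios$snp_id,
                       ratio_beta = base$ratios$ratio_beta,
                       precision = 1 / base$ratios$ratio_se,
                       stringsAsFactors = FALSE)
  structure(list(ratios = base$ratios, estimates = base$estimates,
                 headline = base$headline, outliers = fo,
                 excluding_outliers = excl, leave_one_out = loo,
                 funnel = funnel,
                 audit = list(harmonisation = attr(iset, "audit"),
                              ratio_exclusions = attr(base$ratios,
                                                      "excluded")),
                 k = nrow(base$ratios), seed = seed),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> k = %d instruments\n", x$k))
  cat("headline estimators (beta scale and exponentiated):\n")
  hl <- x$headline
  hl$or <- round(hl$or, 2); hl$or_low <- round(hl$or_low, 2)
  hl$or_high <- round(hl$or_high, 2)
  print(hl, row.names = FALSE)
  if (!x$estimates$egger$valid)
    cat(sprintf("note: MR-Egger gated invalid (I2GX = %.3f < 0.90)\n",
                x$estimates$egger$i2_gx))
  if (x$outliers$applicable && length(x$outliers$outliers))
    cat("funnel outliers:", paste(x$outliers$outliers, collapse = ", "),
        "\n")
  if (!is.null(x$excluding_outliers)) {
    cat(sprintf("excluding outliers (k = %d):\n", x$excluding_outliers$k))
    print(x$excluding_outliers$headline, row.names = FALSE)
  }
  n_out <- sum(x$leave_one_out$outside_full_ci)
  cat(sprintf("leave-one-out: %d of %d exclusions move IVW outside the full-set CI\n",
              n_out, nrow(x$leave_one_out)))
  invisible(x)
}
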