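#' Construct a causal-effect estimate record
#'
#' The common currency of every estimator in the package: a method label,
#' the point estimate, its standard error, a 95% normal-based confidence
#' interval (`beta -/+ 1.96 se`), a two-sided normal p-value, and the
#' number of SNPs (or individuals) it rests on, plus free-form validity
#' flags.
#'
#' @param method character label, e.g. `"ivw_fixed"`.
#' @param beta,se point estimate and standard error.
#' @param k number of instruments (or sample size for individual-level
#'   estimators).
#' @param flags named list of validity flags / notes.
#' @return list of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, k, flags = list()) {
  stopifnot(is.numeric(beta), is.numeric(se))
  ci <- beta + c(-1, 1) * 1.96 * se
  p <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(beta / se))
       else NA_real_
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci[1], ci_high = ci[2], pval = p, k = k,
                 flags = flags),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, k = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval,
              as.integer(x$k)))
  if (length(x$flags))
    cat("  flags:", paste(names(x$flags), unlist(lapply(x$flags, format)),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             k = as.integer(x$k), stringsAsFactors = FALSE)
}

#' Convert a log-scale estimate to an odds-ratio scale
#'
#' Componentwise exponentiation of a beta and its confidence bounds.  The
#' arithmetic is exact; whether an OR reading is meaningful for a
#' continuous-outcome beta is left to the analyst.
#'
#' @param beta point estimate on the log scale.
#' @param ci_low,ci_high confidence bounds on the log scale.
#' @return named list `or`, `or_low`, `or_high`.
#' @export
beta_to_or <- function(beta, ci_low = NA_real_, ci_high = NA_real_) {
  list(or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high))
}
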