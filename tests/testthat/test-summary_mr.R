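test_that("Wald ratios follow the delta-method formula and carry signs", {
  iset <- make_iset(gamma = c(0.1, -0.1), se_gamma = c(0.01, 0.01),
                    big_gamma = c(0.24, 0.24), se_big_gamma = c(0.05, 0.05))
  r <- wald_ratios(iset)
  expect_equal(r$ratio_beta, c(2.4, -2.4))
  expect_equal(r$ratio_se, c(0.5, 0.5))
  expect_equal(r$weight, c(4, 4))
})

test_that("a zero exposure association is excluded with a reason, not kept", {
  iset <- make_iset(gamma = c(0.1, 0, 0.2), se_gamma = rep(0.01, 3),
                    big_gamma = c(0.2, 0.3, 0.4), se_big_gamma = rep(0.05, 3))
  expect_message(r <- wald_ratios(iset), "zero exposure")
  expect_equal(nrow(r), 2L)
  excl <- attr(r, "excluded")
  expect_equal(excl$snp_id, "rs002")
  expect_equal(excl$reason, "zero exposure association")
})

test_that("IVW reduces to known closed forms", {
  r2 <- wald_ratios(make_iset(gamma = c(1, 1), se_gamma = c(0.1, 0.1),
                              big_gamma = c(1, 3), se_big_gamma = c(1, 1)))
  e <- mr_ivw(r2)
  expect_equal(e$beta, 2.0)
  expect_equal(e$se, 1 / sqrt(2))

  r1 <- wald_ratios(make_iset(gamma = 0.1, se_gamma = 0.01,
                              big_gamma = 0.24, se_big_gamma = 0.05))
  e1 <- mr_ivw(r1)
  expect_equal(e1$beta, 2.4)
  expect_equal(e1$se, 0.5)
  expect_error(mr_ivw(r1[0, ]), "at least 1")
})

test_that("IVW equals a weighted through-origin regression of outcome on exposure", {
  for (s in 1:50) {
    iset <- withr::with_seed(s, make_iset(
      gamma = runif(10, 0.05, 0.3) * sample(c(-1, 1), 10, TRUE),
      se_gamma = runif(10, 0.005, 0.02),
      big_gamma = rnorm(10, 0.2, 0.2),
      se_big_gamma = runif(10, 0.02, 0.1)))
    e <- mr_ivw(wald_ratios(iset))
    # independent oracle: lm through the origin with weights 1/se(Gamma)^2
    fit <- lm(big_gamma ~ 0 + gamma, data = iset,
              weights = 1 / iset$se_big_gamma^2)
    expect_equal(e$beta, unname(coef(fit)[1]), tolerance = 1e-9)
  }
})

test_that("multiplicative random effects never shrink below the fixed SE", {
  iset <- make_iset(gamma = rep(0.1, 6), se_gamma = rep(0.01, 6),
                    big_gamma = c(0.1, 0.5, 0.2, 0.9, 0.05, 0.4),
                    se_big_gamma = rep(0.02, 6))
  r <- wald_ratios(iset)
  ef <- mr_ivw(r); er <- mr_ivw(r, "multiplicative_random")
  expect_equal(ef$beta, er$beta)
  expect_gte(er$se, ef$se)
  expect_equal(er$se, ef$se * max(1, sqrt(ef$flags$Q / 5)))
})

test_that("I2GX matches the hand-computed fixture and its limits", {
  same <- make_iset(gamma = rep(0.2, 4), se_gamma = rep(0.01, 4),
                    big_gamma = rep(0.4, 4), se_big_gamma = rep(0.05, 4))
  expect_equal(i2_gx(same), 0)

  # gamma = (0.1, 0.2, 0.4), se = 0.01: v = 1e4, gbar = 7/30,
  # Q = 1e4 * (0.0177778 + 0.0011111 + 0.0277778) = 1400/3,
  # I2GX = 1 - 2/(1400/3) = 1 - 6/1400
  fx <- make_iset(gamma = c(0.1, 0.2, 0.4), se_gamma = rep(0.01, 3),
                  big_gamma = rep(0.1, 3), se_big_gamma = rep(0.05, 3))
  expect_equal(i2_gx(fx), 1 - 6 / 1400, tolerance = 1e-9)

  # shrinking se(gamma) drives I2GX monotonically toward 1
  i2s <- vapply(c(0.05, 0.02, 0.01, 0.005, 0.001), function(s)
    i2_gx(make_iset(gamma = c(0.1, 0.2, 0.4), se_gamma = rep(s, 3),
                    big_gamma = rep(0.1, 3), se_big_gamma = rep(0.05, 3))),
    numeric(1))
  expect_true(all(diff(i2s) > 0))
  expect_gt(i2s[5], 0.999)
  expect_error(i2_gx(fx[1, ]), "at least 2")
})

test_that("MR-Egger interpolates an exact line and reduces to IVW under proportionality", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  exact <- make_iset(gamma = g, se_gamma = rep(0.01, 4),
                     big_gamma = 0.1 + 2 * g,
                     se_big_gamma = c(0.05, 0.04, 0.06, 0.05))
  eg <- mr_egger(exact)
  expect_equal(eg$slope$beta, 2, tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, 0.1, tolerance = 1e-10)

  prop <- make_iset(gamma = g, se_gamma = rep(0.01, 4),
                    big_gamma = 2 * g, se_big_gamma = rep(0.05, 4))
  eg2 <- mr_egger(prop)
  expect_equal(eg2$slope$beta, 2, tolerance = 1e-10)
  expect_equal(eg2$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(mr_ivw(wald_ratios(prop))$beta, 2, tolerance = 1e-10)
  expect_error(mr_egger(exact[1:2, ]), "at least 3")
})

test_that("the I2GX gate marks low-precision exposure sets invalid but still reports", {
  noisy <- make_iset(gamma = c(0.10, 0.11, 0.12, 0.10),
                     se_gamma = rep(0.1, 4),
                     big_gamma = c(0.2, 0.25, 0.22, 0.21),
                     se_big_gamma = rep(0.05, 4))
  expect_lt(i2_gx(noisy), 0.90)
  eg <- mr_egger(noisy)
  expect_false(eg$valid)
  expect_true(is.finite(eg$slope$beta))
  expect_identical(eg$valid, eg$i2_gx >= 0.90)
})

test_that("the weighted median lands on forced values", {
  r <- wald_ratios(make_iset(gamma = rep(1, 3), se_gamma = rep(0.1, 3),
                             big_gamma = c(1, 2, 9),
                             se_big_gamma = rep(1, 3)))
  wm <- weighted_median_mr(r, make_iset(gamma = rep(1, 3),
                                        se_gamma = rep(0.1, 3),
                                        big_gamma = c(1, 2, 9),
                                        se_big_gamma = rep(1, 3)),
                           n_boot = 50, seed = 1)
  expect_equal(wm$beta, 2)

  # 60% of the weight on ratio 2, 40% scattered
  iset <- make_iset(gamma = rep(1, 5), se_gamma = rep(0.1, 5),
                    big_gamma = c(1, 2, 2, 2, 3), se_big_gamma = rep(1, 5))
  r5 <- wald_ratios(iset)
  expect_equal(weighted_median_mr(r5, iset, n_boot = 50, seed = 1)$beta, 2)
  expect_error(weighted_median_mr(r5[1:2, ], iset), "at least 3")
})

test_that("the bootstrap SE is seed-deterministic and stable across seeds", {
  iset <- make_iset(gamma = seq(0.1, 0.4, length.out = 8),
                    se_gamma = rep(0.01, 8),
                    big_gamma = 2.4 * seq(0.1, 0.4, length.out = 8),
                    se_big_gamma = rep(0.05, 8))
  r <- wald_ratios(iset)
  a <- weighted_median_mr(r, iset, n_boot = 1000, seed = 42)
  b <- weighted_median_mr(r, iset, n_boot = 1000, seed = 42)
  expect_identical(a$se, b$se)
  c_ <- weighted_median_mr(r, iset, n_boot = 1000, seed = 43)
  expect_lt(abs(a$se - c_$se) / a$se, 0.10)
})

test_that("funnel outliers follow the 3-IQR rule with interpolated quartiles", {
  iset <- make_iset(gamma = rep(1, 5), se_gamma = rep(0.1, 5),
                    big_gamma = c(1, 2, 3, 4, 100),
                    se_big_gamma = rep(1, 5))
  r <- wald_ratios(iset)
  fo <- funnel_outliers(r)
  expect_true(fo$applicable)
  expect_equal(fo$fences, c(2 - 6, 4 + 6))
  expect_equal(fo$outliers, "rs005")

  same <- wald_ratios(make_iset(gamma = rep(1, 6), se_gamma = rep(0.1, 6),
                                big_gamma = rep(2, 6),
                                se_big_gamma = rep(1, 6)))
  expect_length(funnel_outliers(same)$outliers, 0)

  expect_false(funnel_outliers(r[1:4, ])$applicable)
})

test_that("leave-one-out with two SNPs returns each other's Wald ratio", {
  iset <- make_iset(gamma = c(0.1, 0.2), se_gamma = c(0.01, 0.01),
                    big_gamma = c(0.3, 0.5), se_big_gamma = c(0.05, 0.04))
  loo <- leave_one_out(iset)
  r <- wald_ratios(iset)
  expect_equal(loo$beta[loo$excluded_snp == "rs001"], r$ratio_beta[2])
  expect_equal(loo$beta[loo$excluded_snp == "rs002"], r$ratio_beta[1])
  expect_equal(loo$se[loo$excluded_snp == "rs001"], r$ratio_se[2])
})

test_that("excluding a planted outlier moves IVW strictly toward the truth", {
  g <- seq(0.1, 0.27, length.out = 18)
  iset <- make_iset(gamma = g, se_gamma = rep(0.01, 18),
                    big_gamma = 2.4 * g, se_big_gamma = rep(0.02, 18))
  iset$big_gamma[18] <- 30 * iset$gamma[18]  # one wildly pleiotropic SNP
  full <- mr_ivw(wald_ratios(iset))
  loo <- leave_one_out(iset)
  excl <- loo$beta[loo$excluded_snp == "rs018"]
  expect_lt(abs(excl - 2.4), abs(full$beta - 2.4))
  expect_true(loo$outside_full_ci[loo$excluded_snp == "rs018"] ||
                abs(excl - full$beta) > 0)
})

test_that("no-pleiotropy synthetic sets keep every leave-one-out IVW inside the CI", {
  panel <- default_panel(18, seed = 3)
  for (s in 1:20) {
    iset <- sim_twosample_iset(panel, n = 5000, beta = 2.4,
                               seed_base = 500 + 2 * s)
    loo <- leave_one_out(iset)
    expect_false(any(loo$outside_full_ci))
  }
})

test_that("estimates are invariant to allele orientation and weight rescaling", {
  iset <- make_iset(gamma = c(0.1, -0.15, 0.2, 0.25, -0.3),
                    se_gamma = rep(0.01, 5),
                    big_gamma = c(0.2, -0.4, 0.5, 0.6, -0.7),
                    se_big_gamma = rep(0.05, 5))
  flip <- iset
  flip$gamma[c(2, 4)] <- -flip$gamma[c(2, 4)]
  flip$big_gamma[c(2, 4)] <- -flip$big_gamma[c(2, 4)]

  expect_equal(mr_ivw(wald_ratios(iset))$beta,
               mr_ivw(wald_ratios(flip))$beta)
  expect_equal(mr_ivw(wald_ratios(iset))$se,
               mr_ivw(wald_ratios(flip))$se)
  expect_equal(mr_egger(iset)$slope$beta, mr_egger(flip)$slope$beta)
  expect_equal(mr_egger(iset)$intercept$estimate,
               mr_egger(flip)$intercept$estimate)
  expect_equal(i2_gx(iset), i2_gx(flip))
  r1 <- wald_ratios(iset); r2 <- wald_ratios(flip)
  expect_equal(weighted_median_mr(r1, iset, n_boot = 10, seed = 1)$beta,
               weighted_median_mr(r2, flip, n_boot = 10, seed = 1)$beta)

  # rescaling all weights by a positive constant changes nothing
  rs <- r1; rs$weight <- rs$weight * 7.3
  expect_equal(mr_ivw(rs)$beta, mr_ivw(r1)$beta)
  expect_equal(.wm <- mrcausal:::.weighted_median(rs$ratio_beta, rs$weight),
               mrcausal:::.weighted_median(r1$ratio_beta, r1$weight))
})

test_that("beta_to_or exponentiates componentwise", {
  expect_equal(beta_to_or(0)$or, 1)
  or <- beta_to_or(2, 1, 3)
  expect_equal(or$or, exp(2))
  expect_equal(or$or_low, exp(1))
  expect_equal(or$or_high, exp(3))
})

test_that("the report assembles all components with consistent structure", {
  panel <- default_panel(18, seed = 3)
  iset <- sim_twosample_iset(panel, n = 4000, beta = 2.4, seed_base = 900)
  rep <- mr_report(iset, n_boot = 100, seed = 2)
  expect_equal(nrow(rep$headline), 3L)
  expect_setequal(rep$headline$method,
                  c("ivw_fixed", "mr_egger", "weighted_median"))
  expect_equal(nrow(rep$leave_one_out), nrow(iset))
  expect_equal(nrow(rep$funnel), rep$k)
  expect_true(all(c("or", "or_low", "or_high") %in% names(rep$headline)))
  expect_identical(rep$headline$valid[rep$headline$method == "mr_egger"],
                   rep$estimates$egger$valid)
  expect_false(is.null(rep$audit$harmonisation))

  # planted outlier triggers the excluding-outliers re-run with k - 1 SNPs
  g8 <- seq(0.1, 0.3, length.out = 8)
  iset2 <- make_iset(gamma = g8, se_gamma = rep(0.01, 8),
                     big_gamma = c(2 * g8[1:7] + rnorm(7, 0, 0.01), 40),
                     se_big_gamma = rep(0.02, 8))
  rep2 <- mr_report(iset2, n_boot = 50, seed = 3)
  expect_length(rep2$outliers$outliers, 1)
  expect_equal(rep2$excluding_outliers$k, 7L)
})
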