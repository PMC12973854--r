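test_that("p-value filtering is strict and order-preserving", {
  st <- make_stats(c("a", "b", "c"), beta = c(1, 1, 1), se = c(1, 1, 1))
  st$pval <- c(5e-8, 1e-9, 4.999e-8)
  out <- filter_by_pvalue(st, 5e-8)
  expect_equal(out$snp_id, c("b", "c"))  # exact threshold excluded, order kept

  expect_equal(nrow(filter_by_pvalue(st[0, ], 5e-8)), 0L)
  st$pval <- rep(1e-9, 3)
  expect_equal(filter_by_pvalue(st, 5e-8)$snp_id, c("a", "b", "c"))
  expect_error(filter_by_pvalue(st, 0), "threshold")
})

test_that("pairwise r-squared matches the Pearson formula and is sign-invariant", {
  G <- make_gm(cbind(c(0, 1, 2, 0), c(0, 1, 2, 0), c(2, 1, 0, 2)))
  expect_equal(pairwise_r2(G, "rs001", "rs002"), 1.0)
  expect_equal(pairwise_r2(G, "rs001", "rs003"), 1.0)  # anticorrelation

  # hand-computed: a=(0,1,2,1), b=(0,0,2,2): cov=2/3?, r = 2/sqrt(2*4) on
  # sums of squares -> r^2 = 0.5
  G2 <- make_gm(cbind(c(0, 1, 2, 1), c(0, 0, 2, 2)))
  expect_equal(pairwise_r2(G2, "rs001", "rs002"), 0.5, tolerance = 1e-12)

  G3 <- make_gm(cbind(c(1, 1, 1, 1), c(0, 1, 2, 0)))
  expect_message(r2 <- pairwise_r2(G3, "rs001", "rs002"), "undefined")
  expect_true(is.na(r2))
})

test_that("greedy clumping keeps the most significant SNP of a tight cluster", {
  dos <- c(0, 1, 2, 0, 1, 2, 1, 0)
  G <- make_gm(cbind(dos, dos, dos), pos_bp = c(1000L, 2000L, 3000L))
  st <- make_stats(c("rs001", "rs002", "rs003"), beta = c(1, 1, 1),
                   se = c(1, 1, 1), pos_bp = c(1000L, 2000L, 3000L))
  st$pval <- c(1e-8, 1e-9, 1e-7)
  kept <- greedy_ld_clump(st, G, clump_params())
  expect_equal(kept, "rs002")
})

test_that("SNPs outside the window are retained regardless of r-squared", {
  dos <- c(0, 1, 2, 0, 1, 2, 1, 0)
  G <- make_gm(cbind(dos, dos), pos_bp = c(1000L, 20000000L))
  st <- make_stats(c("rs001", "rs002"), beta = c(1, 1), se = c(1, 1),
                   pos_bp = c(1000L, 20000000L))  # 20,000 kb apart
  st$pval <- c(1e-9, 1e-8)
  expect_setequal(greedy_ld_clump(st, G, clump_params(window_kb = 10000)),
                  c("rs001", "rs002"))
})

test_that("clumping equals an independent brute-force oracle on random instances", {
  params <- clump_params(window_kb = 50, r2_threshold = 0.3,
                         p_index = 0.5, p_secondary = 0.5)
  for (s in 1:100) {
    m <- withr::with_seed(s, sample(3:10, 1))
    blocks <- withr::with_seed(s + 1000, sample(1:3, m, replace = TRUE))
    panel <- withr::with_seed(s + 2000, snp_panel(
      sprintf("v%02d", 1:m), chrom = as.character(sample(1:2, m, TRUE)),
      pos_bp = sample(1:100, m) * 1000L,
      effect_allele = "A", other_allele = "G",
      maf = runif(m, 0.2, 0.5), ld_block = blocks))
    G <- simulate_genotypes(panel, 300, rho = 0.9, seed = s + 3000)
    st <- make_stats(panel$snp_id, beta = rep(1, m), se = rep(1, m),
                     chrom = panel$chrom, pos_bp = panel$pos_bp)
    st$pval <- withr::with_seed(s + 4000, runif(m, 1e-10, 0.6))

    kept <- greedy_ld_clump(st, G, params)
    oracle <- brute_clump(st, function(a, b)
      suppressMessages(pairwise_r2(G, a, b)),
      params$window_kb, params$r2_threshold, params$p_index,
      params$p_secondary)
    expect_equal(sort(kept), oracle)

    # post-hoc guarantees: no retained pair violates window+r2; every
    # removed candidate conflicts with a retained SNP of smaller p
    cand <- st[st$pval < params$p_index, ]
    for (a in kept) for (b in kept) {
      if (a >= b) next
      ra <- st[st$snp_id == a, ]; rb <- st[st$snp_id == b, ]
      if (ra$chrom == rb$chrom &&
          abs(ra$pos_bp - rb$pos_bp) <= params$window_kb * 1000 &&
          rb$pval < params$p_secondary && ra$pval < params$p_secondary) {
        r2 <- suppressMessages(pairwise_r2(G, a, b))
        expect_lt(ifelse(is.na(r2), 0, r2), params$r2_threshold)
      }
    }
    for (d in setdiff(cand$snp_id, kept)) {
      rd <- st[st$snp_id == d, ]
      conflict <- vapply(kept, function(a) {
        ra <- st[st$snp_id == a, ]
        ra$pval <= rd$pval && ra$chrom == rd$chrom &&
          abs(ra$pos_bp - rd$pos_bp) <= params$window_kb * 1000 &&
          {
            r2 <- suppressMessages(pairwise_r2(G, a, d))
            !is.na(r2) && r2 >= params$r2_threshold
          }
      }, logical(1))
      expect_true(any(conflict))
    }
  }
})

test_that("clumping output is independent of input record order", {
  panel <- default_panel(8, snps_per_block = 2, seed = 10)
  G <- simulate_genotypes(panel, 400, rho = 0.9, seed = 11)
  st <- make_stats(panel$snp_id, beta = rep(1, 16), se = rep(1, 16),
                   chrom = panel$chrom, pos_bp = panel$pos_bp)
  st$pval <- withr::with_seed(12, runif(16, 1e-10, 1e-6))
  params <- clump_params(r2_threshold = 0.3, p_index = 1e-5,
                         p_secondary = 1e-5)
  k1 <- greedy_ld_clump(st, G, params)
  k2 <- greedy_ld_clump(st[16:1, ], G, params)
  expect_identical(k1, k2)
})

test_that("a SNP absent from the reference errors by default, drops on request", {
  G <- make_gm(cbind(c(0, 1, 2, 0)))
  st <- make_stats(c("rs001", "ghost"), beta = c(1, 1), se = c(1, 1))
  st$pval <- c(1e-9, 1e-9)
  expect_error(greedy_ld_clump(st, G), "ghost")
  expect_equal(greedy_ld_clump(st, G, missing_ref = "drop"), "rs001")
})

test_that("harmonisation flips swapped alleles and complements strand swaps", {
  ex <- make_stats("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G",
                   eaf = 0.3)
  # swapped alleles: sign flips, EAF complements
  out <- make_stats("rs1", beta = 0.3, se = 0.05, ea = "G", oa = "A",
                    eaf = 0.7)
  h <- harmonize_instruments(ex, out)
  expect_equal(h$big_gamma, -0.3)
  expect_equal(h$eaf_outcome, 0.3)
  expect_true(h$flipped)

  # strand-complemented representation: A/G vs T/C
  out2 <- make_stats("rs1", beta = 0.3, se = 0.05, ea = "T", oa = "C",
                     eaf = 0.3)
  h2 <- harmonize_instruments(ex, out2)
  expect_true(h2$strand_swapped)
  expect_false(h2$flipped)
  # the Wald ratio is invariant to the representation
  r_direct <- wald_ratios(harmonize_instruments(
    ex, make_stats("rs1", beta = 0.3, se = 0.05, ea = "A", oa = "G",
                   eaf = 0.3)))
  r_strand <- wald_ratios(h2)
  expect_equal(r_strand$ratio_beta, r_direct$ratio_beta)
  expect_equal(r_strand$ratio_se, r_direct$ratio_se)
})

test_that("palindromic SNPs follow the stated policy", {
  ex <- make_stats("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T",
                   eaf = 0.2)
  amb <- make_stats("rs1", beta = 0.3, se = 0.05, ea = "A", oa = "T",
                    eaf = 0.50)
  expect_error(harmonize_instruments(ex, amb), "no SNPs")
  # inspect the audit through a two-SNP set so harmonisation succeeds
  ex2 <- rbind(ex, make_stats("rs2", beta = 0.2, se = 0.01, ea = "A",
                              oa = "G", eaf = 0.3))
  class(ex2) <- class(ex)
  out2 <- rbind(amb, make_stats("rs2", beta = 0.1, se = 0.05, ea = "A",
                                oa = "G", eaf = 0.3))
  class(out2) <- class(out2)
  h <- harmonize_instruments(ex2, out2)
  expect_equal(h$snp_id, "rs2")
  audit <- attr(h, "audit")
  expect_equal(audit$reason[audit$snp_id == "rs1"],
               "palindromic_ambiguous")

  # unambiguous palindromic SNP aligned by frequency
  clear_same <- make_stats("rs1", beta = 0.3, se = 0.05, ea = "A",
                           oa = "T", eaf = 0.2)
  h_same <- harmonize_instruments(ex, clear_same)
  expect_equal(h_same$big_gamma, 0.3)
  clear_opp <- make_stats("rs1", beta = 0.3, se = 0.05, ea = "A",
                          oa = "T", eaf = 0.8)
  h_opp <- harmonize_instruments(ex, clear_opp)
  expect_equal(h_opp$big_gamma, -0.3)

  # drop_all removes every palindromic SNP regardless of frequency
  expect_error(harmonize_instruments(ex, clear_same,
                                     palindrome_policy = "drop_all"),
               "no SNPs")
})

test_that("harmonisation audit conserves counts and flags duplicates", {
  ex <- make_stats(c("a", "b", "c"), beta = c(0.1, 0.2, 0.3),
                   se = c(0.01, 0.01, 0.01))
  out <- make_stats(c("a", "b"), beta = c(0.2, 0.1), se = c(0.05, 0.05))
  h <- harmonize_instruments(ex, out)
  audit <- attr(h, "audit")
  expect_equal(nrow(audit), 3L)  # retained + dropped = input
  expect_equal(sum(audit$action == "retained"), nrow(h))
  expect_equal(audit$reason[audit$snp_id == "c"], "not_in_outcome")

  dup <- rbind(ex, ex[1, ])
  class(dup) <- class(ex)
  expect_error(harmonize_instruments(dup, out), "duplicate")
})

test_that("harmonizing an already-harmonized set is the identity", {
  ex <- make_stats(c("a", "b"), beta = c(0.1, -0.2), se = c(0.01, 0.02),
                   ea = "A", oa = "G")
  out <- make_stats(c("a", "b"), beta = c(0.3, 0.1), se = c(0.05, 0.04),
                    ea = "G", oa = "A", eaf = 0.7)
  h1 <- harmonize_instruments(ex, out)
  # rebuild outcome stats from the harmonized set and harmonize again
  out2 <- make_stats(h1$snp_id, beta = h1$big_gamma, se = h1$se_big_gamma,
                     ea = "A", oa = "G", eaf = h1$eaf_outcome[1])
  h2 <- harmonize_instruments(ex, out2)
  expect_equal(h2$big_gamma, h1$big_gamma)
  expect_equal(h2$gamma, h1$gamma)
  expect_false(any(h2$flipped))
})
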