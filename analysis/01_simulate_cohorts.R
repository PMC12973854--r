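#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Three cohorts stand in for the data sources of a migraine -> cognition
# MR study:
#   * a large exposure "discovery" cohort (n = 80,000) playing the role
#     of the external migraine GWAS from which instruments are selected,
#   * a biobank-like cohort (n = 1,386) with individual-level genotypes,
#     migraine status and an MMSE-like outcome (strategies 1 and 2),
#   * an independent outcome cohort (n = 20,000) for the two-sample
#     design (strategy 3).
#
# The SNP panel has 18 causal loci, each tagged by two extra SNPs in
# strong LD, so instrument selection has something to prune.  The true
# causal effect is -2.31 MMSE points per liability SD.

suppressPackageStartupMessages(library(mrcausal))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260926L

panel <- default_panel(n_loci = 18, snps_per_block = 3, seed = 3)
write.table(panel, file.path(out, "snp_panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("discovery exposure cohort (n = 80,000) ...")
disc <- simulate_cohort(panel, cohort_config(
  n_individuals = 80000, within_block_rho = 0.9, causal_beta = -2.31,
  seed = seed))
exp_disc <- gwas_summary(disc$genotypes,
                         disc$phenotypes$exposure_liability,
                         trait_label = "migraine_liability")
write_summary_stats(exp_disc, file.path(out, "exposure_discovery.tsv"))

message("biobank cohort (n = 1,386) ...")
bio <- simulate_cohort(panel, cohort_config(
  n_individuals = 1386, within_block_rho = 0.9, causal_beta = -2.31,
  clip_outcome = TRUE, round_outcome = TRUE, seed = seed + 1L))
write_genotype_tsv(bio$genotypes, file.path(out, "biobank_genotypes.tsv"))
write_genotype_vcf(subset_genotypes(bio$genotypes, rows = 1:3),
                   file.path(out, "biobank_genotypes_head.vcf"))
write_phenotypes(bio$phenotypes, file.path(out, "biobank_phenotypes.csv"))
exp_bio <- gwas_summary(bio$genotypes, bio$phenotypes$exposure_binary,
                        trait_label = "migraine")
out_bio <- gwas_summary(bio$genotypes, bio$phenotypes$outcome,
                        trait_label = "mmse")
write_summary_stats(exp_bio, file.path(out, "exposure_biobank.tsv"))
write_summary_stats(out_bio, file.path(out, "outcome_biobank.tsv"))

message("independent outcome cohort (n = 20,000) ...")
oc <- simulate_cohort(panel, cohort_config(
  n_individuals = 20000, within_block_rho = 0.9, causal_beta = -2.31,
  seed = seed + 2L))
out_two <- gwas_summary(oc$genotypes, oc$phenotypes$outcome,
                        trait_label = "mmse")
write_summary_stats(out_two, file.path(out, "outcome_twosample.tsv"))

cat(sprintf(paste0(
  "simulated %d SNPs (%d loci x 3), true causal effect -2.31\n",
  "biobank migraine prevalence: %.3f; MMSE mean (sd): %.1f (%.1f)\n"),
  nrow(panel), 18, mean(bio$phenotypes$exposure_binary),
  mean(bio$phenotypes$outcome), sd(bio$phenotypes$outcome)))
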