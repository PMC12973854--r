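#' Run configuration for the three MR strategies
#'
#' @param strategy `"prs_2sls"` (one-sample PRS two-stage least squares),
#'   `"one_sample_summary"` (summary MR, both associations from the same
#'   cohort) or `"two_sample_summary"` (summary MR across two cohorts).
#' @param exposure_stats path to the exposure summary-statistics TSV.
#' @param outcome_stats path to the outcome summary-statistics TSV
#'   (summary strategies).
#' @param genotypes path to a dosage TSV or VCF (individual-level
#'   strategy, and the clumping reference panel when clumping is
#'   requested).
#' @param genotype_format `"tsv_dosage"` or `"vcf"`.
#' @param phenotypes path to the phenotype CSV (individual-level
#'   strategy).
#' @param clump a [clump_params()], or `NULL` to skip selection/clumping.
#' @param rounding_dp optional decimals for the fitted PRS in stage 2.
#' @param seed integer seed, stamped into every artifact.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(strategy = c("prs_2sls", "one_sample_summary",
                                    "two_sample_summary"),
                       exposure_stats = NULL, outcome_stats = NULL,
                       genotypes = NULL,
                       genotype_format = c("tsv_dosage", "vcf"),
                       phenotypes = NULL, clump = clump_params(),
                       rounding_dp = NULL, seed = 1L, out_dir = ".") {
  strategy <- match.arg(strategy)
  genotype_format <- match.arg(genotype_format)
  cfg <- list(strategy = strategy, exposure_stats = exposure_stats,
              outcome_stats = outcome_stats, genotypes = genotypes,
              genotype_format = genotype_format, phenotypes = phenotypes,
              clump = clump, rounding_dp = rounding_dp,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a flat key-value file
#'
#' Plain-text format, trivially diffable: one `key = value` per line,
#' `#` comments, optional `[clump]` section whose keys feed
#' [clump_params()].
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  main <- list(); clump <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln); next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    suppressWarnings(num <- as.numeric(val))
    if (!is.na(num)) val <- num
    if (section == "clump") clump[[key]] <- val else main[[key]] <- val
  }
  main$clump <- if (length(clump)) do.call(clump_params, clump)
                else clump_params()
  do.call(run_config, main)
}

.log <- function(...) message(sprintf(...))

.config_hash <- function(cfg) {
  cfg$out_dir <- NULL  # the hash identifies the analysis, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run an MR strategy end to end
#'
#' Chains the pipeline stages for the configured strategy and writes all
#' artifacts under `cfg$out_dir`, each stamped with the config hash, seed
#' and package version.  Progress and instrument counts at every
#' filtering step are logged to standard error; on any stage failure the
#' error message names the failing input.
#'
#' * `prs_2sls`: select + clump instruments from the exposure summary
#'   statistics against the genotype reference, fit PRS weights, run
#'   two-stage least squares, and write the estimate plus the
#'   PRS-tertile descriptive table.
#' * `one_sample_summary` / `two_sample_summary`: read the two
#'   summary-statistics files (optionally select + clump the exposure
#'   side), harmonize, and write the full summary-MR report.  The two
#'   strategies share mechanics; they differ in where the inputs came
#'   from.
#'
#' @param cfg a [run_config()].
#' @return list of results and artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("exposure_stats", "outcome_stats", "genotypes",
              "phenotypes")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("configured ", f, " file not found: ", p)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                package_version =
                  as.character(utils::packageVersion("mrcausal")))
  .log("strategy: %s (seed %d)", cfg$strategy, cfg$seed)

  select_instruments <- function(stats, ref) {
    n0 <- nrow(stats)
    sig <- filter_by_pvalue(stats, cfg$clump$gwas_threshold)
    .log("significance filter: %d -> %d SNPs", n0, nrow(sig))
    kept <- greedy_ld_clump(sig, ref, cfg$clump)
    .log("LD clumping: %d -> %d SNPs", nrow(sig), length(kept))
    sig[match(kept, sig$snp_id), , drop = FALSE]
  }

  if (cfg$strategy == "prs_2sls") {
    if (is.null(cfg$genotypes) || is.null(cfg$phenotypes) ||
        is.null(cfg$exposure_stats))
      stop("prs_2sls needs exposure_stats, genotypes and phenotypes")
    G <- read_genotype_matrix(cfg$genotypes, cfg$genotype_format)
    ph <- read_phenotypes(cfg$phenotypes)
    stats <- read_summary_stats(cfg$exposure_stats)
    sel <- if (is.null(cfg$clump)) stats else select_instruments(stats, G)
    Gs <- subset_genotypes(G, snps = sel$snp_id)
    fit <- two_stage_ls(Gs, ph$exposure_binary, ph$outcome,
                        rounding_dp = cfg$rounding_dp)
    .log("2SLS: beta = %.4f, F = %.2f%s", fit$estimate$beta,
         fit$stage1$f_statistic,
         if (fit$stage1$weak_instrument) " (weak instrument)" else "")
    tt <- tertile_descriptives(fit$stage1$fitted_prs, ph,
                               continuous_vars = c("outcome", "age"),
                               discrete_vars = c("sex", "education"))
    est_path <- file.path(cfg$out_dir, "estimate.jsonl")
    rec <- c(as.list(as.data.frame(fit$estimate)),
             list(f_statistic = fit$stage1$f_statistic,
                  weak_instrument = fit$stage1$weak_instrument),
             stamp)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
               est_path)
    tt_path <- file.path(cfg$out_dir, "tertile_table.tsv")
    utils::write.table(rbind(
      cbind(type = "continuous",
            tt$continuous[, c("variable", "p_anova", "p_trend")],
            p_chisq = NA),
      cbind(type = "discrete",
            tt$discrete[, c("variable", "p_trend")],
            p_anova = NA, p_chisq = tt$discrete$p_chisq)[,
              c("type", "variable", "p_anova", "p_trend", "p_chisq")]),
      tt_path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(list(estimate = fit$estimate, stage1 = fit$stage1,
                          tertiles = tt,
                          artifacts = c(est_path, tt_path))))
  }

  # summary strategies
  if (is.null(cfg$exposure_stats) || is.null(cfg$outcome_stats))
    stop(cfg$strategy, " needs exposure_stats and outcome_stats")
  exp_stats <- read_summary_stats(cfg$exposure_stats)
  out_stats <- read_summary_stats(cfg$outcome_stats)
  if (!is.null(cfg$genotypes) && !is.null(cfg$clump)) {
    ref <- read_genotype_matrix(cfg$genotypes, cfg$genotype_format)
    exp_stats <- select_instruments(exp_stats, ref)
  }
  iset <- harmonize_instruments(exp_stats, out_stats)
  aud <- attr(iset, "audit")
  .log("harmonized %d of %d SNPs", nrow(iset), nrow(aud))
  rep <- mr_report(iset, seed = cfg$seed)
  paths <- write_mr_report(rep, iset, cfg$out_dir, stamp = stamp)
  invisible(list(report = rep, instruments = iset, artifacts = paths))
}
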