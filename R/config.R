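#' Run configuration
#'
#' Thresholds and windows for cis scanning and matching.  Defaults follow
#' common practice for cis-regulatory QC of array cohorts: SNP-trait pairs
#' are tested within 1 Mb of the gene/probe region, methyl probes pair to the
#' nearest transcript start within 10 kb, association p < 0.01 retains a cis
#' pair, data-driven top-n is capped at 3 (decided by a Welch t-test at
#' p < 0.01 between top-1 and top-n z-score distributions), and a trio match
#' additionally requires a combined z of at least 2.5.
#'
#' @param cis_window_snp_bp window for SNP-to-gene/probe cis tests (bp).
#' @param cis_window_methyl_bp max distance methyl probe to transcript start.
#' @param cis_window_cnv_bp window for CNV-to-trait cis tests.
#' @param p_threshold association p-value cutoff retaining a cis pair.
#' @param q_threshold optional BH q-value cutoff (`NULL` = p only).
#' @param fdr_method `"bh"` or `"permutation"` (reporting only).
#' @param permutations permutation count for [permutation_fdr()].
#' @param min_samples minimum co-aligned samples for any cis scan.
#' @param top_n_cap maximum top-n for duo matching.
#' @param topn_ttest_p t-test p-value deciding top-n.
#' @param trio_z_min minimum combined trio score.
#' @param omega weight of the genotype-methylation z relative to the
#'   expression-methylation z in the trio score, or `"auto"` to estimate it
#'   as the square root of the ratio of mean row-maximum z-scores.
#' @param trio_combine `"average"` (default; threshold stays on the z scale)
#'   or `"sum"`.
#' @param concordance `"match"` (fraction of identical genotype calls) or
#'   `"dosage"` (1 - mean |g - ghat| / 2).
#' @param max_rounds maximum alignment rounds.
#' @param gender_F_male,gender_F_female inbreeding-coefficient cutoffs for
#'   calling male/female from X-heterozygosity.
#' @param min_x_snps minimum non-missing X SNPs for an F call.
#' @param marker_threshold optional fixed sex-marker threshold (overrides the
#'   learned two-means midpoint).
#' @param rng_seed seed driving permutation tests.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cis_window_snp_bp = 1e6,
                       cis_window_methyl_bp = 1e4,
                       cis_window_cnv_bp = 1e6,
                       p_threshold = 0.01,
                       q_threshold = NULL,
                       fdr_method = c("bh", "permutation"),
                       permutations = 100,
                       min_samples = 20,
                       top_n_cap = 3,
                       topn_ttest_p = 0.01,
                       trio_z_min = 2.5,
                       omega = "auto",
                       trio_combine = c("average", "sum"),
                       concordance = c("match", "dosage"),
                       max_rounds = 20,
                       gender_F_male = 0.8,
                       gender_F_female = 0.2,
                       min_x_snps = 50,
                       marker_threshold = NULL,
                       rng_seed = 1L) {
  cfg <- list(cis_window_snp_bp = cis_window_snp_bp,
              cis_window_methyl_bp = cis_window_methyl_bp,
              cis_window_cnv_bp = cis_window_cnv_bp,
              p_threshold = p_threshold, q_threshold = q_threshold,
              fdr_method = match.arg(fdr_method),
              permutations = as.integer(permutations),
              min_samples = as.integer(min_samples),
              top_n_cap = as.integer(top_n_cap), topn_ttest_p = topn_ttest_p,
              trio_z_min = trio_z_min, omega = omega,
              trio_combine = match.arg(trio_combine),
              concordance = match.arg(concordance),
              max_rounds = as.integer(max_rounds),
              gender_F_male = gender_F_male, gender_F_female = gender_F_female,
              min_x_snps = as.integer(min_x_snps),
              marker_threshold = marker_threshold,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$p_threshold > 0, cfg$p_threshold < 1,
            cfg$top_n_cap >= 1, cfg$max_rounds >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}
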