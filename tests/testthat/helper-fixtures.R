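# Fixture builders shared across the suite; everything is generated in code.

# minimal ProfileMatrix with evenly spaced single-base features on one chrom
toy_pm <- function(values, data_type = "expression", chrom = "chr1",
                   starts = NULL, width = 0) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("p", seq_len(ncol(values)))
  if (is.null(starts)) starts <- seq_len(nrow(values)) * 1e6
  pos <- data.frame(feature_id = rownames(values), chrom = chrom,
                    start = starts, end = starts + width,
                    stringsAsFactors = FALSE)
  suppressMessages(profile_matrix(values, data_type, pos))
}

# identity sample pairing p1<->p1 etc. for two matrices with equal columns
self_pairs <- function(pm_a, pm_b) {
  data.frame(a = colnames(pm_a$values), b = colnames(pm_b$values),
             stringsAsFactors = FALSE)
}

# small fast cohort for pipeline tests
small_cohort <- function(seed = 1, n = 40, errors = c(), ...) {
  simulate_cohort(sim_config(n_subjects = n, n_cis_esnp = 40, n_cis_msnp = 40,
                             n_cis_em = 40, n_null_snps = 10, n_null_genes = 10,
                             n_null_probes = 10,
                             errors_per_type = errors, seed = seed, ...))
}

quiet_match <- function(...) suppressWarnings(suppressMessages(mod_match(...)))

fast_cfg <- function(...) run_config(min_samples = 10, ...)

# wrap a bare score matrix as a z-filled SimilarityMatrix
sim_from_score <- function(S, kind = "rank_correlation",
                           row_type = "methylation", col_type = "expression") {
  if (is.null(rownames(S))) rownames(S) <- paste0("r", seq_len(nrow(S)))
  if (is.null(colnames(S))) colnames(S) <- paste0("c", seq_len(ncol(S)))
  zscore(omicmatch:::new_similarity_matrix(S, kind, row_type, col_type))
}
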