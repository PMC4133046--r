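# Cis pair discovery between two data types under the current alignment.
#
# A CisPairSet holds the significant (source feature, target feature) pairs
# plus the full candidate list, so permutation FDR can re-test the same
# candidates under shuffled sample alignments.

new_cis_pair_set <- function(pair_type, pairs, tested, n_samples, method,
                             stratum = NA_character_) {
  pairs <- pairs[order(pairs$p_value, pairs$source, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pair_type = pair_type, pairs = pairs, tested = tested,
                 n_samples_used = n_samples, method = method, stratum = stratum),
            class = "CisPairSet")
}

#' @export
print.CisPairSet <- function(x, ...) {
  cat(sprintf("CisPairSet <%s>: %d significant / %d tested pairs (n = %d%s)\n",
              x$pair_type, nrow(x$pairs), nrow(x$tested), x$n_samples_used,
              if (is.na(x$stratum)) "" else paste0(", stratum ", x$stratum)))
  invisible(x)
}

# gap between two intervals on the same chromosome; 0 when they touch/overlap
interval_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s2 - e1, s1 - e2))

# candidate feature pairs whose intervals lie within `window` bp of each
# other (edge-to-edge; 0 inside), via GenomicRanges overlap with padding
cis_candidates <- function(source_pm, target_pm, window) {
  sp <- source_pm$positions; tp <- target_pm$positions
  if (nrow(sp) == 0 || nrow(tp) == 0)
    return(data.frame(source = character(), target = character(),
                      distance_bp = integer()))
  hits <- suppressWarnings(           # disjoint seqlevels are expected
    GenomicRanges::findOverlaps(feature_ranges(source_pm),
                                feature_ranges(target_pm),
                                maxgap = window + 2))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  d <- interval_gap(sp$start[i], sp$end[i], tp$start[j], tp$end[j])
  keep <- d <= window
  data.frame(source = sp$feature_id[i][keep], target = tp$feature_id[j][keep],
             distance_bp = as.integer(d[keep]), stringsAsFactors = FALSE)
}

# resolve a sample-pair specification: either a data.frame(a, b) of profile
# ids, or a LabelAssignment from which co-labeled pairs are taken
resolve_pairs <- function(pairs, source_pm, target_pm) {
  if (inherits(pairs, "LabelAssignment")) {
    sa <- subjects_of(pairs, source_pm$data_type)
    sb <- subjects_of(pairs, target_pm$data_type)
    shared <- intersect(stats::na.omit(sa), stats::na.omit(sb))
    pairs <- data.frame(a = names(sa)[match(shared, sa)],
                        b = names(sb)[match(shared, sb)],
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(pairs$a %in% profile_ids(source_pm)),
            all(pairs$b %in% profile_ids(target_pm)))
  pairs[order(pairs$a), , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (wraps [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in the input order; empty input gives an empty vector.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(!is.na(p_values) & (p_values <= 0 | p_values > 1)))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

ols_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3 || var(x[ok]) == 0 || var(y[ok]) == 0)
    return(c(stat = NA_real_, p = NA_real_, n = n))
  r <- cor(x[ok], y[ok])
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  if (abs(r) >= 1) tt <- sign(r) * Inf
  c(stat = tt, p = max(2 * pt(-abs(tt), n - 2), .Machine$double.xmin), n = n)
}

spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3 || var(x[ok]) == 0 || var(y[ok]) == 0)
    return(c(stat = NA_real_, p = NA_real_, n = n))
  if (n < 10) {
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = TRUE))
    return(c(stat = unname(ct$estimate),
             p = max(ct$p.value, .Machine$double.xmin), n = n))
  }
  rho <- cor(x[ok], y[ok], method = "spearman")
  if (abs(rho) >= 1) return(c(stat = rho, p = .Machine$double.xmin, n = n))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  c(stat = rho, p = max(2 * pt(-abs(tt), n - 2), .Machine$double.xmin), n = n)
}

scan_candidates <- function(source_pm, target_pm, pairs, cand, assoc_fun,
                            p_threshold, q_threshold = NULL) {
  X <- source_pm$values[, pairs$a, drop = FALSE]
  Y <- target_pm$values[, pairs$b, drop = FALSE]
  res <- t(vapply(seq_len(nrow(cand)), function(k) {
    assoc_fun(X[cand$source[k], ], Y[cand$target[k], ])
  }, c(stat = 0, p = 0, n = 0)))
  out <- data.frame(source = cand$source, target = cand$target,
                    statistic = res[, "stat"], p_value = res[, "p"],
                    q_value = NA_real_, distance_bp = cand$distance_bp,
                    n = as.integer(res[, "n"]), stringsAsFactors = FALSE)
  out <- out[!is.na(out$p_value), , drop = FALSE]
  out$q_value <- bh_fdr(out$p_value)
  keep <- out$p_value < p_threshold
  if (!is.null(q_threshold)) keep <- keep & out$q_value < q_threshold
  out[keep, , drop = FALSE]
}

#' Scan for cis SNP-trait associations under an additive linear model
#'
#' Every SNP within `window_bp` (edge distance, 0 inside the feature's
#' region) of an expression or methylation feature is tested by ordinary
#' least squares of trait on genotype dosage; the reported statistic is the
#' slope t (df = n - 2).  Pairs with p below the threshold are retained
#' (cis-eSNPs when the trait is expression, cis-mSNPs for methylation).
#' Monomorphic SNPs are skipped; missing genotypes are dropped pairwise.
#'
#' @param geno genotype `ProfileMatrix`.
#' @param trait expression or methylation `ProfileMatrix`.
#' @param pairs aligned sample pairs: a `LabelAssignment` (co-labeled pairs
#'   are used) or a data frame with columns `a` (genotype profile id) and
#'   `b` (trait profile id).
#' @param window_bp cis window in bp (default 1 Mb).
#' @param p_threshold retention p-value cutoff.
#' @param q_threshold optional additional BH q cutoff.
#' @param min_samples minimum aligned samples; below it an empty set is
#'   returned with a warning.
#' @param stratum optional stratum label recorded in the result.
#' @return A `CisPairSet`.
#' @export
additive_linear_scan <- function(geno, trait, pairs, window_bp = 1e6,
                                 p_threshold = 0.01, q_threshold = NULL,
                                 min_samples = 20, stratum = NA_character_) {
  pairs <- resolve_pairs(pairs, geno, trait)
  ptype <- if (trait$data_type == "methylation") "mSNP" else "eSNP"
  if (nrow(pairs) < min_samples) {
    warning(sprintf("only %d aligned samples (< %d); empty %s set",
                    nrow(pairs), min_samples, ptype), call. = FALSE)
    return(new_cis_pair_set(ptype, empty_cis_pairs(), empty_cis_pairs(),
                            nrow(pairs), "ols", stratum))
  }
  cand <- cis_candidates(geno, trait, window_bp)
  sig <- scan_candidates(geno, trait, pairs, cand, ols_assoc,
                         p_threshold, q_threshold)
  new_cis_pair_set(ptype, sig, cand, nrow(pairs), "ols", stratum)
}

empty_cis_pairs <- function() {
  data.frame(source = character(), target = character(), statistic = numeric(),
             p_value = numeric(), q_value = numeric(), distance_bp = integer(),
             n = integer(), stringsAsFactors = FALSE)
}

#' Map cis methylation-mRNA pairs
#'
#' Each methyl probe is assigned to the transcript whose start site is
#' nearest to the probe position, provided that distance is at most
#' `max_tss_bp`; unassignable probes are dropped.  Probe methylation is then
#' tested against the assigned gene's expression by Spearman correlation
#' (average ranks; t approximation for n >= 10, exact for smaller n), and
#' when several probes survive for one gene only the smallest-p probe is
#' kept, so the set has at most a single pair per gene.  An exactly
#' equidistant transcript tie goes to the lexicographically smaller id.
#'
#' @param methyl methylation `ProfileMatrix`.
#' @param expr expression `ProfileMatrix`.
#' @param pairs aligned sample pairs (`LabelAssignment` or data frame with
#'   `a` = methylation profile, `b` = expression profile).
#' @param transcripts optional positions data frame (`feature_id`, `chrom`,
#'   `start`, `end`) giving transcript starts; defaults to the expression
#'   matrix's own feature positions.
#' @param max_tss_bp probe-to-transcript-start cutoff (default 10 kb).
#' @param p_threshold retention p-value cutoff.
#' @param min_samples minimum aligned samples.
#' @param stratum optional stratum label.
#' @return A `CisPairSet` (source = methyl probe, target = gene).
#' @export
map_cis_methyl_mrna <- function(methyl, expr, pairs, transcripts = NULL,
                                max_tss_bp = 1e4, p_threshold = 0.01,
                                min_samples = 20, stratum = NA_character_) {
  pairs <- resolve_pairs(pairs, methyl, expr)
  if (nrow(pairs) < min_samples) {
    warning(sprintf("only %d aligned samples (< %d); empty methyl-mRNA set",
                    nrow(pairs), min_samples), call. = FALSE)
    return(new_cis_pair_set("methyl_mRNA", empty_cis_pairs(), empty_cis_pairs(),
                            nrow(pairs), "spearman", stratum))
  }
  tx <- transcripts %||% expr$positions
  tx <- tx[tx$feature_id %in% feature_ids(expr), , drop = FALSE]
  cand <- assign_probes_to_tss(methyl$positions, tx, max_tss_bp)
  if (nrow(cand) == 0) {
    warning("no methyl probe within range of any transcript start", call. = FALSE)
    return(new_cis_pair_set("methyl_mRNA", empty_cis_pairs(), empty_cis_pairs(),
                            nrow(pairs), "spearman", stratum))
  }
  sig <- scan_candidates(methyl, expr, pairs, cand, spearman_assoc, p_threshold)
  # at most a single pair per gene: best p wins, probe id breaks exact ties
  sig <- sig[order(sig$p_value, sig$source), , drop = FALSE]
  sig <- sig[!duplicated(sig$target), , drop = FALSE]
  new_cis_pair_set("methyl_mRNA", sig, cand, nrow(pairs), "spearman", stratum)
}

# nearest transcript start within max_bp for each probe (probe position =
# interval start, matching single-base methyl probes)
assign_probes_to_tss <- function(probe_pos, tx_pos, max_bp) {
  if (nrow(probe_pos) == 0 || nrow(tx_pos) == 0)
    return(data.frame(source = character(), target = character(),
                      distance_bp = integer()))
  tx_pos <- tx_pos[order(tx_pos$feature_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(probe_pos)), function(i) {
    same <- tx_pos$chrom == probe_pos$chrom[i]
    if (!any(same)) return(NULL)
    d <- abs(tx_pos$start[same] - probe_pos$start[i])
    j <- which(d == min(d))[1]              # tx sorted: tie -> smaller id
    if (d[j] > max_bp) return(NULL)
    data.frame(source = probe_pos$feature_id[i],
               target = tx_pos$feature_id[same][j],
               distance_bp = as.integer(d[j]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out %||% data.frame(source = character(), target = character(),
                      distance_bp = integer())
}

#' Map cis CNV-trait pairs
#'
#' CNV features (segment means or dosages) are tested by Spearman
#' correlation against expression or methylation features whose regions
#' overlap or lie within `window_bp`; thresholds follow the methyl-mRNA
#' scan.  Zero-variance CNV features are skipped.
#'
#' @param cnv CNV `ProfileMatrix`.
#' @param trait expression or methylation `ProfileMatrix`.
#' @inheritParams additive_linear_scan
#' @return A `CisPairSet`.
#' @export
map_cis_cnv <- function(cnv, trait, pairs, window_bp = 1e6, p_threshold = 0.01,
                        min_samples = 20, stratum = NA_character_) {
  pairs <- resolve_pairs(pairs, cnv, trait)
  ptype <- if (trait$data_type == "methylation") "cnv_methyl" else "cnv_mRNA"
  if (nrow(pairs) < min_samples) {
    warning(sprintf("only %d aligned samples (< %d); empty %s set",
                    nrow(pairs), min_samples, ptype), call. = FALSE)
    return(new_cis_pair_set(ptype, empty_cis_pairs(), empty_cis_pairs(),
                            nrow(pairs), "spearman", stratum))
  }
  cand <- cis_candidates(cnv, trait, window_bp)
  sig <- scan_candidates(cnv, trait, pairs, cand, spearman_assoc, p_threshold)
  new_cis_pair_set(ptype, sig, cand, nrow(pairs), "spearman", stratum)
}

#' Permutation estimate of the false discovery rate of a cis pair set
#'
#' Sample alignments are permuted B times (the target-side profile of each
#' aligned pair is shuffled); the FDR estimate is the mean number of
#' candidate pairs passing the p-value threshold in permuted data divided by
#' the observed number of significant pairs.
#'
#' @param pair_set a `CisPairSet` (its stored candidate list is re-tested).
#' @param source_pm,target_pm the two profile matrices the set came from.
#' @param pairs the aligned sample pairs used for the observed scan.
#' @param B number of permutations (>= 1).
#' @param p_threshold p-value cutoff, matching the observed scan.
#' @param seed RNG seed.
#' @return FDR estimate, or `NA` (with a message) when the observed set is
#'   empty.
#' @export
permutation_fdr <- function(pair_set, source_pm, target_pm, pairs, B = 100,
                            p_threshold = 0.01, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  n_obs <- nrow(pair_set$pairs)
  if (n_obs == 0) {
    msg("no observed cis pairs: permutation FDR not applicable")
    return(NA_real_)
  }
  pairs <- resolve_pairs(pairs, source_pm, target_pm)
  assoc <- if (pair_set$method == "ols") ols_assoc else spearman_assoc
  cand <- pair_set$tested
  counts <- withr_seed(seed, {
    vapply(seq_len(B), function(b) {
      perm <- pairs
      perm$b <- sample(perm$b)
      nrow(scan_candidates(source_pm, target_pm, perm, cand, assoc, p_threshold))
    }, numeric(1))
  })
  mean(counts) / n_obs
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Write a cis pair set to TSV
#'
#' @param ps a `CisPairSet`.
#' @param path output file.
#' @export
write_cis_pairs <- function(ps, path) {
  out <- cbind(pair_type = ps$pair_type, ps$pairs,
               stratum = ps$stratum, n_samples = ps$n_samples_used)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
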