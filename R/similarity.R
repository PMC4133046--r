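# Identity similarity scores between profiles of two data types, computed
# over the significant cis pairs linking them.

new_similarity_matrix <- function(score, score_kind, row_type, col_type) {
  structure(list(score = score, z_row = NULL, z_col = NULL,
                 score_kind = score_kind, row_type = row_type,
                 col_type = col_type),
            class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat(sprintf("SimilarityMatrix <%s ~ %s> (%s): %d x %d%s\n",
              x$row_type, x$col_type, x$score_kind,
              nrow(x$score), ncol(x$score),
              if (is.null(x$z_row)) "" else ", z filled"))
  invisible(x)
}

#' Infer genotypes at cis features from a trait profile
#'
#' For each cis pair (SNP, trait feature) and each trait profile, the mean
#' trait level of every genotype class in \{0, 1, 2\} is estimated from the
#' currently aligned sample pairs, excluding the profile being scored
#' (leave-one-out); the inferred genotype is the class whose mean is closest
#' to the profile's own trait value.  Classes unrepresented among the other
#' aligned samples are not candidates, and an exact distance tie is broken
#' to the lower genotype code.
#'
#' @param cis_pairs a `CisPairSet` from [additive_linear_scan()].
#' @param geno genotype `ProfileMatrix`.
#' @param trait expression or methylation `ProfileMatrix`.
#' @param pairs aligned sample pairs (`LabelAssignment` or data frame `a` =
#'   genotype profile, `b` = trait profile).
#' @param trait_profiles profiles to infer for (default: all in `trait`).
#' @return Numeric matrix, cis features x trait profiles, entries in
#'   \{0, 1, 2, NA\}.
#' @export
infer_genotype_from_trait <- function(cis_pairs, geno, trait, pairs,
                                      trait_profiles = profile_ids(trait)) {
  pairs <- resolve_pairs(pairs, geno, trait)
  cp <- cis_pairs$pairs
  inf <- matrix(NA_real_, nrow(cp), length(trait_profiles),
                dimnames = list(NULL, trait_profiles))
  if (nrow(cp) == 0) return(inf)
  loo_idx <- match(trait_profiles, pairs$b)     # NA when profile not aligned
  for (r in seq_len(nrow(cp))) {
    gv <- geno$values[cp$source[r], pairs$a]
    tv <- trait$values[cp$target[r], pairs$b]
    ok <- !is.na(gv) & !is.na(tv)
    sums <- vapply(0:2, function(g) sum(tv[ok & gv == g]), numeric(1))
    cnts <- vapply(0:2, function(g) sum(ok & gv == g), numeric(1))
    x <- trait$values[cp$target[r], trait_profiles]
    for (j in seq_along(trait_profiles)) {
      if (is.na(x[j])) next
      s <- sums; n <- cnts
      li <- loo_idx[j]
      if (!is.na(li) && ok[li]) {               # leave self out of the means
        cls <- gv[li] + 1
        s[cls] <- s[cls] - tv[li]; n[cls] <- n[cls] - 1
      }
      mu <- ifelse(n > 0, s / n, NA_real_)
      d <- abs(x[j] - mu)
      if (all(is.na(d))) next
      inf[r, j] <- which.min(d) - 1             # which.min: tie -> lower code
    }
  }
  inf
}

#' Concordance between observed and inferred genotype vectors
#'
#' Fraction of cis features, among those non-missing in both vectors, where
#' the observed and inferred genotypes agree.  `method = "dosage"` instead
#' scores 1 - mean |g - ghat| / 2.
#'
#' @param observed,inferred genotype vectors aligned on the same cis
#'   feature list.
#' @param method `"match"` or `"dosage"`.
#' @return Score in [0, 1], or `NA` when no feature is usable.
#' @export
genotype_concordance <- function(observed, inferred,
                                 method = c("match", "dosage")) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(inferred))
  ok <- !is.na(observed) & !is.na(inferred)
  if (!any(ok)) return(NA_real_)
  if (method == "match") mean(observed[ok] == inferred[ok])
  else 1 - mean(abs(observed[ok] - inferred[ok])) / 2
}

#' All-vs-all genotype-concordance similarity matrix
#'
#' Builds the identity similarity between every genotype profile and every
#' trait (expression or methylation) profile: genotypes at the cis features
#' are inferred from each trait profile and compared with each observed
#' genotype profile.
#'
#' @inheritParams infer_genotype_from_trait
#' @param method concordance flavour, see [genotype_concordance()].
#' @return A `SimilarityMatrix` (rows = genotype profiles, cols = trait
#'   profiles), scores in [0, 1].
#' @export
similarity_concordance <- function(cis_pairs, geno, trait, pairs,
                                   method = c("match", "dosage")) {
  method <- match.arg(method)
  inf <- infer_genotype_from_trait(cis_pairs, geno, trait, pairs)
  gids <- profile_ids(geno)
  obs <- geno$values[cis_pairs$pairs$source, gids, drop = FALSE]
  S <- matrix(NA_real_, length(gids), ncol(inf),
              dimnames = list(gids, colnames(inf)))
  for (j in seq_len(ncol(inf))) {
    ok <- !is.na(obs) & !is.na(inf[, j])
    n <- colSums(ok)
    S[, j] <- if (method == "match")
      ifelse(n > 0, colSums((obs == inf[, j]) & ok) / n, NA_real_)
    else
      ifelse(n > 0, 1 - colSums(abs(obs - inf[, j]) * ok) / (2 * n), NA_real_)
  }
  new_similarity_matrix(S, "genotype_concordance", "genotype", trait$data_type)
}

rank_rows <- function(m) t(apply(m, 1, rank))    # average ranks across profiles

#' Rank-correlation identity score between one methylation and one
#' expression profile
#'
#' Both matrices are rank-transformed feature-wise across their own
#' profiles; the score is the Pearson correlation, over the cis
#' methyl-mRNA pairs, between the methylation profile's ranks at the probes
#' and the expression profile's ranks at the paired genes.  No sign flip is
#' applied: anticorrelated cis pairs contribute through their observed
#' ranks.
#'
#' @param cis_pairs a `CisPairSet` from [map_cis_methyl_mrna()].
#' @param methyl,expr the two profile matrices.
#' @param m_profile,e_profile profile ids to score.
#' @return Correlation in [-1, 1]; `NA` when fewer than 3 cis pairs.
#' @export
rank_correlation_score <- function(cis_pairs, methyl, expr, m_profile, e_profile) {
  S <- similarity_rank(cis_pairs, methyl, expr, sign_align = FALSE)
  S$score[m_profile, e_profile]
}

#' All-vs-all rank-correlation similarity matrix
#'
#' With `sign_align = TRUE` (the matcher's setting) the expression ranks of
#' each cis pair whose cis correlation is negative are reversed before
#' correlating, so that a profile pair belonging to the same subject scores
#' high regardless of whether its cis pairs are repressive or activating;
#' without it the raw observed-rank correlation is returned.
#'
#' @inheritParams rank_correlation_score
#' @param sign_align reverse target ranks of anticorrelated cis pairs.
#' @return A `SimilarityMatrix` (rows = methylation profiles, cols =
#'   expression profiles).
#' @export
similarity_rank <- function(cis_pairs, methyl, expr, sign_align = TRUE) {
  cp <- cis_pairs$pairs
  mids <- profile_ids(methyl); eids <- profile_ids(expr)
  if (nrow(cp) < 3) {
    S <- matrix(NA_real_, length(mids), length(eids),
                dimnames = list(mids, eids))
    return(new_similarity_matrix(S, "rank_correlation",
                                 methyl$data_type, expr$data_type))
  }
  Rm <- rank_rows(methyl$values[cp$source, , drop = FALSE])
  Re <- rank_rows(expr$values[cp$target, , drop = FALSE])
  if (sign_align) {
    neg <- !is.na(cp$statistic) & cp$statistic < 0
    Re[neg, ] <- ncol(Re) + 1 - Re[neg, ]
  }
  S <- cor(Rm, Re)
  dimnames(S) <- list(mids, eids)
  new_similarity_matrix(S, "rank_correlation", methyl$data_type, expr$data_type)
}

#' Fill row and column z-scores of a similarity matrix
#'
#' `z_row[i, j]` standardises `score[i, j]` within row i (mean and SD over
#' the finite entries of the row); `z_col` is the column analogue.  Rows or
#' columns with fewer than 3 finite scores or zero SD get `NA` z-scores.
#'
#' @param sim a `SimilarityMatrix`.
#' @return The matrix with `z_row` and `z_col` filled.
#' @export
zscore <- function(sim) {
  std <- function(M) {
    t(apply(M, 1, function(r) {
      ok <- is.finite(r)
      if (sum(ok) < 3) return(rep(NA_real_, length(r)))
      s <- sd(r[ok])
      if (!is.finite(s) || s == 0) return(rep(NA_real_, length(r)))
      (r - mean(r[ok])) / s
    }))
  }
  sim$z_row <- std(sim$score)
  sim$z_col <- t(std(t(sim$score)))
  dimnames(sim$z_row) <- dimnames(sim$z_col) <- dimnames(sim$score)
  sim
}

#' Estimate the trio weight from two z-scored similarity matrices
#'
#' The weight of the genotype-methylation signal relative to the
#' expression-methylation signal: the square root of the ratio of the mean
#' row-maximum z-scores of the two matrices.  Falls back to 1 (with a
#' warning) when the denominator is non-positive or undefined.
#'
#' @param sim_gm,sim_em z-filled `SimilarityMatrix` objects.
#' @return omega (positive scalar).
#' @export
estimate_omega <- function(sim_gm, sim_em) {
  mean_max <- function(sim) {
    mx <- apply(sim$z_row, 1, function(r) if (any(is.finite(r))) max(r, na.rm = TRUE) else NA_real_)
    mean(mx, na.rm = TRUE)
  }
  num <- mean_max(sim_gm); den <- mean_max(sim_em)
  if (!is.finite(den) || den <= 0 || !is.finite(num) || num <= 0) {
    warning("degenerate z-score distributions: omega fell back to 1", call. = FALSE)
    return(1)
  }
  sqrt(num / den)
}

#' Three-way trio identity score
#'
#' Combines the genotype-methylation and expression-methylation z-scores of
#' a candidate methylation profile with weight omega.  The default weighted
#' average `(omega * z_gm + z_em) / (1 + omega)` keeps the score on the z
#' scale, so the acceptance threshold (2.5) is comparable with its
#' components; `combine = "sum"` gives the raw weighted sum.
#'
#' @param z_gm,z_em component z-scores.
#' @param omega weight of `z_gm` relative to `z_em`.
#' @param combine `"average"` or `"sum"`.
#' @return The combined score.
#' @export
trio_score <- function(z_gm, z_em, omega, combine = c("average", "sum")) {
  combine <- match.arg(combine)
  s <- omega * z_gm + z_em
  if (combine == "average") s / (1 + omega) else s
}

#' Write a similarity matrix (scores) to TSV
#'
#' @param sim a `SimilarityMatrix`.
#' @param path output file.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(profile = rownames(sim$score), sim$score,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
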