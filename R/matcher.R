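# The matching decision procedure: gender gate, duo matching with
# data-driven top-n and reciprocal rescue, trio resolution, and the outer
# iteration loop with cis-pair-count QC.

#' Data-driven top-n for duo matching
#'
#' Per row of the z-scored similarity matrix the best and the n-th best
#' z-scores are collected; starting at n = 1, the top-1 distribution is
#' compared with the top-(n+1) distribution by a Welch t-test.  The first
#' n whose next distribution differs at `alpha` is returned; if no
#' comparison separates, n is the cap.  With a dominant self-signal the
#' top-1 scores stand clearly above the rest and n = 1; as score
#' separation degrades n grows, admitting more candidate ranks.
#'
#' @param sim z-filled `SimilarityMatrix`.
#' @param cap maximum n (default 3).
#' @param alpha t-test significance cutoff (default 0.01).
#' @return Integer n in 1..cap.
#' @export
determine_top_n <- function(sim, cap = 3, alpha = 0.01) {
  if (cap <= 1) return(1L)
  Z <- sim$z_row
  usable <- apply(Z, 1, function(r) sum(is.finite(r)) >= cap)
  if (sum(usable) < 5) {
    warning("fewer than 5 usable rows: top-n set to cap", call. = FALSE)
    return(as.integer(cap))
  }
  tops <- t(apply(Z[usable, , drop = FALSE], 1, function(r)
    sort(r[is.finite(r)], decreasing = TRUE)[seq_len(cap)]))
  for (k in 2:cap) {
    p <- tryCatch(t.test(tops[, 1], tops[, k])$p.value, error = function(e) 1)
    if (is.finite(p) && p < alpha) return(k - 1L)
  }
  as.integer(cap)
}

# is score s within the top n of vector v (ties inclusive)?
within_top_n <- function(s, v, n) {
  if (is.na(s)) return(FALSE)
  sum(v > s, na.rm = TRUE) < n
}

#' Confirm aligned profile pairs by reciprocal top-n rank
#'
#' For each currently aligned pair (a, b): the pair is kept (self-matched)
#' iff its score is within the top n of row a and within the top n of
#' column b, ties inclusive.  Gender-barred pairs are flagged; pairs with a
#' missing score or failing the rank test dissolve and both profiles enter
#' the unmatched pools.
#'
#' @param sim `SimilarityMatrix` (scores suffice; z not required).
#' @param aligned data frame with columns `a` (row profile) and `b` (column
#'   profile).
#' @param n top-n rank (from [determine_top_n()]).
#' @param barred optional logical matrix (same shape as the scores), `TRUE`
#'   where a pair is excluded by the gender gate.
#' @return data frame `a`, `b`, `status` in \{self_matched, unmatched,
#'   gender_conflict\}, `score`.
#' @export
duo_match <- function(sim, aligned, n, barred = NULL) {
  S <- sim$score
  status <- character(nrow(aligned)); sc <- numeric(nrow(aligned))
  for (k in seq_len(nrow(aligned))) {
    a <- aligned$a[k]; b <- aligned$b[k]
    s <- S[a, b]; sc[k] <- s
    if (!is.null(barred) && isTRUE(barred[a, b])) { status[k] <- "gender_conflict"; next }
    status[k] <- if (within_top_n(s, S[a, ], n) && within_top_n(s, S[, b], n))
      "self_matched" else "unmatched"
  }
  data.frame(a = aligned$a, b = aligned$b, status = status, score = sc,
             stringsAsFactors = FALSE)
}

#' Rescue unmatched profiles by reciprocal best match
#'
#' Pair (a, b) is rescued iff b is the unique best-scoring column of row a
#' over ALL columns, a is the unique best-scoring row of column b over ALL
#' rows, and both profiles are currently unmatched.  Ties at the maximum
#' block the rescue (no relabeling on ambiguous evidence).
#'
#' @param sim `SimilarityMatrix`.
#' @param unmatched_a,unmatched_b pools of unmatched row/column profiles.
#' @param barred optional gender-gate matrix as in [duo_match()].
#' @return data frame `a`, `b`, `score` of rescued pairs (possibly empty).
#' @export
reciprocal_rescue <- function(sim, unmatched_a, unmatched_b, barred = NULL) {
  S <- sim$score
  if (!is.null(barred)) S[barred] <- NA_real_
  out <- list()
  for (a in sort(unmatched_a)) {
    row <- S[a, ]
    if (all(is.na(row))) next
    m <- max(row, na.rm = TRUE)
    hits <- names(row)[which(!is.na(row) & row == m)]
    if (length(hits) != 1 || !(hits %in% unmatched_b)) next
    b <- hits
    col <- S[, b]
    m2 <- max(col, na.rm = TRUE)
    back <- names(col)[which(!is.na(col) & col == m2)]
    if (length(back) == 1 && back == a)
      out[[a]] <- data.frame(a = a, b = b, score = m, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(a = character(), b = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Resolve methylation partners for SNP-mRNA matches by trio score
#'
#' For each aligned genotype-expression pair (g, e), candidate methylation
#' profiles are scored by the weighted trio score combining z_gm (genotype
#' vs methylation, within row g) and z_em (methylation vs expression,
#' within column e).  The best candidate is accepted when both component
#' z-scores are within the top 3 of their score vectors and the trio score
#' reaches `z_min`.  Matches are claimed greedily by decreasing trio score
#' so each methylation profile is used at most once.
#'
#' @param ge_aligned data frame `a` (genotype), `b` (expression) of aligned
#'   pairs.
#' @param sim_gm z-filled genotype x methylation `SimilarityMatrix`.
#' @param sim_em z-filled methylation x expression `SimilarityMatrix`.
#' @param omega trio weight (see [estimate_omega()]).
#' @param z_min acceptance threshold on the combined score (default 2.5).
#' @param top_k rank condition on each component (default 3).
#' @param combine `"average"` or `"sum"`, see [trio_score()].
#' @param barred_gm,barred_em optional gender-gate matrices.
#' @return data frame `g`, `e`, `m`, `z_gm`, `z_em`, `s3`.
#' @export
trio_resolve <- function(ge_aligned, sim_gm, sim_em, omega, z_min = 2.5,
                         top_k = 3, combine = "average",
                         barred_gm = NULL, barred_em = NULL) {
  empty <- data.frame(g = character(), e = character(), m = character(),
                      z_gm = numeric(), z_em = numeric(), s3 = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(ge_aligned) == 0) return(empty)
  mids <- rownames(sim_em$score)       # methylation profiles
  cands <- list()
  for (k in seq_len(nrow(ge_aligned))) {
    g <- ge_aligned$a[k]; e <- ge_aligned$b[k]
    zg <- sim_gm$z_row[g, mids]
    ze <- sim_em$z_col[mids, e]
    ok <- is.finite(zg) & is.finite(ze)
    if (!is.null(barred_gm)) ok <- ok & !barred_gm[g, mids]
    if (!is.null(barred_em)) ok <- ok & !t(barred_em[mids, e, drop = FALSE])[1, ]
    if (!any(ok)) next
    s3 <- trio_score(zg, ze, omega, combine)
    s3[!ok] <- NA_real_
    best <- which.max(s3)
    m <- mids[best]
    if (!within_top_n(zg[best], zg, top_k)) next
    if (!within_top_n(ze[best], ze, top_k)) next
    if (s3[best] < z_min) next
    cands[[length(cands) + 1]] <-
      data.frame(g = g, e = e, m = m, z_gm = unname(zg[best]),
                 z_em = unname(ze[best]), s3 = unname(s3[best]),
                 stringsAsFactors = FALSE)
  }
  if (length(cands) == 0) return(empty)
  res <- do.call(rbind, cands)
  res <- res[order(-res$s3, res$g), , drop = FALSE]
  res <- res[!duplicated(res$m), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Attribute the source of labeling errors from three pairwise alignments
#'
#' When two data types cross-match the same two subjects while the third
#' pair type self-matches them, the data type common to both cross-matched
#' pair types carries the mis-labeled profiles (e.g. cross-matched in
#' CNV-mRNA and mRNA-methylation but self-matched in CNV-methylation means
#' the mRNA labels are swapped).
#'
#' @param alignments named list (`GE`, `GM`, `EM`) of alignment data frames
#'   with columns `a`, `b`.
#' @param labels a `LabelAssignment` giving the (possibly wrong) initial
#'   subject of every profile.
#' @param types named character vector mapping the `a`/`b` roles of each
#'   pair type to data types.
#' @return data frame `subject_1`, `subject_2`, `mislabeled_type`,
#'   `evidence`; zero rows when nothing can be attributed.
#' @export
attribute_error_source <- function(alignments, labels,
                                   types = c(GE_a = "genotype", GE_b = "expression",
                                             GM_a = "genotype", GM_b = "methylation",
                                             EM_a = "methylation", EM_b = "expression")) {
  # cross pairs per pair type: unordered subject pairs matched across labels
  cross <- lapply(names(alignments), function(pt) {
    al <- alignments[[pt]]
    if (nrow(al) == 0) return(NULL)
    sa <- subjects_of(labels, types[[paste0(pt, "_a")]])[al$a]
    sb <- subjects_of(labels, types[[paste0(pt, "_b")]])[al$b]
    keep <- !is.na(sa) & !is.na(sb) & sa != sb
    if (!any(keep)) return(NULL)
    data.frame(pt = pt, s1 = pmin(sa[keep], sb[keep]),
               s2 = pmax(sa[keep], sb[keep]), stringsAsFactors = FALSE)
  })
  cross <- do.call(rbind, cross)
  if (is.null(cross) || nrow(cross) == 0)
    return(data.frame(subject_1 = character(), subject_2 = character(),
                      mislabeled_type = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (key in unique(paste(cross$s1, cross$s2))) {
    rows <- cross[paste(cross$s1, cross$s2) == key, ]
    if (length(unique(rows$pt)) < 2) next
    pts <- unique(rows$pt)
    shared <- Reduce(intersect, lapply(pts, function(pt)
      c(types[[paste0(pt, "_a")]], types[[paste0(pt, "_b")]])))
    if (length(shared) != 1) next
    out[[key]] <- data.frame(
      subject_1 = rows$s1[1], subject_2 = rows$s2[1], mislabeled_type = shared,
      evidence = sprintf("cross-matched in %s", paste(pts, collapse = "+")),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(subject_1 = character(), subject_2 = character(),
                      mislabeled_type = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Count significant cis pairs under an alignment
#'
#' The quality readout of the iteration: the number of significant cis
#' pairs of each pair type under the given sample alignments (or, when a
#' `LabelAssignment` is supplied, under its co-labeled pairs).
#'
#' @param profiles named list of `ProfileMatrix` objects.
#' @param alignments named list of alignment data frames (`GE`, `GM`, `EM`)
#'   or a `LabelAssignment`.
#' @param cfg a [run_config()].
#' @return Named integer vector of counts per pair type present.
#' @export
count_cis_pairs <- function(profiles, alignments, cfg = run_config()) {
  cis <- compute_cis_sets(profiles, alignments, cfg)
  vapply(cis, function(ps) nrow(ps$pairs), integer(1))
}

pair_type_roles <- function(profiles) {
  gt <- intersect(c("genotype", "cnv"), names(profiles))[1]
  roles <- list()
  if (!is.na(gt) && "expression" %in% names(profiles))
    roles$GE <- c(a = gt, b = "expression")
  if (!is.na(gt) && "methylation" %in% names(profiles))
    roles$GM <- c(a = gt, b = "methylation")
  if (all(c("methylation", "expression") %in% names(profiles)))
    roles$EM <- c(a = "methylation", b = "expression")
  roles
}

alignment_from_labels <- function(la, type_a, type_b) {
  sa <- subjects_of(la, type_a); sb <- subjects_of(la, type_b)
  shared <- sort(intersect(stats::na.omit(sa), stats::na.omit(sb)))
  data.frame(a = names(sa)[match(shared, sa)], b = names(sb)[match(shared, sb)],
             stringsAsFactors = FALSE)
}

compute_cis_sets <- function(profiles, alignments, cfg) {
  roles <- pair_type_roles(profiles)
  if (inherits(alignments, "LabelAssignment"))
    alignments <- lapply(roles, function(r)
      alignment_from_labels(alignments, r[["a"]], r[["b"]]))
  out <- list()
  for (pt in names(roles)) {
    r <- roles[[pt]]
    al <- alignments[[pt]][, c("a", "b"), drop = FALSE]
    a_pm <- profiles[[r[["a"]]]]; b_pm <- profiles[[r[["b"]]]]
    out[[pt]] <- suppressWarnings(
      if (pt == "EM")
        map_cis_methyl_mrna(a_pm, b_pm, al,
                            max_tss_bp = cfg$cis_window_methyl_bp,
                            p_threshold = cfg$p_threshold,
                            min_samples = cfg$min_samples)
      else if (r[["a"]] == "cnv")
        map_cis_cnv(a_pm, b_pm, al, window_bp = cfg$cis_window_cnv_bp,
                    p_threshold = cfg$p_threshold,
                    min_samples = cfg$min_samples)
      else
        additive_linear_scan(a_pm, b_pm, al, window_bp = cfg$cis_window_snp_bp,
                             p_threshold = cfg$p_threshold,
                             q_threshold = cfg$q_threshold,
                             min_samples = cfg$min_samples))
  }
  out
}

compute_similarities <- function(profiles, cis, alignments, cfg) {
  roles <- pair_type_roles(profiles)
  sims <- list()
  for (pt in names(roles)) {
    r <- roles[[pt]]
    al <- alignments[[pt]][, c("a", "b"), drop = FALSE]
    a_pm <- profiles[[r[["a"]]]]; b_pm <- profiles[[r[["b"]]]]
    sims[[pt]] <- zscore(
      if (pt == "EM") similarity_rank(cis[[pt]], a_pm, b_pm)
      else if (r[["a"]] == "cnv") {
        # CNV treated as a real-valued trait: rank-correlation over cis pairs
        similarity_rank(cis[[pt]], a_pm, b_pm)
      } else
        similarity_concordance(cis[[pt]], a_pm, b_pm, al,
                               method = cfg$concordance))
  }
  sims
}

# gender gate: TRUE where two profiles have conflicting non-ambiguous
# molecular gender calls
gender_bar_matrix <- function(gcalls, rows_type, cols_type, row_ids, col_ids) {
  bar <- matrix(FALSE, length(row_ids), length(col_ids),
                dimnames = list(row_ids, col_ids))
  gr <- gcalls[[rows_type]]; gc <- gcalls[[cols_type]]
  if (is.null(gr) || is.null(gc)) return(bar)
  cr <- setNames(gr$call, gr$profile_id)[row_ids]
  cc <- setNames(gc$call, gc$profile_id)[col_ids]
  known_r <- !is.na(cr) & cr != "ambiguous"
  known_c <- !is.na(cc) & cc != "ambiguous"
  bar[] <- outer(seq_along(cr), seq_along(cc), function(i, j)
    known_r[i] & known_c[j] & cr[i] != cc[j])
  bar
}

#' Run the full iterative multi-omics matching procedure
#'
#' Each round recomputes cis pairs under the current alignments, rebuilds
#' the similarity matrices, applies the gender gate, confirms and rescues
#' pairs duo by duo (genotype-expression first, then
#' genotype-methylation, then methylation-expression, in decreasing order
#' of signal confidence), resolves methylation partners by the trio score,
#' and chains pairwise matches through shared profiles.  Rounds repeat
#' until the alignments stop changing (or a previously seen state recurs,
#' or `max_rounds` is hit).  Labels are then corrected by propagating
#' subjects from the most trusted data type (genotype, then CNV, then
#' expression, then methylation) through the final alignments.
#'
#' @param profiles list of `ProfileMatrix` objects (>= 2 data types).
#' @param annotation subject annotation table (see [harmonize()]).
#' @param cfg a [run_config()].
#' @param mode `"trio"` (default) or `"duo"` (skips the three-way step;
#'   pairwise matches are still chained).
#' @return List of class `mod_match_result`: `labels` (corrected
#'   `LabelAssignment`), `matches` (per-pair report), `rounds` (per-round
#'   cis counts and change counts), `alignments`, `attribution`, `omega`,
#'   `top_n`, `genders`, `converged`.
#' @export
mod_match <- function(profiles, annotation, cfg = run_config(),
                      mode = c("trio", "duo")) {
  mode <- match.arg(mode)
  types <- vapply(profiles, function(p) p$data_type, character(1))
  names(profiles) <- types
  if (length(profiles) < 2) stop("need at least 2 data types")
  if ("stratum" %in% names(annotation) &&
      length(unique(annotation$stratum)) > 1)
    return(mod_match_stratified(profiles, annotation, cfg, mode))
  la0 <- harmonize(profiles, annotation)
  roles <- pair_type_roles(profiles)
  if (length(roles) == 0) stop("no supported pair type among supplied data types")
  gcalls <- infer_genders(profiles, la0, cfg)
  bars <- lapply(roles, function(r)
    gender_bar_matrix(gcalls, r[["a"]], r[["b"]],
                      profile_ids(profiles[[r[["a"]]]]),
                      profile_ids(profiles[[r[["b"]]]])))

  # initial alignments: co-labeled pairs passing the gender gate
  align <- list(); matches <- list()
  for (pt in names(roles)) {
    al <- alignment_from_labels(la0, roles[[pt]][["a"]], roles[[pt]][["b"]])
    conflict <- mapply(function(a, b) bars[[pt]][a, b], al$a, al$b)
    if (length(conflict) > 0 && any(conflict)) {
      matches[[paste0(pt, "-gender")]] <- data.frame(
        pair_type = pt, a = al$a[conflict], b = al$b[conflict],
        status = "gender_conflict", evidence = "gender", round = 0L,
        score = NA_real_, stringsAsFactors = FALSE)
      al <- al[!conflict, , drop = FALSE]
    }
    al$status <- "initial"; al$evidence <- "initial"
    align[[pt]] <- al
  }

  rounds <- list(); seen <- character(); converged <- FALSE
  omega_used <- NA_real_; top_n_used <- list(); trio_res <- NULL
  state_key <- function(al) paste(vapply(names(al), function(pt)
    paste(pt, paste(sort(paste(al[[pt]]$a, al[[pt]]$b)), collapse = ";")),
    character(1)), collapse = "|")

  for (round in seq_len(cfg$max_rounds)) {
    cis <- compute_cis_sets(profiles, align, cfg)
    sims <- compute_similarities(profiles, cis, align, cfg)
    new_align <- list()
    for (pt in names(roles)) {
      sim <- sims[[pt]]
      n <- determine_top_n(sim, cfg$top_n_cap, cfg$topn_ttest_p)
      top_n_used[[pt]] <- n
      dm <- duo_match(sim, align[[pt]], n, bars[[pt]])
      kept <- dm[dm$status == "self_matched", , drop = FALSE]
      kept$status <- if (nrow(kept) == 0) character() else
        ifelse(align[[pt]]$status[match(paste(kept$a, kept$b),
                                        paste(align[[pt]]$a, align[[pt]]$b))]
               %in% c("initial", "self_matched"),
               "self_matched", "rescued")
      kept$evidence <- if (nrow(kept) == 0) character() else paste0("duo-", pt)
      pool_a <- setdiff(rownames(sim$score), kept$a)
      pool_b <- setdiff(colnames(sim$score), kept$b)
      rs <- reciprocal_rescue(sim, pool_a, pool_b, bars[[pt]])
      if (nrow(rs) > 0) {
        rs$status <- "rescued"; rs$evidence <- paste0("rescue-", pt)
        kept <- rbind(kept[, c("a", "b", "status", "evidence")],
                      rs[, c("a", "b", "status", "evidence")])
      } else kept <- kept[, c("a", "b", "status", "evidence")]
      new_align[[pt]] <- kept[order(kept$a), , drop = FALSE]
    }

    if (mode == "trio" && all(c("GE", "GM", "EM") %in% names(roles))) {
      omega_used <- if (identical(cfg$omega, "auto"))
        estimate_omega(sims$GM, sims$EM) else as.numeric(cfg$omega)
      tr <- trio_resolve(new_align$GE, sims$GM, sims$EM, omega_used,
                         z_min = cfg$trio_z_min, combine = cfg$trio_combine,
                         barred_gm = bars$GM, barred_em = bars$EM)
      trio_res <- tr
      if (nrow(tr) > 0) {
        free <- !(tr$m %in% new_align$GM$b) & !(tr$g %in% new_align$GM$a)
        if (any(free))
          new_align$GM <- rbind(new_align$GM,
            data.frame(a = tr$g[free], b = tr$m[free], status = "rescued",
                       evidence = "trio", stringsAsFactors = FALSE))
        free <- !(tr$m %in% new_align$EM$a) & !(tr$e %in% new_align$EM$b)
        if (any(free))
          new_align$EM <- rbind(new_align$EM,
            data.frame(a = tr$m[free], b = tr$e[free], status = "rescued",
                       evidence = "trio", stringsAsFactors = FALSE))
      }
    }

    # chain matches through shared profiles (g-e and g-m imply m-e, etc.)
    new_align <- chain_alignments(new_align, roles)
    new_align <- lapply(new_align, function(al) {
      al <- al[order(al$a), , drop = FALSE]; rownames(al) <- NULL; al
    })

    changes <- sum(vapply(names(roles), function(pt) {
      old <- paste(align[[pt]]$a, align[[pt]]$b)
      new <- paste(new_align[[pt]]$a, new_align[[pt]]$b)
      length(setdiff(old, new)) + length(setdiff(new, old))
    }, numeric(1)))
    rounds[[round]] <- data.frame(
      round = round, t(vapply(cis, function(ps) nrow(ps$pairs), integer(1))),
      n_changes = changes, stringsAsFactors = FALSE)
    key <- state_key(new_align)
    align <- new_align
    if (changes == 0) { converged <- TRUE; break }
    if (key %in% seen) {
      warning("alignment state cycle detected; stopping", call. = FALSE)
      break
    }
    seen <- c(seen, key)
  }

  labels <- propagate_labels(la0, align, roles, profiles)
  matches <- c(matches, lapply(names(align), function(pt) {
    al <- align[[pt]]
    sa <- subjects_of(la0, roles[[pt]][["a"]])[al$a]
    sb <- subjects_of(la0, roles[[pt]][["b"]])[al$b]
    cross <- !is.na(sa) & !is.na(sb) & sa != sb
    data.frame(pair_type = pt, a = al$a, b = al$b,
               status = ifelse(cross & al$status != "self_matched",
                               "cross_matched", al$status),
               evidence = al$evidence, round = round, score = NA_real_,
               stringsAsFactors = FALSE)
  }))
  # unmatched profiles
  for (pt in names(roles)) {
    r <- roles[[pt]]
    ua <- setdiff(profile_ids(profiles[[r[["a"]]]]), align[[pt]]$a)
    ub <- setdiff(profile_ids(profiles[[r[["b"]]]]), align[[pt]]$b)
    if (length(ua) + length(ub) > 0)
      matches[[paste0(pt, "-unmatched")]] <- data.frame(
        pair_type = pt, a = c(ua, rep(NA_character_, length(ub))),
        b = c(rep(NA_character_, length(ua)), ub), status = "unmatched",
        evidence = "none", round = round, score = NA_real_,
        stringsAsFactors = FALSE)
  }
  structure(list(
    labels = labels,
    matches = do.call(rbind, c(matches, list(make.row.names = FALSE))),
    rounds = do.call(rbind, rounds),
    alignments = align,
    attribution = attribute_error_source(
      align[intersect(c("GE", "GM", "EM"), names(align))], la0,
      types = unlist(lapply(names(roles), function(pt)
        setNames(as.list(roles[[pt]]), paste0(pt, c("_a", "_b")))))),
    omega = omega_used, top_n = top_n_used, trio = trio_res,
    genders = gcalls, converged = converged, mode = mode),
    class = "mod_match_result")
}

# cis pairs are discovered and used within stratum: partition the cohort by
# the annotation's stratum column (via each profile's initial label) and run
# the procedure independently per stratum, then merge the reports
mod_match_stratified <- function(profiles, annotation, cfg, mode) {
  strata <- sort(unique(annotation$stratum))
  la0 <- harmonize(profiles, annotation)
  parts <- lapply(strata, function(st) {
    ann <- annotation[annotation$stratum == st, , drop = FALSE]
    profs <- lapply(profiles, function(pm) {
      subj <- subjects_of(la0, pm$data_type)
      keep <- profile_ids(pm)[!is.na(subj) & subj %in% ann$subject_id]
      pm$values <- pm$values[, keep, drop = FALSE]
      pm
    })
    dropped <- sum(vapply(profiles, ncol, integer(1))) -
      sum(vapply(profs, ncol, integer(1)))
    res <- mod_match(profs, ann[, setdiff(names(ann), "stratum"), drop = FALSE],
                     cfg, mode)
    res$rounds$stratum <- st
    res$matches$stratum <- st
    res
  })
  merged <- parts[[1]]
  if (length(parts) > 1) for (p in parts[-1]) {
    for (t in names(merged$labels))
      merged$labels[[t]] <- rbind(merged$labels[[t]], p$labels[[t]])
    merged$matches <- rbind(merged$matches, p$matches)
    merged$rounds <- rbind(merged$rounds, p$rounds)
    for (pt in names(merged$alignments))
      merged$alignments[[pt]] <- rbind(merged$alignments[[pt]],
                                       p$alignments[[pt]])
    merged$attribution <- rbind(merged$attribution, p$attribution)
    merged$converged <- merged$converged && p$converged
  }
  unassigned <- vapply(profiles, function(pm)
    sum(is.na(subjects_of(la0, pm$data_type))), integer(1))
  if (sum(unassigned) > 0)
    warning(sprintf("%d unlabeled profile(s) excluded from stratified matching",
                    sum(unassigned)), call. = FALSE)
  merged
}

# add implied pairs: if g-e (GE) and g-m (GM) are aligned, imply m-e (EM)
# for profiles not already aligned in EM; analogous completions for GE/GM
chain_alignments <- function(align, roles) {
  pts <- names(roles)
  if (!all(c("GE", "GM", "EM") %in% pts)) return(align)
  add_chain <- function(al, new_a, new_b) {
    free <- !(new_a %in% al$a) & !(new_b %in% al$b)
    if (!any(free)) return(al)
    rbind(al, data.frame(a = new_a[free], b = new_b[free], status = "rescued",
                         evidence = "chain", stringsAsFactors = FALSE))
  }
  ge <- align$GE; gm <- align$GM; em <- align$EM
  shared <- intersect(ge$a, gm$a)
  if (length(shared) > 0)
    align$EM <- add_chain(em, gm$b[match(shared, gm$a)], ge$b[match(shared, ge$a)])
  shared <- intersect(ge$b, em$b)          # e in both GE and EM -> g-m
  if (length(shared) > 0)
    align$GM <- add_chain(gm, ge$a[match(shared, ge$b)], em$a[match(shared, em$b)])
  shared <- intersect(gm$b, em$a)          # m in both GM and EM -> g-e
  if (length(shared) > 0)
    align$GE <- add_chain(ge, gm$a[match(shared, gm$b)], em$b[match(shared, em$a)])
  align
}

# propagate subject ids through final alignments from the most trusted type
propagate_labels <- function(la0, align, roles, profiles) {
  trust <- c(genotype = 4, cnv = 3, expression = 2, methylation = 1)
  la <- la0
  ord <- intersect(c("GE", "GM", "EM"), names(align))
  for (pt in ord) {
    r <- roles[[pt]]; al <- align[[pt]]
    if (nrow(al) == 0) next
    anchor_is_a <- trust[r[["a"]]] >= trust[r[["b"]]]
    anchor_type <- if (anchor_is_a) r[["a"]] else r[["b"]]
    target_type <- if (anchor_is_a) r[["b"]] else r[["a"]]
    anchor_ids <- if (anchor_is_a) al$a else al$b
    target_ids <- if (anchor_is_a) al$b else al$a
    subj <- subjects_of(la, anchor_type)[anchor_ids]
    tl <- la[[target_type]]
    for (k in seq_along(target_ids)) {
      if (is.na(subj[k])) next
      i <- match(target_ids[k], tl$profile_id)
      if (is.na(tl$subject_id[i]) || tl$subject_id[i] != subj[k]) {
        if (tl$provenance[i] %in% c(NA, "initial")) {
          tl$subject_id[i] <- unname(subj[k])
          tl$provenance[i] <- al$evidence[k]
        }
      }
    }
    # a relabel may have claimed a subject still held by an initial label
    dup <- duplicated(tl$subject_id, incomparables = NA) |
      duplicated(tl$subject_id, incomparables = NA, fromLast = TRUE)
    displace <- dup & tl$provenance %in% "initial"
    keepers <- tl$subject_id[dup & !(tl$provenance %in% "initial")]
    displace <- displace & tl$subject_id %in% keepers
    if (any(displace)) {
      tl$subject_id[displace] <- NA_character_
      tl$provenance[displace] <- "displaced"
    }
    la[[target_type]] <- tl
  }
  la
}

#' @export
print.mod_match_result <- function(x, ...) {
  cat(sprintf("mod_match (%s): %d round(s)%s\n", x$mode, nrow(x$rounds),
              if (x$converged) ", converged" else ""))
  st <- table(x$matches$status)
  cat("  pair status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  if (nrow(x$attribution) > 0)
    cat(sprintf("  attributed errors: %d (types: %s)\n", nrow(x$attribution),
                paste(unique(x$attribution$mislabeled_type), collapse = ", ")))
  invisible(x)
}

#' Write the match and round reports of a run
#'
#' @param result a `mod_match_result`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_match_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labels(result$labels, file.path(dir, "corrected_labels.tsv"))
  write.table(result$matches, file.path(dir, "match_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$rounds, file.path(dir, "round_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(result$attribution) > 0)
    write.table(result$attribution, file.path(dir, "error_attribution.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
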