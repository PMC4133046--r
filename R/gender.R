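#' X-chromosome heterozygosity inbreeding coefficient
#'
#' Computes, per profile, the excess-homozygosity statistic
#' F = (O_hom - E_hom) / (N - E_hom) over non-missing X-chromosome SNPs,
#' where E_hom = sum_k (1 - 2 p_k (1 - p_k)) under Hardy-Weinberg with p_k
#' the cohort allele frequency at SNP k and N the number of SNPs used.
#' Males are hemizygous on X, so their calls are homozygous and F is near 1;
#' females are near 0.  Allele frequencies are estimated from all profiles
#' in the matrix (including the one under test; the difference is O(1/n)).
#'
#' @param geno genotype `ProfileMatrix` (dosage coding 0/1/2).
#' @param x_chrom chromosome name(s) treated as X (default `"chrX"`/`"X"`).
#' @param min_snps minimum non-missing X SNPs for a value; profiles below it
#'   get `NA` with a warning.
#' @return Named numeric vector of F, one entry per profile.
#' @export
x_heterozygosity_F <- function(geno, x_chrom = c("chrX", "X"), min_snps = 50) {
  xf <- geno$positions$feature_id[geno$positions$chrom %in% x_chrom]
  if (length(xf) == 0) stop("no X-chromosome SNPs in genotype positions")
  g <- geno$values[xf, , drop = FALSE]
  p <- rowMeans(g, na.rm = TRUE) / 2            # cohort allele frequency
  e_hom_k <- 1 - 2 * p * (1 - p)
  obs <- !is.na(g)
  n_used <- colSums(obs)
  o_hom <- colSums(g != 1, na.rm = TRUE)
  e_hom <- colSums(e_hom_k * obs)
  f <- (o_hom - e_hom) / (n_used - e_hom)
  low <- n_used < min_snps
  if (any(low)) {
    warning(sprintf("%d profile(s) with < %d non-missing X SNPs: no F call",
                    sum(low), min_snps), call. = FALSE)
    f[low] <- NA_real_
  }
  f
}

#' Call gender from the inbreeding coefficient
#'
#' F above `male_min` calls male, below `female_max` calls female, anything
#' in between (or `NA`) is ambiguous and excluded from gender gating.
#'
#' @param F numeric vector of inbreeding coefficients (named by profile).
#' @param male_min,female_max call thresholds.
#' @return data frame `profile_id`, `source`, `call`, `statistic`.
#' @export
call_gender_from_F <- function(F, male_min = 0.8, female_max = 0.2) {
  call <- rep("ambiguous", length(F))
  call[!is.na(F) & F > male_min] <- "male"
  call[!is.na(F) & F < female_max] <- "female"
  data.frame(profile_id = names(F) %||% seq_along(F), source = "genotype",
             call = call, statistic = unname(F), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the Y-chromosome feature that best separates the sexes
#'
#' Among features placed on the Y chromosome, picks the one with the
#' smallest Welch two-sample t-test p-value between profiles annotated male
#' and female.
#'
#' @param pm expression or methylation-intensity `ProfileMatrix`.
#' @param genders data frame `profile_id`, `call` giving the (clinical)
#'   gender of each profile; at least 2 per sex required.
#' @param y_chrom chromosome name(s) treated as Y.
#' @return list `feature_id`, `p_value`.
#' @export
select_sex_marker <- function(pm, genders, y_chrom = c("chrY", "Y")) {
  yf <- pm$positions$feature_id[pm$positions$chrom %in% y_chrom]
  if (length(yf) == 0)
    stop("no Y-chromosome feature available; supply a sex marker explicitly")
  sex <- genders$call[match(profile_ids(pm), genders$profile_id)]
  males <- which(sex == "male"); females <- which(sex == "female")
  if (length(yf) == 1)
    return(list(feature_id = yf, p_value = NA_real_))
  if (length(males) < 2 || length(females) < 2)
    stop("need >= 2 annotated profiles per sex to rank Y markers")
  pv <- vapply(yf, function(f) {
    v <- pm$values[f, ]
    tryCatch(t.test(v[males], v[females])$p.value, error = function(e) 1)
  }, numeric(1))
  list(feature_id = yf[which.min(pv)], p_value = min(pv))
}

# 1-D two-means: midpoint between the two cluster centers (Lloyd iterations
# from the extremes; deterministic).
two_means_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) return(NA_real_)
  c1 <- min(x); c2 <- max(x)
  for (i in 1:100) {
    grp <- abs(x - c1) <= abs(x - c2)
    n1 <- mean(x[grp]); n2 <- mean(x[!grp])
    if (isTRUE(all.equal(c(c1, c2), c(n1, n2)))) break
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}

#' Call gender from a sex-marker value
#'
#' Profiles above the threshold receive the high-group gender (male for
#' Y-chromosome markers: present Y DNA/expression gives high signal).  When
#' no threshold is supplied it is learned as the midpoint between the two
#' cluster centers of a 1-D two-means split of the marker across profiles.
#'
#' @param values named numeric vector, marker value per profile.
#' @param threshold decision boundary; `NULL` to learn it.
#' @param polarity `"male_high"` (Y markers) or `"female_high"`.
#' @param source label recorded in the output (`"expression"` etc.).
#' @param margin half-width of an ambiguity zone around the threshold.
#' @return data frame `profile_id`, `source`, `call`, `statistic`.
#' @export
call_gender_from_marker <- function(values, threshold = NULL,
                                    polarity = c("male_high", "female_high"),
                                    source = "expression", margin = 0) {
  polarity <- match.arg(polarity)
  if (is.null(threshold)) threshold <- two_means_threshold(values)
  call <- rep("ambiguous", length(values))
  if (is.na(threshold)) {
    warning("degenerate (constant) sex marker: all calls ambiguous", call. = FALSE)
  } else {
    hi <- if (polarity == "male_high") "male" else "female"
    lo <- setdiff(c("male", "female"), hi)
    call[!is.na(values) & values > threshold + margin] <- hi
    call[!is.na(values) & values < threshold - margin] <- lo
  }
  data.frame(profile_id = names(values) %||% seq_along(values), source = source,
             call = call, statistic = unname(values), stringsAsFactors = FALSE)
}

#' Compare molecular gender calls with clinical annotation
#'
#' Joins per-source molecular calls to the clinical gender of the subject
#' each profile is currently labeled as, flags mismatches, and summarises a
#' mismatch rate per source (mismatches / non-ambiguous calls, as percent
#' rounded to one decimal).  Ambiguous calls are excluded from both the
#' numerator and denominator.
#'
#' @param calls data frame of molecular calls (`profile_id`, `source`,
#'   `call`, `statistic`), typically several sources stacked.
#' @param clinical data frame `profile_id`, `call` with the clinically
#'   annotated gender per profile label.
#' @return list with `table` (per profile: calls and mismatch flags) and
#'   `rates` (per source: `n_called`, `n_mismatch`, `rate_pct`).
#' @export
gender_consistency <- function(calls, clinical) {
  clin <- setNames(clinical$call, clinical$profile_id)
  tab <- calls
  tab$clinical <- unname(clin[tab$profile_id])
  tab$mismatch <- tab$call != "ambiguous" & !is.na(tab$clinical) &
    tab$clinical != "ambiguous" & tab$call != tab$clinical
  called <- tab$call != "ambiguous" & !is.na(tab$clinical) & tab$clinical != "ambiguous"
  rates <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$source), function(i) {
    n <- sum(called[i]); m <- sum(tab$mismatch[i])
    data.frame(source = tab$source[i[1]], n_called = n, n_mismatch = m,
               rate_pct = if (n > 0) round(100 * m / n, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL
  list(table = tab, rates = rates)
}

# Per-profile inferred genders for all data types present; used as the
# matching gate.  Genotype -> F on X SNPs; expression / methylation -> best
# Y marker (fixed threshold from config if given, else learned).
infer_genders <- function(profiles, la, cfg) {
  ann <- attr(la, "annotation")
  out <- list()
  for (t in names(profiles)) {
    pm <- profiles[[t]]
    gc <- tryCatch({
      if (t == "genotype") {
        f <- x_heterozygosity_F(pm, min_snps = cfg$min_x_snps)
        call_gender_from_F(f, cfg$gender_F_male, cfg$gender_F_female)
      } else {
        clin <- clinical_calls(pm, la[[t]], ann)
        mk <- select_sex_marker(pm, clin)
        call_gender_from_marker(pm$values[mk$feature_id, ],
                                threshold = cfg$marker_threshold,
                                source = t)
      }
    }, error = function(e) {
      msg("gender inference skipped for %s: %s", t, conditionMessage(e))
      NULL
    })
    if (!is.null(gc)) { gc$source <- t; out[[t]] <- gc }
  }
  out
}

clinical_calls <- function(pm, labels, ann) {
  subj <- labels$subject_id[match(profile_ids(pm), labels$profile_id)]
  g <- if ("gender" %in% names(ann)) ann$gender[match(subj, ann$subject_id)]
       else rep(NA_character_, length(subj))
  data.frame(profile_id = profile_ids(pm),
             call = ifelse(is.na(g), "ambiguous", g), stringsAsFactors = FALSE)
}
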