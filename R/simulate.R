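# Synthetic multi-omics cohorts with planted cis structure, sex markers and
# injected label errors.  Planted features are laid out in private 4 Mb
# blocks so every planted pair falls inside its cis window and nothing else
# does; levels are on a continuous M-value-like scale.

#' Simulation configuration
#'
#' Defaults describe the study conditions the test suite and experiments
#' run under: 60 subjects, 60 planted cis units per pair type with an
#' additive allelic effect of 3 noise SDs, methylation-expression coupling
#' of -0.7, an 8-SD sex-marker effect, and a 3% label error rate between
#' expression and genotype (errors in the expression labels), with
#' methylation errors varied by the experiments.
#'
#' @param n_subjects cohort size.
#' @param n_cis_esnp,n_cis_msnp,n_cis_em planted cis units per pair type.
#' @param n_null_snps,n_null_genes,n_null_probes unassociated features.
#' @param n_x_snps X-chromosome SNPs carrying the sex signal; the default
#'   keeps the sampling SD of the heterozygosity statistic F (about
#'   1/sqrt(n)) well clear of the 0.2/0.8 call thresholds.
#' @param maf_range allele-frequency range for all SNPs.
#' @param effect_size_beta additive effect per allele, in noise-SD units.
#' @param noise_sd residual SD of expression/methylation levels.
#' @param methyl_expr_rho target |correlation| of planted methyl-mRNA
#'   pairs; the sign is negative by default (promoter methylation
#'   represses).
#' @param methyl_expr_sign +1 or -1.
#' @param sex_marker_effect male-female shift of the Y markers, in
#'   noise-SD units.
#' @param missing_rate genotype missingness rate.
#' @param errors_per_type named counts of mislabeled profiles per data
#'   type (each must be <= `n_subjects`).
#' @param error_mode `"swap"` (disjoint 2-cycles) or `"shuffle"`
#'   (derangement of the chosen labels).
#' @param seed RNG seed; everything is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 60,
                       n_cis_esnp = 60, n_cis_msnp = 60, n_cis_em = 60,
                       n_null_snps = 30, n_null_genes = 30, n_null_probes = 30,
                       n_x_snps = 400,
                       maf_range = c(0.2, 0.5),
                       effect_size_beta = 3, noise_sd = 1,
                       methyl_expr_rho = 0.7, methyl_expr_sign = -1,
                       sex_marker_effect = 8,
                       missing_rate = 0,
                       errors_per_type = c(expression = 2 * round(0.03 * n_subjects / 2)),
                       error_mode = c("swap", "shuffle"),
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_cis_esnp = as.integer(n_cis_esnp),
              n_cis_msnp = as.integer(n_cis_msnp),
              n_cis_em = as.integer(n_cis_em),
              n_null_snps = as.integer(n_null_snps),
              n_null_genes = as.integer(n_null_genes),
              n_null_probes = as.integer(n_null_probes),
              n_x_snps = as.integer(n_x_snps),
              maf_range = maf_range,
              effect_size_beta = effect_size_beta, noise_sd = noise_sd,
              methyl_expr_rho = methyl_expr_rho,
              methyl_expr_sign = methyl_expr_sign,
              sex_marker_effect = sex_marker_effect,
              missing_rate = missing_rate,
              errors_per_type = errors_per_type,
              error_mode = match.arg(error_mode), seed = as.integer(seed))
  stopifnot(cfg$n_subjects > 0, all(cfg$maf_range > 0), all(cfg$maf_range < 1),
            all(cfg$errors_per_type <= cfg$n_subjects), cfg$noise_sd > 0,
            cfg$methyl_expr_rho >= 0, cfg$methyl_expr_rho < 1)
  class(cfg) <- "sim_config"
  cfg
}

# block layout: unit k of track t gets a private 4 Mb block on a cycling
# autosome; tracks interleave so blocks never approach each other's cis
# windows and coordinates stay within 32-bit range
N_TRACKS <- 6
block_pos <- function(k, track) {
  chrom <- paste0("chr", (k - 1) %% 22 + 1)
  base <- (((k - 1) %/% 22) * N_TRACKS + track) * 4e6
  if (base + 4e6 > .Machine$integer.max)
    stop("infeasible layout: too many features per chromosome window")
  list(chrom = chrom, base = base)
}

#' Simulate a multi-omics cohort
#'
#' Generates genotype, expression and methylation profile matrices with
#' planted cis-eSNPs (expression = beta x dosage + noise), cis-mSNPs
#' (likewise for methylation), methyl-mRNA pairs sharing a latent factor,
#' X-chromosome heterozygosity and Y-marker sex structure, plus
#' unassociated filler features.  Label errors from
#' `cfg$errors_per_type` are injected via [inject_errors()].
#'
#' @param cfg a [sim_config()].
#' @return List: `profiles` (named list of `ProfileMatrix`), `annotation`
#'   (subject table with gender), `truth` (true subject per profile,
#'   planted pair lists, planted sexes, injected error log).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  withr_seed(cfg$seed, {
    n <- cfg$n_subjects
    subj <- sprintf("S%03d", seq_len(n))
    sex <- sample(rep(c("male", "female"), length.out = n))
    ann <- data.frame(subject_id = subj, gender = sex, stringsAsFactors = FALSE)

    maf <- function(k) runif(k, cfg$maf_range[1], cfg$maf_range[2])
    rgeno <- function(k) {
      p <- maf(k)
      matrix(rbinom(k * n, 2, rep(p, n)), k, n)
    }

    # --- genotypes -------------------------------------------------------
    g_esnp <- rgeno(cfg$n_cis_esnp)
    g_msnp <- rgeno(cfg$n_cis_msnp)
    g_null <- rgeno(cfg$n_null_snps)
    px <- maf(cfg$n_x_snps)
    g_x <- matrix(0, cfg$n_x_snps, n)
    for (j in seq_len(n))
      g_x[, j] <- if (sex[j] == "male") 2 * rbinom(cfg$n_x_snps, 1, px)
                  else rbinom(cfg$n_x_snps, 2, px)
    G <- rbind(g_esnp, g_msnp, g_null, g_x)
    snp_ids <- c(sprintf("esnp%03d", seq_len(cfg$n_cis_esnp)),
                 sprintf("msnp%03d", seq_len(cfg$n_cis_msnp)),
                 sprintf("nsnp%03d", seq_len(cfg$n_null_snps)),
                 sprintf("xsnp%03d", seq_len(cfg$n_x_snps)))
    rownames(G) <- snp_ids
    if (cfg$missing_rate > 0)
      G[matrix(runif(length(G)) < cfg$missing_rate, nrow(G))] <- NA

    # --- expression ------------------------------------------------------
    b <- cfg$effect_size_beta * cfg$noise_sd
    e_cis <- b * g_esnp + matrix(rnorm(cfg$n_cis_esnp * n, sd = cfg$noise_sd),
                                 cfg$n_cis_esnp, n)
    rho <- cfg$methyl_expr_rho
    a <- sqrt(rho / (1 - rho))
    L <- matrix(rnorm(cfg$n_cis_em * n), cfg$n_cis_em, n)
    e_em <- a * L + matrix(rnorm(cfg$n_cis_em * n), cfg$n_cis_em, n)
    m_em <- cfg$methyl_expr_sign * a * L +
      matrix(rnorm(cfg$n_cis_em * n), cfg$n_cis_em, n)
    e_null <- matrix(rnorm(cfg$n_null_genes * n), cfg$n_null_genes, n)
    y_expr <- 4 + cfg$sex_marker_effect * cfg$noise_sd * (sex == "male") +
      rnorm(n, sd = cfg$noise_sd)
    E <- rbind(e_cis, e_em, e_null, y_expr)
    gene_ids <- c(sprintf("egene%03d", seq_len(cfg$n_cis_esnp)),
                  sprintf("emgene%03d", seq_len(cfg$n_cis_em)),
                  sprintf("ngene%03d", seq_len(cfg$n_null_genes)),
                  "ygene_RPS4Y1like")
    rownames(E) <- gene_ids

    # --- methylation -----------------------------------------------------
    m_cis <- b * g_msnp + matrix(rnorm(cfg$n_cis_msnp * n, sd = cfg$noise_sd),
                                 cfg$n_cis_msnp, n)
    m_null <- matrix(rnorm(cfg$n_null_probes * n), cfg$n_null_probes, n)
    y_meth <- 4 + cfg$sex_marker_effect * cfg$noise_sd * (sex == "male") +
      rnorm(n, sd = cfg$noise_sd)
    M <- rbind(m_cis, m_em, m_null, y_meth)
    probe_ids <- c(sprintf("mprobe%03d", seq_len(cfg$n_cis_msnp)),
                   sprintf("emprobe%03d", seq_len(cfg$n_cis_em)),
                   sprintf("nprobe%03d", seq_len(cfg$n_null_probes)),
                   "yprobe")
    rownames(M) <- probe_ids

    # --- positions -------------------------------------------------------
    pos <- function(ids, track, offset_bp, width) {
      do.call(rbind, lapply(seq_along(ids), function(k) {
        bp <- block_pos(k, track)
        data.frame(feature_id = ids[k], chrom = bp$chrom,
                   start = bp$base + offset_bp,
                   end = bp$base + offset_bp + width, stringsAsFactors = FALSE)
      }))
    }
    snp_pos <- rbind(
      pos(sprintf("esnp%03d", seq_len(cfg$n_cis_esnp)), 0, 1e3, 0),
      pos(sprintf("msnp%03d", seq_len(cfg$n_cis_msnp)), 1, 1e3, 0),
      pos(sprintf("nsnp%03d", seq_len(cfg$n_null_snps)), 3, 1e3, 0),
      data.frame(feature_id = sprintf("xsnp%03d", seq_len(cfg$n_x_snps)),
                 chrom = "chrX", start = seq_len(cfg$n_x_snps) * 1e5,
                 end = seq_len(cfg$n_x_snps) * 1e5, stringsAsFactors = FALSE))
    gene_pos <- rbind(
      pos(sprintf("egene%03d", seq_len(cfg$n_cis_esnp)), 0, 5e4, 1e4),
      pos(sprintf("emgene%03d", seq_len(cfg$n_cis_em)), 2, 5e4, 1e4),
      pos(sprintf("ngene%03d", seq_len(cfg$n_null_genes)), 4, 5e4, 1e4),
      data.frame(feature_id = "ygene_RPS4Y1like", chrom = "chrY",
                 start = 1e5, end = 1.1e5, stringsAsFactors = FALSE))
    probe_pos <- rbind(
      pos(sprintf("mprobe%03d", seq_len(cfg$n_cis_msnp)), 1, 5e4, 1),
      pos(sprintf("emprobe%03d", seq_len(cfg$n_cis_em)), 2, 5.2e4, 1),
      pos(sprintf("nprobe%03d", seq_len(cfg$n_null_probes)), 5, 5e4, 1),
      data.frame(feature_id = "yprobe", chrom = "chrY",
                 start = 5e6, end = 5e6 + 1, stringsAsFactors = FALSE))

    mk <- function(vals, type, prefix, ppos) {
      colnames(vals) <- paste0(prefix, subj)
      profile_matrix(vals, type, ppos)
    }
    profiles <- list(
      genotype = mk(G, "genotype", "GT_", snp_pos),
      expression = mk(E, "expression", "EX_", gene_pos),
      methylation = mk(M, "methylation", "ME_", probe_pos))

    truth <- list(
      true_subject = lapply(profiles, function(pm)
        setNames(sub("^[A-Z]+_", "", profile_ids(pm)), profile_ids(pm))),
      planted = list(
        eSNP = data.frame(source = sprintf("esnp%03d", seq_len(cfg$n_cis_esnp)),
                          target = sprintf("egene%03d", seq_len(cfg$n_cis_esnp)),
                          stringsAsFactors = FALSE),
        mSNP = data.frame(source = sprintf("msnp%03d", seq_len(cfg$n_cis_msnp)),
                          target = sprintf("mprobe%03d", seq_len(cfg$n_cis_msnp)),
                          stringsAsFactors = FALSE),
        methyl_mRNA = data.frame(source = sprintf("emprobe%03d", seq_len(cfg$n_cis_em)),
                                 target = sprintf("emgene%03d", seq_len(cfg$n_cis_em)),
                                 stringsAsFactors = FALSE)),
      sexes = setNames(sex, subj),
      errors = data.frame(data_type = character(), profile_id = character(),
                          labeled_subject = character(),
                          true_subject = character(), stringsAsFactors = FALSE),
      error_rate_pct = setNames(numeric(0), character(0)))

    out <- list(profiles = profiles, annotation = ann, truth = truth)
    if (sum(cfg$errors_per_type) > 0)
      out <- inject_errors(out, cfg$errors_per_type, cfg$error_mode,
                           seed = cfg$seed + 1000L)
    out
  })
}

#' Inject label errors into a simulated cohort
#'
#' In `"swap"` mode the requested number of mislabeled profiles is formed
#' from disjoint label swaps (2-cycles), so the count must be even; in
#' `"shuffle"` mode the chosen profiles' labels undergo a random
#' derangement.  The truth channel records every move and the per-type
#' injected error rate (percent of profiles mislabeled).
#'
#' @param sim a cohort from [simulate_cohort()].
#' @param errors_per_type named counts of mislabeled profiles.
#' @param mode `"swap"` or `"shuffle"`.
#' @param seed RNG seed.
#' @return The cohort with relabeled profiles and an updated truth log.
#' @export
inject_errors <- function(sim, errors_per_type, mode = c("swap", "shuffle"),
                          seed = 1L) {
  mode <- match.arg(mode)
  withr_seed(seed, {
    for (t in names(errors_per_type)) {
      k <- errors_per_type[[t]]
      if (k == 0) next
      pm <- sim$profiles[[t]]
      if (is.null(pm)) stop("no ", t, " profiles to inject errors into")
      ids <- profile_ids(pm)
      if (k > length(ids)) stop("more errors than profiles for ", t)
      if (mode == "swap") {
        if (k %% 2 != 0) stop("swap mode needs an even error count, got ", k)
        chosen <- sample(ids, k)
        new <- chosen
        for (i in seq(1, k, by = 2))
          new[c(i, i + 1)] <- chosen[c(i + 1, i)]
      } else {
        chosen <- sample(ids, k)
        repeat {
          new <- sample(chosen)
          if (all(new != chosen)) break
        }
      }
      # profile `chosen[i]`'s data now carries label `new[i]`
      cn <- colnames(pm$values)
      cn[match(chosen, cn)] <- new
      colnames(pm$values) <- cn
      sim$profiles[[t]] <- pm
      strip <- function(x) sub("^[A-Z]+_", "", x)
      ts <- sim$truth$true_subject[[t]]
      ts[new] <- strip(chosen)
      sim$truth$true_subject[[t]] <- ts
      sim$truth$errors <- rbind(sim$truth$errors, data.frame(
        data_type = t, profile_id = new, labeled_subject = strip(new),
        true_subject = strip(chosen), stringsAsFactors = FALSE))
      sim$truth$error_rate_pct[t] <- 100 * k / ncol(sim$profiles[[t]]$values)
    }
    sim
  })
}

#' Score a matching result against the simulation truth
#'
#' For each pair type, an aligned profile pair is correct when both
#' profiles truly belong to the same subject.  Coverage is correct pairs
#' divided by the number of subjects carrying both data types; the true
#' positive rate is correct pairs divided by all aligned pairs (`NA` when
#' nothing aligned).  Also reports, per data type, the fraction of final
#' labels equal to the true subject.
#'
#' @param result a `mod_match_result` from [mod_match()].
#' @param truth the truth channel of a simulated cohort.
#' @return List: `pairs` (data frame per pair type: `n_aligned`,
#'   `n_correct`, `coverage`, `tpr`), `label_accuracy` (named vector),
#'   `n_relabel` (profiles whose final label differs from the initial one).
#' @export
evaluate_alignment <- function(result, truth) {
  roles <- list(GE = c("genotype", "expression"),
                GM = c("genotype", "methylation"),
                EM = c("methylation", "expression"))
  rows <- list()
  for (pt in names(result$alignments)) {
    al <- result$alignments[[pt]]
    ta <- truth$true_subject[[roles[[pt]][1]]]
    tb <- truth$true_subject[[roles[[pt]][2]]]
    n_subj <- length(intersect(ta, tb))
    correct <- sum(ta[al$a] == tb[al$b], na.rm = TRUE)
    rows[[pt]] <- data.frame(
      pair_type = pt, n_aligned = nrow(al), n_correct = correct,
      coverage = correct / n_subj,
      tpr = if (nrow(al) > 0) correct / nrow(al) else NA_real_,
      stringsAsFactors = FALSE)
  }
  lab_acc <- vapply(names(result$labels), function(t) {
    lt <- result$labels[[t]]
    ts <- truth$true_subject[[t]]
    mean(lt$subject_id == ts[lt$profile_id], na.rm = TRUE)
  }, numeric(1))
  n_relabel <- sum(vapply(result$labels, function(lt)
    sum(!lt$provenance %in% c("initial") & !is.na(lt$subject_id)), numeric(1)))
  list(pairs = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       label_accuracy = lab_acc, n_relabel = n_relabel)
}

#' Duo-versus-trio alignment experiment on simulated cohorts
#'
#' For each injected methylation error count, simulates `n_seeds`
#' independent cohorts (expression label errors stay at the configured
#' base rate), runs the matcher in both duo and trio mode, and scores the
#' methylation-expression alignment.  Averages over seeds reproduce the
#' coverage/TPR comparison of the two procedures.
#'
#' @param error_counts methylation error counts to scan.
#' @param n_seeds simulated cohorts per error count.
#' @param cfg_base a [sim_config()] giving all other generator settings.
#' @param run_cfg a [run_config()].
#' @param modes matching modes to run.
#' @param pair_type pair type scored (default `"EM"`).
#' @return data frame: `error_count`, `error_rate_pct`, `seed`, `mode`,
#'   `coverage`, `tpr`.
#' @export
run_alignment_experiment <- function(error_counts, n_seeds = 5,
                                     cfg_base = sim_config(),
                                     run_cfg = run_config(min_samples = 10),
                                     modes = c("duo", "trio"),
                                     pair_type = "EM") {
  out <- list()
  for (k in error_counts) {
    for (s in seq_len(n_seeds)) {
      cfg <- cfg_base
      cfg$errors_per_type <- c(cfg$errors_per_type[
        setdiff(names(cfg$errors_per_type), "methylation")],
        methylation = as.integer(k))
      cfg$seed <- cfg_base$seed + 7919L * k + s
      sim <- simulate_cohort(cfg)
      for (mode in modes) {
        res <- suppressWarnings(suppressMessages(
          mod_match(sim$profiles, sim$annotation, run_cfg, mode = mode)))
        ev <- evaluate_alignment(res, sim$truth)
        row <- ev$pairs[ev$pairs$pair_type == pair_type, ]
        out[[length(out) + 1]] <- data.frame(
          error_count = k, error_rate_pct = 100 * k / cfg$n_subjects,
          seed = s, mode = mode, coverage = row$coverage, tpr = row$tpr,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
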