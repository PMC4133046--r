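# build a 1-SNP/1-gene system with controlled matched samples
tiny_cis_system <- function(geno_vec, trait_vec) {
  G <- toy_pm(matrix(geno_vec, 1, length(geno_vec), dimnames = list("s1", NULL)),
              "genotype", starts = 1000)
  E <- toy_pm(matrix(trait_vec, 1, length(trait_vec), dimnames = list("g1", NULL)),
              starts = 2000)
  cp <- omicmatch:::new_cis_pair_set(
    "eSNP", data.frame(source = "s1", target = "g1", statistic = 1,
                       p_value = 1e-6, q_value = 1e-6, distance_bp = 1000L,
                       n = length(geno_vec), stringsAsFactors = FALSE),
    data.frame(source = "s1", target = "g1", distance_bp = 1000L),
    length(geno_vec), "ols")
  list(G = G, E = E, cp = cp)
}

test_that("genotype inference picks the nearest class mean with leave-one-out", {
  # matched samples give class means 1.0 / 2.0 / 3.0 for an outside profile
  sys <- tiny_cis_system(c(0, 0, 1, 1, 2, 2), c(0.9, 1.1, 1.9, 2.1, 2.9, 3.1))
  pairs <- self_pairs(sys$G, sys$E)
  # unaligned probe profile with value 2.2 -> class 1 (mean 2.0 nearest)
  E2 <- toy_pm(matrix(c(0.9, 1.1, 1.9, 2.1, 2.9, 3.1, 2.2), 1, 7,
                      dimnames = list("g1", NULL)), starts = 2000)
  inf <- infer_genotype_from_trait(sys$cp, sys$G, E2, pairs,
                                   trait_profiles = "p7")
  expect_equal(unname(inf[1, "p7"]), 1)
  # value exactly at a class mean -> that class
  E3 <- toy_pm(matrix(c(0.9, 1.1, 1.9, 2.1, 2.9, 3.1, 3.0), 1, 7,
                      dimnames = list("g1", NULL)), starts = 2000)
  inf3 <- infer_genotype_from_trait(sys$cp, sys$G, E3, pairs,
                                    trait_profiles = "p7")
  expect_equal(unname(inf3[1, "p7"]), 2)
})

test_that("leave-one-out removes the scored sample and ties break low", {
  # p2 is the only class-1 sample; when scored, class 1 vanishes and its
  # value 2 is equidistant from means 0 and 4 -> tie to genotype 0
  sys <- tiny_cis_system(c(0, 1, 2), c(0, 2, 4))
  inf <- infer_genotype_from_trait(sys$cp, sys$G, sys$E,
                                   self_pairs(sys$G, sys$E))
  expect_equal(unname(inf[1, "p2"]), 0)
  # without leave-one-out the answer would be its own class, 1
  E_out <- toy_pm(matrix(c(0, 2, 4, 2), 1, 4, dimnames = list("g1", NULL)),
                  starts = 2000)
  inf2 <- infer_genotype_from_trait(sys$cp, sys$G, E_out,
                                    self_pairs(sys$G, sys$E),
                                    trait_profiles = "p4")
  expect_equal(unname(inf2[1, "p4"]), 1)
})

test_that("concordance counts agree with the pairwise-complete rule", {
  expect_equal(genotype_concordance(rep(1, 50), rep(1, 50)), 1)
  expect_equal(genotype_concordance(c(0, 0, 2), c(2, 2, 0)), 0)
  obs <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, NA)
  inf <- c(0, 1, 2, 0, 1, 2, 0, 2, 0, 1)
  expect_equal(genotype_concordance(obs, inf), 7 / 9)
  expect_true(is.na(genotype_concordance(c(NA, NA), c(1, NA))))
  # dosage flavour: 1 - mean|g - ghat|/2
  expect_equal(genotype_concordance(c(0, 2), c(2, 2), method = "dosage"), 0.5)
})

test_that("rank-correlation score matches hand-computed Pearson on ranks", {
  # 5 cis pairs, 5 profiles; matrices hold permutations of 1..5 per feature
  # so within-feature ranks equal the stored values.  Profile p1 carries the
  # target rank patterns; other profiles fill in the remaining ranks.
  m_ranks <- c(1, 2, 3, 4, 5); e_ranks <- c(2, 1, 3, 5, 4)
  fill <- function(first_col) t(vapply(first_col, function(r)
    c(r, setdiff(1:5, r)), numeric(5)))
  Mv <- fill(m_ranks); Ev <- fill(e_ranks)
  dimnames(Mv) <- list(paste0("pr", 1:5), paste0("p", 1:5))
  dimnames(Ev) <- list(paste0("g", 1:5), paste0("p", 1:5))
  Mpm <- toy_pm(Mv, "methylation", starts = (1:5) * 1e6)
  Epm <- toy_pm(Ev, "expression", starts = (1:5) * 1e6 + 2000)
  cp <- omicmatch:::new_cis_pair_set(
    "methyl_mRNA",
    data.frame(source = paste0("pr", 1:5), target = paste0("g", 1:5),
               statistic = 1, p_value = 1e-6, q_value = 1e-6,
               distance_bp = 2000L, n = 5, stringsAsFactors = FALSE),
    data.frame(), 5, "spearman")
  s <- rank_correlation_score(cp, Mpm, Epm, "p1", "p1")
  expect_equal(s, cor(m_ranks, e_ranks))   # independent route
  expect_equal(s, 0.8)                     # hand value: 1 - 6*4/(5*24)
  # identical rank vectors -> 1; reversed -> -1
  Ev1 <- fill(m_ranks); dimnames(Ev1) <- dimnames(Ev)
  expect_equal(rank_correlation_score(
    cp, Mpm, toy_pm(Ev1, "expression", starts = (1:5) * 1e6 + 2000),
    "p1", "p1"), 1)
  Evr <- fill(6 - m_ranks); dimnames(Evr) <- dimnames(Ev)
  expect_equal(rank_correlation_score(
    cp, Mpm, toy_pm(Evr, "expression", starts = (1:5) * 1e6 + 2000),
    "p1", "p1"), -1)
  # fewer than 3 cis pairs -> missing score
  cp2 <- cp; cp2$pairs <- cp$pairs[1:2, ]
  expect_true(is.na(rank_correlation_score(cp2, Mpm, Epm, "p1", "p1")))
})

test_that("similarity is invariant under monotone transforms of raw values", {
  sim <- small_cohort(seed = 31)
  la <- harmonize(sim$profiles, sim$annotation)
  al <- omicmatch:::alignment_from_labels(la, "methylation", "expression")
  cis <- map_cis_methyl_mrna(sim$profiles$methylation, sim$profiles$expression,
                             al, min_samples = 10)
  S1 <- similarity_rank(cis, sim$profiles$methylation, sim$profiles$expression)
  warped <- sim$profiles
  warped$expression$values <- exp(warped$expression$values / 4)
  warped$methylation$values <- warped$methylation$values^3
  S2 <- similarity_rank(cis, warped$methylation, warped$expression)
  expect_equal(S1$score, S2$score, tolerance = 1e-12)
})

test_that("self concordance under planted cis effects beats every cross score", {
  sim <- small_cohort(seed = 37)
  la <- harmonize(sim$profiles, sim$annotation)
  al <- omicmatch:::alignment_from_labels(la, "genotype", "expression")
  cis <- additive_linear_scan(sim$profiles$genotype, sim$profiles$expression,
                              la, min_samples = 10)
  S <- similarity_concordance(cis, sim$profiles$genotype,
                              sim$profiles$expression, al)
  sc <- S$score[al$a, al$b]
  for (i in seq_len(nrow(sc))) {
    expect_equal(unname(which.max(sc[i, ])), i)
    expect_gt(sc[i, i], max(sc[i, -i]))
  }
})

test_that("z-scores standardise rows/columns and flag degenerate rows", {
  S <- rbind(c(1, 2, 3), c(5, 5, 5), c(0, 1, 5))
  zs <- sim_from_score(S)
  expect_equal(unname(zs$z_row[1, ]), c(-1, 0, 1))   # sample-SD convention
  expect_true(all(is.na(zs$z_row[2, ])))             # constant row flagged
  ok <- is.finite(zs$z_row[3, ])
  expect_equal(mean(zs$z_row[3, ok]), 0, tolerance = 1e-9)
  expect_equal(sd(zs$z_row[3, ok]), 1, tolerance = 1e-9)
  # permutation equivariance
  perm <- c(3, 1, 2)
  zp <- sim_from_score(S[, perm])
  expect_equal(unname(zp$z_row[1, ]), unname(zs$z_row[1, perm]))
})

test_that("omega is the root ratio of mean row-maximum z-scores", {
  set.seed(41)
  mk <- function(target_meanmax) {
    S <- matrix(rnorm(400), 20, 20)
    zs <- sim_from_score(S)
    zs
  }
  zs <- mk()
  expect_equal(estimate_omega(zs, zs), 1)            # identical distributions
  # constructed ratio 2.88 / 2.0 -> omega = 1.2
  fake <- function(mm) {
    z <- matrix(0, 4, 3)
    z[, 1] <- mm                                      # row max = mm
    list(z_row = z)
  }
  o <- estimate_omega(structure(fake(2.88), class = "SimilarityMatrix"),
                      structure(fake(2.0), class = "SimilarityMatrix"))
  expect_equal(o, 1.2, tolerance = 1e-12)
  expect_warning(
    o2 <- estimate_omega(structure(fake(2.88), class = "SimilarityMatrix"),
                         structure(fake(-1), class = "SimilarityMatrix")),
    "omega")
  expect_equal(o2, 1)
})

test_that("trio score is the omega-weighted average of its components", {
  expect_equal(trio_score(2.2, 2.2, 0.7), 2.2)       # average of equals
  expect_equal(trio_score(3.0, 2.0, 1.2), (3.6 + 2.0) / 2.2)
  expect_equal(trio_score(3.0, 2.0, 0), 2.0)         # omega = 0 limit
  expect_equal(trio_score(3.0, 2.0, 1.2, combine = "sum"), 5.6)
})
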