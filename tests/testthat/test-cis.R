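# independent brute-force step-up BH: q_i = min over j with p_j >= p_i of
# m * p_j / rank_j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r_i <- which(o == i)            # rank of p[i] (ties resolved by order)
    cand <- vapply(r_i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[i] <- min(1, cand)
  }
  q
}

geno_pm <- function(G, starts = NULL) {
  if (is.null(colnames(G))) colnames(G) <- paste0("p", seq_len(ncol(G)))
  toy_pm(G, "genotype", starts = starts)
}

test_that("BH q-values match spec cases and a brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(0.5, 4)), rep(0.5, 4))
  expect_equal(bh_fdr(numeric()), numeric())
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), brute_bh(p))
  }
})

test_that("additive scan reproduces closed-form OLS and keeps perfect fits", {
  G <- geno_pm(matrix(c(0, 1, 2), 1, 3, dimnames = list("s1", NULL)),
               starts = 1000)
  # perfectly linear trait: slope t is infinite, p numerically 0
  E <- toy_pm(matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", NULL)),
              starts = 2000)
  ps <- additive_linear_scan(G, E, self_pairs(G, E), min_samples = 3)
  expect_equal(nrow(ps$pairs), 1)
  expect_lt(ps$pairs$p_value, 1e-300)
  expect_true(is.infinite(ps$pairs$statistic))

  # noisy trait: t and p agree with lm()
  set.seed(2)
  g <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  y <- 0.8 * g + rnorm(10)
  G2 <- geno_pm(matrix(g, 1, 10, dimnames = list("s1", NULL)), starts = 1000)
  E2 <- toy_pm(matrix(y, 1, 10, dimnames = list("g1", NULL)), starts = 2000)
  ps2 <- additive_linear_scan(G2, E2, self_pairs(G2, E2), min_samples = 5,
                              p_threshold = 1 - 1e-12)
  ref <- summary(lm(y ~ g))$coefficients["g", ]
  expect_equal(ps2$pairs$statistic, unname(ref["t value"]), tolerance = 1e-10)
  expect_equal(ps2$pairs$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("scan statistics are invariant to sample order and trait rescaling", {
  set.seed(3)
  g <- rbinom(20, 2, 0.4); y <- g + rnorm(20)
  mk <- function(gg, yy) list(
    G = geno_pm(matrix(gg, 1, 20, dimnames = list("s1", NULL)), starts = 1000),
    E = toy_pm(matrix(yy, 1, 20, dimnames = list("g1", NULL)), starts = 2000))
  d1 <- mk(g, y)
  t1 <- additive_linear_scan(d1$G, d1$E, self_pairs(d1$G, d1$E),
                             min_samples = 5, p_threshold = 1 - 1e-12)$pairs$statistic
  perm <- sample(20)
  d2 <- mk(g[perm], y[perm])
  colnames(d2$G$values) <- colnames(d2$E$values) <- paste0("p", 1:20)
  t2 <- additive_linear_scan(d2$G, d2$E, self_pairs(d2$G, d2$E),
                             min_samples = 5, p_threshold = 1 - 1e-12)$pairs$statistic
  d3 <- mk(g, 5 - 2.3 * y)
  t3 <- additive_linear_scan(d3$G, d3$E, self_pairs(d3$G, d3$E),
                             min_samples = 5, p_threshold = 1 - 1e-12)$pairs$statistic
  expect_equal(t1, t2, tolerance = 1e-10)
  expect_equal(abs(t1), abs(t3), tolerance = 1e-10)   # affine rescale flips sign only
})

test_that("monomorphic SNPs and undersized cohorts are handled", {
  G <- geno_pm(matrix(1, 1, 25, dimnames = list("s1", NULL)), starts = 1000)
  E <- toy_pm(matrix(rnorm(25), 1, 25, dimnames = list("g1", NULL)), starts = 2000)
  ps <- additive_linear_scan(G, E, self_pairs(G, E), min_samples = 20)
  expect_equal(nrow(ps$pairs), 0)
  expect_warning(
    ps2 <- additive_linear_scan(G, E, self_pairs(G, E)[1:5, ], min_samples = 20),
    "aligned samples")
  expect_equal(nrow(ps2$pairs), 0)
})

test_that("cis windows are respected when recomputing distances", {
  sim <- small_cohort(seed = 21)
  la <- harmonize(sim$profiles, sim$annotation)
  ps <- additive_linear_scan(sim$profiles$genotype, sim$profiles$expression, la,
                             min_samples = 10)
  gp <- sim$profiles$genotype$positions
  ep <- sim$profiles$expression$positions
  i <- match(ps$pairs$source, gp$feature_id)
  j <- match(ps$pairs$target, ep$feature_id)
  expect_true(all(gp$chrom[i] == ep$chrom[j]))
  d <- omicmatch:::interval_gap(gp$start[i], gp$end[i], ep$start[j], ep$end[j])
  expect_true(all(d <= 1e6))
  expect_equal(as.integer(d), ps$pairs$distance_bp)
})

test_that("methyl probes map to the nearest transcript start within 10 kb", {
  probes <- data.frame(feature_id = c("pr1", "pr2"), chrom = "chr1",
                       start = c(10000L, 200000L), end = c(10001L, 200001L))
  tx <- data.frame(feature_id = c("gA", "gB"), chrom = "chr1",
                   start = c(12000L, 18000L), end = c(13000L, 19000L))
  asn <- omicmatch:::assign_probes_to_tss(probes, tx, 1e4)
  expect_equal(asn$source, "pr1")        # pr2 is 182 kb away -> dropped
  expect_equal(asn$target, "gA")         # 2 kb beats 8 kb
  expect_equal(asn$distance_bp, 2000L)
  # exact tie goes to the lexicographically smaller transcript id
  tx2 <- data.frame(feature_id = c("gB", "gA"), chrom = "chr1",
                    start = c(8000L, 12000L), end = c(9000L, 13000L))
  asn2 <- omicmatch:::assign_probes_to_tss(probes[1, ], tx2, 1e4)
  expect_equal(asn2$target, "gA")
})

test_that("methyl-mRNA pairs keep one best probe per gene with exact Spearman", {
  n <- 12
  e <- matrix(seq_len(n), 1, n, dimnames = list("gA", NULL))
  m <- matrix(rev(seq_len(n)), 1, n, dimnames = list("prA", NULL))
  E <- toy_pm(e, "expression", starts = 12000, width = 1000)
  M <- toy_pm(m, "methylation", starts = 10000)
  ps <- map_cis_methyl_mrna(M, E, self_pairs(M, E), min_samples = 5)
  expect_equal(ps$pairs$statistic, -1)
  expect_equal(nrow(ps$pairs), 1)

  # two probes on one gene: smaller-p probe wins, one pair per gene
  set.seed(9)
  noisy <- rank(rev(seq_len(n)) + rnorm(n, sd = 4))
  M2 <- toy_pm(rbind(prA = m[1, ], prB = noisy), "methylation",
               starts = c(10000, 11000))
  ps2 <- map_cis_methyl_mrna(M2, E, self_pairs(M2, E), min_samples = 5)
  expect_equal(nrow(ps2$pairs), 1)
  expect_equal(ps2$pairs$source, "prA")
  expect_lte(max(table(ps2$pairs$target)), 1)
})

test_that("CNV-trait mapping uses rank correlation and skips flat features", {
  n <- 10
  cnv <- rbind(c1 = seq_len(n) / 2, c2 = rep(1, n))
  tr <- matrix(2^(seq_len(n)), 1, n, dimnames = list("gA", NULL))
  C <- toy_pm(cnv, "cnv", starts = c(10000, 20000), width = 5000)
  E <- toy_pm(tr, "expression", starts = 12000, width = 1000)
  ps <- map_cis_cnv(C, E, self_pairs(C, E), min_samples = 5)
  expect_equal(nrow(ps$pairs), 1)
  expect_equal(ps$pairs$source, "c1")
  expect_equal(ps$pairs$statistic, 1)      # strictly increasing -> rho = 1
})

test_that("planted null pairs are retained near the nominal rate", {
  cfg <- sim_config(n_subjects = 50, n_cis_esnp = 300, effect_size_beta = 0,
                    n_cis_msnp = 2, n_cis_em = 2, n_null_snps = 2,
                    n_null_genes = 2, n_null_probes = 2, errors_per_type = c(),
                    seed = 17)
  sim <- simulate_cohort(cfg)
  la <- harmonize(sim$profiles, sim$annotation)
  ps <- additive_linear_scan(sim$profiles$genotype, sim$profiles$expression, la,
                             min_samples = 10)
  frac <- nrow(ps$pairs) / nrow(ps$tested)
  se <- sqrt(0.01 * 0.99 / nrow(ps$tested))
  expect_lt(abs(frac - 0.01), 4 * se)
})

test_that("permutation FDR separates noise from signal and validates B", {
  set.seed(23)
  n <- 30
  em <- function(mm, ee) {
    M <- toy_pm(mm, "methylation", starts = seq_len(nrow(mm)) * 1e6)
    E <- toy_pm(ee, "expression", starts = seq_len(nrow(ee)) * 1e6 + 2000,
                width = 500)
    list(M = M, E = E)
  }
  # strong planted signal in every pair
  base <- matrix(rnorm(20 * n), 20, n)
  d <- em(base + matrix(rnorm(20 * n, sd = 0.2), 20, n),
          base + matrix(rnorm(20 * n, sd = 0.2), 20, n))
  ps <- map_cis_methyl_mrna(d$M, d$E, self_pairs(d$M, d$E), min_samples = 10)
  expect_gt(nrow(ps$pairs), 15)
  fdr <- permutation_fdr(ps, d$M, d$E, self_pairs(d$M, d$E), B = 20, seed = 4)
  expect_lt(fdr, 0.2)
  expect_error(permutation_fdr(ps, d$M, d$E, self_pairs(d$M, d$E), B = 0),
               "B must be")
  # reproducibility under the same seed
  expect_equal(fdr, permutation_fdr(ps, d$M, d$E, self_pairs(d$M, d$E),
                                    B = 20, seed = 4))
  # pure noise: permuted counts resemble observed counts
  d0 <- em(matrix(rnorm(40 * n), 40, n), matrix(rnorm(40 * n), 40, n))
  ps0 <- map_cis_methyl_mrna(d0$M, d0$E, self_pairs(d0$M, d0$E),
                             p_threshold = 0.3, min_samples = 10)
  fdr0 <- permutation_fdr(ps0, d0$M, d0$E, self_pairs(d0$M, d0$E), B = 20,
                          p_threshold = 0.3, seed = 4)
  expect_gt(fdr0, 0.5)
})
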