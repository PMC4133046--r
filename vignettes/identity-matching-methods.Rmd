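---
title: "Multi-omics sample identity matching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics sample identity matching: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicmatch)
```

## The model

`omicmatch` treats cis-regulation as a per-subject fingerprint shared across
omics layers. Its statistical core is three identity similarity scores
between profiles of different data types, each computed over the significant
cis pairs linking those types:

* **Genotype vs trait (S_GE, S_GM).** Under an additive model, the trait
  level of a cis feature clusters by dosage class {0, 1, 2}. For a trait
  profile, the genotype at each cis feature is inferred as the class whose
  mean trait level — estimated from the currently aligned samples,
  *excluding the profile being scored* — is nearest to the profile's own
  value. The score against an observed genotype profile is the fraction of
  cis features where inferred and observed genotypes agree (pairwise
  complete over missing calls). An alternative dosage-distance score,
  1 − mean|g − ĝ|/2, is available via `run_config(concordance = "dosage")`.
* **Methylation vs expression (S_EM).** Both matrices are rank-transformed
  feature-wise across their own profiles; the score is the Pearson
  correlation, across cis pairs, of one profile's probe ranks against the
  other's paired gene ranks. Rank transformation makes the score invariant
  to any strictly monotone change of scale, so array normalisation details
  do not matter.

Assumptions worth stating: subjects are unrelated (a relative's genotype
profile can resemble a subject's trait-inferred genotypes and weaken the
self-vs-background separation); cis effects are additive and stable across
the cohort; and the initial labels are mostly correct, since cis pairs are
discovered under the current alignment. With very high initial error rates
the cis sets shrink and matching power degrades — the trio score is exactly
the mitigation for that regime.

### Sign alignment of rank-correlation scores

Promoter methylation predominantly *represses* expression, so cis
methylation–mRNA pairs are mostly anticorrelated. The raw observed-rank
correlation of a same-subject profile pair is then strongly *negative*,
i.e. the self score would sit at the bottom of its row and top-rank
matching would fail outright. The matcher therefore reverses the target
ranks of each cis pair whose own cis correlation is negative before
correlating (`similarity_rank(sign_align = TRUE)`); a same-subject pair
then scores high regardless of the mixture of repressive and activating
pairs. `rank_correlation_score()` exposes the raw unflipped statistic for
inspection.

### z-scores, top-n, and the trio score

Scores are standardised within each row and column (mean/SD over finite
entries; rows or columns with fewer than 3 finite scores, or zero SD, are
flagged undefined). The SD is the sample SD (n − 1), matching R's `sd()`.

The matching rank *n* is data-driven: per row the best and k-th best
z-scores are collected; starting at n = 1, if a Welch t-test separates the
top-1 from the top-(n+1) distribution at p < 0.01, n stays; otherwise n
grows, up to a cap of 3. With a dominant self signal top-1 stands far above
everything and n = 1; as separation degrades more ranks are admitted. The
t-test is applied to tied or degenerate distributions by treating a failed
test as "no separation". Note that for *continuously* noisy score matrices
the order statistics of exchangeable rows are themselves systematically
ordered, so the rule is meaningful only when self signal dominates — which
is also the only regime in which top-rank matching is trustworthy at all.

The trio score combines a methylation candidate's two component z-scores as
a weighted average, s3 = (ω·z_GM + z_EM)/(1 + ω), rather than a weighted
sum: the average stays on the z scale, so the acceptance threshold (2.5)
is directly comparable with its components. ω weights the
genotype–methylation signal, which is typically the stronger of the two; it
is estimated as the square root of the ratio of mean row-maximum z-scores
of the two matrices, and can be fixed in the configuration. Both choices
(`trio_combine = "sum"`, `omega = <value>`) are overridable because the
combination rule and the direction of the weight are genuinely open design
points; the defaults are the ones under which the 2.5 threshold has a clear
interpretation.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cis_window_snp_bp` | 1e6 | bp | conventional cis-eQTL window; distance is edge-to-edge to the gene region, 0 inside |
| `cis_window_methyl_bp` | 1e4 | bp | probe-to-transcript-start cutoff; nearest start wins, exact ties to the lexicographically smaller id |
| `p_threshold` | 0.01 | — | retention cutoff for all cis scans |
| `q_threshold` | unset | — | optional BH q cutoff on top of p |
| `min_samples` | 20 | samples | minimum aligned pairs for any scan; below it the scan returns empty with a warning |
| `top_n_cap`, `topn_ttest_p` | 3, 0.01 | — | the top-n rule above |
| `trio_z_min` | 2.5 | z | acceptance threshold of the trio score |
| `omega` | `"auto"` | — | estimated per round; fixable |
| `max_rounds` | 20 | rounds | safety cap; the loop usually stops by convergence |
| `gender_F_male` / `gender_F_female` | 0.8 / 0.2 | F | hemizygous X gives F ≈ 1 in males, ≈ 0 in females |
| `min_x_snps` | 50 | SNPs | below this the F statistic is too noisy to call |

Gender thresholds deserve a note: profiles with F between 0.2 and 0.8 are
*ambiguous* and simply excluded from gender-based gating rather than
forced into a call. The expression/methylation marker threshold defaults to
the midpoint between the two centers of a 1-D two-means split of the marker
across profiles, because any fixed cutoff is platform-specific; an explicit
`marker_threshold` overrides it.

## The matching loop

Each round: recompute cis pairs under the current alignments → rebuild
similarity matrices → confirm co-labeled pairs by reciprocal top-n →
rescue dissolved profiles by reciprocal best match (ties at the maximum
block a rescue — the procedure never relabels on ambiguous evidence) →
resolve methylation partners by the trio score (greedy by decreasing s3,
each methylation profile claimed once; trio assignments only fill slots
left open by the duo steps) → chain matches through shared profiles
(g–e and g–m imply m–e). Duos run in decreasing order of signal strength:
genotype–expression, then genotype–methylation, then
methylation–expression. Rounds repeat until the alignment set is unchanged;
a recurrence of a previously seen state (an oscillation) also stops the
loop with a warning. Final labels propagate subject ids from the most
trusted data type (genotype > CNV > expression > methylation) through the
final alignments; a profile is only ever relabeled when an alignment step
produced positive evidence for it.

When the annotation table has a `stratum` column (e.g. disease vs control),
the whole procedure runs independently per stratum, since cis-regulatory
architecture can differ between strata and pooled scans would blur both.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates, per subject: diploid genotypes from uniform
allele frequencies (0.2–0.5); expression and methylation levels with
additive cis-genotype effects (`effect_size_beta`, in noise-SD units per
allele); methylation–expression cis pairs coupled through a shared latent
factor with correlation `methyl_expr_rho`, negative by default (promoter
methylation represses); X-chromosome SNPs that are hemizygous in males
(400 by default, keeping the sampling SD of F, roughly 1/sqrt(n), far from
the 0.2/0.8 thresholds); and one Y-marker feature each in the expression
and methylation matrices with a `sex_marker_effect` of 8 noise SDs.
Features are laid out in private 4 Mb blocks on cycling autosomes so that
every planted pair falls inside its cis window and no unplanned pair does;
an impossible layout (coordinates beyond 2^31) errors out. Levels are on a
continuous M-value-like scale rather than bounded beta values — the methods
only use ranks and class means, so the scale is immaterial.

Label errors are injected as disjoint label swaps (2-cycles; the paper-style
"mis-labeled pairs" count) or as a derangement of a chosen label subset,
with every move recorded in a truth channel.

Deliberately **not** modeled: linkage disequilibrium, population structure
and relatedness, batch effects, probe cross-hybridisation, copy-number
segmentation noise, and bounded beta-value error structure. Passing tests
on this generator therefore demonstrate that the procedure is correct and
self-consistent under its own assumptions — clean additive cis signal and
independent noise — not that it attains any particular power on real
arrays, where cis effects are weaker and error modes messier. Under the
default strong-effect conditions both duo and trio modes recover
essentially all injected swaps; the trio step's added value (bridging
profiles whose single pairwise score is ambiguous, and attributing the
error source) is exercised directly by its unit tests and by the error
attribution table.

## Numerical choices and degenerate inputs

* Association p-values: OLS t with df = n − 2 for dosage scans; Spearman
  via the t approximation for n ≥ 10 and the exact permutation
  distribution (`cor.test(exact = TRUE)`) below; ties get average ranks.
  p-values are floored at the smallest positive double so perfect fits
  remain inside (0, 1].
* Monomorphic SNPs and zero-variance features are skipped, not errored.
* Missing genotypes are never imputed; they drop out pairwise.
* Nearest-class-mean ties in genotype inference break to the lower dosage;
  rank-n ties in duo matching are inclusive (a tied self score passes);
  argmax ties in rescue block the rescue. The asymmetry is intentional:
  keep plausible labels, never rewrite on ambiguous evidence.
* Coordinates are 1-based inclusive internally; BED input is converted on
  read.
* All randomness (simulation, error injection, permutation FDR) flows from
  explicit seeds; the same seed reproduces matrices bit-exactly.

## Problem sizes used by the test suite

The suite runs cohorts of 30–65 subjects with 40–60 planted cis units per
pair type (plus a 1000-unit null cohort for type-I calibration), five
simulated cohorts per condition on the 0–37% error grid, and 20 clean
cohorts for the no-false-relabel property. These sizes give stable
pass/fail behaviour at strong effect sizes while keeping the full suite in
the low minutes on one core.

## Known limitations

* Relatedness breaks the "one subject, one fingerprint" assumption.
* The method corrects labels *between omics layers*; errors in the clinical
  annotation itself are out of scope (only flagged indirectly via gender).
* With error rates far above ~30%, cis discovery under the initial labels
  collapses and only the trio bridge retains traction; beyond that, nothing
  can.
* Attribution requires all three data types; with two, a cross-match
  identifies the pair but not the offending side.
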