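Package: omicmatch
Title: Sample Identity Verification and Label Correction Across Multi-Omics Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and corrects sample labeling errors (swaps, shuffles,
    annotation mistakes) across multiple omics profile sets -- SNP genotypes,
    copy-number, mRNA expression and DNA methylation -- by exploiting
    cis-regulatory relationships between data types.  Gender is inferred
    independently from each data type (X-chromosome heterozygosity,
    Y-chromosome marker expression and methyl-probe intensity) and used as a
    first matching gate.  Significant cis pairs (cis-eSNPs, cis-mSNPs, cis
    methylation-mRNA pairs) yield per-pair identity similarity scores
    (genotype concordance and rank correlation); reciprocal best matching and
    a weighted three-way trio score correct mis-labeled profiles over
    iterated rounds, with cis-pair counts as a quality readout.  Includes a
    synthetic multi-omics cohort simulator with planted cis structure, sex
    markers and injected label errors so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
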