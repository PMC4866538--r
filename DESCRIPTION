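Package: poolER
Title: Divergence Analysis for Replicated Evolve-and-Resequence Pooled Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for replicated evolve-and-resequence (E&R)
    experiments sequenced as pools. Provides a Wright-Fisher forward simulator
    from isofemale-line founders to pooled allele counts, count-level variant
    quality control (third-allele error thresholding, coverage filters, and a
    Clopper-Pearson minor-allele confidence filter), a per-variant binomial
    mixed-model test of treatment divergence with exhaustive label-permutation
    empirical false discovery rate, replicate-consistency statistics
    (diffStat), a hypergeometric sliding-window scan that consolidates
    clusters of diverged variants into differentiated blocks, gene-set
    enrichment by SNP resampling, and population-branch-statistic (PBS)
    candidate-gene enrichment for cross-species comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
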