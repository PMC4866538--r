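#!/usr/bin/env Rscript
# Stage 2: count-level variant QC.
#
# Merges the 12 samples into a variant reference, derives the third-allele
# sequencing-error threshold, calls biallelic sites, applies coverage
# filters and the Clopper-Pearson minor-allele confidence filter, and
# writes the analyzable variant table.

suppressPackageStartupMessages(library(poolER))
dat <- "results/data"
pc <- read_sync(file.path(dat, "experiment.sync"))
design <- read_design(file.path(dat, "design.tsv"))

flt <- filter_variants(pc, design)
write_biallelic(flt$table, file.path(dat, "variants_qc.tsv"))

rep <- flt$report
message(sprintf("input sites: %d; merged median depth: %.0fx", rep$n_input,
                rep$median_merged_depth))
message(sprintf("third-allele threshold (75th quantile): %d",
                rep$third_allele_threshold))
message(sprintf(
  "biallelic: %d -> after coverage filters (high-cov cutoff %.0fx): %d -> high-confidence: %d",
  rep$n_biallelic, rep$high_cov_cutoff, rep$n_after_coverage,
  rep$n_high_confidence))
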