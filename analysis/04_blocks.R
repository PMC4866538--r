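#!/usr/bin/env Rscript
# Stage 4: differentiated blocks.
#
# Scans the arm in 50-kb windows every 10 kb, tests each window's SDV count
# against the hypergeometric background, adjusts genome-wide (BH), merges
# significant windows into blocks, and nominates each block's top variant
# and its candidate genes from a deterministic gene model.

suppressPackageStartupMessages(library(poolER))
res_dir <- "results"
res <- read.table(file.path(res_dir, "variants.tsv"), sep = "\t",
                  header = TRUE, stringsAsFactors = FALSE)

arm_lengths <- c(chr2L = 1e7)
w <- adjust_windows(scan_windows(res, window = 5e4, step = 1e4,
                                 arm_lengths = arm_lengths), alpha = 0.05)
blocks <- consolidate_blocks(w)
write.table(w, file.path(res_dir, "windows.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

if (nrow(blocks)) {
  # deterministic toy gene model: 3-kb genes every 10 kb
  genes <- data.frame(gene = sprintf("gene%04d", seq_len(1000)),
                      arm = "chr2L",
                      start = (seq_len(1000) - 1) * 1e4 + 2001,
                      end = (seq_len(1000) - 1) * 1e4 + 5000,
                      stringsAsFactors = FALSE)
  write_bed(data.frame(arm = genes$arm, start = genes$start - 1,
                       end = genes$end),
            file.path(res_dir, "genes.bed"), names = genes$gene)
  cand <- nominate_candidates(blocks, res, genes)
  write.table(blocks, file.path(res_dir, "blocks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(blocks, file.path(res_dir, "blocks.bed"), names = blocks$block)
  write.table(cand, file.path(res_dir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  s <- block_summary(blocks)
  message(sprintf("%d significant windows -> %d blocks", sum(w$significant),
                  nrow(blocks)))
  message(sprintf("median block length: %.0f bp; median inter-block gap: %s bp",
                  s$median_length,
                  ifelse(is.na(s$median_gap), "NA", s$median_gap)))
  message(sprintf("top variants: %s",
                  paste(unique(cand$pos), collapse = ", ")))
} else {
  message("no significant windows at FDR < 5%")
}
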