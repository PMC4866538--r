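#!/usr/bin/env Rscript
# Stage 5: gene-level enrichment and the cross-species comparison.
#
# (a) SNP-resampling gene-set test: are the genes around driver loci
#     overrepresented among genes hit by the most significant variants,
#     against a gene-length-bias-corrected resampling null?
# (b) PBS stage on synthetic three-population frequency data: Reynolds FST
#     -> branch lengths -> per-SNP PBS, top-5% tail enrichment of the
#     candidate genes' orthologs, and the shared-gene report across
#     populations.

suppressPackageStartupMessages(library(poolER))
seed <- 20240917L
res_dir <- "results"
res <- read.table(file.path(res_dir, "variants.tsv"), sep = "\t",
                  header = TRUE, stringsAsFactors = FALSE)
truth <- read.table("results/data/truth.tsv", sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
genes <- read_genes(file.path(res_dir, "genes.bed"))

## (a) gene-set resampling
gmp <- gene_min_p(res, genes, flank = 500)
driver_pos <- truth$pos[truth$driver]
driver_genes <- unique(unlist(lapply(driver_pos, function(p) {
  g <- genes$gene[genes$start - 500 <= p & genes$end + 500 >= p]
  if (length(g)) g else genes$gene[which.min(abs((genes$start + genes$end) / 2 - p))]
})))
set.seed(stage_seed(seed, "enrich"))
random_genes <- sample(setdiff(gmp$scores$gene, driver_genes),
                       length(driver_genes))
enr <- geneset_resampling_test(
  list(driver_genes = driver_genes, random_genes = random_genes),
  gmp, res, n_sims = 10000, seed = stage_seed(seed, "enrich"))
write.table(enr, file.path(res_dir, "geneset_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("gene-set resampling: driver genes p = %.4g, random p = %.2f",
                enr$p_empirical[1], enr$p_empirical[2]))

## (b) synthetic three-population PBS stage
set.seed(stage_seed(seed, "pbs"))
n_snp <- 20000
gene_pool <- sprintf("HG%04d", 1:800)
snp_gene <- sample(gene_pool, n_snp, replace = TRUE)
p_anc <- rbeta(n_snp, 0.8, 0.8)
drift <- function(p, sd) pmin(pmax(p + rnorm(n_snp, 0, sd), 0.01), 0.99)
# population H carries extra divergence at SNPs in "selected" ortholog genes
sel_genes <- gene_pool[1:40]
bump <- ifelse(snp_gene %in% sel_genes, 0.08, 0)
freqs <- data.frame(chrom = "chr1", pos = seq_len(n_snp) * 500,
                    gene = snp_gene,
                    freq_h = drift(p_anc + bump, 0.05), n_h = 138,
                    freq_l = drift(p_anc, 0.05), n_l = 192,
                    freq_o = drift(p_anc, 0.08), n_o = 134)
pbs <- pbs_from_frequencies(freqs)
write.table(pbs[seq_len(200), ], file.path(res_dir, "pbs_head.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cand_orth <- sel_genes[1:30]   # candidates: 30 of the 40 truly selected
tail5 <- pbs_tail_enrichment(pbs, cand_orth, tail = 0.05)
tail1 <- pbs_tail_enrichment(pbs, cand_orth, tail = 0.01)
write.table(rbind(cbind(tail = "5%", tail5), cbind(tail = "1%", tail1)),
            file.path(res_dir, "pbs_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("PBS tail enrichment: top 5%%: %d/%d vs p0 = %.3f (p = %.3g)",
                tail5$k, tail5$n, tail5$p0, tail5$p_two_sided))

# shared genes across three synthetic high-altitude populations
hit_genes <- function(shift_sd) {
  f2 <- freqs
  f2$freq_h <- drift(p_anc + bump, shift_sd)
  p2 <- pbs_from_frequencies(f2)
  thr <- quantile(p2$pbs, 0.95)
  unique(p2$gene[p2$pbs >= thr & p2$gene %in% cand_orth])
}
hits <- list(pop1 = hit_genes(0.05), pop2 = hit_genes(0.06),
             pop3 = hit_genes(0.07))
rep3 <- shared_gene_report(hits)
write.table(rep3$counts, file.path(res_dir, "shared_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("candidate genes with tail SNPs: %s; shared by all three: %d",
                paste(rep3$counts$n[1:3], collapse = "/"),
                length(rep3$shared_all)))

# fly -> human ortholog joining on a synthetic mapping table covering 80%
# of the gene model through two agreeing sources
covered <- genes$gene[seq_len(floor(0.8 * nrow(genes)))]
orth <- data.frame(
  fly_gene = rep(covered, each = 2),
  human_gene = paste0("HG", sprintf("%04d", rep(seq_along(covered), each = 2))),
  source = rep(c("orthodb", "homologene"), length(covered)),
  stringsAsFactors = FALSE)
joined <- ortholog_join(orth, candidates = driver_genes, max_fanout = 1)
write.table(joined, file.path(res_dir, "orthologs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d driver genes have retained human orthologs",
                length(unique(joined$fly_gene)), length(driver_genes)))
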