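# Gene-set resampling, Reynolds FST / PBS, tail enrichment, orthologs

test_that("SNP-to-gene assignment respects the flank boundary", {
  genes <- data.frame(gene = "g1", arm = "chr2L", start = 10000, end = 12000,
                      stringsAsFactors = FALSE)
  res <- data.frame(arm = "chr2L", pos = c(9600, 9400, 11000, 12500, 12600),
                    p = c(0.3, 0.2, 0.01, 0.5, 0.9))
  gmp <- gene_min_p(res, genes, flank = 500)
  # 400 bp upstream and 500 bp downstream are in; 600 bp upstream is out
  expect_equal(gmp$scores$n_snps, 3L)
  expect_equal(gmp$scores$min_p, 0.01)
  expect_setequal(gmp$map$snp, c(1, 3, 4))
})

test_that("a SNP in two overlapping genes is assigned to both", {
  genes <- data.frame(gene = c("g1", "g2"), arm = "chr2L",
                      start = c(1000, 1500), end = c(2000, 2500),
                      stringsAsFactors = FALSE)
  res <- data.frame(arm = "chr2L", pos = 1800, p = 0.05)
  gmp <- gene_min_p(res, genes, flank = 0)
  expect_equal(nrow(gmp$map), 2)
  expect_setequal(gmp$scores$gene, c("g1", "g2"))
  expect_equal(gmp$scores$min_p, c(0.05, 0.05))
})

test_that("resampling test is calibrated under the null and powered when spiked", {
  set.seed(5)
  n_snp <- 2000
  genes <- data.frame(gene = sprintf("g%03d", 1:100), arm = "chr2L",
                      start = (0:99) * 1e4 + 1, end = (0:99) * 1e4 + 5e3,
                      stringsAsFactors = FALSE)
  pos <- sort(sample(seq(1, 1e6), n_snp))
  null_res <- data.frame(arm = "chr2L", pos = pos, p = runif(n_snp))
  gmp <- gene_min_p(null_res, genes, flank = 0)

  rand_set <- sample(gmp$scores$gene, 15)
  out <- geneset_resampling_test(list(rand = rand_set), gmp, null_res,
                                 n_sims = 2000, seed = 7)
  expect_gt(out$p_empirical, 0.05)

  # spike: make every SNP in 10 chosen genes highly significant
  spike_genes <- gmp$scores$gene[1:10]
  spiked <- null_res
  spike_snps <- gmp$map$snp[gmp$map$gene %in% spike_genes]
  spiked$p[spike_snps] <- 1e-8
  gmp2 <- gene_min_p(spiked, genes, flank = 0)
  out2 <- geneset_resampling_test(list(spike = spike_genes), gmp2, spiked,
                                  n_sims = 2000, seed = 7)
  expect_lt(out2$p_bonferroni, 0.01)

  # estimator bounds: p >= 1/(1+n_sims), and observed 0 -> p = 1
  empty_set <- setdiff(gmp$scores$gene, gmp$map$gene)  # none: use low overlap
  expect_gte(out$p_empirical, 1 / 2001)
})

test_that("resampling p-values are stochastically valid under the null", {
  set.seed(99)
  genes <- data.frame(gene = sprintf("g%02d", 1:50), arm = "chr2L",
                      start = (0:49) * 2e4 + 1, end = (0:49) * 2e4 + 1e4,
                      stringsAsFactors = FALSE)
  pvals <- replicate(50, {
    res <- data.frame(arm = "chr2L", pos = sort(sample(seq(1, 1e6), 800)),
                      p = runif(800))
    gmp <- gene_min_p(res, genes, flank = 0)
    st <- sample(gmp$scores$gene, 8)
    geneset_resampling_test(list(s = st), gmp, res, n_sims = 400,
                            seed = sample.int(1e6, 1))$p_empirical
  })
  # stochastically >= uniform: empirical CDF below the diagonal (with slack)
  for (q in c(0.1, 0.25, 0.5)) {
    expect_lt(mean(pvals <= q), q + 3 * sqrt(q * (1 - q) / 50))
  }
})

test_that("Reynolds FST matches an independent transcription and its limits", {
  expect_equal(reynolds_fst(0.3, 0.3, 100, 100)$fst, 0)
  expect_gt(reynolds_fst(1, 0, 1000, 1000)$fst, 0.99)
  expect_equal(reynolds_fst(0.5, 0.5, 10, 10)$fst, 0)  # identical freqs
  # monomorphic in both populations
  expect_equal(reynolds_fst(0, 0, 50, 50)$fst, 0)
  expect_equal(reynolds_fst(1, 1, 50, 50)$fst, 0)

  # independent symbolic transcription at p1=0.8, p2=0.2, n1=n2=100
  p1 <- 0.8; p2 <- 0.2; n1 <- 100; n2 <- 100
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- num + n1 * p1 * (1 - p1) / (n1 - 1) + n2 * p2 * (1 - p2) / (n2 - 1)
  expect_equal(reynolds_fst(0.8, 0.2, 100, 100)$fst, num / den)
  # large-sample limit (p1-p2)^2 / (p1 q2 + p2 q1)
  expect_equal(reynolds_fst(0.8, 0.2, 1e7, 1e7)$fst,
               0.36 / (0.8 * 0.8 + 0.2 * 0.2), tolerance = 1e-5)
  # negative raw estimates clip to zero but are reported
  r <- reynolds_fst(0.5, 0.52, 10, 10)
  expect_equal(r$fst, 0)
  expect_lt(r$fst_raw, 0)
})

test_that("PBS follows its closed form and branch additivity", {
  expect_equal(compute_pbs(0, 0, 0)$pbs, 0)
  expect_equal(compute_pbs(0.2, 0.2, 0)$pbs, -log(0.8), tolerance = 1e-12)
  expect_lt(compute_pbs(0, 0, 0.2)$pbs, 0)
  expect_error(compute_pbs(1, 0.2, 0.2), "FST")

  # additivity: scaling all branch lengths by c scales PBS by c
  f <- function(t) 1 - exp(-t)   # T -> FST
  t1 <- c(0.1, 0.25, 0.05)
  for (cc in c(0.5, 2)) {
    p1 <- compute_pbs(f(t1[1]), f(t1[2]), f(t1[3]))$pbs
    p2 <- compute_pbs(f(cc * t1[1]), f(cc * t1[2]), f(cc * t1[3]))$pbs
    expect_equal(p2, cc * p1, tolerance = 1e-12)
  }
})

test_that("per-SNP PBS from three-population frequencies is coherent", {
  set.seed(17)
  n <- 200
  freqs <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000,
                      gene = sample(c("A", "B", NA), n, replace = TRUE),
                      freq_h = runif(n), n_h = 138,
                      freq_l = runif(n), n_l = 192,
                      freq_o = runif(n), n_o = 134)
  tab <- pbs_from_frequencies(freqs)
  expect_equal(nrow(tab), n)
  expect_true(all(tab$t_hl >= 0 & tab$t_ho >= 0 & tab$t_lo >= 0))
  # a focal-specific shift inflates PBS
  shifted <- freqs
  shifted$freq_h <- pmin(1, shifted$freq_l + 0.4)
  expect_gt(mean(pbs_from_frequencies(shifted)$pbs), mean(tab$pbs))
})

test_that("two-sided binomial p matches the outcome-summation oracle for n <= 30", {
  for (n in c(5, 12, 30)) {
    for (p0 in c(0.05, 0.3, 0.5)) {
      for (k in c(0, 1, floor(n / 2), n)) {
        expect_equal(binom.test(k, n, p0)$p.value,
                     oracle_binom_two_sided(k, n, p0), tolerance = 1e-10,
                     label = sprintf("k=%d n=%d p0=%.2f", k, n, p0))
      }
    }
  }
  # the documented example: k=3, n=10, p0=0.1 by exhaustive summation
  expect_equal(binom.test(3, 10, 0.1)$p.value,
               oracle_binom_two_sided(3, 10, 0.1), tolerance = 1e-12)
})

test_that("PBS tail enrichment reproduces the published study's scale", {
  # reconstruct a PBS table with the printed marginals: 277,553 SNPs of
  # which 13,867 in the 5% tail; 3,158 candidate-gene SNPs with 223 in the
  # tail. The exact printed P (2.1e-07) depends on an unstated two-sided
  # convention; the minimum-likelihood and doubled-tail conventions agree
  # with it within an order of magnitude.
  n_total <- 277553; n_tail <- 13867; n_cand <- 3158; k_cand <- 223
  pbs_val <- numeric(n_total)
  tail_rows <- seq_len(n_tail)
  pbs_val[tail_rows] <- 1                       # tail SNPs
  gene <- rep("other", n_total)
  gene[seq_len(k_cand)] <- "cand"               # candidate tail SNPs
  gene[seq(n_tail + 1, n_tail + (n_cand - k_cand))] <- "cand"
  tab <- data.frame(gene = gene, pbs = pbs_val)
  out <- pbs_tail_enrichment(tab, "cand", tail = n_tail / n_total)
  expect_equal(out$k, k_cand)
  expect_equal(out$n, n_cand)
  expect_equal(out$p0, n_tail / n_total, tolerance = 1e-6)
  expect_equal(out$direction, "enriched")
  expect_lt(out$p_two_sided, 2.1e-6)
  expect_gt(out$p_two_sided, 2.1e-8)
  # doubled-tail option agrees to the same order
  out2 <- pbs_tail_enrichment(tab, "cand", tail = n_tail / n_total,
                              alternative = "doubled")
  expect_lt(out2$p_two_sided, 2.1e-6)

  # a candidate set at the null center gives p ~ 1
  k0 <- round(n_cand * n_tail / n_total)
  gene0 <- rep("other", n_total)
  gene0[seq_len(k0)] <- "cand"
  gene0[seq(n_tail + 1, n_tail + (n_cand - k0))] <- "cand"
  out0 <- pbs_tail_enrichment(data.frame(gene = gene0, pbs = pbs_val), "cand",
                              tail = n_tail / n_total)
  expect_gt(out0$p_two_sided, 0.5)

  expect_error(pbs_tail_enrichment(tab, "cand", tail = 1), "tail")
  expect_error(pbs_tail_enrichment(tab, "absent"), "candidate")
})

test_that("shared-gene reports compute set intersections", {
  hits <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3"), C = "g3")
  rep3 <- shared_gene_report(hits)
  expect_equal(rep3$shared_all, "g3")
  expect_equal(rep3$intersections[["A&B"]], c("g2", "g3"))
  expect_equal(rep3$counts$n[rep3$counts$combination == "A&B&C"], 1)

  disjoint <- shared_gene_report(list(A = "g1", B = "g2"))
  expect_equal(length(disjoint$shared_all), 0)
  ident <- shared_gene_report(list(A = c("g1", "g2"), B = c("g1", "g2")))
  expect_setequal(ident$shared_all, c("g1", "g2"))
  expect_error(shared_gene_report(list(A = "g1")), ">= 2")
})

test_that("ortholog joining applies fan-out and conflict rules", {
  map <- data.frame(
    fly_gene = c("f1", "f2", "f2", "f3", "f3", "f3", "f4", "f4"),
    human_gene = c("H1", "H2", "H2", "H3a", "H3b", "H3c", "H4", "H4x"),
    source = c("orthodb", "orthodb", "homologene", "modencode", "modencode",
               "modencode", "orthodb", "homologene"),
    stringsAsFactors = FALSE)

  # one source, one mapping: passes; two agreeing sources: kept
  out <- ortholog_join(map, max_fanout = 2)
  expect_true("H1" %in% out$human_gene)
  expect_true("H2" %in% out$human_gene)
  # f3 has 3 orthologs in modencode under fan-out 2: dropped from that source
  expect_false(any(out$fly_gene == "f3"))
  # f4: orthodb asserts H4, homologene asserts H4x -> both pairs conflicted
  expect_false(any(out$fly_gene == "f4"))

  # silence is not conflict: homologene says nothing about f1
  expect_equal(out$sources[out$fly_gene == "f1"], "orthodb")

  # candidate restriction
  out2 <- ortholog_join(map, candidates = "f2", max_fanout = 2)
  expect_equal(out2$fly_gene, "f2")
  expect_equal(out2$sources, "homologene,orthodb")

  expect_error(ortholog_join(data.frame(a = 1)), "columns")
})
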