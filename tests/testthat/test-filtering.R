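# Count-level QC: VarRef, error thresholding, coverage and CI filters

make_pc <- function(count_list, arm = "chr2L", ref = NULL) {
  # count_list: list of sites, each a samples x 6 matrix (or vector for one
  # sample)
  L <- length(count_list)
  mats <- lapply(count_list, function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (ncol(m) == 4) m <- cbind(m, 0L, 0L)
    m
  })
  ns <- nrow(mats[[1]])
  counts <- array(0L, c(L, 6, ns),
                  dimnames = list(NULL, NULL, paste0("S", seq_len(ns))))
  for (i in seq_len(L)) counts[i, , ] <- t(mats[[i]])
  if (is.null(ref)) ref <- rep("A", L)
  pooled_counts(data.frame(arm = arm, pos = seq_len(L) * 100L, ref = ref,
                           stringsAsFactors = FALSE), counts)
}

simple_design <- function(samples, generation = 17) {
  data.frame(id = samples,
             treatment = rep(c("selected", "control"),
                             length.out = length(samples)),
             replicate = seq_along(samples), generation = generation,
             pool_chromosomes = 200, stringsAsFactors = FALSE)
}

test_that("VarRef is the element-wise sample sum", {
  pc1 <- make_pc(list(c(3, 0, 0, 0), c(10, 5, 0, 0)))
  expect_equal(unname(merge_varref(pc1)[, 1:4]),
               rbind(c(3, 0, 0, 0), c(10, 5, 0, 0)))  # one sample: identity

  pc2 <- make_pc(list(rbind(c(3, 0, 0, 0), c(1, 2, 0, 0)),
                      rbind(c(5, 5, 0, 0), c(0, 0, 1, 0))))
  v <- merge_varref(pc2)
  expect_equal(unname(v[1, 1:4]), c(4, 2, 0, 0))
  expect_equal(unname(v[2, 1:4]), c(5, 5, 1, 0))
  expect_equal(attr(v, "median_depth"), median(c(6, 11)))
})

test_that("merging 12 samples with ~85x medians exceeds 1000x median depth", {
  # negative-binomial depth is right-skewed, so a per-sample median of ~85
  # corresponds to a slightly larger mean
  cfg <- quick_config(n_loci = 200, depth_mean = 90)
  ex <- generate_experiment(cfg)
  per_sample_med <- apply(ex$counts$counts, 3, function(m) median(rowSums(m)))
  expect_gt(mean(per_sample_med), 80)
  v <- merge_varref(ex$counts)
  expect_gt(attr(v, "median_depth"), 1000)
})

test_that("third-allele threshold is the lower empirical 75th quantile", {
  # strictly biallelic everywhere -> 0
  pc <- make_pc(list(c(10, 5, 0, 0), c(8, 3, 0, 0)))
  expect_identical(third_allele_threshold(merge_varref(pc)), 0L)

  # hand-enumerated order statistics: thirds {0,0,1,3,5} -> 3 at q = 0.75
  thirds <- c(0, 0, 1, 3, 5)
  pc2 <- make_pc(lapply(thirds, function(t) c(50, 20, t, 0)))
  expect_identical(third_allele_threshold(merge_varref(pc2), 0.75), 3L)
})

test_that("biallelic calling applies the tri-allelic and minor-count rules", {
  pc <- make_pc(list(c(100, 4, 10, 0),    # third allele 4 > 3: dropped
                     c(100, 50, 3, 0),    # kept; depth excludes third allele
                     c(100, 3, 0, 0)))    # minor 3 not > 3: dropped
  bt <- call_biallelic(pc, merge_varref(pc), 3L)
  expect_equal(nrow(bt$sites), 1)
  expect_equal(bt$sites$pos, 200L)
  expect_equal(bt$sites$ref, "A")
  expect_equal(bt$sites$alt, "T")
  expect_equal(as.vector(bt$depth), 150)
  expect_equal(as.vector(bt$alt), 50)
})

test_that("declared ref is kept as ref when it is a major allele", {
  pc <- make_pc(list(c(40, 100, 0, 0)), ref = "A")  # T outnumbers ref A
  bt <- call_biallelic(pc, merge_varref(pc), 3L)
  expect_equal(bt$sites$ref, "A")
  expect_equal(bt$sites$alt, "T")
  expect_equal(as.vector(bt$alt), 100)
})

test_that("coverage filters: strict global minimum, high quantile, cohort rule", {
  # two samples, one generation
  cl <- list(rbind(c(5, 6, 0, 0), c(0, 0, 0, 0)),    # merged depth 11 > 10
             rbind(c(5, 5, 0, 0), c(0, 0, 0, 0)),    # merged depth 10: dropped
             rbind(c(30, 30, 0, 0), c(20, 20, 0, 0)))
  pc <- make_pc(cl)
  bt <- call_biallelic(pc, merge_varref(pc), 0L)
  expect_equal(nrow(bt$sites), 3)
  cfg <- filter_config(min_global_depth = 10, high_cov_quantile = 0.95,
                       per_sample_min_depth = 1)
  out <- coverage_filters(bt, simple_design(bt$samples), cfg)
  # site 2 fails the strict > 10 rule; with only 3 sites the lower 95th
  # quantile is the maximum, so the quantile rule drops nothing
  expect_equal(out$sites$pos, c(100L, 300L))

  # with enough sites the quantile rule drops the extreme-coverage site
  cl3 <- c(replicate(20, c(10, 10, 0, 0), simplify = FALSE),
           list(c(500, 500, 0, 0)))
  pc3 <- make_pc(cl3)
  bt3 <- call_biallelic(pc3, merge_varref(pc3), 0L)
  out3 <- coverage_filters(bt3, simple_design(bt3$samples),
                           filter_config(per_sample_min_depth = 1))
  expect_equal(nrow(out3$sites), 20)       # ceiling(21 * .95) = 20 -> cutoff 20
  expect_equal(attr(out3, "high_cov_cutoff"), 20)

  # degenerate distribution: equal depths, none dropped by the quantile rule
  cl2 <- list(c(20, 20, 0, 0), c(25, 15, 0, 0), c(10, 30, 0, 0))
  pc2 <- make_pc(cl2)
  bt2 <- call_biallelic(pc2, merge_varref(pc2), 0L)
  out2 <- coverage_filters(bt2, simple_design(bt2$samples),
                           filter_config(per_sample_min_depth = 1))
  expect_equal(nrow(out2$sites), 3)
})

test_that("a site covered in only one cohort sample passes the low-coverage rule", {
  # sample 1 deep, sample 2 shallow: failure requires *all* cohort samples
  # below the per-sample minimum
  cl <- list(rbind(c(30, 30, 0, 0), c(2, 2, 0, 0)),
             rbind(c(4, 5, 0, 0), c(3, 3, 0, 0)))   # all < 10: dropped
  pc <- make_pc(cl)
  bt <- call_biallelic(pc, merge_varref(pc), 0L)
  out <- coverage_filters(bt, simple_design(bt$samples),
                          filter_config(min_global_depth = 10,
                                        high_cov_quantile = 0.99,
                                        per_sample_min_depth = 10))
  expect_equal(out$sites$pos, 100L)
})

test_that("Clopper-Pearson lower bound matches the tail-bisection oracle", {
  expect_equal(binomial_ci_lower(0, 50), 0)
  expect_gt(binomial_ci_lower(50, 50), 0.8)
  cases <- rbind(c(5, 100), c(1, 20), c(10, 20), c(50, 50), c(3, 1000))
  for (lev in c(0.95, 0.9973)) {
    for (i in seq_len(nrow(cases))) {
      expect_equal(binomial_ci_lower(cases[i, 1], cases[i, 2], lev),
                   oracle_cp_lower(cases[i, 1], cases[i, 2], lev),
                   tolerance = 1e-8)
    }
  }
  expect_error(binomial_ci_lower(1, 0), "depth")
})

test_that("high-confidence filter keeps a site iff any sample clears the bound", {
  cl <- list(rbind(c(50, 0, 0, 0), c(40, 10, 0, 0)),  # minor 10/50 in S2: kept
             rbind(c(50, 5, 0, 0), c(45, 5, 0, 0)))
  pc <- make_pc(cl)
  bt <- call_biallelic(pc, merge_varref(pc), 0L)
  out <- high_confidence_filter(bt, 0.9973)
  expect_true(100L %in% out$sites$pos)

  # minor observed nowhere -> dropped even with deep coverage
  cl2 <- list(rbind(c(100, 0, 0, 0), c(90, 0, 0, 0)))
  pc2 <- make_pc(cl2)
  bt2 <- structure(list(sites = data.frame(arm = "chr2L", pos = 100L,
                                           ref = "A", alt = "T"),
                        alt = matrix(0L, 1, 2), depth = matrix(c(100L, 90L), 1),
                        samples = c("S1", "S2"), kept = 1L),
                   class = "biallelic_table")
  expect_equal(nrow(high_confidence_filter(bt2)$sites), 0)
})

test_that("allele frequencies are alt/depth with NA at zero depth", {
  bt <- structure(list(sites = data.frame(arm = "chr2L", pos = c(100L, 200L),
                                          ref = "A", alt = "T"),
                       alt = rbind(c(5L, 0L), c(3L, 2L)),
                       depth = rbind(c(50L, 10L), c(30L, 0L)),
                       samples = c("S1", "S2"), kept = 1:2),
                  class = "biallelic_table")
  f <- allele_frequencies(bt)
  expect_equal(f[1, ], c(S1 = 0.10, S2 = 0))
  expect_equal(unname(f[2, 1]), 0.1)
  expect_true(is.na(f[2, 2]))
})

test_that("the filter pipeline is idempotent and keeps clean simulated variants", {
  cfg <- quick_config(n_loci = 400, depth_mean = 60, error_rate = 0)
  ex <- generate_experiment(cfg)
  flt <- filter_variants(ex$counts, ex$design)
  bt <- flt$table
  expect_equal(flt$report$third_allele_threshold, 0L)
  expect_true(all(bt$sites$ref != bt$sites$alt))
  expect_false(anyDuplicated(bt$sites[c("arm", "pos")]) > 0)

  # frequencies track the simulator truth within binomial error
  f <- allele_frequencies(bt)
  pops <- sub("_F\\d+$", "", bt$samples)
  gens <- sub("^.*_(F\\d+)$", "\\1", bt$samples)
  err <- vapply(seq_along(bt$samples), function(k) {
    truth <- ex$truth$pool_fraction[bt$kept, gens[k], pops[k]]
    mean(abs(f[, k] - truth), na.rm = TRUE)
  }, numeric(1))
  expect_lt(max(err), 4 / sqrt(cfg$depth_mean))

  # idempotence: re-applying the filters with the recorded thresholds
  # (thresholds are ascertained once, on the full data) changes nothing
  cfgf <- filter_config()
  again <- high_confidence_filter(
    coverage_filters(bt, ex$design, cfgf,
                     high_cov_cutoff = flt$report$high_cov_cutoff),
    cfgf$ci_level)
  expect_equal(again$sites, bt$sites)

  # biallelic TSV round trip
  path <- tempfile(fileext = ".tsv")
  write_biallelic(bt, path)
  rt <- read_biallelic(path)
  expect_equal(rt$sites$pos, bt$sites$pos)
  expect_equal(rt$alt, unname(bt$alt))
  expect_equal(rt$depth, unname(bt$depth))
  unlink(path)
})
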