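# Wright-Fisher pooled-sequencing simulator

test_that("founder pool matches the isofemale-line design", {
  cfg <- sim_config(n_lines = 27, haploids_per_line = 4, n_loci = 120,
                    arms = c(chr2L = 1e6), seed = 11)
  fp <- build_founders(cfg)
  expect_equal(nrow(fp$haplotypes), 108)  # 27 lines x 4 haploid genomes
  expect_true(all(fp$founder_freq > 0 & fp$founder_freq < 1))
  expect_true(all(diff(fp$sites$pos) > 0))
  # determinism under a fixed seed
  expect_identical(fp, build_founders(cfg))
})

test_that("fully homozygous lines force founder frequencies onto the 1/27 grid", {
  cfg <- sim_config(n_lines = 27, haploids_per_line = 4, n_loci = 150,
                    arms = c(chr2L = 1e6), within_line_identity = 1, seed = 5)
  fp <- build_founders(cfg)
  k <- fp$founder_freq * 27
  expect_equal(k, round(k), tolerance = 1e-12)
})

test_that("an unattainable site-frequency target errors with the constraint named", {
  # a single line with one haploid genome can never be polymorphic
  expect_error(build_founders(sim_config(n_lines = 1, haploids_per_line = 1,
                                         n_loci = 5, arms = c(a = 100),
                                         seed = 1)),
               "segregating")
})

test_that("without recombination every chromosome is a founder haplotype", {
  cfg <- sim_config(n_loci = 60, ne = 40, pool_individuals = 20,
                    arms = c(chr2L = 1e6),
                    recomb_rate = 0, seed = 9, sampled_generations = c(2, 5))
  fp <- build_founders(cfg)
  ev <- evolve_population(fp, cfg, selected = FALSE)
  founder_keys <- apply(fp$haplotypes, 1, paste, collapse = "")
  pop_keys <- apply(ev$states[[2]], 2, paste, collapse = "")
  expect_true(all(pop_keys %in% founder_keys))
})

test_that("neutral drift is a martingale: mean frequency stays at the founder value", {
  cfg <- sim_config(n_loci = 150, ne = 200, arms = c(chr2L = 1e6),
                    unlinked = TRUE, seed = 21)
  fp <- build_founders(cfg)
  reps <- 25
  finals <- replicate(reps, evolve_population(fp, cfg)$freq[, "F17"])
  shift <- rowMeans(finals) - fp$founder_freq
  # site-level MC error ~ sqrt(pq * 18/(2 ne) / reps); test the average shift
  expect_lt(abs(mean(shift)), 3 * sd(shift) / sqrt(length(shift)) + 0.005)
  # drift variance matches p(1-p) * t/(2 ne) with one extra founding draw
  pq <- fp$founder_freq * (1 - fp$founder_freq)
  vr <- apply(finals, 1, var)
  ratio <- sum(vr) / sum(pq * 18 / (2 * cfg$ne))
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("selection follows the deterministic single-locus recursion", {
  # small-scale version of the check (the acceptance suite runs the large one)
  s <- 0.5; h <- 0.5; ne <- 2000; reps <- 40
  fp <- list(haplotypes = matrix(rep(c(0L, 1L), each = 54), 108, 1),
             sites = data.frame(arm = "chr2L", pos = 1000L, ref = "A",
                                alt = "T"),
             founder_freq = 0.5)
  cfg <- sim_config(n_loci = 1, ne = ne, arms = c(chr2L = 1e6),
                    driver_loci = data.frame(site = 1, s = s, h = h),
                    sampled_generations = c(4, 17), seed = 31)
  set.seed(31)
  finals <- replicate(reps, evolve_population(fp, cfg, selected = TRUE)$freq[1, "F17"])
  expected <- oracle_selection_recursion(0.5, s, h, 17)
  expect_lt(abs(mean(finals) - expected), 4 * sd(finals) / sqrt(reps) + 0.01)
})

test_that("driver loci are inert in control populations", {
  cfg <- sim_config(n_loci = 50, ne = 150, arms = c(chr2L = 1e6),
                    driver_loci = data.frame(site = 1:5, s = 1, h = 0.5),
                    unlinked = TRUE, seed = 3)
  fp <- build_founders(cfg)
  set.seed(99)
  finals <- replicate(20, evolve_population(fp, cfg, selected = FALSE)$freq[1:5, "F17"])
  expect_lt(abs(mean(finals - fp$founder_freq[1:5])), 0.05)
})

test_that("pooled sequencing obeys its error and depth models", {
  cfg <- sim_config(n_loci = 500, ne = 100, pool_individuals = 50,
                    arms = c(chr2L = 1e6), depth_mean = 100,
                    depth_dispersion = Inf, error_rate = 0, seed = 13)
  fp <- build_founders(cfg)
  state <- matrix(1L, cfg$n_loci, 2L * cfg$ne)  # fixed for alt
  set.seed(1)
  sq <- sequence_pool(state, fp, cfg)
  ai <- cbind(seq_len(cfg$n_loci), match(fp$sites$alt, c("A", "T", "C", "G")))
  expect_equal(sq$counts[ai], rowSums(sq$counts))  # all reads are alt
  # Poisson limit: mean depth ~ depth_mean
  expect_lt(abs(mean(rowSums(sq$counts)) - 100), 3 * sqrt(100 / 500))

  # error process: pool fixed for ref, non-ref fraction ~ error_rate
  cfg2 <- sim_config(n_loci = 2000, ne = 100, pool_individuals = 50,
                     arms = c(chr2L = 1e6), depth_mean = 500,
                     error_rate = 0.003, seed = 13)
  fp2 <- build_founders(cfg2)
  state0 <- matrix(0L, cfg2$n_loci, 2L * cfg2$ne)
  set.seed(2)
  sq2 <- sequence_pool(state0, fp2, cfg2)
  ri <- cbind(seq_len(cfg2$n_loci), match(fp2$sites$ref, c("A", "T", "C", "G")))
  total <- sum(sq2$counts)
  nonref <- total - sum(sq2$counts[ri])
  expect_gt(total, 9e5)
  expect_equal(nonref / total, 0.003, tolerance = 0.15)
})

test_that("pool counts are binomial around the error-adjusted pool fraction", {
  e <- 0.01
  cfg <- quick_config(n_loci = 1000, error_rate = e, depth_mean = 100)
  ex <- generate_experiment(cfg)
  bases <- c("A", "T", "C", "G")
  ai <- match(ex$counts$sites$alt, bases)
  # moment match pooled over all 12 samples: total alt reads vs the
  # Binomial(d, f(1-e) + (1-f)e/3) expectation, within 4 binomial SD
  obs <- expd <- vard <- 0
  for (k in seq_along(ex$counts$samples)) {
    id <- ex$counts$samples[k]
    pop <- sub("_F\\d+$", "", id)
    gen <- sub("^.*_(F\\d+)$", "\\1", id)
    f <- ex$truth$pool_fraction[, gen, pop]
    alt_counts <- ex$counts$counts[cbind(seq_len(cfg$n_loci), ai, k)]
    depth <- rowSums(ex$counts$counts[, , k])
    pexp <- f * (1 - e) + (1 - f) * e / 3
    obs <- obs + sum(alt_counts)
    expd <- expd + sum(depth * pexp)
    vard <- vard + sum(depth * pexp * (1 - pexp))
  }
  expect_lt(abs(obs - expd), 4 * sqrt(vard))
})

test_that("truth table and emitted counts agree at high depth", {
  cfg <- quick_config(n_loci = 400, depth_mean = 1e4, error_rate = 0)
  ex <- generate_experiment(cfg)
  bases <- c("A", "T", "C", "G")
  ai <- match(ex$counts$sites$alt, bases)
  k <- which(ex$counts$samples == "CF2_F17")
  alt_counts <- ex$counts$counts[cbind(seq_len(cfg$n_loci), ai, k)]
  depth <- rowSums(ex$counts$counts[, , k])
  f <- ex$truth$pool_fraction[, "F17", "CF2"]
  expect_lt(max(abs(alt_counts / depth - f)), 0.03)
})

test_that("the default experiment yields 12 samples and is seed-reproducible", {
  cfg <- quick_config()
  ex <- generate_experiment(cfg)
  expect_equal(length(ex$counts$samples), 12)  # 2 treatments x 3 reps x 2 gens
  expect_equal(nrow(ex$design), 12)
  expect_equal(sum(ex$design$treatment == "selected"), 6)
  expect_setequal(unique(ex$design$generation), c(4, 17))

  f1 <- tempfile(); f2 <- tempfile()
  write_sync(ex$counts, f1)
  write_sync(generate_experiment(cfg)$counts, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical reruns
  unlink(c(f1, f2))
})

test_that("sync files round-trip exactly", {
  cfg <- quick_config(n_loci = 50)
  ex <- generate_experiment(cfg)
  f <- tempfile()
  write_sync(ex$counts, f)
  pc <- read_sync(f)
  expect_identical(pc$counts, ex$counts$counts)
  expect_identical(pc$sites$pos, ex$counts$sites$pos)
  expect_identical(pc$samples, ex$counts$samples)
  unlink(f)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(error_rate = 0.3), "error_rate")
  expect_error(sim_config(driver_loci = data.frame(site = 10, s = -1.5, h = 0.5),
                          n_loci = 20), "selection")
  expect_error(sim_config(driver_loci = data.frame(site = 50, s = 0.1, h = 0.5),
                          n_loci = 20), "1..n_loci", fixed = TRUE)
  expect_error(sim_config(pool_individuals = 200, ne = 100), "pool_individuals")
  expect_error(sim_config(arms = c(1e6, 2e6)), "named")
})
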