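# Forward simulation of a replicated evolve-and-resequence experiment:
# isofemale-line founders -> Wright-Fisher drift/selection/recombination ->
# pooled sequencing counts, with a truth table of population allele
# frequencies for downstream calibration checks.

NUCS <- c("A", "T", "C", "G")
ALLELE_CLASSES <- c("A", "T", "C", "G", "N", "del")

#' Simulation configuration for a replicated E&R experiment
#'
#' Describes the experimental design emulated by the simulator: a founding
#' population assembled from wild-derived isofemale lines, split into
#' replicate populations per treatment, evolved under Wright-Fisher dynamics
#' with optional selection at driver loci, and sequenced as whole-fly pools
#' at selected generations.
#'
#' @param n_lines Number of founder isofemale lines (default 27, the study
#'   design).
#' @param haploids_per_line Distinct haploid genomes carried per line
#'   (default 4: a wild-mated female contributes at least four).
#' @param arms Named numeric vector of chromosome-arm lengths in bp.
#' @param n_loci Number of segregating sites to simulate.
#' @param recomb_rate Per-bp per-generation crossover rate. Interval
#'   recombination fractions follow Haldane's map function; loci on
#'   different arms assort independently.
#' @param ne Diploid census size of each replicate population (default
#'   2000, the reported scale of the replicate cages).
#' @param n_replicates_per_treatment Replicate populations per treatment
#'   (default 3).
#' @param sampled_generations Generations at which pools are sequenced
#'   (default c(4, 17)).
#' @param driver_loci Data frame with columns \code{site} (locus index),
#'   \code{s} (selection coefficient > -1) and \code{h} (dominance), plus
#'   an optional \code{start_freq} column forcing the founder target
#'   frequency at that site (NA = draw from the SFS like any other site);
#'   may be empty for a neutral simulation.
#' @param pool_individuals Flies pooled for sequencing (default 100, i.e.
#'   200 chromosomes).
#' @param depth_mean Expected read depth per site per sample.
#' @param depth_dispersion Negative-binomial size parameter for depth;
#'   \code{Inf} gives Poisson depth.
#' @param error_rate Per-read miscall probability (uniform to the three
#'   other nucleotides); must be < 0.25.
#' @param within_line_identity Probability that a founder line is fully
#'   homozygous at a site (its haploids share one allele), mimicking partial
#'   inbreeding of isofemale lines.
#' @param founder_ld_scale Mean length (bp) of founder haplotype blocks:
#'   each arm is partitioned into exponential-length segments whose sites
#'   share a per-line template pattern, mimicking the identical-by-descent
#'   blocks of lab-cultured isofemale lines that drive local hitchhiking.
#'   0 disables; ignored when \code{unlinked = TRUE}.
#' @param founder_ld_strength Probability that a line adopts its block
#'   template at a site (default 0.5, i.e. between-site r-squared ~ 0.25
#'   within a founder block: partial long-range hitchhiking rather than
#'   near-duplication of the driven site).
#' @param selection_onset First generation at which drivers confer fitness
#'   effects in selected populations (default 1).
#' @param unlinked If TRUE, all loci assort independently regardless of
#'   positions (free recombination).
#' @param seed Integer seed; every simulator entry point is deterministic
#'   given the seed.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_lines = 27,
                       haploids_per_line = 4,
                       arms = c(chr2L = 23e6, chr2R = 21e6, chr3L = 24e6,
                                chr3R = 28e6, chrX = 22e6),
                       n_loci = 2000,
                       recomb_rate = 2e-8,
                       ne = 2000,
                       n_replicates_per_treatment = 3,
                       sampled_generations = c(4, 17),
                       driver_loci = data.frame(site = integer(), s = numeric(),
                                                h = numeric()),
                       pool_individuals = 100,
                       depth_mean = 80,
                       depth_dispersion = 5,
                       error_rate = 0.001,
                       within_line_identity = 0.5,
                       founder_ld_scale = 1e5,
                       founder_ld_strength = 0.5,
                       selection_onset = 1,
                       unlinked = FALSE,
                       seed = 1) {
  cfg <- list(n_lines = as.integer(n_lines),
              haploids_per_line = as.integer(haploids_per_line),
              arms = arms, n_loci = as.integer(n_loci),
              recomb_rate = recomb_rate, ne = as.integer(ne),
              n_replicates_per_treatment = as.integer(n_replicates_per_treatment),
              sampled_generations = as.integer(sampled_generations),
              driver_loci = driver_loci,
              pool_individuals = as.integer(pool_individuals),
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              error_rate = error_rate,
              within_line_identity = within_line_identity,
              founder_ld_scale = founder_ld_scale,
              founder_ld_strength = founder_ld_strength,
              selection_onset = as.integer(selection_onset),
              unlinked = isTRUE(unlinked),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$arms), length(cfg$arms) >= 1)
  if (is.null(names(cfg$arms)) || anyNA(names(cfg$arms)) ||
      any(names(cfg$arms) == ""))
    stop("'arms' must be a named vector of arm lengths", call. = FALSE)
  pos_counts <- c(cfg$n_lines, cfg$haploids_per_line, cfg$n_loci, cfg$ne,
                  cfg$n_replicates_per_treatment, cfg$pool_individuals)
  if (any(pos_counts <= 0L)) stop("all counts must be positive", call. = FALSE)
  if (any(cfg$arms <= 0)) stop("arm lengths must be positive", call. = FALSE)
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.25)
    stop("error_rate must be in [0, 0.25)", call. = FALSE)
  if (cfg$recomb_rate < 0) stop("recomb_rate must be >= 0", call. = FALSE)
  if (cfg$depth_mean <= 0 || cfg$depth_dispersion <= 0)
    stop("depth_mean and depth_dispersion must be positive", call. = FALSE)
  if (any(cfg$sampled_generations < 1L))
    stop("sampled_generations must be >= 1", call. = FALSE)
  if (cfg$pool_individuals > cfg$ne)
    stop("pool_individuals must not exceed ne", call. = FALSE)
  if (cfg$within_line_identity < 0 || cfg$within_line_identity > 1)
    stop("within_line_identity must be in [0, 1]", call. = FALSE)
  if (cfg$founder_ld_scale < 0)
    stop("founder_ld_scale must be >= 0", call. = FALSE)
  if (cfg$founder_ld_strength < 0 || cfg$founder_ld_strength > 1)
    stop("founder_ld_strength must be in [0, 1]", call. = FALSE)
  d <- cfg$driver_loci
  if (nrow(d)) {
    stopifnot(all(c("site", "s", "h") %in% names(d)))
    if (any(d$site < 1L) || any(d$site > cfg$n_loci))
      stop("driver site indices must lie in 1..n_loci", call. = FALSE)
    if (any(d$s <= -1)) stop("selection coefficients must be > -1", call. = FALSE)
  }
  invisible(cfg)
}

#' Build the founder haplotype pool
#'
#' Draws per-site target allele frequencies from a 1/f site-frequency
#' spectrum truncated to [1/H, 0.5] (H = total founder haplotypes) and
#' assigns alleles line-wise: with probability \code{within_line_identity} a
#' line is homozygous at the site (all its haploids share one allele drawn at
#' the target frequency), otherwise its haploids are independent draws.
#' Sites are redrawn until segregating; positions are strictly increasing
#' within each arm.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{founder_pool} with elements
#'   \code{haplotypes} (0/1 matrix, rows = founder haploid genomes),
#'   \code{sites} (data frame: arm, pos, ref, alt), and \code{founder_freq}
#'   (per-site alt-allele fraction among founder haplotypes).
#' @export
build_founders <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  H <- config$n_lines * config$haploids_per_line
  L <- config$n_loci

  # positions: allocate loci to arms proportional to length, sorted within arm
  arm_alloc <- round(config$arms / sum(config$arms) * L)
  # fix rounding so the total is exactly L
  while (sum(arm_alloc) != L) {
    i <- if (sum(arm_alloc) > L) which.max(arm_alloc) else which.min(arm_alloc)
    arm_alloc[i] <- arm_alloc[i] + sign(L - sum(arm_alloc))
  }
  if (any(arm_alloc > config$arms))
    stop("n_loci exceeds the number of distinct positions available", call. = FALSE)
  arm <- rep(names(config$arms), arm_alloc)
  pos <- unlist(lapply(seq_along(config$arms), function(i) {
    sort(sample.int(config$arms[i], arm_alloc[i]))
  }), use.names = FALSE)

  # 1/f SFS on attainable frequencies
  kmax <- floor(H / 2)
  if (kmax < 1L)
    stop("no segregating site is attainable: the truncated SFS needs at ",
         "least 2 founder haplotypes (n_lines x haploids_per_line = ", H,
         ")", call. = FALSE)
  fgrid <- seq_len(kmax) / H
  w <- 1 / fgrid
  line_id <- rep(seq_len(config$n_lines), each = config$haploids_per_line)

  haps <- matrix(0L, nrow = H, ncol = L)
  f_target <- fgrid[sample.int(kmax, L, replace = TRUE, prob = w)]
  forced <- rep(NA_real_, L)
  if (nrow(config$driver_loci) && "start_freq" %in% names(config$driver_loci))
    forced[config$driver_loci$site] <- config$driver_loci$start_freq
  f_target[!is.na(forced)] <- forced[!is.na(forced)]

  # founder haplotype blocks: each arm is partitioned into segments with
  # exponential lengths (mean founder_ld_scale); all sites of a segment
  # share a per-line template pattern which each line adopts with
  # probability founder_ld_strength, giving moderate distance-limited LD
  # like the identical-by-descent blocks of lab-cultured isofemale lines
  persist <- !config$unlinked && config$founder_ld_scale > 0
  fresh_pattern <- function(f) {
    homo <- runif(config$n_lines) < config$within_line_identity
    line_allele <- rbinom(config$n_lines, 1L, f)
    a <- line_allele[line_id]                         # homozygous-line states
    free <- !homo[line_id]
    a[free] <- rbinom(sum(free), 1L, f)               # independent haploids
    a
  }
  blk <- integer(L)
  if (persist) {
    nb <- 0L
    for (aname in unique(arm)) {
      rows <- which(arm == aname)
      cuts <- cumsum(stats::rexp(length(rows), 1 / config$founder_ld_scale))
      edge <- pos[rows[1L]] + cuts
      nblk <- findInterval(pos[rows], c(-Inf, edge)) + nb
      blk[rows] <- nblk
      nb <- max(nblk)
    }
  } else {
    blk <- seq_len(L)
  }
  rho <- if (persist) config$founder_ld_strength else 0
  # block template frequencies: a block holding a forced driver site adopts
  # the forced frequency so the driver's hitchhikers start near it
  templates <- list()
  for (j in which(!is.na(forced))) {
    templates[[as.character(blk[j])]] <- fresh_pattern(forced[j])
  }
  for (j in seq_len(L)) {
    b <- as.character(blk[j])
    if (is.null(templates[[b]]))
      templates[[b]] <- fresh_pattern(fgrid[sample.int(kmax, 1L, prob = w)])
    ok <- FALSE
    use_rho <- rho
    for (attempt in seq_len(1000L)) {
      f_site <- if (!is.na(forced[j])) forced[j] else f_target[j]
      a <- fresh_pattern(f_site)
      if (use_rho > 0) {
        adopt <- (runif(config$n_lines) < use_rho)[line_id]
        a[adopt] <- templates[[b]][adopt]
      }
      s <- sum(a)
      if (s > 0L && s < H) { haps[, j] <- a; ok <- TRUE; break }
      use_rho <- 0                          # retry without the template
    }
    if (!ok)
      stop("could not make site ", j, " segregating: the requested SFS ",
           "(target frequency ", signif(f_target[j], 3),
           ") cannot produce a polymorphic site among ", H,
           " founder haplotypes", call. = FALSE)
  }

  ref <- sample(NUCS, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(NUCS, r), 1L), character(1))
  founders <- list(haplotypes = haps,
                   sites = data.frame(arm = arm, pos = pos, ref = ref,
                                      alt = unname(alt),
                                      stringsAsFactors = FALSE),
                   founder_freq = colMeans(haps),
                   config_seed = config$seed)
  class(founders) <- "founder_pool"
  founders
}

# Per-interval recombination fractions between adjacent loci (Haldane map);
# loci on different arms assort independently (fraction 1/2).
interval_recomb <- function(sites, recomb_rate, unlinked = FALSE) {
  L <- nrow(sites)
  if (L <= 1L) return(numeric(0))
  if (unlinked) return(rep(0.5, L - 1L))
  d <- diff(sites$pos)
  r <- 0.5 * (1 - exp(-2 * recomb_rate * d))
  r[sites$arm[-L] != sites$arm[-1L]] <- 0.5
  r
}

# Form n gametes from diploid parents (rows 2i-1, 2i of `haps`) with
# crossovers realized as per-interval Bernoulli switches.
make_gametes <- function(haps, parents, rfrac) {
  storage.mode(haps) <- "integer"
  .make_gametes_cpp(haps, as.integer(parents), as.numeric(rfrac))
}

#' Evolve one replicate population by Wright-Fisher dynamics
#'
#' Starts from \code{ne} diploids whose haplotypes are drawn uniformly from
#' the founder pool, then each generation samples parents with probability
#' proportional to multiplicative fitness over driver loci (1, 1+hs, 1+s by
#' genotype; drivers act only when \code{selected} and the generation has
#' reached \code{selection_onset}) and forms gametes with Haldane-model
#' crossovers. Population allele frequencies and haplotype states are
#' recorded at \code{sampled_generations}.
#'
#' @param founders A \code{\link{build_founders}} result.
#' @param config A \code{\link{sim_config}}.
#' @param selected Logical; do driver loci confer fitness effects?
#' @return List with \code{freq} (loci x sampled generations matrix of true
#'   population allele frequencies) and \code{states} (list of haplotype
#'   matrices, loci x chromosomes, at the sampled generations; chromosome
#'   columns 2i-1 and 2i belong to diploid i).
#' @export
evolve_population <- function(founders, config, selected = FALSE) {
  L <- config$n_loci
  ne <- config$ne
  rfrac <- interval_recomb(founders$sites, config$recomb_rate, config$unlinked)
  H <- founders$haplotypes
  # population lives loci-major: one column per chromosome
  pop <- t(H[sample.int(nrow(H), 2L * ne, replace = TRUE), , drop = FALSE])

  drivers <- config$driver_loci
  has_drivers <- nrow(drivers) > 0L
  gmax <- max(config$sampled_generations)
  freq <- matrix(NA_real_, L, length(config$sampled_generations),
                 dimnames = list(NULL, paste0("F", config$sampled_generations)))
  states <- vector("list", length(config$sampled_generations))

  for (gen in seq_len(gmax)) {
    w <- rep(1, ne)
    if (selected && has_drivers && gen >= config$selection_onset) {
      idx <- drivers$site
      g <- pop[idx, seq(1L, 2L * ne, by = 2L), drop = FALSE] +
           pop[idx, seq(2L, 2L * ne, by = 2L), drop = FALSE]
      logw_site <- rbind(0, log1p(drivers$h * drivers$s), log1p(drivers$s))
      lw <- colSums(matrix(logw_site[cbind(as.vector(g) + 1L,
                                           rep(seq_along(idx), times = ne))],
                           length(idx), ne))
      w <- exp(lw - max(lw))
      if (all(w == 0)) stop("population extinct: all fitnesses are zero",
                            call. = FALSE)
    }
    p1 <- sample.int(ne, ne, replace = TRUE, prob = w)
    p2 <- sample.int(ne, ne, replace = TRUE, prob = w)
    g1 <- make_gametes(pop, p1, rfrac)
    g2 <- make_gametes(pop, p2, rfrac)
    pop <- matrix(0L, L, 2L * ne)
    pop[, seq(1L, 2L * ne, by = 2L)] <- g1
    pop[, seq(2L, 2L * ne, by = 2L)] <- g2
    hit <- which(config$sampled_generations == gen)
    if (length(hit)) {
      freq[, hit] <- rowMeans(pop)
      states[[hit]] <- pop
    }
  }
  list(freq = freq, states = states)
}

#' Sequence a pooled sample of whole flies
#'
#' Samples \code{pool_individuals} diploids without replacement (both
#' chromosomes of each fly enter the pool), draws per-site depth from a
#' negative binomial (Poisson when \code{depth_dispersion = Inf}), draws
#' alt-origin reads binomially from the pool allele fraction, and miscalls
#' each read to a uniformly chosen other nucleotide with probability
#' \code{error_rate}.
#'
#' @param state Haplotype matrix (loci x 2*ne chromosomes) of the live
#'   population.
#' @param founders Founder pool (provides ref/alt base identities).
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{counts} (loci x 6 matrix over A,T,C,G,N,del),
#'   and \code{pool_fraction} (true alt fraction among pooled chromosomes).
#' @export
sequence_pool <- function(state, founders, config) {
  ne <- ncol(state) / 2L
  L <- nrow(state)
  flies <- sample.int(ne, config$pool_individuals)
  cols <- as.vector(rbind(2L * flies - 1L, 2L * flies))
  f <- rowMeans(state[, cols, drop = FALSE])

  depth <- if (is.finite(config$depth_dispersion)) {
    rnbinom(L, size = config$depth_dispersion, mu = config$depth_mean)
  } else {
    rpois(L, config$depth_mean)
  }

  e <- config$error_rate
  alt_origin <- rbinom(L, depth, f)
  ref_origin <- depth - alt_origin
  alt_kept <- rbinom(L, alt_origin, 1 - e)
  ref_kept <- rbinom(L, ref_origin, 1 - e)

  counts <- matrix(0L, L, 6L, dimnames = list(NULL, ALLELE_CLASSES))
  ri <- match(founders$sites$ref, NUCS)
  ai <- match(founders$sites$alt, NUCS)
  counts[cbind(seq_len(L), ri)] <- ref_kept
  counts[cbind(seq_len(L), ai)] <- counts[cbind(seq_len(L), ai)] + alt_kept
  counts[, 1:4] <- counts[, 1:4] +
    spread_miscalls(ref_origin - ref_kept, ri) +
    spread_miscalls(alt_origin - alt_kept, ai)
  list(counts = counts, pool_fraction = f, depth = depth)
}

# Distribute miscalled reads uniformly over the three nucleotides other
# than their origin base. `err` = miscalled reads per site, `origin` =
# origin base index (1..4). Returns an L x 4 count matrix.
spread_miscalls <- function(err, origin) {
  L <- length(err)
  out <- matrix(0L, L, 4L)
  if (!any(err > 0L)) return(out)
  others_tab <- t(vapply(1:4, function(b) setdiff(1:4, b), integer(3)))
  others <- others_tab[origin, , drop = FALSE]
  c1 <- rbinom(L, err, 1 / 3)
  c2 <- rbinom(L, err - c1, 1 / 2)
  c3 <- err - c1 - c2
  idx <- seq_len(L)
  out[cbind(idx, others[, 1])] <- c1
  out[cbind(idx, others[, 2])] <- out[cbind(idx, others[, 2])] + c2
  out[cbind(idx, others[, 3])] <- out[cbind(idx, others[, 3])] + c3
  out
}

#' Simulate the full replicated experiment
#'
#' Builds founders, evolves every replicate of both treatments from the same
#' founder pool (drivers under selection only in treatment replicates from
#' \code{selection_onset} onward), sequences pools at each sampled
#' generation, and returns the pooled counts, the sample design and a truth
#' table of population and pool allele frequencies.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{counts} (a \code{pooled_counts} object),
#'   \code{design} (sample design data frame), and \code{truth} (list:
#'   driver sites, founder frequencies, per-population true trajectories and
#'   pool fractions).
#' @export
generate_experiment <- function(config) {
  validate_sim_config(config)
  founders <- build_founders(config)      # seeds the RNG with config$seed
  nrep <- config$n_replicates_per_treatment
  gens <- config$sampled_generations
  treatments <- c("selected", "control")
  prefix <- c(selected = "AF", control = "CF")

  samples <- character(0)
  design <- NULL
  counts <- array(0L, dim = c(config$n_loci, 6L,
                              2L * nrep * length(gens)),
                  dimnames = list(NULL, ALLELE_CLASSES, NULL))
  traj <- array(NA_real_, dim = c(config$n_loci, length(gens), 2L * nrep),
                dimnames = list(NULL, paste0("F", gens), NULL))
  pool_frac <- traj
  pops <- character(0)

  k <- 0L
  for (tr in treatments) {
    for (r in seq_len(nrep)) {
      ev <- evolve_population(founders, config, selected = (tr == "selected"))
      pop_id <- paste0(prefix[[tr]], r)
      pops <- c(pops, pop_id)
      traj[, , length(pops)] <- ev$freq
      for (gi in seq_along(gens)) {
        sq <- sequence_pool(ev$states[[gi]], founders, config)
        k <- k + 1L
        counts[, , k] <- sq$counts
        pool_frac[, gi, length(pops)] <- sq$pool_fraction
        samples <- c(samples, paste0(pop_id, "_F", gens[gi]))
        design <- rbind(design, data.frame(
          id = paste0(pop_id, "_F", gens[gi]), treatment = tr,
          replicate = r, generation = gens[gi],
          pool_chromosomes = 2L * config$pool_individuals,
          stringsAsFactors = FALSE))
      }
      ev$states <- NULL
    }
  }
  dimnames(counts)[[3]] <- samples
  dimnames(traj)[[3]] <- pops
  dimnames(pool_frac)[[3]] <- pops

  pc <- pooled_counts(founders$sites, counts)
  truth <- list(driver_sites = config$driver_loci$site,
                founder_freq = founders$founder_freq,
                trajectory = traj, pool_fraction = pool_frac)
  list(counts = pc, design = design, truth = truth)
}
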