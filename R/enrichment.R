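# Gene-level enrichment: SNP-resampling gene-set tests (gene-length-bias
# corrected), Reynolds FST / population branch statistic computation, PBS
# tail enrichment of candidate genes, and fly-to-human ortholog joining.

#' Per-gene minimum GLMM p over assigned SNPs
#'
#' Assigns each SNP to every gene whose interval extended by \code{flank}
#' bp contains it (a SNP may hit several overlapping genes) and records the
#' smallest per-SNP p-value per gene. Genes with no assigned SNP are
#' excluded.
#'
#' @param results Per-variant data frame with arm, pos (1-based) and p.
#' @param genes Gene models (gene, arm, start, end; 1-based closed).
#' @param flank Flanking width in bp added to both gene ends (default 500).
#' @return List with \code{scores} (gene, min_p, n_snps) and \code{map}
#'   (data frame snp row index -> gene) for resampling.
#' @export
gene_min_p <- function(results, genes, flank = 500) {
  gr_snp <- GenomicRanges::GRanges(results$arm,
                                   IRanges::IRanges(results$pos, results$pos))
  gr_gene <- GenomicRanges::GRanges(
    genes$arm, IRanges::IRanges(pmax(genes$start - flank, 1L),
                                genes$end + flank))
  hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene)
  map <- data.frame(snp = S4Vectors::queryHits(hits),
                    gene = genes$gene[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  if (!nrow(map))
    return(list(scores = data.frame(gene = character(0), min_p = numeric(0),
                                    n_snps = integer(0)),
                map = map))
  sp <- split(results$p[map$snp], map$gene)
  scores <- data.frame(gene = names(sp),
                       min_p = vapply(sp, min, numeric(1)),
                       n_snps = lengths(sp), row.names = NULL,
                       stringsAsFactors = FALSE)
  list(scores = scores, map = map)
}

#' Gene-set enrichment by SNP resampling
#'
#' Tests whether a gene set is overrepresented among the genes hit by the
#' most significant SNPs. The candidate SNP set is the top \code{tail}
#' fraction of per-SNP p-values; the observed statistic is the number of
#' set genes hit by at least one candidate SNP (a gene counts once no
#' matter how many of its SNPs qualify, which corrects the gene-length
#' bias). The null resamples SNP sets of the same size uniformly from all
#' scored SNPs \code{n_sims} times. The empirical p-value is
#' \eqn{(1 + \#\{null \ge obs\})/(1 + n_{sims})}, Bonferroni-adjusted
#' across the tested sets.
#'
#' @param gene_sets Named list of character vectors of gene ids; members
#'   without any assigned SNP are dropped with a warning.
#' @param gmp Result of \code{\link{gene_min_p}}.
#' @param results The per-variant results used for \code{gmp} (provides
#'   per-SNP p-values).
#' @param n_sims Resampling draws (default 10000; use >= 1000 for reported
#'   p-values).
#' @param tail Candidate tail fraction of SNP p-values (default 0.05).
#' @param seed Integer seed for the resampling RNG.
#' @return Data frame: set, n_set_genes, observed, p_empirical,
#'   p_bonferroni.
#' @export
geneset_resampling_test <- function(gene_sets, gmp, results, n_sims = 10000L,
                                    tail = 0.05, seed = 1L) {
  stopifnot(tail > 0, tail < 1, n_sims >= 1L)
  if (!length(gene_sets)) stop("no gene sets supplied", call. = FALSE)
  if (is.character(gene_sets)) gene_sets <- list(set = gene_sets)
  set.seed(seed)
  scored_genes <- gmp$scores$gene
  snp_p <- results$p
  n_snp <- length(snp_p)
  cutoff <- lower_quantile(snp_p, tail)
  cand <- which(snp_p <= cutoff)
  n_cand <- length(cand)

  # snp -> set-gene incidence, per set
  res <- lapply(names(gene_sets), function(nm) {
    set <- unique(gene_sets[[nm]])
    if (!length(set)) stop("empty gene set: ", nm, call. = FALSE)
    missing <- setdiff(set, scored_genes)
    if (length(missing))
      warning(length(missing), " unscored gene(s) dropped from set ", nm,
              call. = FALSE)
    set <- intersect(set, scored_genes)
    if (!length(set)) stop("gene set ", nm, " has no scored genes",
                           call. = FALSE)
    sub <- gmp$map[gmp$map$gene %in% set, , drop = FALSE]
    gene_id <- match(sub$gene, set)
    # observed: set genes hit by >= 1 candidate SNP
    obs <- length(unique(gene_id[sub$snp %in% cand]))
    null <- integer(n_sims)
    snp_hits <- split(gene_id, sub$snp)     # per-SNP set-gene lists
    hit_snps <- as.integer(names(snp_hits))
    for (b in seq_len(n_sims)) {
      draw <- sample.int(n_snp, n_cand)
      sel <- snp_hits[match(intersect(draw, hit_snps), hit_snps)]
      null[b] <- length(unique(unlist(sel, use.names = FALSE)))
    }
    p_emp <- (1 + sum(null >= obs)) / (1 + n_sims)
    data.frame(set = nm, n_set_genes = length(set), n_candidate_snps = n_cand,
               observed = obs, null_mean = mean(null), p_empirical = p_emp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p_empirical * nrow(out), 1)
  out
}

#' Reynolds-family FST estimator from allele frequencies
#'
#' Moment estimator of the coancestry coefficient for two populations from
#' allele frequencies and chromosome sample sizes, with small-sample
#' correction: the numerator \eqn{(p_1-p_2)^2 - p_1q_1/(n_1-1) -
#' p_2q_2/(n_2-1)} is unbiased for the squared frequency difference and the
#' denominator adds unbiased within-population diversity terms so that the
#' ratio estimates \eqn{(p_1-p_2)^2 / (p_1q_2 + p_2q_1)} at large n.
#' Negative estimates are clipped to 0 (the raw value is returned
#' alongside); sites monomorphic in both populations give 0.
#'
#' @param p1,p2 Allele frequencies in the two populations.
#' @param n1,n2 Chromosome (haploid) sample sizes, >= 2.
#' @return Data frame with \code{fst} (clipped) and \code{fst_raw}.
#' @export
reynolds_fst <- function(p1, p2, n1, n2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  q1 <- 1 - p1
  q2 <- 1 - p2
  num <- (p1 - p2)^2 - p1 * q1 / (n1 - 1) - p2 * q2 / (n2 - 1)
  den <- num + n1 * p1 * q1 / (n1 - 1) + n2 * p2 * q2 / (n2 - 1)
  fst_raw <- ifelse(den > 0, num / den, 0)
  data.frame(fst = pmin(pmax(fst_raw, 0), 1), fst_raw = fst_raw)
}

#' Population branch statistic
#'
#' Converts pairwise FST values among the focal high-altitude population
#' (H), a lowland population (L) and an outgroup (O) into branch lengths
#' \eqn{T = -log(1 - F_{ST})} and returns the focal branch
#' \eqn{PBS = (T_{HL} + T_{HO} - T_{LO})/2}. Large values indicate
#' focal-specific allele-frequency divergence.
#'
#' @param fst_hl,fst_ho,fst_lo Pairwise FST values in [0, 1).
#' @return Data frame with t_hl, t_ho, t_lo and pbs (may be negative).
#' @export
compute_pbs <- function(fst_hl, fst_ho, fst_lo) {
  vals <- c(fst_hl, fst_ho, fst_lo)
  if (any(vals < 0 | vals >= 1))
    stop("FST values must lie in [0, 1); FST = 1 gives an infinite branch",
         call. = FALSE)
  t_hl <- -log1p(-fst_hl)
  t_ho <- -log1p(-fst_ho)
  t_lo <- -log1p(-fst_lo)
  data.frame(t_hl = t_hl, t_ho = t_ho, t_lo = t_lo,
             pbs = (t_hl + t_ho - t_lo) / 2)
}

#' Per-SNP PBS from three-population allele frequencies
#'
#' @param freqs Data frame with columns chrom, pos, gene (optional),
#'   freq_h, n_h, freq_l, n_l, freq_o, n_o (frequencies and chromosome
#'   counts for the focal, lowland and outgroup populations).
#' @return PBS record data frame: chrom, pos, gene, pairwise fst, branch
#'   lengths and pbs.
#' @export
pbs_from_frequencies <- function(freqs) {
  req <- c("chrom", "pos", "freq_h", "n_h", "freq_l", "n_l", "freq_o", "n_o")
  stopifnot(all(req %in% names(freqs)))
  f_hl <- reynolds_fst(freqs$freq_h, freqs$freq_l, freqs$n_h, freqs$n_l)$fst
  f_ho <- reynolds_fst(freqs$freq_h, freqs$freq_o, freqs$n_h, freqs$n_o)$fst
  f_lo <- reynolds_fst(freqs$freq_l, freqs$freq_o, freqs$n_l, freqs$n_o)$fst
  # an exact fixed difference would give an infinite branch; back off to
  # the largest finite value representable from the sample sizes
  cap <- 1 - 1e-12
  pbs <- compute_pbs(pmin(f_hl, cap), pmin(f_ho, cap), pmin(f_lo, cap))
  cbind(data.frame(chrom = freqs$chrom, pos = freqs$pos,
                   gene = if ("gene" %in% names(freqs)) freqs$gene
                          else NA_character_,
                   fst_hl = f_hl, fst_ho = f_ho, fst_lo = f_lo,
                   stringsAsFactors = FALSE),
        pbs)
}

#' Candidate-gene enrichment in the PBS tail
#'
#' Tests whether SNPs in candidate genes are overrepresented at or above
#' the (1 - tail) quantile of the genome-wide PBS distribution, by an exact
#' two-sided binomial test (minimum-likelihood convention, the
#' \code{binom.test} default; optionally doubling the smaller tail). The
#' baseline proportion is the realized tail fraction by default, or the
#' nominal \code{tail}.
#'
#' @param pbs Data frame with columns gene and pbs (e.g. from
#'   \code{\link{pbs_from_frequencies}} or an external PBS table).
#' @param candidate_genes Character vector of candidate gene ids.
#' @param tail Tail fraction in (0, 1) (default 0.05).
#' @param baseline "realized" (default) or "nominal".
#' @param alternative "minlik" (default) or "doubled".
#' @return Data frame: k (candidate SNPs in tail), n (candidate SNPs),
#'   p0, p_two_sided, direction, threshold.
#' @export
pbs_tail_enrichment <- function(pbs, candidate_genes, tail = 0.05,
                                baseline = c("realized", "nominal"),
                                alternative = c("minlik", "doubled")) {
  baseline <- match.arg(baseline)
  alternative <- match.arg(alternative)
  if (tail <= 0 || tail >= 1) stop("tail must lie in (0, 1)", call. = FALSE)
  is_cand <- pbs$gene %in% candidate_genes
  n <- sum(is_cand)
  if (n == 0L) stop("no SNPs in candidate genes", call. = FALSE)
  threshold <- quantile(pbs$pbs, 1 - tail, names = FALSE, na.rm = TRUE)
  in_tail <- pbs$pbs >= threshold
  k <- sum(is_cand & in_tail)
  p0 <- if (baseline == "realized") mean(in_tail, na.rm = TRUE) else tail
  p <- if (alternative == "minlik") {
    binom.test(k, n, p0)$p.value
  } else {
    pl <- pbinom(k, n, p0)
    pu <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    min(1, 2 * min(pl, pu))
  }
  data.frame(k = k, n = n, p0 = p0, p_two_sided = p,
             direction = if (k / n >= p0) "enriched" else "depleted",
             threshold = threshold, n_tail = sum(in_tail),
             n_total = nrow(pbs))
}

#' Shared candidate genes across populations
#'
#' Per-population hit lists and all pairwise and higher-order
#' intersections.
#'
#' @param hit_sets Named list (>= 2 populations) of character vectors of
#'   genes with at least one tail SNP.
#' @return List with \code{counts} (per combination), \code{shared_all}
#'   (genes in every population) and \code{intersections} (gene lists per
#'   combination).
#' @export
shared_gene_report <- function(hit_sets) {
  if (length(hit_sets) < 2L) stop("need >= 2 populations", call. = FALSE)
  pops <- names(hit_sets)
  hit_sets <- lapply(hit_sets, unique)
  combos <- unlist(lapply(2:length(pops), function(k)
    combn(pops, k, simplify = FALSE)), recursive = FALSE)
  inter <- lapply(combos, function(cmb) Reduce(intersect, hit_sets[cmb]))
  names(inter) <- vapply(combos, paste, character(1), collapse = "&")
  counts <- data.frame(
    combination = c(pops, names(inter)),
    n = c(vapply(hit_sets, length, integer(1)),
          vapply(inter, length, integer(1))), row.names = NULL,
    stringsAsFactors = FALSE)
  list(counts = counts,
       shared_all = inter[[length(inter)]],
       intersections = inter)
}

#' Join fly candidate genes to human orthologs
#'
#' Per source, drops fly genes mapped to more human genes than
#' \code{max_fanout}; takes the union of the surviving (fly, human) pairs
#' across sources; then removes pairs that any other source contradicts (a
#' source contradicts a pair when it asserts orthologs for the fly gene but
#' not that human gene — silence is not conflict).
#'
#' @param mapping Data frame with columns fly_gene, human_gene, source.
#' @param candidates Optional character vector of fly genes to translate;
#'   default: all.
#' @param max_fanout Maximum human orthologs per fly gene within one source
#'   (default 1, i.e. drop >= 2:1 mappings).
#' @return Data frame of retained fly_gene / human_gene pairs (restricted
#'   to \code{candidates} when given), with supporting sources.
#' @export
ortholog_join <- function(mapping, candidates = NULL, max_fanout = 1L) {
  req <- c("fly_gene", "human_gene", "source")
  if (!is.data.frame(mapping) || !all(req %in% names(mapping)))
    stop("mapping must have columns fly_gene, human_gene, source",
         call. = FALSE)
  mapping <- unique(mapping[req])
  # per-source fan-out filter
  keep <- rep(TRUE, nrow(mapping))
  for (src in unique(mapping$source)) {
    rows <- mapping$source == src
    fan <- table(mapping$fly_gene[rows])
    bad <- names(fan)[fan > max_fanout]
    keep[rows & mapping$fly_gene %in% bad] <- FALSE
  }
  mapping <- mapping[keep, , drop = FALSE]
  if (!nrow(mapping))
    return(data.frame(fly_gene = character(0), human_gene = character(0),
                      sources = character(0), stringsAsFactors = FALSE))
  pairs <- unique(data.frame(fly_gene = mapping$fly_gene,
                             human_gene = mapping$human_gene,
                             stringsAsFactors = FALSE))
  # conflict: a source asserts the fly gene but not this pair
  conflicted <- vapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$fly_gene[i]
    h <- pairs$human_gene[i]
    srcs <- unique(mapping$source[mapping$fly_gene == g])
    any(vapply(srcs, function(src) {
      asserted <- mapping$human_gene[mapping$fly_gene == g &
                                       mapping$source == src]
      !(h %in% asserted)
    }, logical(1)))
  }, logical(1))
  pairs <- pairs[!conflicted, , drop = FALSE]
  pairs$sources <- vapply(seq_len(nrow(pairs)), function(i) {
    paste(sort(unique(mapping$source[
      mapping$fly_gene == pairs$fly_gene[i] &
        mapping$human_gene == pairs$human_gene[i]])), collapse = ",")
  }, character(1))
  if (!is.null(candidates))
    pairs <- pairs[pairs$fly_gene %in% candidates, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
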