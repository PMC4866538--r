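# Count-level variant QC: VarRef merging, third-allele (sequencing error)
# thresholding, coverage filters, and the binomial confidence-interval
# minor-allele filter that defines the analyzable biallelic variant set.

#' Filtering configuration
#'
#' @param third_allele_quantile Quantile of the third-allele count
#'   distribution used as the sequencing-error threshold (default 0.75).
#' @param min_global_depth Sites with merged depth less than or equal to
#'   this are dropped (strict ">" retention; default 10).
#' @param high_cov_quantile Sites above this quantile of the merged-depth
#'   distribution at biallelic sites are dropped (default 0.95).
#' @param per_sample_min_depth A site failing this depth in every sample of
#'   a generation cohort is dropped (default 10).
#' @param ci_level Two-sided confidence level for the minor-allele
#'   Clopper-Pearson bound (default 0.9973).
#' @param third_allele_per_sample If TRUE, the tri-allelic rule drops a site
#'   when any single sample exceeds the threshold, instead of the merged
#'   counts (alternative reading of the rule).
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(third_allele_quantile = 0.75,
                          min_global_depth = 10,
                          high_cov_quantile = 0.95,
                          per_sample_min_depth = 10,
                          ci_level = 0.9973,
                          third_allele_per_sample = FALSE) {
  stopifnot(third_allele_quantile > 0, third_allele_quantile < 1,
            high_cov_quantile > 0, high_cov_quantile < 1,
            ci_level > 0.5, ci_level < 1,
            min_global_depth >= 0, per_sample_min_depth >= 0)
  structure(list(third_allele_quantile = third_allele_quantile,
                 min_global_depth = min_global_depth,
                 high_cov_quantile = high_cov_quantile,
                 per_sample_min_depth = per_sample_min_depth,
                 ci_level = ci_level,
                 third_allele_per_sample = isTRUE(third_allele_per_sample)),
            class = "filter_config")
}

# lower empirical quantile (type 1) -- integer thresholds on count data
lower_quantile <- function(x, q) {
  sort(x)[max(1L, ceiling(length(x) * q))]
}

#' Merge all samples into a variant reference (VarRef)
#'
#' Element-wise sum of per-nucleotide counts across samples, emulating the
#' merged high-depth alignment used to ascertain candidate variant sites.
#'
#' @param pc A \code{\link{pooled_counts}} object.
#' @return Matrix (sites x 6 allele classes) of summed counts, with the
#'   median merged depth in attribute \code{median_depth}.
#' @export
merge_varref <- function(pc) {
  v <- rowSums(pc$counts, dims = 2L)
  storage.mode(v) <- "integer"
  attr(v, "median_depth") <- median(rowSums(v))
  v
}

#' Sequencing-error threshold from the third-allele count distribution
#'
#' Sorts the merged allele-class counts of every site in descending order,
#' collects the third-largest count per site, and returns the lower
#' empirical quantile of that distribution as an integer threshold.
#'
#' @param varref Merged counts from \code{\link{merge_varref}}.
#' @param q Quantile (default 0.75).
#' @return Integer threshold.
#' @export
third_allele_threshold <- function(varref, q = 0.75) {
  if (!nrow(varref)) stop("empty VarRef", call. = FALSE)
  third <- nth_largest(varref, 3L)
  as.integer(lower_quantile(third, q))
}

# per-row k-th largest value of a count matrix
nth_largest <- function(m, k) {
  apply(m, 1L, function(x) sort(x, decreasing = TRUE)[k])
}

#' Call candidate biallelic sites
#'
#' Drops sites whose merged third-allele count exceeds the error threshold
#' (tri-allelic sites), assigns ref/alt as the two most frequent merged
#' allele classes, requires the merged minor-allele count to exceed the
#' threshold, and recomputes depth from the two retained alleles only.
#'
#' @param pc A \code{\link{pooled_counts}} object.
#' @param varref Merged counts from \code{\link{merge_varref}}.
#' @param threshold Integer error threshold from
#'   \code{\link{third_allele_threshold}}.
#' @param per_sample Use the per-sample reading of the tri-allelic rule.
#' @return A biallelic variant table: list of class \code{biallelic_table}
#'   with \code{sites} (arm, pos, ref, alt), \code{alt} and \code{depth}
#'   (sites x samples integer matrices), \code{samples}, and the row index
#'   of each kept site in the input (\code{kept}).
#' @export
call_biallelic <- function(pc, varref, threshold, per_sample = FALSE) {
  stopifnot(threshold >= 0)
  L <- nrow(varref)
  ord <- t(apply(varref, 1L, order, decreasing = TRUE))
  top1 <- varref[cbind(seq_len(L), ord[, 1])]
  top2 <- varref[cbind(seq_len(L), ord[, 2])]
  third <- varref[cbind(seq_len(L), ord[, 3])]
  if (per_sample) {
    # a site is tri-allelic if any sample's third-largest count exceeds
    # the threshold
    third_any <- apply(pc$counts, 3L, nth_largest, k = 3L)
    tri <- apply(third_any > threshold, 1L, any)
  } else {
    tri <- third > threshold
  }
  keep <- !tri & top2 > threshold
  kept <- which(keep)
  if (!length(kept))
    return(empty_biallelic(pc))

  a1 <- ord[kept, 1]
  a2 <- ord[kept, 2]
  in_ref <- pc$sites$ref[kept]
  ref_idx <- match(in_ref, ALLELE_CLASSES)
  # keep the declared reference base as ref when it is one of the two major
  # alleles; otherwise fall back to count order
  ref_is_a2 <- !is.na(ref_idx) & ref_idx == a2
  ref_a <- ifelse(ref_is_a2, a2, a1)
  alt_a <- ifelse(ref_is_a2, a1, a2)

  ns <- length(pc$samples)
  idx <- cbind(rep(kept, ns),
               rep(ref_a, ns),
               rep(seq_len(ns), each = length(kept)))
  ref_counts <- matrix(pc$counts[idx], ncol = ns)
  idx[, 2] <- rep(alt_a, ns)
  alt_counts <- matrix(pc$counts[idx], ncol = ns)

  sites <- data.frame(arm = pc$sites$arm[kept], pos = pc$sites$pos[kept],
                      ref = ALLELE_CLASSES[ref_a], alt = ALLELE_CLASSES[alt_a],
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, alt = alt_counts,
                 depth = ref_counts + alt_counts,
                 samples = pc$samples, kept = kept),
            class = "biallelic_table")
}

empty_biallelic <- function(pc) {
  structure(list(sites = pc$sites[0, , drop = FALSE],
                 alt = matrix(0L, 0, length(pc$samples)),
                 depth = matrix(0L, 0, length(pc$samples)),
                 samples = pc$samples, kept = integer(0)),
            class = "biallelic_table")
}

#' @export
print.biallelic_table <- function(x, ...) {
  cat("biallelic_table:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

subset_biallelic <- function(bt, keep) {
  bt$sites <- bt$sites[keep, , drop = FALSE]
  bt$alt <- bt$alt[keep, , drop = FALSE]
  bt$depth <- bt$depth[keep, , drop = FALSE]
  bt$kept <- bt$kept[keep]
  rownames(bt$sites) <- NULL
  bt
}

#' Coverage filters on biallelic sites
#'
#' Drops sites with merged depth at or below \code{min_global_depth}
#' (retention requires depth strictly over the minimum), sites above the
#' \code{high_cov_quantile} of the merged-depth distribution at biallelic
#' sites (lower empirical quantile convention), and sites sequenced below
#' \code{per_sample_min_depth} in every sample of any generation cohort.
#'
#' @param bt A \code{\link{call_biallelic}} table (depths already exclude
#'   dropped alleles).
#' @param design Sample design data frame (provides generation cohorts).
#' @param config A \code{\link{filter_config}}.
#' @param high_cov_cutoff Absolute depth cutoff to reuse instead of
#'   recomputing the quantile; pass the recorded cutoff when re-applying
#'   the filter to its own output (thresholds are ascertained once, on the
#'   full site set).
#' @return The filtered \code{biallelic_table}, with the applied cutoff in
#'   attribute \code{high_cov_cutoff}.
#' @export
coverage_filters <- function(bt, design, config = filter_config(),
                             high_cov_cutoff = NULL) {
  if (!nrow(bt$sites)) return(bt)
  merged <- rowSums(bt$depth)
  keep <- merged > config$min_global_depth
  hi <- if (is.null(high_cov_cutoff)) {
    lower_quantile(merged, config$high_cov_quantile)
  } else high_cov_cutoff
  keep <- keep & merged <= hi
  design <- design[match(bt$samples, design$id), , drop = FALSE]
  for (g in unique(design$generation)) {
    cols <- which(design$generation == g)
    if (!length(cols)) next
    all_low <- rowSums(bt$depth[, cols, drop = FALSE] >=
                         config$per_sample_min_depth) == 0L
    keep <- keep & !all_low
  }
  out <- subset_biallelic(bt, keep)
  attr(out, "high_cov_cutoff") <- hi
  out
}

#' Clopper-Pearson lower confidence bound for a minor-allele fraction
#'
#' Exact (beta-quantile) lower bound of the two-sided
#' \code{level} confidence interval for a binomial proportion; exactly 0
#' when the minor count is 0, which gives the high-confidence filter its
#' "lower bound above zero" semantics.
#'
#' @param minor Minor-allele read count(s).
#' @param depth Total depth(s), > 0.
#' @param level Two-sided confidence level (default 0.9973).
#' @return Lower bound(s) in [0, 1].
#' @export
binomial_ci_lower <- function(minor, depth, level = 0.9973) {
  stopifnot(level > 0.5, level < 1)
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  if (any(minor < 0) || any(minor > depth))
    stop("minor count must lie in [0, depth]", call. = FALSE)
  alpha <- 1 - level
  lo <- numeric(length(minor))
  nz <- minor > 0
  lo[nz] <- qbeta(alpha / 2, minor[nz], depth[nz] - minor[nz] + 1)
  lo
}

#' High-confidence variant filter
#'
#' Keeps a site iff the Clopper-Pearson lower bound for its (site-level)
#' minor allele is above zero in at least one sample.
#'
#' @param bt A \code{biallelic_table}.
#' @param level Confidence level (default 0.9973).
#' @return The filtered \code{biallelic_table}.
#' @export
high_confidence_filter <- function(bt, level = 0.9973) {
  if (!nrow(bt$sites)) return(bt)
  merged_alt <- rowSums(bt$alt)
  merged_depth <- rowSums(bt$depth)
  alt_is_minor <- merged_alt * 2L <= merged_depth
  minor <- bt$alt
  minor[!alt_is_minor, ] <- (bt$depth - bt$alt)[!alt_is_minor, ]
  keep <- logical(nrow(bt$sites))
  for (k in seq_along(bt$samples)) {
    d <- bt$depth[, k]
    ok <- d > 0
    lo <- numeric(length(d))
    lo[ok] <- binomial_ci_lower(minor[ok, k], d[ok], level)
    keep <- keep | (lo > 0)
  }
  subset_biallelic(bt, keep)
}

#' Per-site per-sample alternate allele frequencies
#'
#' @param bt A \code{biallelic_table}.
#' @return Matrix (sites x samples) of alt/depth; NA where depth is 0.
#' @export
allele_frequencies <- function(bt) {
  f <- bt$alt / bt$depth
  f[bt$depth == 0L] <- NA_real_
  dimnames(f) <- list(NULL, bt$samples)
  f
}

#' Full count-QC pipeline
#'
#' Chains \code{\link{merge_varref}}, \code{\link{third_allele_threshold}},
#' \code{\link{call_biallelic}}, \code{\link{coverage_filters}} and
#' \code{\link{high_confidence_filter}}, recording site counts at each
#' stage.
#'
#' @param pc A \code{\link{pooled_counts}} object.
#' @param design Sample design data frame.
#' @param config A \code{\link{filter_config}}.
#' @return List with the final \code{table} (a \code{biallelic_table}) and a
#'   \code{report} of thresholds and per-stage site counts.
#' @export
filter_variants <- function(pc, design, config = filter_config()) {
  varref <- merge_varref(pc)
  thr <- third_allele_threshold(varref, config$third_allele_quantile)
  bt <- call_biallelic(pc, varref, thr,
                       per_sample = config$third_allele_per_sample)
  n_biallelic <- nrow(bt$sites)
  bt <- coverage_filters(bt, design, config)
  n_covered <- nrow(bt$sites)
  hi_cut <- attr(bt, "high_cov_cutoff")
  bt <- high_confidence_filter(bt, config$ci_level)
  report <- list(n_input = nrow(pc$sites),
                 third_allele_threshold = thr,
                 median_merged_depth = attr(varref, "median_depth"),
                 high_cov_cutoff = hi_cut,
                 n_biallelic = n_biallelic,
                 n_after_coverage = n_covered,
                 n_high_confidence = nrow(bt$sites),
                 ci_level = config$ci_level)
  list(table = bt, report = report)
}

#' Write / read a biallelic variant table as TSV
#'
#' Columns: arm, pos (1-based), ref, alt, then per sample "alt:depth".
#'
#' @param bt A \code{biallelic_table}.
#' @param path TSV path.
#' @export
write_biallelic <- function(bt, path) {
  pair_cols <- lapply(seq_along(bt$samples), function(k)
    paste(bt$alt[, k], bt$depth[, k], sep = ":"))
  tab <- cbind(bt$sites, setNames(as.data.frame(pair_cols), bt$samples))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biallelic
#' @export
read_biallelic <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  samples <- names(tab)[-(1:4)]
  alt <- depth <- matrix(0L, nrow(tab), length(samples))
  for (k in seq_along(samples)) {
    parts <- strsplit(tab[[4L + k]], ":", fixed = TRUE)
    v <- as.integer(unlist(parts))
    alt[, k] <- v[c(TRUE, FALSE)]
    depth[, k] <- v[c(FALSE, TRUE)]
  }
  structure(list(sites = tab[1:4], alt = alt, depth = depth,
                 samples = samples, kept = seq_len(nrow(tab))),
            class = "biallelic_table")
}
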