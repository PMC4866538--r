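# Replicate-consistency descriptive statistics: diffStat, between-generation
# allele-frequency-change consistency, and the binned treatment/control
# consistency-ratio summary.

#' diffStat: smallest consistent cross-treatment frequency difference
#'
#' For each variant, forms the nine signed differences
#' \eqn{d_{ij} = freq(AF_i) - freq(CF_j)} between the three treatment and
#' three control replicates. When all nine share one sign the score is the
#' minimum absolute difference; otherwise (including any zero difference)
#' the variant is inconsistent and scores 0.
#'
#' @param af Matrix (variants x replicates) of treatment frequencies, or a
#'   vector for a single variant.
#' @param cf Control frequencies, same shape.
#' @return Data frame with \code{consistent} (logical), \code{sign} (+1/-1,
#'   0 when inconsistent) and \code{diffstat}.
#' @export
diffstat <- function(af, cf) {
  if (is.null(dim(af))) af <- matrix(af, nrow = 1L)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L)
  stopifnot(nrow(af) == nrow(cf))
  if (any(af < 0 | af > 1, na.rm = TRUE) || any(cf < 0 | cf > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  dmin <- rep(Inf, nrow(af))
  dmax <- rep(-Inf, nrow(af))
  for (i in seq_len(ncol(af))) {
    for (j in seq_len(ncol(cf))) {
      d <- af[, i] - cf[, j]
      dmin <- pmin(dmin, d)
      dmax <- pmax(dmax, d)
    }
  }
  consistent <- (dmin > 0 & dmax > 0) | (dmin < 0 & dmax < 0)
  consistent[is.na(consistent)] <- FALSE
  ds <- ifelse(consistent, pmin(abs(dmin), abs(dmax)), 0)
  data.frame(consistent = consistent,
             sign = ifelse(consistent, sign(dmax), 0),
             diffstat = ds)
}

#' Between-generation allele-frequency-change consistency
#'
#' For each variant and each replicate within one treatment, computes
#' \eqn{\Delta_i = freq(late, i) - freq(early, i)}; a variant is consistent
#' when every replicate changed in the same direction (a zero change breaks
#' consistency). The change magnitude is binned at 5\% width using the
#' minimum \eqn{|\Delta_i|} across replicates (the magnitude all replicates
#' reach) by default, or the mean.
#'
#' @param freq_early Matrix (variants x replicates) at the early generation.
#' @param freq_late Matrix at the late generation, same replicate order.
#' @param bin_width Magnitude bin width (default 0.05).
#' @param magnitude "min" (default) or "mean" of the absolute changes.
#' @return List with \code{records} (per-variant data frame: consistent,
#'   direction, magnitude, bin) and \code{fraction_consistent}.
#' @export
generation_consistency <- function(freq_early, freq_late, bin_width = 0.05,
                                   magnitude = c("min", "mean")) {
  magnitude <- match.arg(magnitude)
  stopifnot(all(dim(freq_early) == dim(freq_late)))
  delta <- freq_late - freq_early
  pos <- rowSums(delta > 0, na.rm = FALSE) == ncol(delta)
  neg <- rowSums(delta < 0, na.rm = FALSE) == ncol(delta)
  consistent <- !is.na(pos) & !is.na(neg) & (pos | neg)
  mag <- if (magnitude == "min") {
    apply(abs(delta), 1L, min)
  } else {
    rowMeans(abs(delta))
  }
  breaks <- seq(0, 1, by = bin_width)
  bin <- cut(mag, breaks = breaks, include.lowest = FALSE, right = TRUE)
  records <- data.frame(consistent = consistent,
                        direction = ifelse(consistent, ifelse(pos, 1L, -1L), 0L),
                        magnitude = mag, bin = bin)
  list(records = records,
       fraction_consistent = mean(consistent, na.rm = TRUE))
}

#' Per-bin ratio of consistently changed variants, treatment over control
#'
#' For each magnitude bin, the number of treatment-consistent variants in
#' the bin divided by the number of control-consistent variants in the bin;
#' missing (NA) where the control bin is empty.
#'
#' @param af_records \code{records} from \code{\link{generation_consistency}}
#'   for the treatment populations.
#' @param cf_records Likewise for the controls.
#' @return Data frame with bin, n_af, n_cf and ratio.
#' @export
change_ratio_histogram <- function(af_records, cf_records) {
  stopifnot(identical(levels(af_records$bin), levels(cf_records$bin)))
  n_af <- as.vector(table(af_records$bin[af_records$consistent]))
  n_cf <- as.vector(table(cf_records$bin[cf_records$consistent]))
  data.frame(bin = levels(af_records$bin), n_af = n_af, n_cf = n_cf,
             ratio = ifelse(n_cf > 0, n_af / n_cf, NA_real_))
}

#' Chi-square comparison of consistent-variant counts between treatments
#'
#' Convenience 2x2 test of the consistent/inconsistent split between the
#' two treatments.
#'
#' @param af_consistent,cf_consistent Logical vectors over the same
#'   variants.
#' @param correct Continuity correction (default FALSE: the textbook 2x2
#'   formula).
#' @return \code{htest} object from \code{chisq.test}.
#' @export
consistency_chisq <- function(af_consistent, cf_consistent, correct = FALSE) {
  tab <- rbind(AF = c(sum(af_consistent), sum(!af_consistent)),
               CF = c(sum(cf_consistent), sum(!cf_consistent)))
  chisq.test(tab, correct = correct)
}
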