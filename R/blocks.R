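# Hypergeometric sliding-window scan for SDV clustering, multiple-testing
# adjustment, consolidation of significant windows into differentiated
# blocks, and nomination of each block's top variant and candidate genes.
# Windows and blocks are 0-based half-open internally; TSV outputs are
# 1-based, BED outputs native 0-based.

#' Hypergeometric sliding-window scan
#'
#' Tiles each arm with half-open windows of \code{window} bp every
#' \code{step} bp and computes, from the per-arm totals of variants (N) and
#' SDV (S), the upper-tail hypergeometric probability of observing at least
#' the window's SDV count s among its n variants. Windows containing no
#' variants are skipped.
#'
#' @param results Per-variant data frame with columns arm, pos (1-based)
#'   and sdv (logical), e.g. from \code{\link{run_divergence_scan}}.
#' @param window Window size in bp (default 50 kb).
#' @param step Step size in bp (default 10 kb); must satisfy
#'   \code{window >= step > 0}.
#' @param arm_lengths Named vector of arm lengths; defaults to the largest
#'   variant position per arm.
#' @return Data frame (arm, start, end in 0-based half-open coordinates,
#'   n, s, p) with per-arm totals in attributes \code{N} and \code{S}.
#' @export
scan_windows <- function(results, window = 5e4, step = 1e4,
                         arm_lengths = NULL) {
  stopifnot(window >= step, step > 0)
  if (is.null(arm_lengths)) {
    arm_lengths <- tapply(results$pos, results$arm, max)
  }
  out <- list()
  Ns <- Ss <- integer(0)
  for (arm in sort(unique(results$arm))) {
    rows <- results$arm == arm
    pos0 <- sort(results$pos[rows]) - 1L           # 0-based
    sdv0 <- sort(results$pos[rows][results$sdv[rows]]) - 1L
    N <- length(pos0)
    S <- length(sdv0)
    Ns[arm] <- N
    Ss[arm] <- S
    alen <- arm_lengths[[arm]]
    starts <- seq(0, max(alen - 1, 0), by = step)
    ends <- pmin(starts + window, alen)
    n <- findInterval(ends - 1L, pos0, left.open = FALSE) -
      findInterval(starts - 1L, pos0, left.open = FALSE)
    # count of pos0 in [start, end): #(pos0 <= end-1) - #(pos0 <= start-1)
    s <- findInterval(ends - 1L, sdv0, left.open = FALSE) -
      findInterval(starts - 1L, sdv0, left.open = FALSE)
    keep <- n > 0L
    p <- phyper(s[keep] - 1L, S, N - S, n[keep], lower.tail = FALSE)
    out[[arm]] <- data.frame(arm = arm, start = starts[keep],
                             end = ends[keep], n = n[keep], s = s[keep],
                             p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "N") <- Ns
  attr(res, "S") <- Ss
  res
}

#' Multiple-testing adjustment of window p-values
#'
#' Benjamini-Hochberg by default, pooled genome-wide across all scanned
#' windows; an optional Storey-style correction rescales BH by an estimate
#' of the null proportion pi0.
#'
#' @param windows Data frame from \code{\link{scan_windows}}.
#' @param alpha Significance level on the adjusted values (default 0.05).
#' @param method "BH" (default) or "storey".
#' @param lambda Tuning grid for the pi0 estimate (storey only).
#' @return The input with columns \code{q} and \code{significant} added.
#' @export
adjust_windows <- function(windows, alpha = 0.05, method = c("BH", "storey"),
                           lambda = seq(0.05, 0.9, by = 0.05)) {
  method <- match.arg(method)
  q <- p.adjust(windows$p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, median(vapply(lambda, function(l)
      mean(windows$p > l) / (1 - l), numeric(1))))
    q <- pmin(q * pi0, 1)
    attr(windows, "pi0") <- pi0
  }
  windows$q <- q
  windows$significant <- q < alpha
  windows
}

#' Consolidate significant windows into differentiated blocks
#'
#' Merges significant windows that overlap or abut (end == next start in
#' half-open coordinates) into maximal nonoverlapping blocks.
#'
#' @param windows Adjusted window data frame; only rows with
#'   \code{significant} are used.
#' @return Data frame (arm, start, end half-open, n_windows, block id).
#' @export
consolidate_blocks <- function(windows) {
  sig <- windows[windows$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(arm = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      block = character(0), stringsAsFactors = FALSE))
  out <- list()
  for (arm in unique(sig$arm)) {
    w <- sig[sig$arm == arm, , drop = FALSE]
    ir <- IRanges::IRanges(start = w$start + 1L, end = w$end)  # 1-based closed
    red <- IRanges::reduce(ir)   # merges overlapping and abutting ranges
    hits <- IRanges::findOverlaps(ir, red)
    nw <- tabulate(S4Vectors::subjectHits(hits), length(red))
    out[[arm]] <- data.frame(arm = arm,
                             start = IRanges::start(red) - 1L,
                             end = IRanges::end(red),
                             n_windows = nw, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$block <- paste0(res$arm, ":", res$start, "-", res$end)
  res
}

#' Block length and spacing summary
#'
#' @param blocks Data frame from \code{\link{consolidate_blocks}}.
#' @return List with \code{median_length} and \code{median_gap} (edge-to-
#'   edge distance between adjacent blocks on the same arm; NA when no two
#'   blocks share an arm).
#' @export
block_summary <- function(blocks) {
  if (!nrow(blocks)) stop("no blocks", call. = FALSE)
  len <- blocks$end - blocks$start
  gaps <- unlist(lapply(split(blocks, blocks$arm), function(b) {
    if (nrow(b) < 2L) return(numeric(0))
    b <- b[order(b$start), ]
    b$start[-1L] - b$end[-nrow(b)]
  }), use.names = FALSE)
  list(median_length = median(len),
       median_gap = if (length(gaps)) median(gaps) else NA_real_)
}

#' Nominate each block's top variant and candidate genes
#'
#' The top variant is the SDV with the smallest GLMM p in the block (all
#' tied variants are reported). Candidate genes are the gene(s) whose
#' interval contains the top variant; an intergenic top variant nominates
#' both the nearest upstream and nearest downstream gene.
#'
#' @param blocks Data frame from \code{\link{consolidate_blocks}}.
#' @param results Per-variant results (arm, pos, p, sdv).
#' @param genes Gene models (gene, arm, start, end; 1-based closed), e.g.
#'   from \code{\link{read_genes}}.
#' @return Data frame with one row per (block, top variant, gene).
#' @export
nominate_candidates <- function(blocks, results, genes) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    rows <- results$arm == b$arm & results$pos > b$start &
      results$pos <= b$end & results$sdv
    if (!any(rows))
      stop("block ", b$block, " contains no SDV", call. = FALSE)
    sub <- results[rows, , drop = FALSE]
    top <- sub[sub$p == min(sub$p), , drop = FALSE]   # ties: all reported
    for (j in seq_len(nrow(top))) {
      g <- host_genes(top$arm[j], top$pos[j], genes)
      out[[length(out) + 1L]] <-
        data.frame(block = b$block, arm = top$arm[j], pos = top$pos[j],
                   p = top$p[j], gene = g$gene, relation = g$relation,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# genes hosting a 1-based position; if intergenic, the nearest gene on each
# flank
host_genes <- function(arm, pos, genes) {
  g <- genes[genes$arm == arm, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene = NA_character_, relation = "none",
                      stringsAsFactors = FALSE))
  inside <- g$start <= pos & g$end >= pos
  if (any(inside))
    return(data.frame(gene = g$gene[inside], relation = "contains",
                      stringsAsFactors = FALSE))
  up <- g[g$end < pos, , drop = FALSE]
  dn <- g[g$start > pos, , drop = FALSE]
  picks <- rbind(
    if (nrow(up)) data.frame(gene = up$gene[which.max(up$end)],
                             relation = "upstream",
                             stringsAsFactors = FALSE),
    if (nrow(dn)) data.frame(gene = dn$gene[which.min(dn$start)],
                             relation = "downstream",
                             stringsAsFactors = FALSE))
  picks
}
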