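# End-to-end pipeline plumbing: deterministic per-stage seeds, run
# manifests, and the stage-chaining driver used by the analysis scripts.

PIPELINE_STAGES <- c("simulate", "filter", "glmm", "fdr", "diffstat",
                     "scan", "enrich", "pbs")

#' Deterministic per-stage seed fan-out
#'
#' Derives an independent, reproducible seed for each pipeline stage from
#' one global seed, so stages can be re-run in isolation with identical
#' results.
#'
#' @param seed Global integer seed.
#' @param stage One of "simulate", "filter", "glmm", "fdr", "diffstat",
#'   "scan", "enrich", "pbs".
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  if (is.na(idx)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.numeric(seed) * 48271 + idx * 65537) %% 2147483629)
}

#' Build and write a run manifest
#'
#' Records everything needed to reproduce a run: package version, the
#' global seed and derived stage seeds, every numerical parameter that
#' affects results, input file digests and a timestamp.
#'
#' @param seed Global seed.
#' @param params Named list of stage parameters.
#' @param inputs Character vector of input file paths (md5-digested).
#' @param path Optional JSON output path.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(seed, params = list(), inputs = character(0),
                         path = NULL) {
  manifest <- list(
    tool = "poolER",
    version = as.character(packageVersion("poolER")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stage_seeds = setNames(lapply(PIPELINE_STAGES, stage_seed, seed = seed),
                           PIPELINE_STAGES),
    params = params,
    inputs = if (length(inputs)) {
      as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs)))
    } else list())
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}

#' Run the full divergence pipeline
#'
#' Chains count QC, the GLMM divergence scan with permutation FDR,
#' diffStat, the hypergeometric window scan with block consolidation, and
#' (when gene models are supplied) candidate nomination. Stage outputs are
#' returned and optionally written as plain-text tables plus a manifest.
#'
#' @param counts A \code{\link{pooled_counts}} object (or path to a sync
#'   file).
#' @param design Sample design data frame (or TSV path).
#' @param genes Optional gene models data frame (or BED/GFF3 path).
#' @param filter_cfg A \code{\link{filter_config}}.
#' @param alpha FDR level for SDV and window significance (default 0.05).
#' @param window,step Window scan geometry in bp (defaults 50 kb / 10 kb).
#' @param arm_lengths Named arm lengths for the window scan.
#' @param mask Optional masked-region data frame (arm, start, end).
#' @param nodes GLMM quadrature nodes.
#' @param seed Global seed (fanned out per stage).
#' @param out_dir Optional output directory for TSV/BED/JSON artifacts.
#' @return List with filter report, variant results, fdr curve, diffstat,
#'   windows, blocks, candidates and the manifest.
#' @export
run_pipeline <- function(counts, design, genes = NULL,
                         filter_cfg = filter_config(), alpha = 0.05,
                         window = 5e4, step = 1e4, arm_lengths = NULL,
                         mask = NULL, nodes = 15L, seed = 1L,
                         out_dir = NULL) {
  inputs <- character(0)
  if (is.character(counts)) { inputs <- c(inputs, counts)
    counts <- read_sync(counts) }
  if (is.character(design)) { inputs <- c(inputs, design)
    design <- read_design(design) }
  if (is.character(genes)) { inputs <- c(inputs, genes)
    genes <- read_genes(genes) }

  flt <- filter_variants(counts, design, filter_cfg)
  bt <- flt$table
  if (!nrow(bt$sites)) stop("no variants pass QC", call. = FALSE)

  scan <- run_divergence_scan(bt, design, alpha = alpha, nodes = nodes,
                              mask = mask)
  res <- scan$results

  # diffStat at the tested generation
  freqs <- allele_frequencies(bt)[match(
    paste(res$arm, res$pos), paste(bt$sites$arm, bt$sites$pos)), ,
    drop = FALSE]
  design_m <- design[match(bt$samples, design$id), ]
  late <- design_m$generation == scan$generation
  af_cols <- which(late & design_m$treatment == "selected")
  cf_cols <- which(late & design_m$treatment == "control")
  ds <- diffstat(freqs[, af_cols, drop = FALSE],
                 freqs[, cf_cols, drop = FALSE])
  res$diffstat <- ds$diffstat
  res$consistent <- ds$consistent

  windows <- adjust_windows(scan_windows(res, window = window, step = step,
                                         arm_lengths = arm_lengths),
                            alpha = alpha)
  blocks <- consolidate_blocks(windows)
  candidates <- if (!is.null(genes) && nrow(blocks)) {
    nominate_candidates(blocks, res, genes)
  } else NULL

  manifest <- run_manifest(
    seed = seed,
    params = list(filter = unclass(filter_cfg), alpha = alpha,
                  window = window, step = step, nodes = nodes,
                  fdr_threshold = scan$threshold),
    inputs = inputs)

  out <- list(report = flt$report, results = res, fdr = scan$fdr,
              threshold = scan$threshold, windows = windows,
              blocks = blocks, candidates = candidates,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(res, file.path(out_dir, "variants.tsv"))
    write_tsv(scan$fdr$curve, file.path(out_dir, "fdr_curve.tsv"))
    write_tsv(windows, file.path(out_dir, "windows.tsv"))
    if (nrow(blocks)) {
      write_tsv(blocks, file.path(out_dir, "blocks.tsv"))
      write_bed(blocks, file.path(out_dir, "blocks.bed"),
                names = blocks$block, zero_based = TRUE)
    }
    if (!is.null(candidates))
      write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
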