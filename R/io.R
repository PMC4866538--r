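# Pooled-count container and plain-text interchange: PoPoolation2-style
# "sync" files, sample-design tables, and gene models (BED / minimal GFF3).

#' Pooled per-site nucleotide counts for a set of samples
#'
#' The universal currency of the pipeline: for every site (arm, 1-based
#' position, reference base) a 6-way count over A, T, C, G, N and deletion
#' alleles in each sequenced pool.
#'
#' @param sites Data frame with columns \code{arm}, \code{pos}, \code{ref}
#'   (and optionally \code{alt}); positions must be unique within an arm.
#' @param counts Integer array of dim (sites x 6 x samples); the second
#'   margin is named A,T,C,G,N,del and the third carries sample ids.
#' @return An object of class \code{pooled_counts}.
#' @export
pooled_counts <- function(sites, counts) {
  stopifnot(is.data.frame(sites), all(c("arm", "pos") %in% names(sites)),
            length(dim(counts)) == 3L, dim(counts)[1] == nrow(sites),
            dim(counts)[2] == 6L)
  if (anyDuplicated(sites[c("arm", "pos")]))
    stop("positions must be unique within an arm", call. = FALSE)
  if (any(counts < 0L)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(dimnames(counts)[[3]]))
    stop("counts must carry sample ids in dimnames", call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts)[[2]] <- ALLELE_CLASSES
  structure(list(sites = sites, counts = counts,
                 samples = dimnames(counts)[[3]]),
            class = "pooled_counts")
}

#' @export
print.pooled_counts <- function(x, ...) {
  cat("pooled_counts:", nrow(x$sites), "sites x", length(x$samples),
      "samples on", length(unique(x$sites$arm)), "arm(s)\n")
  invisible(x)
}

#' Write pooled counts in sync format
#'
#' One line per site: arm, 1-based position, reference base, then one
#' "A:T:C:G:N:del" column per sample (sample order recorded in the header
#' comment line).
#'
#' @param pc A \code{\link{pooled_counts}} object.
#' @param path Output file.
#' @export
write_sync <- function(pc, path) {
  cols <- vapply(seq_along(pc$samples), function(k) {
    m <- pc$counts[, , k, drop = FALSE]
    paste(m[, 1, 1], m[, 2, 1], m[, 3, 1], m[, 4, 1], m[, 5, 1], m[, 6, 1],
          sep = ":")
  }, character(nrow(pc$sites)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)
  lines <- paste(pc$sites$arm, pc$sites$pos, pc$sites$ref,
                 apply(cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(paste0("#arm\tpos\tref\t", paste(pc$samples, collapse = "\t")),
               lines), path)
  invisible(path)
}

#' Read a sync file
#'
#' @param path Sync file written by \code{\link{write_sync}} or any
#'   tab-separated arm/pos/ref + "A:T:C:G:N:del" (or "A:T:C:G") file.
#' @param samples Sample ids; taken from a leading \code{#} header if
#'   present, otherwise "S1", "S2", ...
#' @return A \code{\link{pooled_counts}} object.
#' @export
read_sync <- function(path, samples = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- startsWith(first, "#")
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", colClasses = "character")
  nsamp <- ncol(tab) - 3L
  if (nsamp < 1L) stop("sync file must have at least one sample column",
                       call. = FALSE)
  if (is.null(samples)) {
    samples <- if (has_header) {
      strsplit(sub("^#", "", first), "\t")[[1]][-(1:3)]
    } else paste0("S", seq_len(nsamp))
  }
  stopifnot(length(samples) == nsamp)
  L <- nrow(tab)
  counts <- array(0L, c(L, 6L, nsamp),
                  dimnames = list(NULL, ALLELE_CLASSES, samples))
  for (k in seq_len(nsamp)) {
    parts <- strsplit(tab[[3L + k]], ":", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield < 4L)) stop("malformed count column ", k, call. = FALSE)
    m <- matrix(0L, L, 6L)
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) stop("non-integer counts in sample column ", k, call. = FALSE)
    at <- cumsum(nfield) - nfield
    for (f in 1:6) {
      has <- nfield >= f
      m[has, f] <- v[at[has] + f]
    }
    counts[, , k] <- m
  }
  pooled_counts(data.frame(arm = tab[[1]], pos = as.integer(tab[[2]]),
                           ref = tab[[3]], stringsAsFactors = FALSE),
                counts)
}

#' Write / read the sample design table
#'
#' Columns: id, treatment ("selected"/"control"), replicate, generation,
#' pool_chromosomes.
#'
#' @param design Design data frame.
#' @param path TSV file path.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("id", "treatment", "replicate", "generation")
  if (!all(req %in% names(d)))
    stop("design table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  d
}

#' Read gene models from BED or minimal GFF3
#'
#' BED input is 0-based half-open and converted to 1-based closed
#' coordinates; GFF3 input keeps rows whose type is "gene" and uses the ID
#' or Name attribute. Only gene-level intervals are used.
#'
#' @param path File path; format chosen by extension (".bed" vs
#'   ".gff"/".gff3") unless \code{format} is given.
#' @param format "bed" or "gff3".
#' @return Data frame with columns gene, arm, start, end (1-based closed).
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop("BED gene file needs a name column", call. = FALSE)
    out <- data.frame(gene = tab[[4]], arm = tab[[1]],
                      start = tab[[2]] + 1L, end = tab[[3]],
                      stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "#", quote = "")
    tab <- tab[tab[[3]] == "gene", , drop = FALSE]
    attr_field <- tab[[9]]
    id <- sub("^(?:.*;)?\\s*(?:ID|Name)=([^;]+).*$", "\\1", attr_field,
              perl = TRUE)
    out <- data.frame(gene = id, arm = tab[[1]], start = tab[[4]],
                      end = tab[[5]], stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene))
    stop("gene ids must be unique", call. = FALSE)
  if (any(out$end < out$start)) stop("invalid gene intervals", call. = FALSE)
  out
}

#' Write a gene/interval table as BED (0-based half-open)
#'
#' @param blocks Data frame with columns arm, start, end (1-based closed or
#'   internal 0-based half-open; see \code{zero_based}).
#' @param path Output path.
#' @param names Optional name column.
#' @param zero_based Are the input intervals already 0-based half-open?
#' @export
write_bed <- function(blocks, path, names = NULL, zero_based = TRUE) {
  start0 <- if (zero_based) blocks$start else blocks$start - 1L
  end0 <- blocks$end
  tab <- data.frame(blocks$arm, start0, end0)
  if (!is.null(names)) tab$name <- names
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
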