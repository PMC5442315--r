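# Core coordinate conventions: 0-based half-open [start, end), strand in
# {"+", "-", "*"}.  Genes are data.frames with columns
# gene_id, chrom, start, end, strand (+ optional biotype); regions/peaks are
# data.frames with columns chrom, start, end (+ name, score, strand, signal).

#' Validate a set of genomic intervals
#'
#' Checks the half-open coordinate invariants: `0 <= start < end`, non-empty
#' chromosome names, strand in `+`/`-`/`*`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom))))
    stop(what, ": chrom must be a non-empty string")
  if (any(x$start < 0)) stop(what, ": start must be >= 0")
  if (any(x$end <= x$start)) stop(what, ": end must exceed start (half-open)")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    stop(what, ": strand must be one of '+', '-', '*'")
  invisible(x)
}

#' Construct a gene annotation table
#'
#' @param gene_id unique gene identifiers.
#' @param chrom,start,end gene body in 0-based half-open coordinates.
#' @param strand `"+"` or `"-"` (mandatory for genes).
#' @param biotype free-form tag, default `"protein_coding"`.
#' @return data.frame of gene annotations.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand,
                       biotype = "protein_coding") {
  g <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  strand = as.character(strand),
                  biotype = rep_len(as.character(biotype), length(gene_id)),
                  stringsAsFactors = FALSE)
  validate_intervals(g, "gene")
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id: ", g$gene_id[duplicated(g$gene_id)][1L])
  if (any(!g$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  g
}

#' Transcription start site of stranded genes
#'
#' The biological 5' end: `start` for plus-strand genes and `end - 1` for
#' minus-strand genes under the half-open convention.
#'
#' @param genes gene table (see [gene_table()]); strand must be `+` or `-`.
#' @return numeric vector of TSS base positions, one per gene.
#' @export
tss_of <- function(genes) {
  if (any(!genes$strand %in% c("+", "-")))
    stop("tss_of: strand required ('+' or '-'), got unstranded gene")
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' Overlap length of two intervals
#'
#' Vectorized; returns 0 for intervals on different chromosomes and for
#' half-open adjacency.
#'
#' @param chrom_a,start_a,end_a first interval(s).
#' @param chrom_b,start_b,end_b second interval(s).
#' @return number of shared bases (>= 0).
#' @export
overlap_length <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  ifelse(as.character(chrom_a) == as.character(chrom_b),
         pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b)),
         0)
}

#' Containment test with slack
#'
#' `TRUE` when `inner` lies within `outer` extended by `slack` bases on each
#' side (non-strict: identical intervals contain each other at slack 0).
#'
#' @param outer_start,outer_end outer interval(s).
#' @param inner_start,inner_end inner interval(s).
#' @param slack non-negative slack in bases.
#' @param same_chrom logical; supply `FALSE` where chromosomes differ.
#' @return logical vector.
#' @export
interval_contains <- function(outer_start, outer_end, inner_start, inner_end,
                              slack = 0, same_chrom = TRUE) {
  stopifnot(all(slack >= 0))
  same_chrom &
    (outer_start - slack <= inner_start) &
    (inner_end <= outer_end + slack)
}

#' TSS window
#'
#' The symmetric window `[anchor - halfwidth, anchor + halfwidth + 1)` around a
#' TSS anchor, clipped at position 0.  Covers all bases within +-halfwidth of
#' the anchor, anchor included.
#'
#' @param anchor TSS base position(s).
#' @param halfwidth window half-width in bases (default 500).
#' @return data.frame with columns `start`, `end`.
#' @export
tss_window <- function(anchor, halfwidth = 500) {
  stopifnot(all(halfwidth >= 0))
  data.frame(start = pmax(0, anchor - halfwidth), end = anchor + halfwidth + 1)
}

# IRanges bridge: 0-based half-open -> 1-based closed.
.as_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# Merge overlapping or book-ended intervals within one region set, combining
# signal as a length-weighted mean.  Keeps columns chrom/start/end/signal.
#' Merge overlapping regions within one set
#'
#' Overlapping or directly adjacent regions on the same chromosome are merged;
#' the merged signal is the length-weighted mean of the contributing regions.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `signal`.
#' @return merged, sorted region data.frame.
#' @export
merge_regions <- function(regions) {
  validate_intervals(regions, "region")
  if (!"signal" %in% names(regions)) regions$signal <- NA_real_
  if (nrow(regions) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      signal = numeric(), stringsAsFactors = FALSE))
  out <- lapply(split(regions, regions$chrom), function(r) {
    ir <- .as_iranges(r$start, r$end)
    red <- IRanges::reduce(ir)
    grp <- IRanges::findOverlaps(ir, red, select = "first")
    len <- r$end - r$start
    sig <- vapply(split(seq_len(nrow(r)), grp), function(i) {
      sum(r$signal[i] * len[i]) / sum(len[i])
    }, numeric(1))
    data.frame(chrom = r$chrom[1L], start = IRanges::start(red) - 1,
               end = IRanges::end(red), signal = as.numeric(sig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}
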