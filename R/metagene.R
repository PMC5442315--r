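# Metagene signal matrices: TSS-anchored fixed windows and length-normalized
# gene-body profiles.  All bin-edge arithmetic is carried out on integer
# coordinates (scaled by the body bin count where bin widths are fractional),
# and per-bin contributions are summed in sorted order, so the matrices are
# exactly invariant under mirroring the genome and flipping strands.

.metagene_matrix <- function(vals, mask, genes, colnames_, scheme) {
  rownames(vals) <- genes$gene_id
  colnames(vals) <- colnames_
  dimnames(mask) <- dimnames(vals)
  attr(vals, "mask") <- mask
  attr(vals, "scheme") <- scheme
  vals
}

#' TSS-anchored metagene matrix
#'
#' Per gene, `(upstream + downstream) / binwidth` bins of `binwidth` bases laid
#' out 5'->3' relative to the gene's strand around the TSS (default -4 kb to
#' +8 kb in 100 bp bins, 120 columns).  Bins extending beyond the chromosome
#' (below 0, or above the length in `chrom_sizes` when supplied) read 0 and
#' are flagged in the `"mask"` attribute.
#'
#' @param genes gene table.
#' @param signal a [signal_track()].
#' @param upstream,downstream window extent in bases around the TSS.
#' @param binwidth bin width in bases; must divide `upstream + downstream`.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return numeric matrix (genes x bins) with attributes `mask` (logical
#'   matrix) and `scheme = "tss_anchored"`.
#' @export
tss_anchored_matrix <- function(genes, signal, upstream = 4000,
                                downstream = 8000, binwidth = 100,
                                chrom_sizes = NULL) {
  stopifnot(inherits(signal, "signal_track"),
            (upstream + downstream) %% binwidth == 0)
  B <- (upstream + downstream) / binwidth
  n <- nrow(genes)
  tssv <- tss_of(genes)
  vals <- matrix(0, n, B)
  mask <- matrix(FALSE, n, B)
  for (i in seq_len(n)) {
    cd <- signal$chroms[[genes$chrom[i]]]
    minus <- genes$strand[i] == "-"
    # ascending genome edges; for minus-strand genes the transcript-oriented
    # vector is the reverse of the genome-oriented one
    edges <- if (!minus) tssv[i] - upstream + (0:B) * binwidth
             else tssv[i] + upstream + 1 - (B:0) * binwidth
    ints <- .track_bin_integrals(cd, edges, denom = 1)
    v <- ints / binwidth
    m <- rep(FALSE, B)
    lo <- edges[-(B + 1L)]; hi <- edges[-1L]
    oob <- lo < 0
    if (!is.null(chrom_sizes) && genes$chrom[i] %in% names(chrom_sizes))
      oob <- oob | hi > chrom_sizes[[genes$chrom[i]]]
    v[oob] <- 0; m[oob] <- TRUE
    if (minus) { v <- rev(v); m <- rev(m) }
    vals[i, ] <- v
    mask[i, ] <- m
  }
  offs <- -upstream + (seq_len(B) - 1L) * binwidth
  .metagene_matrix(vals, mask, genes,
                   sprintf("tss%+d", offs + binwidth %/% 2L), "tss_anchored")
}

#' Length-normalized gene-body metagene matrix
#'
#' Fixed-width flanks (default 10 bins of 100 bp upstream of the TSS and
#' downstream of the TTS) around a gene body divided into `body_bins` bins of
#' equal width `L / body_bins` (default 50), with exact fractional per-base
#' weighting at bin boundaries so that total signal mass over the body is
#' conserved.  Genes shorter than `body_bins` bases are handled by the same
#' fractional scheme and flagged in the `"short_genes"` attribute.
#'
#' @param genes gene table.
#' @param signal a [signal_track()].
#' @param flank flank extent in bases.
#' @param flank_bins number of flank bins on each side.
#' @param body_bins number of body bins.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return numeric matrix (genes x `2 * flank_bins + body_bins` bins) with
#'   attributes `mask`, `scheme = "body_normalized"` and `short_genes`.
#' @export
body_normalized_matrix <- function(genes, signal, flank = 1000,
                                   flank_bins = 10, body_bins = 50,
                                   chrom_sizes = NULL) {
  stopifnot(inherits(signal, "signal_track"), flank %% flank_bins == 0)
  fw <- flank / flank_bins
  B <- body_bins
  nb <- 2L * flank_bins + body_bins
  n <- nrow(genes)
  vals <- matrix(0, n, nb)
  mask <- matrix(FALSE, n, nb)
  for (i in seq_len(n)) {
    cd <- signal$chroms[[genes$chrom[i]]]
    s <- genes$start[i]; e <- genes$end[i]; L <- e - s
    # ascending genome edges, scaled by body_bins so every edge is integer:
    # left flank | body (edges s*B + b*L) | right flank
    edges <- c((s - flank + (0:(flank_bins - 1L)) * fw) * B,
               s * B + (0:B) * L,
               (e + (1:flank_bins) * fw) * B)
    ints <- .track_bin_integrals(cd, edges, denom = B)
    widths <- diff(edges)
    v <- ints / widths
    m <- rep(FALSE, nb)
    oob <- edges[-(nb + 1L)] < 0
    if (!is.null(chrom_sizes) && genes$chrom[i] %in% names(chrom_sizes))
      oob <- oob | edges[-1L] > chrom_sizes[[genes$chrom[i]]] * B
    v[oob] <- 0; m[oob] <- TRUE
    if (genes$strand[i] == "-") { v <- rev(v); m <- rev(m) }
    vals[i, ] <- v
    mask[i, ] <- m
  }
  cols <- c(sprintf("up%02d", seq_len(flank_bins)),
            sprintf("body%02d", seq_len(body_bins)),
            sprintf("down%02d", seq_len(flank_bins)))
  out <- .metagene_matrix(vals, mask, genes, cols, "body_normalized")
  attr(out, "short_genes") <- genes$gene_id[(genes$end - genes$start) < body_bins]
  out
}

#' Order metagene rows by expression
#'
#' Expressed genes (FPKM > `threshold`) first, sorted by descending
#' expression; non-expressed genes appended, sorted by descending silent-gene
#' signal (typically the mean H3K27me3 row signal); ties broken by gene id.
#'
#' @param mat metagene matrix (rows named by gene id).
#' @param fpkm named numeric vector of per-gene FPKM at the displayed time
#'   point.
#' @param silent_signal named numeric vector used to sort non-expressed genes
#'   (default: the row means of `mat` itself).
#' @param threshold FPKM threshold (strict `>`).
#' @return the reordered matrix (attributes preserved and reordered).
#' @export
order_rows <- function(mat, fpkm, silent_signal = NULL, threshold = 1) {
  ids <- rownames(mat)
  stopifnot(!is.null(ids), all(ids %in% names(fpkm)))
  if (is.null(silent_signal)) silent_signal <- rowMeans(mat)
  fp <- fpkm[ids]
  expressed <- fp > threshold
  e_ids <- ids[expressed][order(-fp[expressed], ids[expressed])]
  s_ids <- ids[!expressed]
  s_ids <- s_ids[order(-silent_signal[s_ids], s_ids)]
  new_order <- c(e_ids, s_ids)
  out <- mat[new_order, , drop = FALSE]
  attr(out, "mask") <- attr(mat, "mask")[new_order, , drop = FALSE]
  attr(out, "scheme") <- attr(mat, "scheme")
  attr(out, "short_genes") <- attr(mat, "short_genes")
  out
}
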