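# Readers and writers for the standard formats the pipeline touches:
# GFF3 / BED6 gene annotations, BED6 / narrowPeak / broadPeak mark regions,
# bedGraph signal, and the pipeline's own TSV tables (expression, significance
# calls, state calls).  All coordinates are converted to 0-based half-open on
# read and written back in each format's native convention.

.read_noncomment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

.split_fields <- function(x) strsplit(x, "\t", fixed = TRUE)

.check_ncol <- function(fields, lineno, expected, path, at_least = FALSE) {
  nf <- lengths(fields)
  bad <- if (at_least) which(nf < expected) else which(nf != expected)
  if (length(bad))
    stop("malformed line ", lineno[bad[1L]], " in ", path, ": expected ",
         if (at_least) "at least " else "", expected, " tab-separated fields, found ",
         nf[bad[1L]])
}

#' Read gene annotations
#'
#' GFF3 input (1-based closed) is converted to the internal 0-based half-open
#' convention; BED6 is taken as is.  For GFF3, records of type `gene` are used
#' (all records if no `gene` type is present) and the identifier is taken from
#' the `ID` attribute; for BED6 the name column is the identifier.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @return gene annotation data.frame (see [gene_table()]).
#' @export
read_genes <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    nc <- .read_noncomment(path)
    fields <- .split_fields(nc$lines)
    .check_ncol(fields, nc$lineno, 9L, path)
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene records lack ID attributes: ", path)
    biotype <- S4Vectors::mcols(gr)$biotype
    if (is.null(biotype)) biotype <- "protein_coding"
    g <- data.frame(gene_id = as.character(ids),
                    chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1,
                    end = as.numeric(BiocGenerics::end(gr)),
                    strand = as.character(BiocGenerics::strand(gr)),
                    biotype = as.character(biotype),
                    stringsAsFactors = FALSE)
  } else {
    nc <- .read_noncomment(path)
    fields <- .split_fields(nc$lines)
    .check_ncol(fields, nc$lineno, 6L, path)
    m <- do.call(rbind, fields)
    g <- data.frame(gene_id = m[, 4L], chrom = m[, 1L],
                    start = as.numeric(m[, 2L]), end = as.numeric(m[, 3L]),
                    strand = m[, 6L], biotype = "protein_coding",
                    stringsAsFactors = FALSE)
  }
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         g$gene_id[duplicated(g$gene_id)][1L])
  gene_table(g$gene_id, g$chrom, g$start, g$end, g$strand, g$biotype)
}

#' Write gene annotations as GFF3
#'
#' @param genes gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsamstates\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                     genes$chrom, as.integer(genes$start) + 1L,
                     as.integer(genes$end), genes$strand, genes$gene_id,
                     genes$biotype))
  writeLines(lines, path)
  invisible(path)
}

#' Read mark enrichment regions (peaks)
#'
#' ENCODE narrowPeak/broadPeak `signalValue` is mapped to the `signal` column
#' (the ChIP/H3 ratio in this pipeline); BED6 has no signal column and yields
#' `NA` signal.  Strand `"."` is read as unstranded (`"*"`).
#'
#' @param path file path.
#' @param format `"bed6"`, `"narrowPeak"` or `"broadPeak"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal` (plus `summit` for narrowPeak).
#' @export
read_peaks <- function(path, format = c("bed6", "narrowPeak", "broadPeak")) {
  format <- match.arg(format)
  ncols <- switch(format, bed6 = 6L, narrowPeak = 10L, broadPeak = 9L)
  nc <- .read_noncomment(path)
  fields <- .split_fields(nc$lines)
  .check_ncol(fields, nc$lineno, ncols, path)
  m <- do.call(rbind, fields)
  p <- data.frame(chrom = m[, 1L], start = as.numeric(m[, 2L]),
                  end = as.numeric(m[, 3L]), name = m[, 4L],
                  score = as.numeric(m[, 5L]),
                  strand = ifelse(m[, 6L] == ".", "*", m[, 6L]),
                  stringsAsFactors = FALSE)
  p$signal <- if (format == "bed6") NA_real_ else as.numeric(m[, 7L])
  if (format == "narrowPeak") {
    p$summit <- as.numeric(m[, 10L])
    p$summit[p$summit < 0] <- NA_real_
  }
  bad <- which(is.na(p$start) | p$start < 0)
  if (length(bad))
    stop("malformed line ", nc$lineno[bad[1L]], " in ", path,
         ": negative or non-numeric start")
  if (any(!is.na(p$score) & p$score < 0))
    stop("negative score in ", path)
  validate_intervals(p, "peak")
  p
}

#' Write regions as BED6
#'
#' The `signal` column (if present) is written to the BED score field; regions
#' without names are numbered.  Unstranded regions are written with `"."`.
#'
#' @param regions region data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  n <- nrow(regions)
  name <- if ("name" %in% names(regions)) regions$name else sprintf("region_%05d", seq_len(n))
  score <- if ("signal" %in% names(regions)) regions$signal
           else if ("score" %in% names(regions)) regions$score else rep(0, n)
  strand <- if ("strand" %in% names(regions)) ifelse(regions$strand == "*", ".", regions$strand)
            else rep(".", n)
  dt <- data.table::data.table(chrom = regions$chrom,
                               start = as.integer(regions$start),
                               end = as.integer(regions$end),
                               name = name, score = score, strand = strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write peaks in ENCODE narrowPeak format
#'
#' @param peaks peak data.frame with a `signal` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  name <- if ("name" %in% names(peaks)) peaks$name else sprintf("peak_%05d", seq_len(n))
  summit <- if ("summit" %in% names(peaks)) ifelse(is.na(peaks$summit), -1, peaks$summit) else rep(-1, n)
  dt <- data.table::data.table(chrom = peaks$chrom, start = as.integer(peaks$start),
                               end = as.integer(peaks$end), name = name,
                               score = if ("score" %in% names(peaks)) peaks$score else 0,
                               strand = rep(".", n), signalValue = peaks$signal,
                               pValue = -1, qValue = -1, peak = as.integer(summit))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal file
#'
#' @param path file path (4 columns: chrom, start, end, value).
#' @return a [signal_track()]; overlapping intervals raise an error.
#' @export
read_bedgraph <- function(path) {
  nc <- .read_noncomment(path)
  keep <- !startsWith(nc$lines, "track")
  fields <- .split_fields(nc$lines[keep])
  .check_ncol(fields, nc$lineno[keep], 4L, path)
  m <- do.call(rbind, fields)
  signal_track(data.frame(chrom = m[, 1L], start = as.numeric(m[, 2L]),
                          end = as.numeric(m[, 3L]), value = as.numeric(m[, 4L]),
                          stringsAsFactors = FALSE))
}

#' Write a signal track as bedGraph
#'
#' @param track a [signal_track()] or a data.frame with `chrom`, `start`,
#'   `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- if (inherits(track, "signal_track")) {
    do.call(rbind, lapply(names(track$chroms), function(cc)
      cbind(chrom = cc, track$chroms[[cc]])))
  } else track
  dt <- data.table::data.table(chrom = df$chrom, start = as.integer(df$start),
                               end = as.integer(df$end), value = df$value)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, required) {
  nc <- .read_noncomment(path)
  df <- data.table::fread(text = nc$lines, sep = "\t", header = TRUE,
                          data.table = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path)
  df
}

#' Read / write a long-format expression table
#'
#' Columns: `gene_id`, `timepoint`, `replicate`, `fpkm`, `count`.  FPKM and
#' counts must be non-negative; counts integer.
#'
#' @param path file path.
#' @return expression data.frame.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path, c("gene_id", "timepoint", "replicate", "fpkm", "count"))
  df$gene_id <- as.character(df$gene_id)
  df$timepoint <- as.character(df$timepoint)
  if (any(df$fpkm < 0) || any(df$count < 0))
    stop("negative expression values in ", path)
  df
}

#' @rdname read_expression
#' @param expr expression data.frame.
#' @export
write_expression <- function(expr, path) {
  data.table::fwrite(data.table::as.data.table(
    expr[c("gene_id", "timepoint", "replicate", "fpkm", "count")]),
    path, sep = "\t")
  invisible(path)
}

#' Read / write external differential-significance calls
#'
#' Contract for externally computed differential-expression (or differential
#' mark) results: columns `gene_id`, `contrast`, `direction` (`up`/`down`),
#' `significant` (0/1).
#'
#' @param path file path.
#' @return significance-call data.frame.
#' @export
read_signif_calls <- function(path) {
  df <- .read_tsv(path, c("gene_id", "contrast", "direction", "significant"))
  df$gene_id <- as.character(df$gene_id)
  bad <- setdiff(unique(df$direction), c("up", "down"))
  if (length(bad)) stop("unknown direction token: ", bad[1L])
  df
}

#' @rdname read_signif_calls
#' @param calls significance-call data.frame.
#' @export
write_signif_calls <- function(calls, path) {
  data.table::fwrite(data.table::as.data.table(
    calls[c("gene_id", "contrast", "direction", "significant")]),
    path, sep = "\t")
  invisible(path)
}

#' Read / write per-gene chromatin state calls
#'
#' @param path file path.
#' @return state-call data.frame (`gene_id`, `timepoint`, `label`,
#'   `inner_at_tss`, evidence interval columns).
#' @export
read_state_calls <- function(path) {
  df <- .read_tsv(path, c("gene_id", "timepoint", "label", "inner_at_tss"))
  df$gene_id <- as.character(df$gene_id)
  df$timepoint <- as.character(df$timepoint)
  df$label <- as.character(df$label)
  df$inner_at_tss <- as.logical(df$inner_at_tss)
  df
}

#' @rdname read_state_calls
#' @param calls state-call data.frame.
#' @export
write_state_calls <- function(calls, path) {
  cols <- intersect(c("gene_id", "timepoint", "label", "inner_at_tss",
                      "k4_start", "k4_end", "k27_start", "k27_end"),
                    names(calls))
  data.table::fwrite(data.table::as.data.table(calls[cols]), path, sep = "\t")
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  nc <- .read_noncomment(path)
  fields <- .split_fields(nc$lines)
  .check_ncol(fields, nc$lineno, 2L, path)
  m <- do.call(rbind, fields)
  stats::setNames(as.numeric(m[, 2L]), m[, 1L])
}
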