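# Piecewise-constant base-resolution signal (bedGraph semantics): a set of
# sorted, non-overlapping integer intervals per chromosome carrying a value;
# every base not covered by an interval reads as 0 (coverage convention).

#' Construct a piecewise-constant signal track
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open integer intervals).  Intervals may be unsorted but must
#'   not overlap within a chromosome.
#' @return object of class `signal_track` (a per-chromosome list of sorted
#'   interval tables).
#' @export
signal_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  validate_intervals(df, "signal track")
  by_chrom <- lapply(split(df[c("start", "end", "value")], df$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("signal track: overlapping intervals within a chromosome")
    rownames(d) <- NULL
    d
  })
  structure(list(chroms = by_chrom), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  n <- vapply(x$chroms, nrow, integer(1))
  cat("signal_track:", length(n), "chromosome(s),", sum(n), "interval(s)\n")
  invisible(x)
}

# Exact integral of the track over [lo, hi) on one chromosome, with lo/hi and
# interval bounds scaled by `denom` so that all overlap arithmetic is on
# integer-valued doubles.  `edges` is an ascending vector of scaled bin edges;
# returns one integral (in scaled length units) per bin.  Per-bin contributions
# are summed in sorted order so the result is invariant under coordinate
# mirroring of the track.
.track_bin_integrals <- function(chrom_df, edges, denom = 1) {
  nb <- length(edges) - 1L
  out <- numeric(nb)
  if (is.null(chrom_df) || nrow(chrom_df) == 0L) return(out)
  s <- chrom_df$start * denom
  e <- chrom_df$end * denom
  keep <- e > edges[1L] & s < edges[nb + 1L]
  if (!any(keep)) return(out)
  s <- s[keep]; e <- e[keep]; v <- chrom_df$value[keep]
  ov <- pmax(outer(e, edges[-1L], pmin) - outer(s, edges[-(nb + 1L)], pmax), 0)
  contrib <- ov * v
  if (length(v) == 1L) return(as.numeric(contrib))
  vapply(seq_len(nb), function(b) {
    cb <- contrib[, b]
    cb <- cb[ov[, b] > 0]
    if (length(cb) == 0L) 0 else sum(sort(cb))
  }, numeric(1))
}

#' Mean signal over query intervals
#'
#' Length-weighted mean of the piecewise-constant signal over each half-open
#' query interval; uncovered bases contribute 0.  Queries on chromosomes absent
#' from the track return 0.
#'
#' @param track a [signal_track()].
#' @param chrom,start,end query interval(s), vectorized.
#' @return numeric vector of mean signal values.
#' @export
track_query_mean <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "signal_track"), all(end > start))
  chrom <- as.character(chrom)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  out <- numeric(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    cd <- track$chroms[[cc]]
    if (is.null(cd) || nrow(cd) == 0L) next
    out[idx] <- vapply(idx, function(i) {
      ints <- .track_bin_integrals(cd, c(start[i], end[i]), denom = 1)
      ints / (end[i] - start[i])
    }, numeric(1))
  }
  out
}
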