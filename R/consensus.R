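# Replicate-level mark regions -> concordance-filtered consensus regions.
# The signal unit throughout is the normalized ChIP/H3 ratio carried by the
# peak files.

#' Down-sampling contract for per-sample read counts
#'
#' Reduces every sample to the minimum count across samples by seeded sampling
#' without replacement, returning the retained index mask per sample.  This
#' documents the depth-normalization step applied before peak calling;
#' read-level data themselves are outside the pipeline's scope.
#'
#' @param counts_per_sample positive integer vector of read counts.
#' @param seed optional integer seed (local to this call).
#' @return list of sorted integer index vectors, one per sample, each of
#'   length `min(counts_per_sample)`.
#' @export
downsample_counts <- function(counts_per_sample, seed = NULL) {
  if (length(counts_per_sample) == 0L) stop("empty count vector")
  if (any(counts_per_sample <= 0)) stop("all counts must be > 0")
  m <- min(counts_per_sample)
  draw <- function() lapply(counts_per_sample, function(n) {
    if (n == m) seq_len(n) else sort(sample.int(n, m))
  })
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

# Mutual maximal-overlap pairing of two merged replicate region sets.
# Ties broken by larger overlap, then smaller partner start.
.pair_regions <- function(r1, r2) {
  if (nrow(r1) == 0L || nrow(r2) == 0L)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  hits <- list()
  for (cc in intersect(unique(r1$chrom), unique(r2$chrom))) {
    i1 <- which(r1$chrom == cc); i2 <- which(r2$chrom == cc)
    ov <- IRanges::findOverlaps(.as_iranges(r1$start[i1], r1$end[i1]),
                                .as_iranges(r2$start[i2], r2$end[i2]))
    if (length(ov) == 0L) next
    qi <- i1[S4Vectors::queryHits(ov)]; sj <- i2[S4Vectors::subjectHits(ov)]
    w <- overlap_length(r1$chrom[qi], r1$start[qi], r1$end[qi],
                        r2$chrom[sj], r2$start[sj], r2$end[sj])
    hits[[cc]] <- data.frame(i = qi, j = sj, w = w)
  }
  if (length(hits) == 0L)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  h <- do.call(rbind, hits)
  # best partner of each rep1 region and of each rep2 region
  o1 <- order(h$i, -h$w, r2$start[h$j])
  best1 <- h[o1, ][!duplicated(h$i[o1]), c("i", "j")]
  o2 <- order(h$j, -h$w, r1$start[h$i])
  best2 <- h[o2, ][!duplicated(h$j[o2]), c("i", "j")]
  merged <- merge(best1, best2, by = c("i", "j"))  # mutual best
  merged[order(merged$i), , drop = FALSE]
}

#' Replicate concordance filter
#'
#' Matches regions between two biological replicates of the same mark and time
#' point by mutual maximal overlap, computes the per-pair signal difference
#' `d = signal1 - signal2`, and removes pairs whose centred difference
#' `|d - mean(d)|` exceeds `sd_mult` sample standard deviations of `d`.
#' Unmatched regions pass through unfiltered to the consensus step.  With
#' fewer than 3 matched pairs the s.d. is not estimable and filtering is
#' disabled with a warning.
#'
#' @param rep1,rep2 merged region data.frames (`chrom`, `start`, `end`,
#'   `signal`); overlapping regions within each replicate are merged first.
#' @param sd_mult threshold in standard deviations (default 2).
#' @param centred use `|d - mean(d)|` (default) rather than raw `|d|`.
#' @return list with `rep1_kept`, `rep2_kept` (region sets after removal),
#'   `kept_pairs`, `removed_pairs` (paired coordinates and signals),
#'   `sd_estimate` and `mean_d`.
#' @export
concordance_filter <- function(rep1, rep2, sd_mult = 2, centred = TRUE) {
  r1 <- merge_regions(rep1)
  r2 <- merge_regions(rep2)
  pairs <- .pair_regions(r1, r2)
  mkpairs <- function(p) data.frame(
    chrom = r1$chrom[p$i],
    start1 = r1$start[p$i], end1 = r1$end[p$i], signal1 = r1$signal[p$i],
    start2 = r2$start[p$j], end2 = r2$end[p$j], signal2 = r2$signal[p$j],
    d = r1$signal[p$i] - r2$signal[p$j], stringsAsFactors = FALSE)
  if (nrow(pairs) < 3L) {
    if (nrow(pairs) > 0L)
      warning("fewer than 3 matched pairs; concordance filter disabled")
    return(list(rep1_kept = r1, rep2_kept = r2, kept_pairs = mkpairs(pairs),
                removed_pairs = mkpairs(pairs[0, ]), sd_estimate = NA_real_,
                mean_d = NA_real_))
  }
  d <- r1$signal[pairs$i] - r2$signal[pairs$j]
  sd_est <- stats::sd(d)
  mu <- if (centred) mean(d) else 0
  dev <- abs(d - mu)
  drop <- dev > sd_mult * sd_est
  list(rep1_kept = r1[setdiff(seq_len(nrow(r1)), pairs$i[drop]), , drop = FALSE],
       rep2_kept = r2[setdiff(seq_len(nrow(r2)), pairs$j[drop]), , drop = FALSE],
       kept_pairs = mkpairs(pairs[!drop, , drop = FALSE]),
       removed_pairs = mkpairs(pairs[drop, , drop = FALSE]),
       sd_estimate = sd_est, mean_d = mean(d))
}

#' Consensus regions from two replicates
#'
#' A consensus region is the union span of a connected chain of regions that
#' overlap (by at least 1 bp) across the two replicates: every emitted interval
#' has support in both replicates, and transitively overlapping regions merge
#' into one.  Regions present in only one replicate are dropped.  The
#' consensus signal is the length-weighted mean of all contributing replicate
#' regions.
#'
#' @param rep1,rep2 region data.frames (filtered replicate sets, see
#'   [concordance_filter()]); each is merged internally first.
#' @return sorted consensus region data.frame (`chrom`, `start`, `end`,
#'   `signal`, `n_contrib`).
#' @export
consensus_regions <- function(rep1, rep2) {
  r1 <- merge_regions(rep1)
  r2 <- merge_regions(rep2)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      signal = numeric(), n_contrib = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(r1) == 0L || nrow(r2) == 0L) return(empty)
  out <- list()
  for (cc in intersect(unique(r1$chrom), unique(r2$chrom))) {
    a <- r1[r1$chrom == cc, , drop = FALSE]
    b <- r2[r2$chrom == cc, , drop = FALSE]
    ov <- IRanges::findOverlaps(.as_iranges(a$start, a$end),
                                .as_iranges(b$start, b$end))
    if (length(ov) == 0L) next
    # union-find over the bipartite overlap graph
    na <- nrow(a)
    parent <- seq_len(na + nrow(b))
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (k in seq_len(length(ov))) {
      ra <- find(S4Vectors::queryHits(ov)[k])
      rb <- find(na + S4Vectors::subjectHits(ov)[k])
      if (ra != rb) parent[rb] <- ra
    }
    ia <- S4Vectors::queryHits(ov); ib <- S4Vectors::subjectHits(ov)
    nodes_a <- sort(unique(ia)); nodes_b <- sort(unique(ib))
    comp_a <- vapply(nodes_a, find, integer(1))
    comp_b <- vapply(nodes_b + na, find, integer(1))
    all_start <- c(a$start[nodes_a], b$start[nodes_b])
    all_end <- c(a$end[nodes_a], b$end[nodes_b])
    all_sig <- c(a$signal[nodes_a], b$signal[nodes_b])
    comp <- c(comp_a, comp_b)
    len <- all_end - all_start
    agg <- function(f, x) vapply(split(x, comp), f, numeric(1))
    st <- agg(min, all_start)
    en <- agg(max, all_end)
    sg <- vapply(split(seq_along(comp), comp),
                 function(i) sum(all_sig[i] * len[i]) / sum(len[i]), numeric(1))
    nc <- lengths(split(seq_along(comp), comp))
    out[[cc]] <- data.frame(chrom = cc, start = st, end = en, signal = sg,
                            n_contrib = as.integer(nc),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

#' Build consensus mark sets for a whole simulated experiment
#'
#' Convenience wrapper running [concordance_filter()] then
#' [consensus_regions()] for every mark and time point of a [simulate_dataset()]
#' result (or any nested `peaks[[mark]][[timepoint]] = list(rep1, rep2)`
#' structure).
#'
#' @param peaks nested replicate peak list.
#' @param sd_mult concordance threshold in standard deviations.
#' @param filter apply the concordance filter (default `TRUE`).
#' @return nested list `consensus[[mark]][[timepoint]]` of consensus region
#'   data.frames; each carries the filter summary as attribute `"filter"`.
#' @export
build_consensus <- function(peaks, sd_mult = 2, filter = TRUE) {
  lapply(peaks, function(by_tp) lapply(by_tp, function(reps) {
    if (filter) {
      cf <- concordance_filter(reps$rep1, reps$rep2, sd_mult = sd_mult)
      cons <- consensus_regions(cf$rep1_kept, cf$rep2_kept)
      attr(cons, "filter") <- cf[c("sd_estimate", "mean_d")]
      attr(cons, "n_removed") <- nrow(cf$removed_pairs)
    } else {
      cons <- consensus_regions(reps$rep1, reps$rep2)
    }
    cons
  }))
}
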