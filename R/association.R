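# Per-gene mark assignment (TSS window and gene body) and the
# mark--expression association statistics: marked-gene proportions with
# standard errors over time points and Spearman rank correlation with the
# t-approximation significance test.

#' Per-gene mark profiles
#'
#' Intersects consensus mark regions with annotated genes.  A gene is
#' `tss_marked` when any consensus region of the mark overlaps its TSS window
#' (TSS +- `window_halfwidth`; the window is symmetric, so strand only moves
#' the anchor).  `tss_signal` is the unweighted mean signal of TSS-overlapping
#' regions; `body_signal` is the overlap-length-weighted mean over the gene
#' body (NA when nothing overlaps).  Genes on chromosomes absent from the
#' consensus set simply receive an unmarked profile.
#'
#' @param genes gene table.
#' @param consensus_by_mark named list of consensus region data.frames, one
#'   per mark (e.g. `H3K4me3`, `H3K27me3`).
#' @param window_halfwidth TSS window half-width in bases (default 500).
#' @return data.frame with one row per gene x mark: `gene_id`, `mark`,
#'   `n_regions`, `tss_marked`, `tss_signal`, `body_signal`.
#' @export
profile_genes <- function(genes, consensus_by_mark, window_halfwidth = 500) {
  tssv <- tss_of(genes)
  win <- tss_window(tssv, window_halfwidth)
  res <- lapply(names(consensus_by_mark), function(mark) {
    cons <- consensus_by_mark[[mark]]
    n <- nrow(genes)
    prof <- data.frame(gene_id = genes$gene_id, mark = mark,
                       n_regions = 0L, tss_marked = FALSE,
                       tss_signal = NA_real_, body_signal = NA_real_,
                       stringsAsFactors = FALSE)
    if (is.null(cons) || nrow(cons) == 0L) return(prof)
    for (cc in intersect(unique(genes$chrom), unique(cons$chrom))) {
      gi <- which(genes$chrom == cc)
      ci <- which(cons$chrom == cc)
      ir_c <- .as_iranges(cons$start[ci], cons$end[ci])
      # TSS window overlaps
      ovw <- IRanges::findOverlaps(.as_iranges(win$start[gi], win$end[gi]), ir_c)
      if (length(ovw)) {
        qh <- S4Vectors::queryHits(ovw); sh <- S4Vectors::subjectHits(ovw)
        sig <- cons$signal[ci[sh]]
        means <- vapply(split(sig, qh), mean, numeric(1))
        rows <- gi[as.integer(names(means))]
        prof$tss_marked[rows] <- TRUE
        prof$tss_signal[rows] <- means
      }
      # gene body overlaps
      ovb <- IRanges::findOverlaps(.as_iranges(genes$start[gi], genes$end[gi]), ir_c)
      if (length(ovb)) {
        qh <- S4Vectors::queryHits(ovb); sh <- S4Vectors::subjectHits(ovb)
        gq <- gi[qh]; cq <- ci[sh]
        ovl <- overlap_length(genes$chrom[gq], genes$start[gq], genes$end[gq],
                              cons$chrom[cq], cons$start[cq], cons$end[cq])
        wsum <- vapply(split(cons$signal[cq] * ovl, qh), sum, numeric(1))
        lsum <- vapply(split(ovl, qh), sum, numeric(1))
        rows <- gi[as.integer(names(wsum))]
        prof$body_signal[rows] <- wsum / lsum
      }
      # regions overlapping body or window
      both <- union(
        paste(S4Vectors::queryHits(ovw), S4Vectors::subjectHits(ovw)),
        paste(S4Vectors::queryHits(ovb), S4Vectors::subjectHits(ovb)))
      if (length(both)) {
        qh <- as.integer(sub(" .*", "", both))
        cnt <- table(qh)
        prof$n_regions[gi[as.integer(names(cnt))]] <- as.integer(cnt)
      }
    }
    prof
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Marked-gene proportions by expression stratum
#'
#' For each time point, the proportion of genes in the stratum (expressed:
#' mean replicate FPKM > `threshold` at that time point; non-expressed:
#' complement) whose TSS window carries the mark, plus the mean proportion and
#' its standard error over time points (s.e. = s.d. of the per-time-point
#' proportions / sqrt(T)).
#'
#' @param profiles_by_tp named list (time point -> [profile_genes()] output).
#' @param expression long expression data.frame (see [read_expression()]).
#' @param mark mark name to tabulate.
#' @param stratum `"expressed"` or `"non_expressed"`.
#' @param threshold FPKM threshold (strict `>`), default 1.
#' @return list with `per_timepoint` (data.frame: timepoint, n, n_marked,
#'   proportion) and `mean`, `se` over time points.
#' @export
marked_fraction <- function(profiles_by_tp, expression, mark,
                            stratum = c("expressed", "non_expressed"),
                            threshold = 1) {
  stratum <- match.arg(stratum)
  flags <- expressed_genes(expression, threshold = threshold)
  tps <- names(profiles_by_tp)
  rows <- lapply(tps, function(tp) {
    prof <- profiles_by_tp[[tp]]
    prof <- prof[prof$mark == mark, , drop = FALSE]
    expr_tp <- flags$local[prof$gene_id, tp]
    keep <- if (stratum == "expressed") expr_tp else !expr_tp
    n <- sum(keep, na.rm = TRUE)
    if (n == 0L) {
      warning("empty stratum '", stratum, "' at ", tp)
      return(data.frame(timepoint = tp, n = 0L, n_marked = 0L,
                        proportion = NA_real_, stringsAsFactors = FALSE))
    }
    nm <- sum(prof$tss_marked & keep, na.rm = TRUE)
    data.frame(timepoint = tp, n = n, n_marked = nm, proportion = nm / n,
               stringsAsFactors = FALSE)
  })
  per_tp <- do.call(rbind, rows)
  p <- per_tp$proportion
  list(per_timepoint = per_tp, mean = mean(p),
       se = stats::sd(p) / sqrt(length(p)))
}

#' Spearman rank correlation with t-approximation test
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' two-sided p-value comes from `t = rho * sqrt((n - 2) / (1 - rho^2))` on a
#' Student t distribution with `n - 2` degrees of freedom.  `|rho| = 1` gives
#' p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_with_t <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 complete paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' TSS signal vs expression correlation per time point
#'
#' The pipeline's association statistic: among genes expressed at a given time
#' point (mean replicate FPKM > threshold) and carrying the mark at the TSS,
#' the Spearman correlation (with t-approximation p-value) between TSS mark
#' signal and FPKM.
#'
#' @inheritParams marked_fraction
#' @return data.frame: timepoint, n, rho, p.
#' @export
tss_expression_correlation <- function(profiles_by_tp, expression, mark,
                                       threshold = 1) {
  flags <- expressed_genes(expression, threshold = threshold)
  rows <- lapply(names(profiles_by_tp), function(tp) {
    prof <- profiles_by_tp[[tp]]
    prof <- prof[prof$mark == mark & prof$tss_marked, , drop = FALSE]
    expr_tp <- flags$local[prof$gene_id, tp]
    fp <- flags$mean_fpkm[prof$gene_id, tp]
    keep <- !is.na(expr_tp) & expr_tp
    ct <- spearman_with_t(prof$tss_signal[keep], fp[keep])
    data.frame(timepoint = tp, n = ct$n, rho = ct$rho, p = ct$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
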