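# Expression-side procedures defined directly by the analysis: the FPKM > 1
# expressed-gene definition, direction-consistency classification of external
# differential-significance calls, the mean-expression slope test, and ddCt
# relative quantification for qPCR.

#' Expressed-gene flags
#'
#' Replicate FPKM values are averaged per gene and time point before
#' thresholding.  A gene is locally expressed at a time point when its mean
#' FPKM exceeds `threshold` (strict `>`), and globally expressed when that
#' holds at at least one time point.
#'
#' @param expr long expression data.frame (`gene_id`, `timepoint`,
#'   `replicate`, `fpkm`).
#' @param threshold FPKM threshold, default 1.
#' @return list with `global` (named logical), `local` (gene x timepoint
#'   logical matrix) and `mean_fpkm` (gene x timepoint numeric matrix).
#' @export
expressed_genes <- function(expr, threshold = 1) {
  dt <- data.table::as.data.table(expr[c("gene_id", "timepoint", "fpkm")])
  agg <- dt[, list(fpkm = mean(fpkm)), by = c("gene_id", "timepoint")]
  tps <- unique(expr$timepoint)
  ids <- unique(expr$gene_id)
  m <- matrix(NA_real_, length(ids), length(tps),
              dimnames = list(ids, tps))
  m[cbind(match(agg$gene_id, ids), match(agg$timepoint, tps))] <- agg$fpkm
  local <- m > threshold
  list(global = apply(local, 1L, any, na.rm = TRUE),
       local = local, mean_fpkm = m)
}

#' Classify differential-expression direction consistency
#'
#' Given externally computed per-contrast significance calls, a gene is `up`
#' when it has at least one significant contrast and all significant
#' directions are up; `down` symmetrically; `complex` when both directions
#' occur among significant contrasts; `ns` otherwise.
#'
#' @param sig_calls data.frame with `gene_id`, `contrast`, `direction`
#'   (`up`/`down`), `significant` (0/1).
#' @param gene_universe optional character vector; genes without significant
#'   calls are reported as `ns`.
#' @return data.frame `gene_id`, `de_class`.
#' @export
classify_de_direction <- function(sig_calls, gene_universe = NULL) {
  bad <- setdiff(unique(sig_calls$direction), c("up", "down"))
  if (length(bad)) stop("unknown direction token: ", bad[1L])
  sig <- sig_calls[sig_calls$significant == 1, , drop = FALSE]
  cls <- vapply(split(sig$direction, sig$gene_id), function(d) {
    if (all(d == "up")) "up" else if (all(d == "down")) "down" else "complex"
  }, character(1))
  ids <- unique(c(names(cls), gene_universe, sig_calls$gene_id))
  out <- data.frame(gene_id = ids, de_class = "ns", stringsAsFactors = FALSE)
  out$de_class[match(names(cls), out$gene_id)] <- unname(cls)
  out[order(out$gene_id), , drop = FALSE]
}

#' Slope test of mean expression against time
#'
#' Ordinary least squares of mean expression on time, with a two-sided t test
#' of zero slope on T - 2 degrees of freedom.  A numerically perfect fit
#' (zero residual) reports p = 0 for a nonzero slope and p = 1 for a zero
#' slope (constant series).
#'
#' @param mean_expression numeric vector of per-time-point mean expression.
#' @param times numeric time values (default equally spaced).
#' @return list with `slope`, `intercept`, `p`, `df`.
#' @export
slope_test <- function(mean_expression, times = seq_along(mean_expression) - 1) {
  y <- as.numeric(mean_expression); t <- as.numeric(times)
  if (length(y) < 3L || length(t) != length(y))
    stop("need >= 3 time points")
  fit <- stats::lm(y ~ t)
  sl <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  scale <- max(sum((y - mean(y))^2), .Machine$double.eps)
  if (rss / scale < 1e-12 || !is.finite(sl)) {
    if (abs(sl) < 1e-12 * max(abs(y), 1)) return(list(slope = 0, intercept = mean(y), p = 1, df = length(y) - 2L))
    return(list(slope = sl, intercept = unname(stats::coef(fit)[1L]), p = 0,
                df = length(y) - 2L))
  }
  sm <- summary(fit)$coefficients
  list(slope = sl, intercept = unname(stats::coef(fit)[1L]),
       p = unname(sm[2L, 4L]), df = length(y) - 2L)
}

#' Relative expression by the ddCt method
#'
#' `dCt = Ct(target) - Ct(reference)` per sample; `ddCt = dCt - mean dCt` over
#' the calibrator samples; relative expression is `2^(-ddCt)`.  Undetected
#' targets (NA, or Ct above the cycle cap) enter at the cap (default 40
#' cycles) before differencing, giving a conservative estimate.  Technical
#' replicates (multiple rows per sample x gene) are averaged on the Ct scale.
#'
#' @param records data.frame with `sample`, `gene`, `ct`.
#' @param target_gene gene to quantify.
#' @param reference_gene normalization control gene; must be measured in every
#'   sample.
#' @param calibrator_samples samples whose mean dCt defines the baseline.
#' @param ct_cap detection cap in cycles (default 40).
#' @return data.frame `sample`, `dct`, `ddct`, `rel_expr`.
#' @export
ddct_relative_expression <- function(records, target_gene, reference_gene,
                                     calibrator_samples, ct_cap = 40) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(records)))
  ct <- records$ct
  ct[is.na(ct) | ct > ct_cap] <- ct_cap
  if (any(ct <= 0)) stop("Ct values must be positive")
  records$ct <- ct
  mean_ct <- function(gene) {
    r <- records[records$gene == gene, , drop = FALSE]
    vapply(split(r$ct, r$sample), mean, numeric(1))
  }
  tgt <- mean_ct(target_gene)
  ref <- mean_ct(reference_gene)
  samples <- sort(unique(records$sample[records$gene == target_gene]))
  if (!all(samples %in% names(ref)))
    stop("reference gene '", reference_gene, "' missing in sample(s): ",
         paste(setdiff(samples, names(ref)), collapse = ", "))
  dct <- tgt[samples] - ref[samples]
  if (!all(calibrator_samples %in% samples))
    stop("calibrator sample(s) not measured: ",
         paste(setdiff(calibrator_samples, samples), collapse = ", "))
  cal <- mean(dct[calibrator_samples])
  ddct <- dct - cal
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             rel_expr = unname(2^(-ddct)), stringsAsFactors = FALSE)
}
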