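# Joint H3K4me3/H3K27me3 state classification around the TSS, transition
# matrices across time points, and state-set overlap arithmetic.
#
# Decision cascade (total: every gene gets exactly one label):
#   (1) no K4 and no K27 -> Unmarked; only one mark -> K4_only / K27_only
#   (2) both present but no cross-mark pair overlaps >= min_overlap -> Non
#   (3) among overlapping K4/K27 pairs, take the pair with maximal overlap
#       whose union intersects the TSS window; if none touches the window,
#       fall back to the overall maximal-overlap pair
#   (4) K27 contains K4 (with slack) and the K4 midpoint lies within
#       TSS +- halfwidth -> H (harbouring)
#   (5) K4 contains K27 (with slack) and the K27 midpoint lies within the
#       window -> E (embedded)
#   (6) otherwise partial: K27_gt_K4 if span(K27) > span(K4), K4_gt_K27 if
#       span(K4) > span(K27); equal spans -> K27_gt_K4 (documented tie-break).
# Containment with the inner peak off-window falls to rule (6) with
# inner_at_tss = FALSE.  Rule (4) is tested before rule (5), so mutually
# containing (identical up to slack) intervals resolve to H.

#' State-call parameters
#'
#' @param tss_halfwidth TSS window half-width in bases (default 500).
#' @param containment_slack slack allowed on containment, in bases (default 0).
#' @param min_overlap minimum K4/K27 overlap in bases to count as overlapping
#'   (default 1).
#' @return a `state_params` list.
#' @export
state_params <- function(tss_halfwidth = 500, containment_slack = 0,
                         min_overlap = 1) {
  stopifnot(tss_halfwidth >= 0, containment_slack >= 0, min_overlap >= 1)
  structure(list(tss_halfwidth = tss_halfwidth,
                 containment_slack = containment_slack,
                 min_overlap = min_overlap), class = "state_params")
}

# Vectorized cascade rules (2)-(6) for a single K4/K27 interval pair per case.
# Returns list(label, inner_at_tss).
.classify_pair <- function(k4s, k4e, k27s, k27e, tss, params) {
  hw <- params$tss_halfwidth; slack <- params$containment_slack
  ov <- pmax(0, pmin(k4e, k27e) - pmax(k4s, k27s))
  mid4 <- (k4s + k4e) / 2
  mid27 <- (k27s + k27e) / 2
  c27c4 <- (k27s - slack <= k4s) & (k4e <= k27e + slack)
  c4c27 <- (k4s - slack <= k27s) & (k27e <= k4e + slack)
  at4 <- abs(mid4 - tss) <= hw
  at27 <- abs(mid27 - tss) <= hw
  span4 <- k4e - k4s
  span27 <- k27e - k27s
  label <- ifelse(ov < params$min_overlap, "Non",
           ifelse(c27c4 & at4, "H",
           ifelse(c4c27 & at27, "E",
           ifelse(span27 >= span4, "K27_gt_K4", "K4_gt_K27"))))
  inner <- ifelse(label == "H", at4, ifelse(label == "E", at27, FALSE))
  list(label = label, inner_at_tss = inner)
}

#' Classify the joint mark state of one gene
#'
#' @param gene single-row gene table.
#' @param k4_regions,k27_regions consensus region data.frames for the two
#'   marks (whole sets are fine; they are clipped to the gene's scope, i.e.
#'   gene body plus TSS window).
#' @param params a [state_params()].
#' @return one-row data.frame: `gene_id`, `label`, `inner_at_tss`, evidence
#'   interval columns `k4_start`, `k4_end`, `k27_start`, `k27_end`.
#' @export
classify_gene_state <- function(gene, k4_regions, k27_regions,
                                params = state_params()) {
  calls <- classify_states(gene, list(H3K4me3 = k4_regions,
                                      H3K27me3 = k27_regions), params)
  calls
}

#' Classify the joint mark state of every gene
#'
#' Applies the decision cascade (see the package vignette) to each gene, using
#' the consensus regions of both marks that overlap the gene body or its TSS
#' window.
#'
#' @param genes gene table.
#' @param consensus_by_mark named list with elements `H3K4me3` and `H3K27me3`.
#' @param params a [state_params()].
#' @return data.frame with one row per gene: `gene_id`, `label`,
#'   `inner_at_tss`, evidence intervals (NA where no pair was considered).
#' @export
classify_states <- function(genes, consensus_by_mark, params = state_params()) {
  k4 <- consensus_by_mark[["H3K4me3"]]
  k27 <- consensus_by_mark[["H3K27me3"]]
  n <- nrow(genes)
  tssv <- tss_of(genes)
  win <- tss_window(tssv, params$tss_halfwidth)
  scope_s <- pmin(genes$start, win$start)
  scope_e <- pmax(genes$end, win$end)

  hits_for <- function(cons) {
    res <- vector("list", n)
    if (is.null(cons) || nrow(cons) == 0L) return(res)
    for (cc in intersect(unique(genes$chrom), unique(cons$chrom))) {
      gi <- which(genes$chrom == cc); ci <- which(cons$chrom == cc)
      ov <- IRanges::findOverlaps(.as_iranges(scope_s[gi], scope_e[gi]),
                                  .as_iranges(cons$start[ci], cons$end[ci]))
      if (length(ov) == 0L) next
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      for (g in unique(qh)) res[[gi[g]]] <- ci[sh[qh == g]]
    }
    res
  }
  h4 <- hits_for(k4)
  h27 <- hits_for(k27)

  label <- character(n)
  inner <- logical(n)
  ev <- matrix(NA_real_, n, 4,
               dimnames = list(NULL, c("k4_start", "k4_end", "k27_start", "k27_end")))
  for (i in seq_len(n)) {
    i4 <- h4[[i]]; i27 <- h27[[i]]
    if (length(i4) == 0L && length(i27) == 0L) { label[i] <- "Unmarked"; next }
    if (length(i27) == 0L) {
      label[i] <- "K4_only"
      best <- i4[which.max(k4$end[i4] - k4$start[i4])]
      ev[i, 1:2] <- c(k4$start[best], k4$end[best]); next
    }
    if (length(i4) == 0L) {
      label[i] <- "K27_only"
      best <- i27[which.max(k27$end[i27] - k27$start[i27])]
      ev[i, 3:4] <- c(k27$start[best], k27$end[best]); next
    }
    # all cross-mark pairs
    pa <- rep(i4, times = length(i27))
    pb <- rep(i27, each = length(i4))
    povl <- pmax(0, pmin(k4$end[pa], k27$end[pb]) - pmax(k4$start[pa], k27$start[pb]))
    ok <- povl >= params$min_overlap
    if (!any(ok)) {
      label[i] <- "Non"
      b4 <- i4[which.max(k4$end[i4] - k4$start[i4])]
      b27 <- i27[which.max(k27$end[i27] - k27$start[i27])]
      ev[i, ] <- c(k4$start[b4], k4$end[b4], k27$start[b27], k27$end[b27])
      next
    }
    pa <- pa[ok]; pb <- pb[ok]; povl <- povl[ok]
    us <- pmin(k4$start[pa], k27$start[pb])
    ue <- pmax(k4$end[pa], k27$end[pb])
    in_win <- us < win$end[i] & ue > win$start[i]
    cand <- if (any(in_win)) which(in_win) else seq_along(pa)
    sel <- cand[order(-povl[cand], k4$start[pa[cand]], k27$start[pb[cand]])[1L]]
    a <- pa[sel]; b <- pb[sel]
    res <- .classify_pair(k4$start[a], k4$end[a], k27$start[b], k27$end[b],
                          tssv[i], params)
    label[i] <- res$label
    inner[i] <- res$inner_at_tss
    ev[i, ] <- c(k4$start[a], k4$end[a], k27$start[b], k27$end[b])
  }
  out <- data.frame(gene_id = genes$gene_id, label = label,
                    inner_at_tss = inner, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(ev))
}

#' Classify states at every time point of a simulated experiment
#'
#' @param genes gene table.
#' @param consensus nested list `consensus[[mark]][[timepoint]]` (see
#'   [build_consensus()]).
#' @param params a [state_params()].
#' @return data.frame of state calls with a `timepoint` column.
#' @export
classify_states_timecourse <- function(genes, consensus,
                                       params = state_params()) {
  tps <- names(consensus[["H3K4me3"]])
  out <- lapply(tps, function(tp) {
    calls <- classify_states(genes, list(
      H3K4me3 = consensus[["H3K4me3"]][[tp]],
      H3K27me3 = consensus[["H3K27me3"]][[tp]]), params)
    cbind(timepoint = tp, calls, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("gene_id", "timepoint", "label", "inner_at_tss",
          "k4_start", "k4_end", "k27_start", "k27_end")]
}

#' Chromatin state transition matrix
#'
#' Counts genes moving between state labels from one time point to another.
#' Genes missing at either time point are excluded and reported via the
#' `excluded` attribute; row fractions are counts normalized per origin row.
#'
#' @param calls_t0,calls_t1 state-call data.frames (`gene_id`, `label`).
#' @param labels label order for the matrix (default [state_labels()]; may be
#'   a subset, which restricts the gene universe to those labels at both time
#'   points).
#' @return object of class `transition_matrix`: list with `counts`,
#'   `row_fractions`, `n_per_row`, `labels`.
#' @export
transition_matrix <- function(calls_t0, calls_t1, labels = state_labels()) {
  common <- intersect(calls_t0$gene_id, calls_t1$gene_id)
  if (length(common) == 0L) stop("disjoint gene universes")
  l0 <- calls_t0$label[match(common, calls_t0$gene_id)]
  l1 <- calls_t1$label[match(common, calls_t1$gene_id)]
  keep <- l0 %in% labels & l1 %in% labels
  counts <- table(factor(l0[keep], levels = labels),
                  factor(l1[keep], levels = labels))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("from", "to")
  n_row <- rowSums(counts)
  fr <- counts / ifelse(n_row == 0, NA, n_row)
  excluded <- c(setdiff(calls_t0$gene_id, common),
                setdiff(calls_t1$gene_id, common))
  structure(list(counts = counts, row_fractions = fr,
                 n_per_row = n_row, labels = labels,
                 excluded = excluded, n_genes = sum(keep)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix over", x$n_genes, "genes\n")
  print(round(x$row_fractions, 3))
  invisible(x)
}

#' Overlap of two gene (or region) id sets
#'
#' @param set_a,set_b character vectors of identifiers.
#' @return list with `n_common`, `frac_a` (|A..B|/|A|), `frac_b` (|A..B|/|B|).
#' @export
state_set_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  nc <- length(intersect(a, b))
  list(n_common = nc,
       frac_a = if (length(a)) nc / length(a) else 0,
       frac_b = if (length(b)) nc / length(b) else 0)
}
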