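# Independent oracles and fixture builders shared across tests.  The oracles
# deliberately use brute-force, per-base mechanisms that differ from the
# package's interval-sweep implementations.

# Per-base consensus oracle: a base supports consensus iff covered in both
# replicates; seeds of shared coverage are grown to the union span of every
# replicate region they (transitively) touch, by fixpoint expansion.
# Coordinates 0-based half-open in and out.
oracle_consensus <- function(rep1, rep2, chrlen) {
  covvec <- function(r) {
    v <- logical(chrlen)
    for (k in seq_len(nrow(r))) v[(r$start[k] + 1):r$end[k]] <- TRUE
    v
  }
  runs <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(s = starts[r$values], e = ends[r$values])  # 1-based inclusive
  }
  c1 <- covvec(rep1); c2 <- covvec(rep2)
  r1 <- runs(c1); r2 <- runs(c2)
  seeds <- runs(c1 & c2)
  if (nrow(seeds) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  spans <- seeds
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(spans))) {
      for (rr in list(r1, r2)) {
        hit <- rr$s <= spans$e[i] & rr$e >= spans$s[i]
        if (any(hit)) {
          ns <- min(spans$s[i], rr$s[hit]); ne <- max(spans$e[i], rr$e[hit])
          if (ns != spans$s[i] || ne != spans$e[i]) {
            spans$s[i] <- ns; spans$e[i] <- ne; changed <- TRUE
          }
        }
      }
    }
    # merge overlapping spans
    spans <- spans[order(spans$s), , drop = FALSE]
    i <- 1L
    while (i < nrow(spans)) {
      if (spans$s[i + 1L] <= spans$e[i]) {
        spans$e[i] <- max(spans$e[i], spans$e[i + 1L])
        spans <- spans[-(i + 1L), , drop = FALSE]
        changed <- TRUE
      } else i <- i + 1L
    }
    if (!changed) break
  }
  data.frame(start = spans$s - 1, end = spans$e)
}

# Truth-table state oracle for a single K4/K27 interval pair, coded over
# explicit per-base sets.
oracle_state <- function(k4s, k4e, k27s, k27e, tss, hw = 500, slack = 0,
                         minov = 1) {
  b4 <- seq(k4s, k4e - 1)
  b27 <- seq(k27s, k27e - 1)
  if (length(intersect(b4, b27)) < minov) return("Non")
  b27x <- seq(k27s - slack, k27e - 1 + slack)
  b4x <- seq(k4s - slack, k4e - 1 + slack)
  mid4 <- (min(b4) + max(b4) + 1) / 2
  mid27 <- (min(b27) + max(b27) + 1) / 2
  if (all(b4 %in% b27x) && abs(mid4 - tss) <= hw) return("H")
  if (all(b27 %in% b4x) && abs(mid27 - tss) <= hw) return("E")
  if (length(b27) >= length(b4)) "K27_gt_K4" else "K4_gt_K27"
}

# Random non-degenerate region set on one chromosome.
random_regions <- function(n, chrlen, min_w = 200, max_w = 3000,
                           chrom = "chrT") {
  s <- floor(runif(n, 0, chrlen - max_w))
  w <- floor(runif(n, min_w, max_w))
  data.frame(chrom = chrom, start = s, end = s + w,
             signal = rlnorm(n, 0.5, 0.5), stringsAsFactors = FALSE)
}

# One-gene table helper.
one_gene <- function(start, end, strand = "+", chrom = "chr1", id = "g1") {
  gene_table(id, chrom, start, end, strand)
}

# Tiny expression table: one replicate, FPKM as given (genes x timepoints).
expr_from_matrix <- function(fpkm_mat, n_reps = 1) {
  ids <- rownames(fpkm_mat); tps <- colnames(fpkm_mat)
  do.call(rbind, lapply(seq_len(n_reps), function(r)
    data.frame(gene_id = rep(ids, times = ncol(fpkm_mat)),
               timepoint = rep(tps, each = nrow(fpkm_mat)),
               replicate = r, fpkm = as.vector(fpkm_mat),
               count = round(as.vector(fpkm_mat) * 10),
               stringsAsFactors = FALSE)))
}
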