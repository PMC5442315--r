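#!/usr/bin/env Rscript
# 05 — Metagene signal matrices.
#
# Two views of the 0 LD H3K4me3 and H3K27me3 signal: a TSS-anchored window
# (-4 kb to +8 kb, 100 bp bins) and a length-normalized gene-body profile
# (10 x 100 bp flank bins either side, 50 equal-width body bins).  Rows are
# ordered by expression; genes with no detectable expression are sorted by
# their H3K27me3 level.

library(samstates)

ind <- "results/data"
out <- "results/metagene"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read_genes(file.path(ind, "genes.gff3"), "gff3")
expr <- read_expression(file.path(ind, "expression.tsv"))
cs <- read_chrom_sizes(file.path(ind, "chrom.sizes"))
k4 <- read_bedgraph(file.path(ind, "H3K4me3_0LD.bedGraph"))
k27 <- read_bedgraph(file.path(ind, "H3K27me3_0LD.bedGraph"))

fl <- expressed_genes(expr)
fp0 <- fl$mean_fpkm[, "0LD"]

mats <- list(
  k4_tss = tss_anchored_matrix(genes, k4, chrom_sizes = cs),
  k27_tss = tss_anchored_matrix(genes, k27, chrom_sizes = cs),
  k4_body = body_normalized_matrix(genes, k4, chrom_sizes = cs),
  k27_body = body_normalized_matrix(genes, k27, chrom_sizes = cs))
k27_row_mean <- rowMeans(mats$k27_body)
for (nm in names(mats)) {
  m <- order_rows(mats[[nm]], fp0, silent_signal = k27_row_mean)
  write.table(round(m, 6), file.path(out, paste0(nm, "_matrix.tsv")),
              sep = "\t", quote = FALSE)
  cat(sprintf("%s: %d genes x %d bins, mean signal %.3f\n",
              nm, nrow(m), ncol(m), mean(m)))
}

# expressed genes should dominate the top H3K4me3 rows
m4 <- order_rows(mats$k4_body, fp0, silent_signal = k27_row_mean)
n_expr <- sum(fp0 > 1)
cat(sprintf("Top-quartile H3K4me3 row mean %.2f vs bottom quartile %.2f (expressed block)\n",
            mean(m4[seq_len(n_expr %/% 4), ]),
            mean(m4[(n_expr - n_expr %/% 4):n_expr, ])))
cat(sprintf("Silent block: mean H3K27me3 row signal %.2f vs %.2f (K4)\n",
            mean(order_rows(mats$k27_body, fp0,
                            silent_signal = k27_row_mean)[(n_expr + 1):nrow(m4), ]),
            mean(m4[(n_expr + 1):nrow(m4), ])))
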