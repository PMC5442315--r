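#!/usr/bin/env Rscript
# 06 — Expression-side analyses.
#
# Expressed-gene flags (strict FPKM > 1 on replicate means), consistency
# classification of the external differential-significance calls
# (up / down / complex / ns), the zero-slope test of mean expression against
# time for the consistently changing classes, and a ddCt demonstration on a
# small synthetic qPCR table with an undetected (Ct-capped) calibrator.

library(samstates)

ind <- "results/data"
out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression(file.path(ind, "expression.tsv"))
sig <- read_signif_calls(file.path(ind, "significance.tsv"))
genes <- read_genes(file.path(ind, "genes.gff3"), "gff3")

fl <- expressed_genes(expr)
cat(sprintf("Expressed (FPKM > 1 at >= 1 time point): %d of %d genes (%.1f%%)\n",
            sum(fl$global), length(fl$global), 100 * mean(fl$global)))

cls <- classify_de_direction(sig, gene_universe = genes$gene_id)
write.table(cls, file.path(out, "de_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("DE direction classes:\n")
print(table(cls$de_class))

# slope of mean expression over time for each consistently changing class
tps <- colnames(fl$mean_fpkm)
for (klass in c("up", "down")) {
  ids <- cls$gene_id[cls$de_class == klass]
  if (length(ids) == 0) next
  y <- colMeans(fl$mean_fpkm[ids, , drop = FALSE])
  st <- slope_test(y, seq_along(tps) - 1)
  cat(sprintf("%-5s genes (n=%d): mean FPKM %s; slope %.2f/day, p = %.3g\n",
              klass, length(ids), paste(sprintf("%.1f", y), collapse = " -> "),
              st$slope, st$p))
}

# ddCt on a small synthetic qPCR table: a flowering-integrator-like target
# induced after the LD shift, undetected (Ct capped at 40) at 0 LD
qpcr <- rbind(
  data.frame(sample = "0LD", gene = "target", ct = NA),     # undetected
  data.frame(sample = "0LD", gene = "ref", ct = 24.1),
  data.frame(sample = "1LD", gene = "target", ct = 33.0),
  data.frame(sample = "1LD", gene = "ref", ct = 24.0),
  data.frame(sample = "2LD", gene = "target", ct = 31.2),
  data.frame(sample = "2LD", gene = "ref", ct = 24.2),
  data.frame(sample = "3LD", gene = "target", ct = 30.1),
  data.frame(sample = "3LD", gene = "ref", ct = 23.9))
dd <- ddct_relative_expression(qpcr, "target", "ref", calibrator_samples = "0LD")
write.table(dd, file.path(out, "qpcr_ddct.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nddCt relative expression (calibrator 0LD, undetected target Ct -> 40):\n")
print(dd, row.names = FALSE)
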