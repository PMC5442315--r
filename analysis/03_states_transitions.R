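#!/usr/bin/env Rscript
# 03 — Chromatin state classification and state transitions.
#
# Each gene's joint H3K4me3/H3K27me3 configuration at each time point is
# classified into H (harbouring: broad K27 containing a narrow K4 peak at the
# TSS), E (embedded: the mirror image), partial overlap (K27>K4, K4>K27),
# Non (both marks, disjoint), single-mark, or Unmarked.  Transitions between
# consecutive time points and across the whole course are tabulated, and the
# calls are compared with the generator's planted labels.

library(samstates)

ind <- "results/data"
cons_dir <- "results/consensus"
out <- "results/states"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read_genes(file.path(ind, "genes.gff3"), "gff3")
tps <- c("0LD", "1LD", "2LD", "3LD")
read_cons <- function(mark, tp) {
  b <- read_peaks(file.path(cons_dir, sprintf("%s_%s_consensus.bed", mark, tp)),
                  "bed6")
  b$signal <- b$score          # BED score column carries the consensus signal
  b
}
consensus <- lapply(c(H3K4me3 = "H3K4me3", H3K27me3 = "H3K27me3"),
                    function(mark) {
                      x <- lapply(tps, function(tp) read_cons(mark, tp))
                      names(x) <- tps
                      x
                    })
calls <- classify_states_timecourse(genes, consensus)
write_state_calls(calls, file.path(out, "state_calls.tsv"))

cat("State calls per time point:\n")
print(table(calls$timepoint, factor(calls$label, levels = state_labels())))

by_tp <- split(calls, calls$timepoint)
tm <- transition_matrix(by_tp[["0LD"]], by_tp[["3LD"]])
write.table(tm$counts, file.path(out, "transitions_0LD_3LD_counts.tsv"),
            sep = "\t", quote = FALSE)
write.table(round(tm$row_fractions, 4),
            file.path(out, "transitions_0LD_3LD_fractions.tsv"),
            sep = "\t", quote = FALSE)
cat("\n0 LD -> 3 LD transition fractions (rows: origin, n in margin):\n")
print(round(tm$row_fractions[c("Non", "H", "E", "K27_gt_K4", "K4_gt_K27"),
                             c("Non", "H", "E", "K27_gt_K4", "K4_gt_K27")], 3))
cat("Origin sizes:", paste(names(tm$n_per_row[1:5]), tm$n_per_row[1:5],
                           sep = "=", collapse = ", "), "\n")
cat(sprintf("H-state retention 0->3 LD: %.1f%% (about half resolve)\n",
            100 * tm$row_fractions["H", "H"]))
cat(sprintf("E-state retention 0->3 LD: %.1f%% (mostly stable)\n",
            100 * tm$row_fractions["E", "E"]))

# agreement with the planted ground truth
truth <- read.delim(file.path(ind, "truth_states.tsv"))
m <- merge(calls, truth, by = c("gene_id", "timepoint"),
           suffixes = c("_called", "_true"))
cat(sprintf("Agreement with planted labels: %.2f%% of %d gene x time point calls\n",
            100 * mean(m$label_called == m$label_true), nrow(m)))
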