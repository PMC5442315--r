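#!/usr/bin/env Rscript
# 01 — Generate the synthetic SAM time-course experiment.
#
# Emulates the structure of an INTACT ChIP-seq/RNA-seq experiment at the
# shoot apical meristem over a short-day -> long-day shift (time points 0-3 LD):
# ~60% expressed genes, a planted Spearman correlation of 0.31 between TSS
# H3K4me3 signal and expression, stratified chromatin-state fractions
# (~66% of expressed and ~5% of silent genes K4-marked at the TSS), two ChIP
# replicates per mark with 2% planted discordant regions, and per-step state
# transitions calibrated so that about half of the H-states resolve over the
# course.  All downstream scripts consume the files written here.

library(samstates)

out <- "results/data"
cfg <- sim_config(seed = 20170, n_genes = 2000)
sim <- simulate_dataset(cfg, out_dir = out)

cat("Simulated", nrow(sim$genes), "genes on", cfg$n_chroms, "chromosomes;",
    "time points:", paste(cfg$timepoints, collapse = ", "), "\n")
st0 <- sim$truth$states[sim$truth$states$timepoint == "0LD", ]
cat("Planted 0 LD state counts:\n")
print(table(factor(st0$label, levels = state_labels())))
cat("Planted discordant regions:", sum(sim$truth$regions$discordant),
    "of", nrow(sim$truth$regions), "\n")
cat("Files written to", out, ":",
    length(list.files(out)), "files\n")
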