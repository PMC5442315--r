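# samstates

Chromatin-state dynamics at gene transcription start sites: an analysis
pipeline for joint H3K4me3/H3K27me3 configurations across a developmental
time course, of the kind produced by tissue-specific (INTACT) ChIP-seq of the
*Arabidopsis* shoot apical meristem during photoperiod-induced flowering.
It is written for computational biologists who have per-replicate histone-mark
enrichment regions (e.g. MACS2 output with ChIP/H3 signal ratios), gene
annotations, an expression table and external differential-significance
calls, and want the downstream state analysis reproducibly in one place.

The core classification assigns each gene, per time point, one of eight
labels from the consensus regions of the two marks around its TSS:

* **H** (harbouring) — a broad H3K27me3 region contains a narrow H3K4me3
  peak whose midpoint lies within TSS ± 500 bp;
* **E** (embedded) — the mirror image: a narrow H3K27me3 peak inside a
  broader H3K4me3 domain;
* **K27>K4**, **K4>K27** — partial overlap, named for the longer-spanning mark;
* **Non** — both marks present but disjoint; plus **K4-only**, **K27-only**,
  **Unmarked**.

Around the classifier sit the supporting analyses: replicate-concordance
filtering (pairs of matched replicate regions with signal difference
`|d − mean(d)| > 2 sd(d)` are removed) and both-replicate consensus regions;
marked-gene proportions by expression stratum (expressed means FPKM > 1,
strictly) with s.e. over time points; Spearman rank correlation between TSS
H3K4me3 signal and expression with the t-approximation test
`t = ρ√((n−2)/(1−ρ²))`; state-transition matrices; TSS-anchored (−4 kb..+8 kb,
100 bp bins) and length-normalized gene-body (10+50+10 bins) metagene
matrices with exact mass conservation; DE direction-consistency classes;
OLS zero-slope tests; and ΔΔCt qPCR quantification with a 40-cycle detection
cap. A seeded synthetic-data generator plants all of these structures
(state geometry, a Gaussian-copula Spearman coupling of 0.31, 2% discordant
replicate regions, stratified state transitions) with recorded ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a simulated
2000-gene experiment (`Rscript analysis/01_simulate.R` … `06_expression.R`),
writing tables under `results/`. In code, the same path is:

```r
library(samstates)
sim <- simulate_dataset(sim_config(seed = 20170, n_genes = 2000))
res <- run_chromatin_pipeline(sim)   # consensus -> profiles -> states -> stats
res$correlation
#>   timepoint   n       rho            p
#> 1       0LD 751 0.2959032 1.214297e-16
#> 2       1LD 738 0.3014966 5.654903e-17
#> 3       2LD 746 0.2819403 4.245200e-15
#> 4       3LD 733 0.2908124 9.412324e-16
```

The recovered Spearman correlation between TSS H3K4me3 signal and FPKM among
expressed genes sits in 0.28–0.30 across the four time points (0.31 was
planted; the small deficit is rank noise from replicate averaging). Marked
fractions and the 0 LD → 3 LD transition matrix follow the planted structure
the same way — `analysis/04_association.R` prints

```
H3K4me3 on TSS, expressed genes: 62.00% +- 0.29% (s.e., n = 4 time points)
H3K4me3 on TSS, non_expressed genes: 4.39% +- 0.17% (s.e., n = 4 time points)
```

(~66% and ~5% are planted; the expressed-stratum deficit is genes whose
single K4 region the concordance filter removed), and
`analysis/03_states_transitions.R` reports

```
H-state retention 0->3 LD: 51.2% (about half resolve)
E-state retention 0->3 LD: 82.3% (mostly stable)
Agreement with planted labels: 98.04% of 8000 gene x time point calls
```

The remaining ~2% of calls differ from the planted labels exactly where a
planted-discordant region was (correctly) filtered out.

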