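---
title: "Classifying joint H3K4me3/H3K27me3 chromatin states at the TSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying joint H3K4me3/H3K27me3 chromatin states at the TSS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samstates)
```

## The problem

Tissue-specific epigenomic profiling of the *Arabidopsis* shoot apical
meristem (SAM) — the stem-cell-containing tip of the shoot — shows the
activating mark H3K4me3 and the repressive mark H3K27me3 co-occurring around
the transcription start sites (TSS) of thousands of genes during
photoperiod-induced flowering (a shift from short days to long days, sampled
daily from 0 to 3 LD).  Two joint configurations are of particular interest:

* **H-state** ("harbouring"): a broad H3K27me3 region containing a narrow
  H3K4me3 peak near the TSS (within ±500 bp);
* **E-state** ("embedded"): the mirror image — a narrow H3K27me3 peak inside
  a broader H3K4me3 domain.

Alongside these sit partial overlaps (`K27_gt_K4`, `K4_gt_K27`, named for the
mark that spans more), `Non` (both marks present but disjoint), the
single-mark labels and `Unmarked`.  `samstates` implements the complete
computational path from per-replicate mark enrichment regions to state calls,
state-transition matrices across the time course, metagene signal matrices
and mark–expression association statistics — together with a synthetic-data
generator that plants all of these structures with recorded ground truth, so
that every step can be recovery-tested at desk scale.

Read mapping, peak calling (the pipeline consumes enrichment regions with
ChIP/H3 signal ratios), differential testing engines and GO enrichment are
out of scope; externally computed differential-significance calls are an
input contract.

## Coordinate conventions

All internal coordinates are 0-based half-open (BED convention); GFF3 input
is shifted by one on read and restored on write.  The TSS of a gene is its
body's 5′ end: `start` on the plus strand and `end − 1` on the minus strand.
The TSS window is the symmetric interval `[tss − h, tss + h + 1)` with
`h = 500` bp by default, clipped at position zero.

## Consensus regions with replicate concordance filtering

Per mark and time point, two biological replicates are reconciled in two
steps:

1. **Concordance filter.**  After merging overlapping regions within each
   replicate, regions are paired across replicates by *mutual maximal
   overlap* (ties: larger overlap, then smaller partner start).  For each
   matched pair the signal difference `d = signal1 − signal2` is computed;
   pairs with `|d − mean(d)| > 2 sd(d)` are removed.  Centred differences
   make the rule robust to a global replicate-depth offset; a raw `|d|` mode
   is available (`centred = FALSE`), as is the multiplier (`sd_mult`).  The
   s.d. is estimated per mark and time point.  With fewer than three matched
   pairs the s.d. is not estimable and filtering is disabled with a warning;
   with zero dispersion the threshold is zero and nothing is removed.
   Unmatched regions pass through unfiltered.
2. **Consensus.**  A consensus region is the union span of a connected chain
   of regions overlapping (≥ 1 bp) *across* the replicates; regions present
   in only one replicate are dropped.  Summing regions from both replicates
   this way requires support in both — a plain union would make the filter
   vacuous.  The consensus signal is the length-weighted mean of all
   contributing replicate regions.

The down-sampling of read counts to the common minimum, which in a full
experiment precedes peak calling, is represented by `downsample_counts()` as
a seeded index-mask contract on abstract count vectors: the pipeline never
touches read-level data.

## The state-classification cascade

`classify_states()` applies a total decision cascade per gene, using the
consensus regions of both marks that overlap the gene's scope (body ∪ TSS
window):

1. no regions → `Unmarked`; one mark only → `K4_only` / `K27_only`;
2. both marks but no cross-mark pair overlapping ≥ `min_overlap` (default
   1 bp) → `Non`;
3. among overlapping pairs, select the one with maximal overlap whose union
   intersects the TSS window (falling back to the overall maximal-overlap
   pair);
4. K27 contains K4 (within `containment_slack`, default 0) **and** the K4
   peak's midpoint `(start + end)/2` lies within ±500 bp of the TSS → `H`;
5. the mirrored condition → `E`;
6. otherwise partial: the longer-spanning mark names the label; equal spans
   break to `K27_gt_K4`.

Two design choices deserve comment.  *Narrow vs broad* is operationalized as
containment, not absolute width: what distinguishes the states is which mark
lies within the other, and a width cutoff would add an arbitrary constant.
*At the TSS* is interpreted as the inner peak's midpoint falling in the
window rather than any overlap — "a narrow peak around the TSS" describes
the peak's location; mere window contact would let a peak centred 1 kb away
qualify through its shoulder.  Containment with an off-window inner peak
falls through to the partial rules with `inner_at_tss = FALSE`.  Rule 4 is
tested before rule 5, so identical intervals resolve to `H`; both tie-breaks
are arbitrary but deterministic and documented.  An exhaustive
grid-enumeration test (~10⁵ interval pairs) pins the cascade to an
independently coded per-base truth-table oracle.

Transition matrices count genes moving between labels from one time point to
another over the shared gene universe; rows are origin states, row fractions
are normalized per row, and row sums equal origin-category sizes exactly.

## Mark–expression association

A gene is *expressed* at a time point when its replicate-mean FPKM exceeds 1
(strictly); the global flag requires this at one time point or more.
Replicates are averaged before thresholding — the least surprising choice
where replicate handling is otherwise unspecified — and the threshold is a
parameter.  Marked-gene proportions are reported per time point within the
expressed / non-expressed strata, summarized as mean ± s.e. with
`s.e. = sd(p) / sqrt(T)` over the `T` time points.  The association between
TSS H3K4me3 signal and expression among expressed genes uses the Spearman
rank correlation with mid-ranks for ties, tested through the t
approximation: `t = rho sqrt((n − 2)/(1 − rho²))` on `n − 2` degrees of
freedom (`p = 0` at `|rho| = 1`; constant inputs are flagged undefined).

On the expression side, externally supplied per-contrast significance calls
are classified by direction consistency (`up` / `down` when all significant
directions agree, `complex` when both occur, `ns` otherwise); the mean
expression of a gene class over time is tested for zero slope by OLS with a
two-sided t test (numerically perfect fits report `p = 0`, constant series
`p = 1`); and qPCR tables are quantified by ΔΔCt with undetected targets
entered at the 40-cycle cap before differencing, which biases fold changes
conservatively.

## Metagene matrices

Two schemes produce gene × bin signal matrices from base-resolution
(bedGraph-backed) tracks, with gaps reading as zero coverage:

* **TSS-anchored**: −4 kb to +8 kb around the TSS in 100-bp bins (120
  columns by default; bin width is a parameter, as the fixed-window figure
  convention does not pin it), laid out 5′→3′ with minus-strand genes
  flipped.  Bins beyond the chromosome read 0 and are flagged in a mask
  attribute rather than set to `NA`, so downstream averaging stays defined
  without losing the information.
* **Body-normalized**: 10 flank bins of 100 bp on each side and 50
  equal-width body bins of `L/50` bases, with *fractional per-base
  weighting* at bin boundaries.  Fractional weighting (rather than
  nearest-bin assignment) makes the scheme exactly mass-conserving: the sum
  of body-bin means times the bin width equals the per-base signal sum over
  the body.

All bin edges are computed on integer-scaled coordinates (multiplying
positions by the body-bin count keeps every edge integral even when `L/50`
is fractional) and per-bin contributions are summed in sorted order; as a
consequence both matrices are *bit-for-bit* invariant under mirroring the
genome and flipping all strands, which the tests assert with `identical()`.
Row ordering follows the display convention: expressed genes first by
descending FPKM, then non-expressed genes by descending H3K27me3 row signal,
ties broken by gene id.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with every planted quantity recorded in a ground-truth object:

* **Genome and genes.**  Non-overlapping genes on both strands, one TSS per
  10-kb slot (well clear of each other relative to the region geometry, so
  consensus chains never bridge genes), bodies of 2–3 kb; chromosomes
  auto-size to the gene count unless a length is given, and an infeasible
  combination raises an error.
* **States.**  Per-gene state labels drawn from configured fractions,
  *stratified by expression*: by default ~66 % of expressed and ~5 % of
  silent genes carry H3K4me3 at the TSS, matching the strong contrast such
  experiments show.  Geometry per state keeps ≥ 100 bp of margin on every
  containment and disjointness relation, so that endpoint jitter (±25 bp per
  replicate) and cross-replicate unions cannot flip a planted relation:
  planted states are unambiguous by construction.  Inner peaks are 150–600
  bp with midpoints within ±300 bp of the TSS; outer domains 1.5–4 kb.
* **Expression.**  Expressed genes draw FPKM as `1.31 + exp(N(logmean,
  logsd))`, silent genes uniformly below 0.69; per-time-point values avoid
  the band `[0.69, 1.31)` entirely (values drifting in are pushed out), so
  the 5 % replicate noise can never flip a planted expressed flag.  Four
  replicates carry log-normal noise and Poisson counts.
* **Mark–expression coupling.**  TSS H3K4me3 signal and FPKM are coupled
  among expressed genes through a Gaussian copula on ranks with latent
  correlation `r = 2 sin(pi rho_s / 6)`, which targets a Spearman
  correlation directly (0.31 by default); monotone marginals leave ranks
  untouched, so the planted value is recovered up to sampling noise and the
  small attenuation from replicate noise.
* **Replicates and discordance.**  The two replicate signals are
  `s·m ± d/2` with a common log-normal factor `m` and a between-replicate
  difference `d` drawn from a truncated normal (bounded at ~2.27 s.d.,
  rescaled to the configured s.d.).  Discordant regions (2 % by default) add
  an offset of 8 × the noise s.d. (plus a uniform margin) to one replicate.
  With unbounded noise no offset can guarantee that a 2-s.d. filter
  separates planted discordance — the largest of ~2000 Gaussian concordant
  differences routinely crosses any threshold the inflated s.d. estimate
  allows — whereas bounded concordant noise plus an 8-s.d. offset yields a
  deterministic margin on both sides, making filter precision and recall
  exactly 1 by construction.  A signal floor of `max(0.8, 1.6 sd)` keeps all
  replicate signals positive.
* **Dynamics.**  States evolve by per-step transition probabilities, again
  stratified: expressed genes follow `transition_spec` (H retains 0.8 per
  step, so about half of the H-states resolve over the three steps, mostly
  into Non and partial states; E is mostly stable), while silent genes
  shuffle almost entirely within the K27-only/unmarked pool, keeping the
  per-time-point marked proportions near-stationary in each stratum.
  DE classes (consistently up / down / complex, at the small fractions such
  experiments report) scale expression by ×1.6 per day and emit matching
  significance calls.

A fixed seed makes the full output byte-identical, file emission included.

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show: there is no read-level sampling noise, no
peak-caller boundary uncertainty beyond the uniform jitter, no mappability
or copy-number artifacts, no correlated signal structure along chromosomes,
no cell-type mixture within a sample (precisely the ambiguity that makes
tissue-level "bivalency" interpretation hard), and only two ChIP replicates.
Recovery of a planted parameter demonstrates that the pipeline's estimators
are consistent under the stated noise model, not that real SAM data meet
that model.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-dispersion concordance
(nothing removed), < 3 matched pairs (filter disabled, warning), empty
strata (flagged `NA` proportion with a warning), constant correlation inputs
(flagged `NA`), genes shorter than the body-bin count (fractional scheme
applies; flagged), chromosomes absent from a consensus set (empty profile,
not an error).  The test suite runs the generator at 120–5000 genes; the
Spearman-recovery property uses ten seeds at 5000 genes, the classifier
equivalence an exhaustive ~10⁵-case grid, and the consensus equivalence 200
random replicate sets on a 100-kb toy chromosome — sizes chosen so the whole
suite completes in a few minutes on one core while leaving binomial bounds
tight enough to detect calibration errors.

## Limitations

The pipeline supports exactly two replicates per mark (as the emulated
design has); the concordance filter's pairing is a stated convention
(mutual maximal overlap), not a published algorithm; and the TSS is taken as
the gene body's 5′ end, ignoring transcript isoforms.  The marked-fraction
and correlation statistics condition on per-time-point expressed status; a
global-flag variant is available through `expressed_genes()`.
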