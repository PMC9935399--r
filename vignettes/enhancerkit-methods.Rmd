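---
title: "enhancerkit: models, thresholds and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{enhancerkit: models, thresholds and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerkit)
```

## The analysis model

enhancerkit analyses aligned sequencing tags — the 5′ ends of reads from
ChIP-seq, CUT&RUN, PRO-seq or ATAC-seq — through a fixed chain:
deduplicated tag directories, windowed quantification, Poisson peak
calling, rule-based enhancer classification, fold-change differential
calls, and interval-overlap statistics. Coordinates are 0-based half-open
(BED) everywhere internally; any 1-based dialect must be converted at the
reader boundary, which removes a whole class of off-by-one errors at the
cost of one conversion per reader.

### Tag directories and normalization

A directory stores the multiset of (chromosome, position, strand) 5′ ends
after a clonal cap: at most `per_position_cap` tags are kept per position
(2 for ChIP/CUT&RUN, where PCR duplicates dominate repeated positions; 3
for PRO-seq, where genuine polymerase pile-ups recur at pause sites). The
cap is applied per strand by default because nascent-transcription data are
strand-specific; a strand-blind cap is available. Counts are reported in
tags-per-10-million using the *post-cap* total (the behaviour of the
standard tag-directory tools); the choice matters only through a constant
factor per sample. Two invariants pin the semantics down and are enforced
by tests: a genome tiling of windows sums exactly to 10⁷, and uniformly
doubling every read below the cap changes no normalized count
(depth-invariance).

Window counts over `[center − h, center + h]` are inclusive on both ends —
the symmetric reading of a "± h bp" window — while profile-matrix bins are
half-open so they tile without double counting. The two conventions differ
by at most the two boundary positions and are documented where they meet
(row sums of a profile matrix versus the corresponding window count).

### Peak calling

The caller slides `window` (200 bp) windows with `step` (50 bp) and tests
each count *k* against λ = max(genome-wide rate, local rate over a 10-kb
span) × window: significant iff the exact Poisson upper tail P(X ≥ k | λ)
is ≤ `pvalue_max` (10⁻⁵) *and* k is ≥ 4-fold over the genome-wide
expectation. Taking the max of local and global background is the standard
defence against locally elevated signal (it can only make the test more
conservative), and the exact tail keeps the null calibration property
provable: across seeded homogeneous genomes the per-window discovery rate
is bounded by `pvalue_max`, with 1.2× slack in the test for discreteness
and merging. Significant windows closer than `merge_gap` merge; the summit
is the leftmost position of maximal tag count (a deterministic tie-break);
the score is the merged region's normalized count.

Replicate reproducibility uses a summit-distance concordance filter: a peak
survives iff its summit lies within `max_center_dist` of a summit in enough
other replicate sets. The full irreproducible-discovery-rate model is a
different statistical machine (a copula mixture) and is deliberately not
reproduced; peak location, not the caller, is what the downstream
classification consumes, and external peak BEDs are accepted everywhere
peaks are.

### Enhancer classification

All six enhancer groups share one gate — region center ≥ 3,000 bp from any
annotated TSS and ≥ 16 H3K27Ac tags-per-10M in the ±1,000 bp window — and
then branch on nascent transcription or Pol II:

* hormone scheme: FC = (nascent treated + 1)/(nascent control + 1);
  receptor-bound regions with treated ≥ 10 and FC ≥ 1.5 are the robustly
  induced class; regions with ≥ 10 in *both* conditions and FC in the open
  band (0.67, 1.5) are "other active", split by receptor binding.
* proinflammatory: Pol II and p65 both ≥ 16 under TNFα, no FC criterion.
* androgen: Pol II and AR ≥ 10 and Pol II FC ≥ 1.5 under DHT.
* neuronal: Pol II ≥ 10 and Pol II FC ≥ 1.5 under KCl depolarization.

Inclusive/exclusive boundaries are honored exactly as printed (≥ 16, ≥ 10,
≥ 1.5 inclusive; the band is open) and are exercised at the boundary by the
test grid. Three genuinely open points were decided here and are
configurable: the FC pseudocount is 1 normalized tag (sources are silent; 1
is the smallest value that tames empty-window ratios without visibly moving
well-expressed ones); the band's tag floor applies to *both* conditions
("treated with either ethanol or E2" read as both-condition expression);
and "receptor-marked" means a receptor anchor-peak summit within the region
flank, since candidate regions are receptor/accessibility-anchored in the
first place. Feature enrichment (e.g. TOP1cc) uses the same geometry: a
region is flagged iff a feature-peak summit lies within ±1,000 bp of its
center — the flank of the putative-enhancer definition, a gap-filling
choice since no overlap rule is published for those subsets.

### Differential layer

eRNA windows use the strict rule (FC > 1.5 plus a tags floor on the
induced side); gene bodies — the first 13 kb excluding the 500 bp
promoter-proximal region, sense strand — use the inclusive rule (FC ≥ 1.5)
plus a read-density floor in tags-per-10M per kb. The negative-binomial
dispersion model of edgeR is out of scope: the enhancer definitions consume
only fold changes and floors. For users who want p-values, an exact test is
provided: conditioning two Poisson totals on their sum gives a binomial
with p = library-size share, tested two-sided by doubling the smaller tail
and BH-adjusted across the gene set. Swapping conditions provably maps
up ↔ down (antisymmetry), which the suite checks on random fixtures.

### Overlap statistics

Interval overlap is half-open (abutting intervals do not overlap) and each
query interval counts once, whatever it touches — the BEDTools convention.
Venn partitions count per set, because an interval of one set can overlap
several of another; per-set counts need not agree and both are reported.
Random backgrounds draw chromosomes proportional to length and starts
uniformly, with lengths fixed or resampled from a matched set; draws are
bit-reproducible under a seed and never touch the caller's RNG stream.
Per-region tag correlations use Pearson on log2(x + 1) counts with the
t-distributed p-value, one-tailed optionally.

## The synthetic world

The generator states one desk-scale world and the tests measure it; its
parameters were fixed before any acceptance run and are not tuned to
outcomes.

* **Geometry.** One 10-Mb chromosome; 40 non-overlapping genes with
  log-uniform lengths in [5, 50] kb; 200 enhancers (50 hormone-induced, 50
  receptor-bound band, 50 unbound band, 50 acutely induced) on intergenic
  grid points ≥ 3 kb from TSSs and clear of gene bodies, plus 30 decoys
  that each violate exactly one gate: planted 1.5 kb from a TSS, planted
  with zero H3K27Ac mass, or planted with zero treated nascent mass.
* **Tags.** Each locus contributes Poisson(mass) tags at Normal(center,
  150 bp) positions — a pileup shape adequate to exercise every counting
  rule without a fragment-length model. Nascent tags split strands by the
  sign of the offset (divergent eRNA geometry, a modeling choice); gene
  bodies transcribe uniformly on the sense strand; promoters carry Pol II
  mass in both conditions.
* **Signal-dominated libraries.** Uniform background is 10⁻⁷ tags/bp.
  This is deliberate: normalizing to 10⁷ tags on a 10-Mb genome inflates
  any uniform background ~300-fold relative to a 3-Gb genome, so the
  published absolute floors (16 and 10 tags-per-10M in 2-kb windows) are
  only meaningful when libraries are dominated by planted signal, as
  capped CUT&RUN libraries are. Background exists to exercise the
  background code paths, not to model genomic noise.
* **Depth balancing.** Two-condition assays receive uniform filler tags in
  the lighter condition so expected library sizes match. Without it,
  per-directory normalization multiplies every fold change by the library
  ratio (~0.78 under the defaults), pushing planted band fold changes in
  (0.75, 1.33) outside the open classification band — a composition
  artifact real experiments avoid by sequencing to matched depth.
* **Effect sizes.** Hormone-induced loci: nascent 600 treated / 200
  control (FC 3); band loci: 400 control with FC uniform in (0.75, 1.33);
  induced loci: Pol II 150/50 (FC 3), TF 100; H3K27Ac 200; TOP1cc mass 100
  planted with probability 1 at acutely induced loci and 0.05 elsewhere,
  making planted TOP1cc mass and eRNA induction positively coupled across
  loci by construction. At these masses Poisson noise puts roughly 1–2% of
  band loci across the open band's edges, so ~99% label recovery is the
  expected behaviour, comfortably above the 95% acceptance bar — and a
  recovery failure signals a code defect, not bad luck.

What a green recovery test does *not* establish: robustness to mappability
artifacts, copy-number variation, GC bias, fragment-length effects,
antibody efficiency differences or replicate-level dispersion — none of
which the generator emulates. It establishes that every counting window,
normalization factor, threshold comparison and flag is wired exactly as
specified.

## Numerical and degenerate-input choices

* Poisson tails via `ppois(k − 1, λ, lower.tail = FALSE)` (exact, no
  normal approximation); the binomial two-sided p doubles the smaller tail
  and caps at 1.
* Region centers are `floor((start + end)/2)`; TSS distance is
  center-to-TSS and strand-agnostic.
* Summit ties resolve leftmost; profile rows at chromosome edges are
  flagged and excluded from column means rather than zero-padded.
* Zero tags after capping, empty TSS sets, genes shorter than the promoter
  exclusion, unknown chromosomes, and zero-variance correlation inputs are
  errors, not silent results.
* Seeds: every stochastic stream derives from the master seed via a string
  hash (`child_seed`), kept below 2³¹, so adding one directory never
  perturbs another, and seeded helpers restore the caller's RNG state.

## Known limitations

The differential layer is not a replacement for replicate-aware dispersion
modeling; the concordance filter is not IDR; random backgrounds are not
GC- or mappability-matched; the pipeline starts from aligned tags, not
reads. These boundaries are inherited from the component scope and are
stated in the function documentation where they apply.
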