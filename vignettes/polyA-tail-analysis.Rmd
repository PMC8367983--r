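---
title: "Methods: poly(A) tail profiling from nanopore DRS"
author: "polyAprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) tail profiling from nanopore DRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyAprofiler)
```

# Scope and data model

Nanopore direct RNA sequencing (DRS) reads native RNA molecules end to end;
the poly(A) tail length of each read is estimated from the raw signal (in
practice by the Nanopolish `polya` segmentation) and reported with a QC tag.
This package starts from that per-read table — it does not touch raw
signal, basecalling or alignment. A read record carries a read id, the
transcript the read was assigned to, a tail-length estimate in adenosines
(A) and a QC tag; only `PASS` estimates are admissible, because the
remaining tags mark failed segmentations whose length column is
meaningless. The pipeline is organized around three tabular stages — reads,
per-transcript summaries, normalized summaries — plus a
`PolyATailExperiment` (a `SummarizedExperiment`) binding per-library
summaries into transcript-by-sample matrices.

Reads on the reverse strand are assumed removed upstream at alignment time;
ingest keys on the transcript assignment and carries the position column
through untouched.

# Summarization and pooling

Per transcript and library we report the read count and the arithmetic
mean, median and geometric mean of tail lengths. Replicates of one
strain/condition/fraction are *summed at the read level*: summaries are
recomputed on the concatenated reads, so counts add and tail statistics are
depth-weighted. The alternative — averaging per-replicate summaries —
weights a 10-read replicate equally with a 1,000-read one; read-level
pooling matches how replicate libraries are actually combined in DRS
practice. `poolReplicates()` refuses to mix the poly(A)+ and total
fractions, which measure different populations.

Numerical conventions: even-length medians use the mean of the two middle
values; empirical quantiles (including the 99.5% quantile used as a gene
set's tail-length "upper limit") use the linear-interpolation convention
(R type 7); the geometric mean floors each tail at 0.01 A so zero-length
tails do not annihilate it — 0.01 is also the placeholder scale below, so a
transcript of all-zero tails reports geometric mean 0.01 rather than 0.

# Detection filter, normalization and expression bins

Transcripts detected by ≤5 reads carry too little information for stable
tail statistics; they are not dropped but masked: count and all tail
statistics are set to the sentinel 0.01 and the row is flagged. Keeping the
rows lets cross-library comparisons see the full transcript universe, while
every downstream computation (cutoff estimation, deltas, correlations,
oligo calls) excludes flagged rows as sentinels, not measurements.

Counts are normalized to library size. The library total is the sum of all
mapped PASS reads *before* the placeholder substitution, so normalization
is independent of the detection filter. For display, library fractions are
multiplied by 1,600,000 — approximately the largest yeast DRS library, so
displayed values are comparable across libraries of different depth. The
log2 abundance used for binning is taken on the library fraction itself
(pre-display-scale), so the bin boundaries −10, −12, −14 correspond to
fractions 2^−10, 2^−12, 2^−14 of the library. When poly(A)+ recovery
differs between strains (e.g. polyadenylation mutants), a per-library
qPCR-derived coefficient multiplies the normalized abundance; its
derivation from Ct values is out of scope and it enters as one scalar per
library in the sample sheet.

The four expression bins are: high (x ≥ −10), moderate-high
(−12 < x < −10), moderate-minimal (−14 < x ≤ −12), minimal (x ≤ −14).
The printed definitions of the top two bins both contain −10; we assign
boundary values to the higher bin, and flag that choice here rather than in
run output. −12 and −14 belong to the lower bin of each pair exactly as
printed.

# The oligoadenylated-fraction caller

Oligo-(dT) selection loses molecules with very short tails. A transcript
with a substantial oligoadenylated subpopulation therefore looks *more
abundant* in a total-RNA library than in the matched poly(A)+ library, and
its mean tail is *lower* there. The caller requires both signals:

1. total/poly(A)+ normalized-abundance ratio > 1.2 (fold criterion), and
2. mean-tail change (total − poly(A)+) ≤ −cutoff for the transcript's
   expression bin (tail criterion).

The per-bin cutoffs are the noise floor of mean-tail estimation: for every
transcript detected in ≥2 replicate libraries, the SD of its per-replicate
mean tails; a bin's cutoff aggregates these SDs over its transcripts.
Mean-of-SDs is the default aggregate (`computeBinSDCutoffs()` also offers
the median); the packaged default cutoffs (1.727579, 2.080906, 2.763902,
4.157491 A from high to minimal expression) are the values established for
yeast DRS work of this kind and can be supplied directly via
`OligoCutoffs()` when no replicate data are at hand. Cutoffs grow toward
low expression because fewer reads make the mean-tail estimate noisier.
The bin used for the lookup is the poly(A)+ (reference-fraction) bin.
Because the published cutoffs are printed as negative numbers, note the
convention here: cutoffs are stored as positive magnitudes and applied to
the signed delta as `delta ≤ −cutoff`, which is the same rule.

# Substrate classification

Between a nuclease-deficient strain and its matched control (declared in
the sample sheet — any library may serve as reference, so double-mutant vs
single-mutant contrasts work the same way), `computeDeltas()` reports the
change in mean tail and the log2 fold change of normalized abundance for
transcripts detected in both. Replicate-to-replicate mean-tail estimates
oscillate within roughly ±10 A, so `flagStrongTargets()` calls a transcript
a strong target when its tail is elongated by ≥10 A (boundary inclusive) —
deliberately more stringent than the oligo-caller cutoffs.
`classifySubstrates()` then partitions annotated mRNAs by which machinery
elongates their tails: exosome only, cytoplasmic deadenylases (PAN2/3
and/or CCR4-NOT) only, both, unaffected, or undetected. Only mRNAs enter
this rule; noncoding classes are reported separately via tail summaries and
`ncRNALoadRatio()` (class counts over protein-coding counts, including
annotated loci with zero reads).

# Group statistics

The statistical battery is implemented from first principles with mid-rank
tie handling throughout:

- Kruskal–Wallis: `H = [12/(N(N+1)) Σ nᵢ R̄ᵢ² − 3(N+1)]`, divided by the
  tie correction `1 − Σ(t³−t)/(N³−N)`; p from χ²(k−1). The chi-square
  approximation is used at every sample size, matching standard R behavior;
  exact small-sample tables are not implemented. All-tied input returns
  H = 0, p = 1 rather than an error.
- Ranked epsilon squared: `E² = H(n+1)/(n²−1)`.
- Dunn pairwise z with the tie term
  `σ² = N(N+1)/12 − Σ(t³−t)/(12(N−1))`, two-sided normal p-values.
- Holm step-down over all pairs of one family (one omnibus test); raw Dunn
  p-values are not truncated before adjustment. Reports mark pairs
  significant at Holm-adjusted p ≤ 0.001.

Placeholder (0.01) values are excluded before any statistic: they are
sentinel codes, not measurements. Pearson correlations are computed only on
the intersection of transcripts detected in both tables.

# What the simulator emulates — and what it does not

`simulateExperiment()` draws per-transcript log2 expression from a normal
(default spread 2, i.e. read counts spanning roughly four log2 decades) and
allocates a library multinomially. Steady-state per-transcript mean tails
interpolate linearly in log2 expression from 50 A at the lowest expression
to 30 A at the highest — the anticorrelation between expression and tail
length is a robust observation but has no established functional form, so
the simplest monotone model is used; with the default expression
distribution the read-weighted global mean lands near 40 A, the
steady-state value in rich-media yeast. De novo (export-blocked) strains
draw tails from a normal with mean 50 A truncated to [0, 200 A] — the
observed mean and hard ceiling for newly synthesized tails. Strain effects
are additive tail shifts and abundance fold factors on declared target
sets. Each read adds Gaussian estimation noise (default SD 5 A, floored at
0); no noise model for signal-level tail estimation is established, so
additive Gaussian is an explicit assumption. A configurable read fraction
(default 10%) receives a random non-PASS tag so QC filtering is always
exercised.

`simulateTotalVsPolyA()` adds the oligoadenylated subpopulation: flagged
transcripts (expected fraction 10%, with flagging probability growing with
expression rank, mirroring the enrichment of short-tailed molecules among
highly expressed transcripts) emit a per-read mixture component with tails
uniform on [0, 9 A] at weight 0.4. The poly(A)+ library keeps each read
with probability `plogis((tail − 10) · steepness)`: no quantitative
capture-efficiency curve for oligo-(dT)25 selection exists, so the logistic
form with midpoint 10 A (the practical lower limit of reliable DRS tail
estimation) is a config-recorded assumption, with infinite steepness giving
a hard threshold. `simulateSpikeins()` emits reads at designed lengths
10–90 A in steps of 10, the standard calibration ladder.

Determinism: every sample file gets its own RNG stream seeded by a hash of
(master seed, sample id), so identical configs are byte-reproducible and
adding a sample never perturbs the others.

Not emulated: signal-level squiggles, sequence content, isoform or 3′-UTR
structure, positional biases, or any kinetic model of deadenylation.
Passing recovery tests on simulated data therefore demonstrates that the
*analysis* is correct under the stated statistical structure — not that
real libraries satisfy that structure.

# Problem sizes and verification

The test suite verifies each statistic against brute-force oracles
(counting-based ranks, literal step-down Holm, grid-integrated truncated
normals) and against independent implementations where available
(`stats::kruskal.test`, `stats::p.adjust`). Recovery experiments use 3,000
transcripts at ≥50 reads per transcript (planted +12 A targets; recall
≥ 0.9 at false-flag rate ≤ 0.05) and 1,000 transcripts at ≥200 reads for
the oligo caller (10% planted, weight 0.4; recall and precision ≥ 0.8);
the Kruskal–Wallis type-I error is measured over 2,000 null simulations of
3 × 30 samples. These sizes make the whole suite run in well under a
minute while leaving comfortable statistical margins.

# Known limitations

- The oligo caller compares one total against one poly(A)+ library;
  replicate-aware calling (e.g. a formal test on the fold change) is not
  implemented, matching the two-criterion rule it reproduces.
- The qPCR coefficient is taken as given; errors in it propagate linearly
  into normalized abundances and the fold criterion.
- Bin cutoff estimation needs every bin populated by ≥1 transcript
  detected in ≥2 replicates; degenerate (zero-variance) input is an error
  by design, signalling that the replicates cannot support a noise floor.
- Printed dataset-scale results that depend on the original sequencing
  libraries (e.g. specific substrate counts) are out of reach by
  construction; only the arithmetic downstream of such counts is
  reproduced.
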