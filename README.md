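# polyAprofiler

Downstream analysis of poly(A) tail lengths measured by nanopore direct RNA
sequencing (DRS), for transcriptome researchers studying polyadenylation and
deadenylation — e.g. in budding yeast, where steady-state mRNA tails
average ~40 adenosines (A), newly made tails ~50 A with an upper limit near
200 A, and tail length is shaped by the nuclear exosome (Rrp6/Dis3 with the
TRAMP4/5 adaptors) and the cytoplasmic deadenylases PAN2/3 and CCR4-NOT.

The package starts from per-read tail-length estimates (the Nanopolish
`polya` table dialect: one row per read with a transcript assignment, a tail
estimate in adenosines and a QC tag) and implements the full downstream
pipeline:

- **Ingest and QC** — only reads tagged `PASS` carry usable estimates;
  replicate libraries are summed at the read level.
- **Per-transcript summaries** — read count, mean, median and geometric
  mean tail per transcript and library.
- **Normalization and binning** — transcripts detected by ≤5 reads are
  masked to the sentinel 0.01 (count and tail alike); counts are normalized
  to library size (optionally scaled by a per-library qPCR-derived
  coefficient) and displayed as reads per 1,600,000 mapped reads;
  transcripts are binned by log2 library fraction at −10 / −12 / −14 into
  four expression classes.
- **Oligoadenylated-fraction calling** — comparing total-RNA and poly(A)+
  libraries, a transcript is called oligoadenylated when it is >1.2-fold
  upregulated in total RNA *and* its mean tail drops by more than a
  per-expression-bin noise cutoff (the replicate SD of mean-tail estimates
  in that bin; defaults 1.73 / 2.08 / 2.76 / 4.16 A from high to minimal
  expression).
- **Substrate classification** — transcripts whose mean tail is elongated
  by ≥10 A in a nuclease-deficient strain versus its matched control are
  strong targets; mRNAs are partitioned into exosome-only,
  cytoplasmic-only, both, unaffected and undetected categories.
- **Group statistics** — tie-corrected Kruskal–Wallis
  (`H = [12/(N(N+1)) Σ nᵢR̄ᵢ² − 3(N+1)] / [1 − Σ(t³−t)/(N³−N)]`), ranked
  epsilon squared (`E² = H(n+1)/(n²−1)`), two-sided Dunn pairwise z tests
  with the tie term, Holm step-down adjustment, and Pearson correlation on
  the intersection of detected transcripts.
- **Simulator** — a seeded read-level generator (multinomial expression,
  expression-anticorrelated tail means, truncated-normal de novo tails,
  an oligoadenylated subpopulation, logistic oligo-(dT) capture bias,
  additive estimation noise, spike-ins of designed lengths 10–90 A) so the
  entire pipeline is testable without sequencing data.

Annotation handling follows the custom-annotation recipe for yeast DRS:
noncoding features shorter than 50 bp and LTR / transposon / tRNA /
replication-origin features are discarded, and overlapping same-strand
noncoding features are merged (ids concatenated with `|`).

## Worked example

Simulate a two-strain experiment (a wild type and a deadenylase mutant with
40 transcripts planted at +12 A) and run the pipeline:

```r
library(polyAprofiler)

cfg <- SimConfig(nTranscripts = 500, libSize = 100000, seed = 42,
                 strains = c("WT", "pan2d"),
                 effectMap = list(pan2d = list(
                     targets = sprintf("TX%05d", 1:40), tailShift = 12)))
simulateExperiment(cfg, dir = "demo")

out <- runPipeline(readRunConfig(overrides = list(
    sample_sheet = "demo/sample_sheet.tsv",
    annotation   = "demo/annotation.bed",
    outdir       = "demo_out", reference_strain = "WT")))

wt <- out$summaries[["WT.steady_state.polyA_plus"]]
sum(!wt$placeholder_flag)                      # 479 detected transcripts
mean(wt$mean_tail[!wt$placeholder_flag])       # 40.72 A global mean tail

strong <- out$strongTargets[["pan2d.steady_state.polyA_plus"]]
length(strong)                                 # 32 strong targets called
out$stats$H                                    # 6.6  (Kruskal-Wallis)
out$stats$p_value                              # 0.0101
```

The run prints per-stage progress and writes per-group summary TSVs, a
transcript-by-sample matrix, delta/strong-target tables, group statistics
and `manifest.json` to `demo_out/`. Of the 32 strong-target calls, 30 are
planted targets — at ~80 reads per transcript the ≥10 A rule recovers a
+12 A shift with high precision; deeper libraries sharpen recall (see the
vignette). A normalized summary row looks like:

```
  transcript_id n_reads mean_tail norm_count      bin
1       TX00001      76     53.12    1351.14 mod_high
```

`norm_count` is reads per 1,600,000 mapped reads; `bin` is the expression
class used for per-bin decisions.

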