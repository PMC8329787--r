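---
title: "Detecting antisense transcription from stranded RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting antisense transcription from stranded RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antisenseq)
```

## Scope and model

`antisenseq` identifies and quantifies antisense transcription units from
aligned, strand-specific RNA-seq reads. It was designed for the classic
yeast setting — a wild-type strain against a mutant (for example a
*SET2*-deletion) in which cryptic antisense transcripts are derepressed —
but nothing in the code is yeast-specific: any compact genome with a
stranded gene annotation and single-end stranded libraries fits.

The analysis chain is: strand-aware read classification against the
annotation, reference-free assembly of antisense and intergenic reads into
transcription units, per-sample counting, an exact conditional
negative-binomial test between conditions, association of units with
opposite-strand genes, cross-tabulation of sense regulation against
antisense upregulation, and set-level comparisons (Venn arithmetic,
hypergeometric over-representation).

## Strand conventions

The package's frame of reference is the **transcript strand**. Under the
dUTP single-end protocol (`stranded_reverse`, the default), the sequenced
read aligns opposite to its transcript, so the transcript strand is the
flip of the alignment strand (SAM FLAG bit 0x10). `stranded_forward` keeps
the alignment strand; `unstranded` libraries cannot support sense/antisense
calls and classification refuses to run on them rather than guessing.

All internal coordinates are held in `GRanges` (1-based, closed intervals),
the canonical Bioconductor representation; the 0-based half-open BED
convention and the 1-based GFF convention are handled entirely by
`rtracklayer` at the I/O boundary. Interval abutment is never overlap
regardless of convention, and unit identifiers `chrom_start_end` are the
1-based inclusive coordinates, matching how such units are named in the
literature (e.g. `chrIII_268287_269650`).

## Read filtering and classification

Records that are unmapped, secondary (0x100) or supplementary (0x800), or
below a MAPQ floor (default 10) are excluded before classification. The
floor is a deliberate policy, not a data-derived value: single-end 75-bp
reads multimap readily in repetitive regions, and unique-alignment
filtering is the conservative default; it is a plain argument for
libraries where multimappers matter.

A gene "qualifies" for a read when it overlaps at least `min_overlap_frac`
(default 0.5) of the read length. The fraction prevents boundary reads —
a read dangling 10 bp into a gene — from flipping category. With no
qualifying gene the read is *intergenic*; all qualifying genes on the
transcript strand makes it *sense*; all on the opposite strand,
*antisense*; genes on both strands make it *ambiguous*, and ambiguous reads
are excluded from assembly and counting to avoid double-attributing signal
between overlapping genes.

## Assembly of transcription units

Antisense and intergenic reads are pooled (the mutant-condition samples
only, since the units of interest are the ones present in the mutant) and
merged per (chromosome, transcript strand): reads whose gap is at most
`max_gap` join a cluster, and clusters survive at `min_reads` support and
`min_length` span. Defaults — 50 bp gap, 3 reads, 100 bp — suppress
singleton noise while keeping genuinely expressed units; they are plain
arguments surfaced in the run log because no published parameter set
exists for this step (the original analyses delegated it to reference-free
assemblers without printing parameters). Assembly is idempotent: merging
the models themselves reproduces the same intervals. Units are labelled by
origin (*antisense* if any supporting read is antisense, else
*intergenic*). Spliced antisense units are out of scope: merging is
contiguous, which is appropriate for yeast where antisense units are
unspliced; intron-aware assembly would need a different engine.

## Counting and the exact test

A read increments a feature when strand matches and the overlap fraction
holds; library sizes are the per-sample totals of mapped, filtered,
non-ambiguous reads. CPM is counts / library size × 10⁶, with no
composition normalisation (trimmed-mean scaling is deliberately absent —
the screen below operates on fold changes between library-normalised sums,
and a composition hook can be supplied by passing explicit `lib` values).

The test conditions on the pooled total of a feature across both
conditions. Writing $s_a, s_b$ for the condition sums and $L_a, L_b$ for
the summed library sizes, under the null the split of $t = s_a + s_b$
follows

* Binomial$(t,\; L_b/(L_a+L_b))$ when the dispersion $\varphi = 0$
  (the Poisson limit), and
* the conditional law of two negative-binomial sums with sizes
  $n_g/\varphi$ and means proportional to $L_g$ otherwise, evaluated by
  direct enumeration over the split (a windowed enumeration, 40+ standard
  deviations wide, for totals above $10^5$ — the truncated mass is far
  below double precision).

The two-sided p-value doubles the smaller tail and caps at 1. The fold
change is $\log_2$ of the ratio of pseudocounted (0.5),
library-size-normalised sums; the pseudocount affects only the fold
change, never the p-value, and keeps zero-count features finite.

Dispersion is estimated per feature by method of moments on
library-scaled counts, $(\widehat{\mathrm{var}} - \hat\mu)/\hat\mu^2$
pooled across conditions with df weights and floored at 0. With three
replicates this per-feature estimate is noisy, so the default used in the
test is the **moderated** estimate: per-feature values shrunk towards the
common median with 10 prior degrees of freedom — the usual empirical-Bayes
compromise. A single common value is available (`dispersion = "common"`),
as is any fixed number; with no replication anywhere the estimator falls
back to a prior of 0.1 with a warning.

Feature screening uses the raw p-value at twofold / P < 0.05 — the
selection rule this analysis tradition prints for antisense screens — with
BH q-values always reported alongside; over-representation, by contrast,
selects at adjusted P < 0.05. Both cut-offs are arguments.

## Sets, cross-tabulation and enrichment

Counts over genes are always deduplicated: a gene covered by two antisense
units is one ATE gene, one member of a projected set, one cross-tab entry.
The cross-tab assigns each paired gene an antisense status (*up* if any
paired unit is up) and its sense DE status, and its detail table lists the
(gene, unit) rows with both fold changes and p-values, mirroring the
published table layout. Enrichment takes a flat term→gene mapping and an
explicit universe — no ontology graph, no propagation — because the
published analyses do not state their universe and the choice materially
changes p-values; making it a required input keeps that decision visible.

## The simulator: what it emulates, and what it does not

`simulation_config()` defaults describe the emulated study: 3 chromosomes
of 40 kb; 60 non-overlapping genes of 500–1500 bp with 200–600 bp gaps and
random strands; 3 wild-type vs 3 mutant replicates; 75-bp single-end
dUTP reads; mean sense depth 200 reads/gene; a wild-type antisense
baseline of 20 reads/gene (10% of sense — cryptic antisense is present but
low before derepression); 10% of genes spiked 4-fold in the mutant, the
spike interval being the central 80% of the gene body so every true unit
is associable with its gene; and negative-binomial dispersion 0.1, a
typical value for replicated RNA-seq in yeast. Reads are emitted
pre-aligned (CIGAR `75M`, MAPQ 60) as coordinate-sorted SAM: the aligner
is out of scope, so the simulator produces exactly what the pipeline
consumes, and every random draw derives from the single seed —
regeneration is byte-identical.

The simulator does **not** model sequencing error, splicing, PCR
duplicates, coverage bias along transcripts, or overlapping gene
annotations. Passing tests therefore demonstrate the correctness of the
classification/assembly/testing machinery and its statistical calibration
under clean alignments, not robustness to alignment artefacts; with real
data those enter upstream of this package.

Scale of the checks shipped with the package: property tests use up to 500
reads against brute-force per-base oracles, the null calibration uses
2000 simulated features, and end-to-end runs use the 60-gene default —
sizes chosen so the full suite exercises every contract at desk scale.

## Numerical and degenerate-input choices

* Both condition sums zero → p = 1, log2FC = 0.
* Fully tied Wilcoxon input (zero rank variance) → p = 1; the exact
  enumeration is used when both sizes ≤ 10 and there are no ties.
* Zero-variance samples in the correlation matrix → `NA` entries with a
  warning, never silent zeros.
* Empty reference set in an overlap → coverage `NA`, flagged.
* Unknown chromosomes in alignments are skipped with one warning, not an
  error, so chromosome-subset SAM files flow through.
* Overlap queries break ties deterministically (start, then gene id), and
  the pipeline is fully deterministic: identical inputs and parameters
  give byte-identical output tables.

## Interface design

The package is library-first: `run_pipeline()` and
`simulate_experiment()` are the orchestration surface and write the full
fixed-filename result bundle (models as BED/GTF, classification summary,
count matrices, DE tables, pair table, cross-tab, gene sets, overlap
report, enrichment, run log with every parameter). Each stage is equally
usable on its own — classification, assembly, counting, testing,
association, sets — which is how the test-suite exercises them. A shell
wrapper would add nothing over `Rscript -e` around these two calls, so
none is shipped.

## Known limitations

* The assembly gap/support/length defaults are heuristics; very lowly
  expressed units below 3 supporting reads are invisible by design.
* The exact test assumes a shared dispersion within a feature and
  library-size-proportional means; no GLM, no batch covariates.
* The raw-p twofold screen controls per-test error, not FDR; the reported
  q-values are the tool for FDR-controlled selection.
* With few replicates and a modest number of truly changed features, the
  false-discovery proportion of the screen has a small denominator and is
  correspondingly variable between simulation seeds.
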