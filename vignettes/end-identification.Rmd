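---
title: "Identifying transcript ends from 5'/3' end-tag data: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying transcript ends from 5'/3' end-tag data: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rcatseq identifies transcription start sites (TSSs) and transcription end
sites (TESs) of RNA isoforms from short-read libraries that tag transcript
ends: 5' reads carry a template-switching-oligo (TSO) tag ending in `GGG`,
and 3' reads carry poly-A evidence plus an RT-primer tag holding a UMI and
a cell barcode. Raw end positions from such libraries are contaminated by
three well-known artifact classes — oligo-dT mispriming at genomic A-rich
stretches (false TESs), spurious internal template switching at G-rich
sites (false TSSs), and RNA degradation (scattered internal 5' ends) — so
the pipeline couples peak calling with a supervised classifier that filters
false ends before isoforms are quantified. This vignette documents the
models, the tunable parameters and the design decisions; the README shows a
worked example.

## From reads to single-base ends

Read selection is exact-match by default: a 5' read must contain the full
TSO tag (`GTGGTATCAACGCAGAGTACATGGG`), of which the constant part
(`GTGGTATCAACGCAGAGTACAT`) is trimmed; the `GGG` added during template
switching is kept and treated as soft clip, so the called 5' end is the
first genome-matching base. A 3' read pair is kept when R1 carries the
RT-primer constant (followed by an 8-nt UMI and a 16-nt cell barcode) and
R2 ends in a poly-A run of at least 10 bases, which is then removed. Tag
search tolerance (0 mismatches) and an optional single interruption in the
poly-A run are configurable; the defaults are the strict readings because
the underlying chemistry gives no reason to expect errors concentrated in
the constant segments. All coordinates are 0-based half-open; a single-base
end is the interval `[pos, pos + 1)`, which keeps every exported file plain
BED.

Alignments are reduced to one strand-aware terminal base each: the 5'-most
aligned base in transcript orientation for TSS reads, the last templated
base before the poly-A for TES reads. Multimapped records and records
overlapping a user-supplied exclusion BED (typically rRNA) are dropped, and
the per-category drop counts are returned, so input records are always
accounted for.

## Peak calling

`call_peaks()` reimplements distance-based tag clustering. Per-position
signal is tags-per-million (TPM) within each sample; a position seeds a
cluster when its signal reaches `threshold` (default 3 TPM) in at least
`nr_pass_threshold` samples (default 1); adjacent seeds on one chromosome
and strand merge while their gap is at most `max_dist` (default 20 bp,
inclusive); singletons are kept by default. Three conventions the
literature leaves open are fixed as follows:

* the cluster span covers seed positions only — sub-threshold interior
  positions contribute to `total_signal` and may carry the dominant
  position, but never extend `start`/`end`;
* the dominant position is the argmax of pooled (summed across samples)
  signal, with ties going to the 5'-most position in transcript
  orientation, so that a tie never biases toward one strand;
* the threshold is evaluated on per-sample TPM before pooling, matching
  multi-sample semantics of `nr_pass_threshold`.

A brute-force `O(n^2)` clusterer in the test suite checks span membership,
seed counts and dominant positions exactly on randomized tracks. Peak
calling can be run per cell, per cell type, or on pooled data — pooling is
a one-line `pool_samples()` call — because end-tag studies use all three
modes.

## Feature engineering

Each peak is described by three named feature groups, all normalized to
`[0, 1]`:

* **distribution** — total and dominant signal, width, number of covered
  positions, the dominant position's share of peak signal, the relative
  position of the peak within its assigned gene (0 = annotated 5' end,
  1 = 3' end, 0.5 when unassigned), `log10(total + 1)`, and one total
  occurrence count per motif;
* **motif** — positional indicators: for TSS peaks, the core-promoter
  motifs BREu (`SSRCGCC`), TATA-box (`TATAWAWR`) and BREd (`RTDKKKK`)
  scanned with up to 2 mismatches at each of the 50 upstream offsets
  (3 × 50 = 150 columns); for TES peaks, the 13 polyadenylation-signal
  hexamers (`AATAAA`, `ATTAAA` and 11 non-canonical variants) matched
  exactly at each of 50 offsets (13 × 50 = 650 columns). Offset *j* means
  "the motif starts exactly *j* nt upstream of the dominant position".
  Because the PAS sits 10–30 nt upstream of cleavage, the TES window is
  the 50 nt upstream of the called end by default; a centred ±25 window
  is available (`orientation = "centered"`) for data where the cleavage
  call is less precise;
* **artifact** — for TES peaks, the adenine fraction and longest A-run in
  the 20 nt downstream of cleavage plus a flag for A-fraction ≥ 0.6
  (internal-priming evidence); for TSS peaks, the G fraction and a `GGG`
  flag in the 3 nt at the start plus the upstream C fraction
  (template-switch evidence).

Mismatch tolerance applies to the degenerate promoter motifs only; PAS
hexamers are short and A-rich enough that allowing mismatches would match
essentially every A-rich window. IUPAC matching is authored in
`scan_motif()` and cross-checked in the tests against both a brute-force
Hamming scan and Biostrings' degenerate matcher. Windows truncated at
contig edges are padded with `N`, which never satisfies a pattern position,
and base fractions use only the available bases.

Normalization maps heavy-tailed signal columns through the empirical CDF of
the assembly data (rank/n), bounded columns through min–max, and leaves
binary indicators untouched. The fitted parameters are stored in the
feature matrix so that prediction-time matrices can be built on the
training scale (`assemble_features(..., normalization = ...)`); applying
stored normalization to its own training data reproduces the matrix
exactly, which the tests assert bit-for-bit.

## The end classifier

Peaks are labeled `TRUE` when their dominant position lies within 50 bp of
a same-strand reference end (reference catalogs of TSSs and
polyadenylation sites, or the generator's planted truth). The 50-bp window
is a package choice — reference catalogs themselves are only
bin-accurate — and is exposed prominently because labels, not features,
are usually the weakest link in this design.

Training follows a fixed protocol: a stratified 70/30 train/test split,
five-fold cross-validation on the training split, and a two-round grid
search (a coarse grid, then a fine grid laid around the best coarse point)
per algorithm, for ridge logistic regression (`glmnet`), random forest
(`randomForest`), RBF-kernel SVM (`e1071`) and k-nearest neighbours
(`class`). Grid contents are package defaults (log-spaced `lambda`, `C`,
`gamma`; `mtry`/`nodesize`; odd `k`), since reasonable grids are not a
scientific claim. Everything is seeded: one seed determines the split, the
folds and each stochastic fit, and identical seed plus data gives
identical hyperparameters and predictions. Class imbalance is handled by
stratification only.

Feature-group importance is measured by ablation: retrain without one
group and report the accuracy drop. The drop is computed on the
cross-validated accuracy (fold-averaged over the training split) rather
than on the 30% held-out set, because with a few hundred peaks the
held-out accuracy moves in steps of one sample and single-sample flips
would dominate the ranking; held-out accuracies are reported alongside.
`filter_peaks()` keeps peaks predicted authentic and attaches the TRUE
probability; `cross_dataset_transfer()` scores a trained model on another
dataset without refitting, with the feature-column contract enforced.

## Isoform quantification and switching

Filtered peaks are assigned to genes when the dominant position lies
between 2 kb upstream of the gene's annotated TSSs and 2 kb downstream of
its annotated TESs on the gene's strand; overlapping-flank ties go to the
gene with the nearest annotated end. Peaks within 50 bp of an annotated
end of their gene are `known_end`; assigned but distant peaks are
`novel_end_known_gene`; unassigned peaks are `novel_gene` candidates.
Expression is reads (or distinct barcode–UMI molecules) per peak,
normalized to reads per million within each cell population. Per gene and
population the major isoform pairs the argmax-RPM TSS with the argmax-RPM
TES; genes with several of each end cannot be paired one-to-one beyond the
major–major pairing, and no attempt is made to do so.

Two populations are compared per co-expressed gene: a TSS switch is a gene
whose major TES agrees within 100 bp while the major TSS differs beyond
it, and symmetrically for TES switches. The 100-bp common-end tolerance
reflects that two independently called peaks for the same cleavage site
rarely coincide to the base. "Co-expressed" is made concrete as a
minimal-evidence floor: each compared major end must carry at least 5
reads in both populations, because a major call supported by one or two
reads flips by sampling noise and carries no isoform information. Switch
direction (proximal/distal) is relative to the centre of the first
population's major isoform. Along a differentiation trajectory the cells
of each of 6 stages are pooled and the usage ratio of the two alternative
ends is reported as `log2((count_A + 1) / (count_B + 1))`; the pseudocount
of 1 read keeps empty stages defined and symmetric. Differential isoform
expression between populations uses a two-sided Wilcoxon rank-sum test on
per-replicate RPMs with Benjamini–Hochberg correction — a deliberately
assumption-light replacement for negative-binomial model fitting, which is
outside this package's scope.

## The synthetic-data generator

`sim_config()` defines the study conditions under which the package tests
itself: a 500-kb single-contig genome (GC 0.45) with 100 genes in regular
slots, 1–3 isoforms per gene (probabilities 0.4/0.4/0.2) whose alternative
ends are separated by ≥ 200 bp, two populations of 200 cells with 200
reads per cell split between end types, and a six-stage trajectory.
Motif context is planted as concrete instances: a TATA-box 25–35 nt
upstream of 70% of true TSSs, and `AATAAA` 15–30 nt upstream of 90% of
true TESs — the PAS is nearly universal at real cleavage sites while
core-promoter motifs mark only a subset of promoters. Artifacts mirror
their biological mechanisms: each gene body carries one internal-priming
site (a planted 8–14-base A-run, embedded in A-rich upstream context that
frequently mimics non-canonical PAS hexamers, exactly as genomic
mispriming sites do) and one internal template-switch site (a planted
`GGG`); 15% of 3' reads arise at priming sites, 8% of 5' reads at switch
sites, and 5% of 5' reads at uniform positions inside the gene body
(degradation). Gene abundances are log-normal with σ = 1.5 (about three
decades, typical of single-cell libraries), positional jitter of σ = 3 bp
applies to every read, and 10% of molecules gain a PCR duplicate sharing
their barcode and UMI. For switching genes, usage of the two alternative
isoforms interpolates linearly from 90/10 at stage 1 to 10/90 at stage 6,
so population 1 (stages 1–3) and population 2 (stages 4–6) have opposite
majors. A reference-end emitter drops a configurable fraction of true ends
(default completeness 0.7 in the pipeline checks), so novelty calling can
be validated against ends that are novel by construction.

The generator emulates end-read *tracks*, not sequencing itself: there are
no base-call errors, no alignment ambiguity, no splicing, no chance motif
background at real-genome scale, and annotation is perfectly consistent
with the planted truth. Passing the pipeline checks therefore demonstrates
that the algorithms are implemented correctly and that the feature design
separates the planted artifact mechanisms — not that any particular
accuracy will be attained on real libraries, where labels come from
incomplete catalogs and artifact context is more varied.

## Numerical conventions and scale

Thresholds are inclusive (`signal >= threshold` seeds; A-fraction `>= 0.6`
flags; gap `<= max_dist` merges). Dominant ties go 5'-most in transcript
orientation. Quantile normalization of a value equal to a training value
returns that value's training rank fraction; min–max of a constant column
returns 0; prediction-time min–max is clamped to `[0, 1]`. Empty inputs
return typed empty tibbles rather than errors; unsorted tracks, unknown
contigs, duplicate peak ids and single-class training data are hard
errors.

The shipped test suite runs the full pipeline at the default scale above
(roughly 90,000 reads, ~1,700 peaks), trains random forests for both end
types, and exercises the clustering and motif oracles on 1,000 random
tracks and 10,000 random 60-mers; the whole suite completes in a few
minutes on one CPU. `scripts/acceptance.R` recomputes the same quantities
from scratch for any seed.

## Known limitations

Exon-level splicing is invisible to end-tag data, so two isoforms sharing
both ends are indistinguishable here. TSS–TES pairing beyond the
major–major pair is not attempted. The labeling tolerance (50 bp), the
common-end tolerance (100 bp) and the co-expression floor (5 reads) are
package choices that real-data users should revisit against their
reference catalogs and sequencing depth. KNN and SVM carry their training
data in the fitted object, which is the usual trade-off of those learners,
and model persistence is R's native serialization plus the embedded
feature contract.
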