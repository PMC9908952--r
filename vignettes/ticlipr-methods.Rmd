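---
title: "Models and methods behind ticlipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ticlipr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticlipr)
```

## The experimental design the package models

Temporal iCLIP follows an RNA-binding protein (RBP) across a
transcription time course: cells are held in a DRB block (CDK9
inhibition pauses RNA polymerase II promoter-proximally), the block is
released, and iCLIP libraries are prepared at serial timepoints (0-60
minutes) plus an untreated steady-state (DMSO) sample. Because cDNA
synthesis truncates at the cross-linked peptide, the protein-RNA contact
is one nucleotide 5' of read1's first base; because the sequencing
adapter is ligated to the RNA 3' end, read2's first base reports the RNA
fragment's 3' terminus ("3'CLIP"). Both coordinates, plus whole-read
coverage, are extracted per library and form the basis of every
downstream computation.

All coordinates inside the package are 0-based half-open and every
windowed computation is strand-aware: offsets are reported in transcript
orientation with the anchor at 0. This makes strand mirroring an exact
symmetry, which the test suite exploits as an invariant.

## Library processing

**Demultiplexing** assigns each pair to the unique sample whose in-line
barcode is within a configurable Hamming distance (default 0) of the
barcode carried in the read name (`name#BARCODE#UMI`); table barcodes
within twice that distance of each other are rejected as a
configuration error.

**Deduplication** keeps the first pair per (UMI, chromosome, read1 5'
coordinate, strand) key — the standard UMI + first-mapping-coordinate
rule — and is idempotent.

**Normalization** uses rRNA recovery rather than reads-per-million,
because libraries from different timepoints do not contain equal RNA
input: the count of deduplicated pairs whose read1 overlaps an rRNA
annotation (sense only) is divided by an arbitrary constant of 30,000 to
give the library's rRNA factor, and track weights are divided by that
factor. Division (not multiplication) is the direction that equalizes
recovery across timepoints; the reciprocal convention is available via
`scale_track(..., direction = "multiply")` for compatibility with
coverage tools whose `-scale` argument multiplies.

## Spatiotemporal profiles and wave velocity

Transcription units (TUs) are stratified by length in 10-kb increments
up to 300 kb plus a final group for everything longer, segmented into
1-kb bins from the TSS, and the per-group mean bin signal is divided by
the group maximum. After DRB release a wave of new transcription (and
hence of RBP binding on nascent RNA) invades each TU; the wave front at
a timepoint is defined here as the largest bin whose moving-average
smoothed (3 bins), group-normalized signal reaches a threshold `tau`
(default 0.1), and the elongation velocity is the ordinary least squares
slope of front position against minutes over the release timepoints
(t = 0 is still paused and the steady-state library has no front, so
both are excluded). The front/OLS estimator is this package's own
definition: published figures typically overlay a reference slope
(~3.5 kb/min for RNAPII) rather than define an estimator. Parameter
recovery on simulations at 1.5-5 kb/min is within a few percent under
the default `tau` and smoothing (see `tests/testthat/test-acceptance.R`).

## Mature-transcript profiles and clustering

Cross-link positions are projected onto mature coordinates (exons
concatenated 5'→3'), binned into 100 equal bins and normalized to the TU
total, keeping only TUs with mature length strictly greater than 200 nt
and strictly more than 20 reads. Position `p` maps to bin
`floor(p * 100 / length)`, with the final position clamped into bin 100.
K-means (Euclidean, raw profiles, 10 restarts, fixed seed) is run
independently per biological replicate with k = 3; clusters are matched
across replicates by greedy maximal centroid cosine similarity and a TU
is retained only if it lands in the matched cluster in every replicate.
The largest intersected group is treated as unstructured background and
suppressed from the report (`report_background = TRUE` overrides);
reported groups are ordered by cap-proximal (first 25 bins) centroid
mass, so `group1` is the most 5'-enriched shape. These two conventions —
background-as-largest and 5'-mass ordering — are this package's
choices where the underlying procedure is usually described only as
"k = 3 then intersect".

## Lariat branchpoint signatures

Limited RNase digestion of an excised intron lariat yields a three-way
junction with two ligatable 3' ends; reverse transcription then stops at
the 2'-5' branch linkage. cDNAs primed inside the circle truncate *on*
the branchpoint (BP) and read through the linkage, acquiring a
mismatched first base; cDNAs primed on the linear tail truncate one
nucleotide downstream. `truncation_signature()` therefore aggregates
**unshifted read1 5' ends** (not the 1-nt-shifted cross-link sites)
around BP, intron-5'-end, or exon-3'-end anchors and calls offsets
exceeding the window mean + 3 SD; `mismatch_profile()` reports the
first-base mismatch rate per offset, with empty offsets reported as
missing rather than zero. The ratio of offset-0 to offset-(+1)
truncation mass estimates the circular-to-linear origin ratio.
BP-centred heatmaps are stratified by the BP to 3' splice site distance
(18-38 nt); with 3'CLIP data the intron-terminal signal sits at offset
`distance - 1` (the last intron nucleotide), producing the diagonal
across strata.

## snoRNA 3'-extension intermediates

Intronic snoRNAs are released by splicing and matured by exonucleolytic
trimming of the 3' flank. Windows are anchored at the snoRNA's annotated
last nucleotide (offset 0; +1 is the first flank base) or at the host
intron's 3' splice site, stratified by CD- vs H/ACA-box class and
normalized per contributing snoRNA (per-class normalization is a package
choice; raw sums satisfy CD + H/ACA = unstratified exactly).
`extension_peaks()` calls local maxima above the search-range mean +
2 SD — laxer than the 3 SD used for truncation peaks because extension
peaks sit on an elevated flank baseline — and reports `max_extension` as
the largest offset above 10% of the range maximum, which captures the
variable-length (but bounded) CD-box intermediates that produce no sharp
peak.

## The synthetic-data generator

Every stage above is exercised against `make_annotation()` +
`simulate_timecourse()`, which emit alignments with full ground truth.
The generator's defaults are the study conditions:

* **Wave kinetics**: nascent transcripts extend
  `min(TU length, 300 + v * 1000 * t)` nt from the TSS; the 300-nt pause
  offset represents cap-proximal sequence transcribed during the DRB
  block (t = 0 signal is 5'-restricted but no published number exists,
  so 300 nt was fixed once as realistic). Velocity defaults to
  3.5 kb/min.
* **Anchoring models**: cap-anchored (exponential from the TSS, scale
  50 nt), EJC-like (Gaussian centred 25 nt upstream of exon 3' ends,
  sd 8), intron-3'/lariat/snoRNA (uniform over the intron −100..−20 nt
  region, reflecting the ~19-nt mapping shadow of sub-20-nt fragments),
  and uniform-nascent.
* **Splicing**: each fully transcribed intron undergoes two sequential
  exponential steps (branching, exon ligation) with a shared
  half-life (default 3 min; no published rate constants exist, so this
  is a surfaced placeholder). The post-first-step population carries a
  free 3'OH at the upstream exon end, so 3'CLIP signal at first-exon
  ends rises and then falls across the time course.
* **Lariats**: a configurable fraction of excised introns persist as
  lariats; circular-origin reads start exactly on the BP with a planted
  terminal mismatch, linear-origin reads 1 nt downstream, both ending at
  the intron's last nucleotide.
* **snoRNAs**: H/ACA precursors carry discrete 3' extensions of 9 or
  25 nt; CD-box extensions are uniform on 1..25 nt. Among reads from
  excised snoRNA-host introns, 75% are such pre-snoRNA intermediates
  (`sno_read_share`); the share is not a published number and was set so
  that intermediates dominate the snoRNA 3' flank, as they visibly do in
  real class-stratified 3'CLIP profiles — at substantially lower shares
  the termini of unrelated intron-3' reads blur the extension-limit
  call.
* **Annotation geometry**: TU lengths log-uniform between 1 kb and
  400 kb (so all 10-kb strata and the >300 kb group are populated), exons
  100-400 nt, introns at least 400 nt (room for the −100..−20 binding
  region, a BP 18-38 nt upstream of the 3' splice site, and optionally a
  70-140 nt snoRNA ending 75-110 nt before the 3' splice site — far
  enough that the 35-nt extension window clears the pileup of generic
  intron-terminal fragment ends).
* **Library artefacts**: in-line barcodes and UMIs in the read name,
  PCR duplicates that copy a previous read's UMI and coordinates
  exactly, and rRNA background reads. UMIs of *independent* fragments
  are rejection-sampled to be unique on the deduplication key, so the
  simulated duplicate count is exactly recoverable — a property real
  UMI schemes only approximate.

What the generator deliberately does **not** model: base-level sequence
(reads carry no sequence, only planted mismatch records), RNA secondary
structure, multimapping, soft-clipping, transcription termination
heterogeneity, and the 1-2 nt upstream shifts of truncation sites seen
in real data. Passing tests therefore demonstrate the *computational*
correctness of each stage under the stated model, not robustness to
every artefact of real libraries.

## Numerical and degenerate-input conventions

* Cross-link sites that would fall before position 0 are dropped and
  counted, never clamped (a clamp would fabricate a position-0 peak).
* bedGraph output merges adjacent equal-weight positions, writes up to
  6 significant digits, and round-trips exactly through per-position
  weights; empty tracks produce empty (legal) files.
* Median insert size uses |TLEN|, excludes zeros, and averages the two
  middle values for even counts. The co-migration calculator uses a
  ceiling, not rounding, for the kDa→nt conversion (65/20 × 70 = 227.5
  reports as 228 nt).
* Top-N snoRNA ranking breaks ties lexicographically by id, and k-means
  seeds are fixed per replicate, so all outputs are deterministic for a
  fixed seed; the pipeline writes a manifest of per-stage counts and
  output digests to make this checkable.
* Exclusion of a TU from mature profiling (length ≤ 200 nt or ≤ 20
  reads) is a normal outcome with a reason code, not an error.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on simulated
data at desk scale: 10-30 TUs and a few thousand reads per library for
unit-level checks; 200 TUs, seven timepoints and 20,000 reads per
library for velocity recovery; 240 planted profiles for clustering; and
12,000-15,000 reads for the lariat and snoRNA signature recoveries
(comfortably above the ~500 reads per snoRNA class needed for exact
extension-peak recovery). Dataset-level figures from real experiments
(tens of thousands of TUs, hundreds of millions of reads) are outside
the scope of these checks.
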