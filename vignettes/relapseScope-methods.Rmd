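---
title: "Methods: models, parameters and design choices in relapseScope"
author: "relapseScope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in relapseScope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`relapseScope` analyses paired diagnosis (Dx) and relapse (Re) AML
samples: plate-based single-cell UMI counts on one axis, exome-level
variant allele depths on the other. This vignette documents the models
behind each stage, the tunable parameters and their defaults, the
numerical choices that matter, and what the bundled synthetic data
generator does and does not emulate — hence what a passing test suite
does and does not establish about real data.

## Quality control and normalization

A cell is discarded when any of four gates fires: detected genes < 500,
total UMIs > 12,000, mitochondrial fraction > 30% of non-spike-in UMIs,
or ERCC spike-in fraction > 20% of all reads. These are the canonical
gates for SORT-seq/CEL-Seq2 experiments on sorted blasts. Two conventions
are deliberate and configurable:

* **Boundary semantics.** All four rules are strict inequalities, read
  literally from their usual statement ("genes detected < 500", "UMI
  count > 12,000", ...): a cell sitting exactly on a boundary passes.
  The fixture tests pin this behaviour.
* **Denominators.** ERCC reads are not transcriptome, so they are
  excluded from the detected-gene count, the UMI total and the
  mitochondrial denominator; the ERCC fraction itself uses the full
  library (ERCC included) as denominator, since it measures how much of
  the sequencing went into spike-ins. Whether mitochondrial and ERCC
  fractions should share a denominator is genuinely underdetermined in
  the field; both gates are exposed as parameters of `qc_thresholds()`.

Normalization is the standard library-size transform
`log1p(count / cell_total * 1e4)` (natural log, scale factor 10,000 —
the Seurat 3 default, which this analysis style presumes). ERCC features
are dropped from the output and from cell totals; mitochondrial genes are
kept, as they are ordinary transcripts for expression purposes once QC
has bounded their fraction.

## Variant-allele-frequency dynamics

For each somatic variant the package forms the 2×2 table of ALT/REF
read counts at Dx and Re and computes a two-sided Fisher's exact test
under the probability-ordering definition: the p-value sums the
hypergeometric probabilities of all tables with the observed margins
whose probability does not exceed the observed table's (with the
customary `1e-7` relative slack against floating-point ties). This is
the definition mainstream implementations use, and the test suite checks
it against exhaustive enumeration over every table with margins ≤ 30 and
against `stats::fisher.test`.

Decisions worth making explicit:

* **Detection vs testing.** A variant is *detected* at a timepoint when
  ALT ≥ 5 reads and VAF ≥ 0.05 (both inclusive — "at least"). Variants
  detected at neither timepoint carry no information and are excluded
  from testing, but kept in the output with `tested = FALSE` rather than
  dropped.
* **Multiplicity.** BH correction is applied across all tested variants
  of one Dx/Re pair — the patient is the reporting unit. Both the raw p
  and the adjusted q are reported, because the selection rule for a
  *reportable* shift (max(VAF) ≥ 0.2 and p < 0.05) is stated on the raw
  p scale while figure-level selection typically uses the corrected one;
  users can filter on either.
* **Zero depth** yields a missing VAF (`NA`), never 0 — a variant with
  no coverage is unobserved, not absent.
* ITD-length dynamics (two internal-tandem-duplication alleles shifting
  between timepoints) are handled as ordinary 2×2 allele-count tests
  between the two allele forms; per-base ITD reconstruction is out of
  scope.

## Inferred CNV from expression tiles

The iCNV stage asks whether large chromosomal segments changed dosage
between the timepoints, using expression alone, and then corroborates
candidate segments with allele fractions at heterozygous SNPs.

**Tiling.** The genome is partitioned into fixed 3 Mb tiles from
position 0 of each chromosome (the last tile of a chromosome may be
shorter). Each gene belongs to exactly one tile, assigned by its midpoint
`floor((start + end)/2)` in 0-based half-open coordinates — single
assignment avoids double-counting genes that straddle a boundary. Tiles
with fewer than 5 assigned genes are excluded with a warning.

**Signal.** Per cell, tile counts are pooled and converted to library
fractions with a pseudocount of 1; the log2 fraction is centered on the
reference-cell mean per tile (log-space, so reference cells average zero
by construction) and then re-centered per cell on the *mode* of the
cell's own tile signal, estimated with a half-sample mode. This "cell
normalization" makes the dominant — presumed diploid — tile population
define zero for every cell. Two numerical points drove this design:

* Averaging per-gene log-normalized values across a tile shrinks a true
  1.5× gain far below log2(1.5) at UMI depths of a few thousand per
  cell, because most genes sit at 0–3 counts where `log1p` is strongly
  concave. Pooling counts at tile level before taking logs keeps the
  signal on the copy-ratio scale, which is what makes the reported
  magnitudes interpretable (gain of one copy ≈ +0.585, loss of one copy
  ≈ −1).
* A median would be dragged by a large aberrant region (a 30 Mb event on
  a small genome can be tens of percent of all tiles); the half-sample
  mode tracks the densest (diploid) population instead. The method still
  assumes aberrant regions cover a *minority* of the tiled genome.

Signals are smoothed with a centered moving average over 3 adjacent
tiles within each chromosome (windows shrink at chromosome ends, never
wrap) and clipped to ±1.5 log2 units for display and marking.

**Segment calling.** A tile is marked in a cell when its smoothed signal
exceeds +0.15 (gain) or falls below −0.15 (loss); maximal runs of ≥ 2
tiles marked in ≥ 50% of target cells become candidates. Candidate edges
are then trimmed on the unsmoothed cross-cell mean, which undoes the
one-tile bleed the moving average introduces. The per-cell segment-level
statistic is a log2 odds of the segment's pooled counts against the
*diploid backdrop* (all used tiles outside any candidate region),
centered on the reference mean of the same quantity. The backdrop
construction matters: the event itself inflates or deflates the carrying
cell's library, and other events would contaminate a naive complement;
scoring against the candidate-free backdrop cancels both effects, so a
clonal `copy_ratio` event sits at `log2(copy_ratio)` without further
correction. A cell is *affected* when its pooled segment signal clears
the threshold; the reported `mean_signal` and its spread are taken over
affected cells. The ±0.15 thresholds with the 3-tile window recover
clonal 1.5×/0.5× events of ≥ 2 tiles at a few hundred cells per
timepoint while keeping diploid runs far below the 50% cell-fraction
gate; events shorter than one tile (3 Mb) are below the method's design
resolution.

**BAF confirmation.** Within a segment, reads at heterozygous SNPs are
pooled (cell-summed) per SNP within the target and reference groups.
Because phase is unknown, the per-SNP ALT fraction f is folded to
|f − 0.5|: ≈ 0 for diploid cells, ≈ 1/6 for a clonal single-copy gain
(f ∈ {1/3, 2/3}), ≈ 0.5 for loss *or copy-neutral LOH* (f ∈ {0, 1}).
A segment is confirmed when the target group's mean folded deviation
exceeds the reference's by > 0.1, requiring ≥ 3 SNPs with ≥ 20 pooled
reads per group; with fewer, the verdict is "unconfirmable" rather than
"not confirmed". Copy-neutral LOH is the case that motivates keeping the
allele-fraction channel separate from expression: it changes allele
fractions to 0/1 while leaving dosage — and therefore the expression
tiles and the differential-expression landscape — untouched.

## Signature scoring

**LSC17.** The 17-gene leukemic-stem-cell score is the weighted sum
`Σ wᵢ xᵢ` of log-normalized expression, with the published Ng et
al. (2016) weights shipped as an editable two-column TSV
(`inst/extdata/lsc17_weights.tsv`). Signature genes absent from a matrix
are scored as zero expression with a loud warning rather than
renormalizing the weights — renormalization would silently change the
score's scale between datasets. Scores are computed per cell and
compared between clusters as distributions (pairwise Student's t by
default, Welch optional), because that is how per-cluster stemness is
typically displayed and starred (\* p < 0.05, \*\* p < 0.01,
\*\*\* p < 0.001).

**Cell cycle.** Tirosh-style module scores: genes are ranked into 24
bins of dataset-average expression; for each phase set (the bundled S
and G2/M lists of Tirosh et al. 2016), the score is the mean expression
of the set minus the mean of 100 control genes per set gene drawn,
seeded, from the same bins. Phase assignment: G1 if both scores are
negative, otherwise the larger score wins (ties go to S). The control
draw is the only stochastic element and is reproducible under the seed
argument.

## Marker and differential-expression detection

Per contrast (one-vs-rest across cluster labels, or two named groups),
genes are pre-filtered on detection (expressed in ≥ 10% of cells of
either group) and effect size (|log2 FC| ≥ 0.25 on de-logged normalized
means with a fixed pseudocount of 1), then tested with the Wilcoxon
rank-sum test — exact enumeration for tiny untied samples (n ≤ 12),
normal approximation with tie and continuity corrections otherwise — and
BH-corrected over the tested genes of that contrast only. "Top N"
selection is deterministic: rank by q, ties by |log2 FC|, then gene id.
Cluster labels are an input; graph clustering itself is routine tooling
and deliberately outside the tested core.

## The synthetic Dx/Re generator

The generator exists so that every stage has planted ground truth. It
emulates one patient's Dx/Re pair as a plate-based UMI experiment:
gene-wise negative-binomial counts (shared dispersion φ = 0.3, variance
μ + φμ²) whose per-cell expected depth is log-normal around 4,000
non-spike-in UMIs over a 2,000-gene panel — the scale at which a few
thousand transcripts and ~1,500 genes are detected per cell, as in
plate-based AML profiling. It plants, with defaults chosen once as a
realistic study condition:

* three expression clusters with 25 exclusive markers each, up-shifted
  4× (log2 FC 2);
* a clonal relapse-specific 30 Mb gain (1.5×), loss (0.5×) and
  copy-neutral LOH on separate 120 Mb chromosomes;
* an LSC-like subpopulation (20% of cells) with a 2× up-shift of the
  positively weighted LSC17 genes;
* planted phases (60% G1 / 20% S / 20% G2M) with a 4× up-shift of the
  corresponding Tirosh set;
* 10% deliberately failing cells, cycling through the four QC failure
  modes;
* a five-variant WES panel (Poisson depth 100, binomial ALT counts)
  spanning shrinking, lost, stable and gained clones; and ~200
  heterozygous SNPs with per-cell Poisson read counts and allele
  fractions set by the local planted copy state (phase random per SNP,
  which is why downstream statistics fold around 0.5).

Design choices a reader should know:

* **Stratified planting.** Cluster, LSC and phase labels are assigned
  with identical proportions in the Dx and Re cells (stratified rather
  than i.i.d.). With i.i.d. labels, the multinomial imbalance of 4×
  up-shifted gene sets between timepoints adds several hundredths of a
  log2 unit of composition noise to any timepoint-pure contrast — a
  confound of the *planted design*, not of the methods under test.
  Stratification keeps the planted structures orthogonal, so the CNV
  contrast measures the CNV. Real Dx/Re pairs are of course not balanced
  this way; tests of cluster-composition *shifts* are not what this
  generator is for.
* **Constructed QC envelope.** Clean cells are clipped inside the
  canonical gates (depth ≤ 80% of the UMI cap, fractions ≤ 80% of their
  caps) and failing cells are pushed well past exactly one gate, so the
  planted clean set and the filter's survivor set coincide exactly —
  the generator is constructed to satisfy the filter, making QC
  exactness testable.
* **CNV model.** A copy ratio multiplies expected expression of the
  genes inside the event in carrier cells, without renormalizing the
  cell's total — a gain genuinely increases the library, as dosage
  does. No dosage compensation is modelled. Copy-neutral LOH changes
  allele fractions only.
* **Quasi-uniform placement.** Gene and SNP positions are stratified
  along each chromosome so every 3 Mb tile receives close to the average
  gene count; signature genes and planted markers draw their relative
  abundance from the upper half of the log-normal abundance
  distribution, reflecting that curated signature/marker genes are
  reliably expressed transcripts.

What the generator does **not** emulate: gene-length and GC biases,
ambient RNA, doublets, batch and plate effects, fusion transcripts,
cluster-composition change between timepoints, or subclonal phylogenies
beyond a single cell fraction per event. Passing tests therefore
demonstrate the statistical machinery recovers planted structure under a
realistic noise model — not robustness to every artefact of real
plate-based data.

Determinism: all three simulators run under a fixed seed
(`withr::with_seed`, sub-seeds offset per simulator), so an identical
configuration reproduces byte-identical artifacts after serialization.

## Problem sizes in the test suite

The shipped tests run the full default study condition (600 cells ×
2,105 features) for QC exactness, phase recovery and the end-to-end
pipeline; five replicate cohorts of 200 + 200 cells for CNV calibration
(mean segment signal vs log2 1.5, with the replicate SEM capturing both
cell-sampling and transcriptome-composition noise); 200 replicate
cohorts of 50 + 50 cells for LSC17 power; 2,000 null and 500
effect variants for the Fisher test's error and power; and exhaustive
enumeration over all 2×2 tables with margins ≤ 30 for its correctness.
These sizes were chosen so each check is statistically meaningful at
desk scale.

## Known limitations

* iCNV resolution is bounded by the tile (3 Mb) and the two-tile
  minimum run; focal events are invisible by design.
* The segment magnitude is calibrated for *clonal* events; at low
  carrier fractions the per-cell affected set, not the magnitude, is the
  informative output.
* Median/mode cell normalization fails if aberrant tiles approach half
  the genome.
* BH is applied per contrast/patient; a cross-patient analysis would
  need its own multiplicity strategy.
* The exact tiling normalization used by any particular published iCNV
  variant differs in details (clipping, smoothing, reference choice);
  all knobs are exposed (`tile_size`, `clip`, `smooth`, thresholds,
  reference group) rather than hard-coded.
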