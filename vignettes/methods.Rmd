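---
title: "Multimodal cfDNA whole-methylome cancer detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal cfDNA whole-methylome cancer detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(themis)
```

## The problem

Plasma cell-free DNA (cfDNA) from cancer patients carries tumor-derived
molecules whose epigenetic and genetic properties differ from those shed by
normal hematopoietic turnover: the tumor genome is globally hypomethylated,
tumor fragments are shorter, arm-level copy-number alterations distort
regional fragment density, and nucleosome-driven cleavage preferences shift
the spectrum of fragment 5' end motifs. Enzymatic whole-methylome sequencing
(WMS) reads all of these signals from the same library, because the mild
TET2/APOBEC3A conversion chemistry, unlike bisulfite, preserves native
fragmentation. This package implements a complete analysis stack over such
data at the fragment level: four feature modalities, an ensemble detection
classifier (the THEMIS score), a cancer-signal-origin (CSO) classifier, and
a synthetic cohort generator that makes the whole pipeline testable without
access to restricted clinical data.

## Fragment model and quality gates

The unit of analysis is the sequenced molecule, not the read: proper read
pairs are merged into fragments whose span is the outer (template) distance,
whose mapping quality is the minimum over mates (pairs below 20 are
dropped), and whose methylation evidence is tallied from per-read call
strings in the standard bisulfite-aligner dialect (`Z`/`z` for
methylated/unmethylated CpG, `X/x`, `H/h`, `U/u` for non-CpG contexts).
Where mates overlap, the overlapping prefix of the rightmost mate is
clipped so each base is observed once, mirroring the effect of upstream
overlap clipping. The reader supports match/mismatch CIGARs with optional
soft clips; indel-containing records are counted and skipped, which is the
appropriate behaviour for the simulated alignments used in testing and a
documented limitation for real data.

Size gates follow the wording of the underlying criteria exactly:
inclusive where a range is given ("between", "within"), strict where a
comparison is given ("shorter/longer than"):

| modality | gate |
|---|---|
| methylated fragment ratio (MFR) | 80–250 bp inclusive, ≥3 CpGs, non-CpG conversion > 95% |
| fragment size index (FSI) | short 100–166 bp, long 169–240 bp, both inclusive |
| aneuploidy (CAFF) | < 151 bp or > 220 bp, strict |
| end motifs (FEM) | < 171 bp, strict |

Fragments with no non-CpG cytosine observations pass the conversion gate:
the rate is undefined and there is no evidence of conversion failure.

## Genomic scaffolding

All profiles live on fixed tilings of the autosomes: 100-kb bins for
copy-number work, 1-Mb windows for MFR, and 5-Mb windows for FSI obtained
by merging 50 consecutive retained 100-kb bins. Coordinates are 0-based
half-open throughout (BED convention); SAM input is converted at the reader
boundary. Three tiling decisions were genuinely open and are resolved as
follows:

* a tile overlapping an exclusion region (blacklist, assembly gap) by one
  or more bases is dropped entirely — the strictest reproducible reading;
* chromosome-terminal tiles shorter than the nominal width are dropped, so
  per-window statistics are comparable;
* when merging 100-kb bins into 5-Mb windows, a terminal group is kept only
  if it holds at least half the nominal complement (≥25 of 50 bins),
  avoiding high-variance stub windows without discarding half-arms.

Arms are delimited by centromere intervals; the five acrocentric p-arms
(13p, 14p, 15p, 21p, 22p) are excluded, giving the standard 39 autosomal
arms. GC content is computed from the reference with ambiguous bases
excluded from numerator and denominator; windows over 50% ambiguous are
dropped.

## Per-modality features

**MFR.** Per 1-Mb window, the fraction of qualifying fragments whose
observed CpGs are all methylated ("fully methylated" = `cpg_methylated ==
cpg_total` with at least 3 CpGs). Windows with no qualifying fragment are
missing and imputed with training means inside the classifiers.

**FSI.** Per 100-kb bin, the ratio of short to long fragment counts with a
+1 pseudocount on both sides — the pseudocount bounds the ratio in sparse
bins and its bias vanishes at realistic depth. Ratios are LOESS-corrected
against GC (span 0.75, degree 2, fitted on unmasked bins; the correction is
applied as residual plus fitted mean, which preserves the profile mean
exactly), averaged within each 5-Mb window, and z-scored across the genome
so every sample's FSI vector has mean 0 and sd 1. A perfectly flat profile
has no fragmentation signal and maps to the all-zero vector.

**CAFF / PA score.** Coverage of size-gated fragments (< 151 or > 220 bp,
enriched for tumor-derived molecules) per 100-kb bin, GC-corrected,
filtered by the baseline stability mask, summed per arm, and normalised to
genome-wide proportions so the statistic is depth-invariant (the original
protocol instead fixes depth by downsampling to 60 million read pairs; the
proportion form behaves identically there and is safer on variable-depth
cohorts). Arm proportions are z-scored against the healthy baseline and the
plasma aneuploidy (PA) score is the sum of |z| over each sample's five most
extreme arms, ties broken by arm label. Arms are chosen per sample, since
the ensemble consumes a single per-sample scalar. The ensemble uses
`log10(PA + 1)`; the offset keeps the transform defined on PA < 1 while
matching `log10(PA)` asymptotically.

**FEM.** Frequencies of the 256 4-mers at the fragment 5' end on the Crick
strand, computed from the *reference* sequence (reverse complement of
reference bases `[end-4, end)`) rather than read bases, so enzymatic
conversion cannot distort the motif alphabet. Fragments ≥ 171 bp or with
ambiguous reference bases are excluded; the vector sums to 1 whenever any
fragment qualifies.

## Baseline filtering and normalization

Unstable genomic bins are removed using healthy training ("baseline")
samples only: a bin is dropped when its |z| across baselines exceeds 2 in
more than `round(0.17 n)` samples (generalising the published 60-of-352
count to cohorts of any size; the absolute count remains available as an
override) or exceeds 4 in any sample, when its baseline variance is zero,
or when raw coverage above 100 collapses to zero after GC correction.
Baseline z-statistics are pooled (not leave-one-out); with hundreds of
baselines the distinction is negligible, and pooling is reproducible.
Quantile normalization maps a sample's values onto the healthy reference
distribution at matching fractional ranks with average-rank ties.

## Detection classifiers

Each of MFR, FSI and FEM feeds a base model: 10 bootstraps of the training
cohort, each taking a stratified 70% for fitting (stratification prevents
single-class folds in small cohorts, where a plain random split would not),
PCA to the fewest leading components explaining ≥ 95% (MFR), 90% (FSI) or
95% (FEM) of the training-fold variance, then a support vector machine
(MFR, FSI; cost ∈ {0.1, 1, 10, 100} × {linear, radial} chosen by 10-fold
cross-validation, probabilities by Platt-type sigmoid calibration as
implemented in e1071) or a logistic regression (FEM — it has no tuned
hyperparameter). A sample's modality score is the mean probability over the
10 sub-models.

The ensemble is an elastic-net-penalised logistic regression on the three
modality scores plus `log10(PA + 1)`, with mixing parameter
α ∈ {0, 0.25, 0.5, 0.75, 1} and penalty strength chosen by 20-fold
cross-validated deviance (folds reduced with a warning when the cohort
cannot sustain three observations per fold). Base scores entering ensemble
training are out-of-fold (each training sample's score averages only the
sub-models that held it out), limiting leakage from base-model overfit into
the ensemble coefficients; test samples use all sub-models. The published
coefficient set

\[
Z = 0.57 + 0.33\,\mathrm{MFR} + 0.34\,\mathrm{FSI} + 0.06\,\mathrm{CAFF}
    + 0.58\,\mathrm{FEM},\qquad
\Pr(\text{cancer}) = \frac{e^Z}{1+e^Z}
\]

ships as `themis_reference_model` so scores can be evaluated without
retraining.

## Cancer signal origin

Per-peak methylation is the fraction of methylated CpG observations among
fragments assigned to the peak by midpoint (the same convention as genomic
binning). Peaks hypomethylated in cancer (one-sided rank-sum p < 0.05) are
retained; healthy baseline statistics use the same retained subset, since
mixing subsets would shift the z-scale. Per cluster, mean retained-peak
methylation and the short/long fragment aggregates (as proportions of the
sample's gated totals, so depth cancels) are z-scored against healthy
controls and min-max scaled to [0, 1] within each sample; a constant
(degenerate) z-vector scales to all 0.5, as does a cluster with no usable
peaks. The 3 × 18 features feed a random forest (2000 trees by default,
√p features per split, no depth cap) evaluated by leave-one-out
cross-validation, with accuracy also reported after merging
esophageal/gastric/colorectal into a digestive group and liver/pancreatic
into a hepatopancreatic group.

## Evaluation utilities

AUC is the rank statistic (ties count one half), with percentile confidence
intervals from 2000 label-stratified bootstrap replicates. Sensitivity at
fixed specificity places the decision threshold at the smallest observed
score cut achieving the target on healthy samples, with ties at the
threshold counted as positive calls, and reports a Wilson 95% interval
(z = 1.959964). The clinical limit of detection fits a logistic regression
of binarized detection on log10(mean VAF) and reports the 50% crossing with
a delta-method CI on the log scale; near-separated fits are flagged rather
than refused. The screening projection is closed-form arithmetic on
(sensitivity, specificity, incidence, population). Hold-one-site-out and
repeated stratified-split harnesses take an arbitrary evaluation closure so
they can wrap the full pipeline or any cheaper surrogate.

## The synthetic cohort generator

The generator works at the fragment-table level on a toy genome of four
30-Mb chromosomes with centromeres at the midpoint and a uniform CpG grid
every 80 bp. It emulates: GC-biased coverage (a smooth per-100-kb GC track
with a multiplicative, length-dependent placement bias, giving the LOESS
step real work); a 167-bp modal discretised-lognormal size distribution
with tumor fragments shifted 20 bp shorter; global tumor hypomethylation
(healthy per-CpG methylation 0.85, multiplied by 0.75 in tumor fragments);
arm-weighted placement under a configurable copy-number spec; a C-rich
healthy end-motif spectrum with tumor fragments drawing from a distorted
spectrum; non-CpG conversion failure at rate 0.006 (so healthy conversion
is ~99.4%, a realistic enzymatic-conversion figure); and 18 clusters of
500-bp open-chromatin peaks, with per-type affected clusters receiving
extra tumor accessibility and hypomethylation. Cancer samples mix tumor and
healthy draws at the sample's tumor fraction; stages map to the bands
I: 0.1–1%, II: 0.5–2%, III: 2–8%, IV: 5–20%. The `signal` presets switch
between these faint staged conditions, a strong regime (tumor fraction
10–30%) used for end-to-end checks, and a null regime (tumor fraction 0).

A companion generator produces mean variant-allele-fraction tables for
limit-of-detection work: VAF proportional to tumor fraction with lognormal
noise, and detection drawn from a logistic in log10(VAF). The default
detection slope is 6 per decade — a sharp transition, reflecting that
classifier detection switches quickly with tumor content around the LOD;
at much shallower slopes the 50% crossing is so weakly identified at a few
hundred samples that no estimator recovers it reliably.

Fragments carry their end motif as a field drawn from the configured
spectrum rather than being read back from a materialised 120-Mb sequence;
reader-level motif fidelity is exercised separately against real sequence
with a small toy FASTA + SAM generator whose motifs *are* taken from the
reference. Peaks receive 20% of fragment placements — on the toy genome
they cover ~1.5% of the sequence versus ~9% for real tumor ATAC peak sets
on hg19, and the boost keeps per-peak read depth at desk scale comparable
to a genome-scale experiment.

What the generator does **not** emulate: sequencing errors and mapping
artifacts, CpG-density heterogeneity, nucleosome-positioned size
periodicity, subclonal copy-number structure, batch and site effects, and
biological variation between healthy donors beyond sampling noise. Tests
passing on this substrate therefore demonstrate that the implementation
computes the intended statistics and that the classifiers recover planted
signal — not that the published clinical operating points transfer to real
cohorts.

## Problem sizes and numerical choices in the shipped checks

The test suite and the acceptance script size their simulations as the
package's own desk-scale choices: detection end-to-end uses 60 healthy +
60 cancer samples at 20,000 fragments each (strong signal preset), the null
control 30 + 30; the aneuploidy/tumor-fraction ladder uses 30 samples at
100,000 fragments, the depth at which arm-proportion noise is small enough
to resolve the low end of the ladder; the CSO check uses 7 pseudo-types ×
20 samples with deliberately strong cluster effects (methylation factor
0.2, accessibility boost 3) and 500 trees per forest, with 2000 remaining
the default for real use; the healthy end-motif fidelity check uses one
1.2-million-fragment sample, since an L1 tolerance of 0.02 over 256
categories is statistically unreachable at much lower counts. Tolerances:
GC correction preserves means to 1e-9 relative by construction; FSI z-score
contracts hold to 1e-6; oracle-equivalence checks are exact or 1e-9.

## Known limitations

* The SAM reader handles M/soft-clip CIGARs only; indel records are
  tallied and skipped.
* Baseline z filtering is pooled, not leave-one-out.
* The top-five-arm PA selection is per sample; a cohort-fixed arm panel is
  a plausible alternative reading of the original method and would be a
  one-line change in `compute_caff()`.
* FSI A/B-compartment labels are carried as metadata only; they do not
  enter the arithmetic.
* No mappability correction beyond exclusion tracks; no sex chromosomes;
  no liftover.
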