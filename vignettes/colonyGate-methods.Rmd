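---
title: "Range-gate classification of colonial phytoplankton morphospecies: methods and design"
author: "colonyGate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-gate classification of colonial phytoplankton morphospecies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyGate)
```

## The problem

Imaging flow cytometry produces one brightfield frame per particle, and
instrument software classifies particles by *range gating*: for each taxon a
filter is a conjunction of inclusive `[min, max]` gates on a handful of
morphological features, and a particle is "selected" by the filter when every
gate is satisfied. colonyGate reimplements this workflow for colonial
*Microcystis* morphospecies (*M. aeruginosa*, *M. ichthyoblabe*,
*M. novacekii*, *M. smithii*, *M. wesenbergii*) and two co-occurring genera
(*Micractinium*, unicellular *Cryptomonas*), together with the statistical
machinery used to validate such classifiers. Because no public image set
accompanies this classification problem at the morphospecies level, the
package ships a synthetic colony-image generator as a first-class, tested
module: every downstream stage is exercised end to end on data whose ground
truth is known by construction.

## The ten particle properties

`extractFeatures()` computes, on a single segmented particle, the ten
properties used by the classifiers (canonical names in `cgFeatureNames()`):
three sizes in micrometres (ABD diameter, Feret length, perimeter), four
8-bit signal statistics (intensity, sigma intensity, average blue, edge
gradient), two channel ratios (red/blue, red/green) and roughness. The
conventions are fixed so that the documented fixed points are exact:

* **Grayscale** is the unweighted mean of the R, G and B planes. The
  instrument's conversion is proprietary and undocumented; the unweighted
  mean keeps intensity and the colour ratios mutually consistent. Absolute
  signal values are therefore convention-dependent, and all within-pipeline
  checks are self-consistent (this is an open question by construction).
* **Segmentation** (`segmentParticle()`) thresholds dark objects at a global
  grayscale level (default 200/255), keeps the largest 8-connected
  component, and *preserves holes*, because the perimeter definition counts
  hole edges. Synthetic brightfield frames have a controlled background, so
  adaptive methods would add nothing; the threshold is exposed in the
  configuration.
* **ABD diameter** is the diameter of the circle whose area equals the pixel
  area: `2 sqrt(area / pi) * pixelSize`.
* **Length** is the maximum of 36 Feret (caliper) measurements, taken at 0,
  5, ..., 175 degrees — 36 directions over a half turn, the standard reading
  of "36 feret measurements". Calipers are measured on the pixel *corner*
  point set, so a single pixel has length `sqrt(2)` at 45 degrees.
* **Perimeter** uses the crack-boundary convention: the number of exposed
  unit pixel edges, outer contour plus every hole contour. **Roughness**
  divides this perimeter by the perimeter of the convex hull of the pixel
  corner points. With both measured on the same corner lattice, a filled
  axis-aligned rectangle has roughness exactly 1 and roughness is >= 1 for
  every mask. A rasterised *disk* has roughness near 4/pi (about 1.27): the
  crack boundary of a digital circle is 4 diameters while its hull perimeter
  approaches pi diameters. This is an inherent property of the crack
  convention, worth knowing when comparing absolute roughness values across
  software.
* **Edge gradient** applies the 3x3 Sobel operator to the grayscale image
  and averages the magnitude over the one-pixel outside border of the mask
  (8-connected dilation minus mask). The magnitude is clamped to [0, 255]
  *per pixel* before averaging, mirroring 8-bit convolution output; an ideal
  step of height `h` gives a border response of `4h` up to that clamp. Sharp
  synthetic edges therefore saturate near 255, while halo-softened edges
  land in the low hundreds — which is exactly the contrast the
  *M. aeruginosa* classifier exploits.
* **Sigma intensity** uses the population (n) denominator: it describes the
  particle's pixels rather than estimating a superpopulation parameter, and
  the tests can assert exact values.

## The synthetic generator

`renderParticle()` draws a colony as a union of jittered filled disks (one
per cell) chained inside a randomly oriented elliptical envelope. Cells are
painted slightly larger than their placement spacing (a mucilage envelope,
factor 1.3), which closes most curvilinear pores between touching cells;
colony growth only accepts cells that add new area, so the target projected
area — and hence the ABD diameter — is hit closely. Interior holes are
carved inside randomly chosen cells (at most three quarters of a cell radius
from its centre, so holes cannot breach the outline) and drive roughness;
*M. smithii* is the extreme case. A semi-transparent halo is modelled in two
parts: an exterior brightness ramp kept just above the segmentation
threshold, and an interior rim that brightens the outermost particle rings
achromatically toward the threshold. The rim, not the ramp, is what lowers
the Sobel border response; hole edges keep their sharp contrast, as they do
in real colonies. The background is fixed at RGB (230, 230, 230) with
Gaussian pixel noise of sd 3 — a brightfield look that keeps the default
threshold trivially valid. The pixel calibration defaults to 0.554 um/px,
the resolution of a 10x objective on the reference instrument.

Per-particle signal targets (intensity, channel ratios, grayscale texture,
target ABD and, for elongated colonies, target length) are drawn uniformly
from per-class *latent ranges*. Each profile also documents a per-feature
*envelope*; at `overlapScale = 0` the generator is self-consistent in the
sense that at least 95% of rendered-and-extracted values fall inside the
envelope for every (class, feature) pair that has one. Where a published
per-class feature range exists for this classification problem, the envelope
is that printed range and the latent range sits comfortably inside it; for
emergent features (perimeter, roughness, edge gradient, average blue) the
geometric knobs (cell radius, hole fraction, halo width, core colour) were
calibrated once against those envelopes and then frozen. The latent ranges
of emergent features, used only by the fast table mode, were set from the
2nd-98th percentiles of the image-mode output so both modes describe the
same classes.

Two design points deserve emphasis:

* **The class structure is the study condition, not a dial.** The envelopes
  of the five *Microcystis* morphospecies genuinely overlap (for example the
  intensity ranges of *M. novacekii* and *M. wesenbergii* share the 67-81
  band, and the roughness ranges of *M. ichthyoblabe* and *M. smithii*
  interleave), while the three genera are separable on diameter and
  intensity alone. The qualitative outcome — intergeneric classification is
  easy, intrageneric classification is harder — is therefore a property of
  the generated world, mirroring the published contrast, and not something
  tests tune for. `overlapScale` additionally inflates within-class
  variability around the latent midpoints (0 = baseline) to emulate bloom
  heterogeneity; it is exercised by tests but defaults to 0.
* **Table mode** (`mode = "table"`) skips rendering and draws every feature
  from a truncated normal centred mid-range (sd a quarter of the width,
  truncated at the overlap-widened ends). It exists as a fast unit-test
  path and is flagged in the manifest; all headline checks run in image
  mode.

What the generator does *not* emulate: optical blur and depth of field,
fluidics artefacts, debris and multi-particle frames, fluorescence channels,
and the real photometric relationship between taxa and RGB response.
Passing tests therefore demonstrate that the classifier and metric machinery
are correct and that the pipeline recovers known structure — not that the
specific numeric accuracies would transfer to a particular instrument's
data.

## Training, reduction, intersection

`sampleTraining()` draws 25 or 50 training particles per class, without
replacement, from a per-class pool capped at the first 150 class members
(the representative-image pool size of the workflow this mirrors).
`fitRanges()` sets each gate to the subset minimum and maximum — exactly
what an instrument filter dialog records. `reduceFeatures()` then performs
greedy backward elimination: at each step it removes the gate whose removal
yields the highest overall accuracy `(TP + TN) / total` on the labeled data,
and stops before any removal would push accuracy to the threshold (default
0.75) or below. "Systematic selection" is not otherwise specified in the
source workflow, so greedy elimination was chosen as the deterministic,
cheap variant; it is oracle-checked against exhaustive subset search on
small gate sets, with ties broken by canonical feature order. A filter
already at or below the floor is returned unchanged with a warning rather
than silently emptied.

`intersectFilters()` narrows the 25- and 50-image filters of a class to
`[max(min25, min50), min(max25, max50)]` per feature. A feature gated in
only one parent carries over unchanged — the published per-class tables
show identical feature lists in both columns, so the case is unobserved
there and carrying over is the conservative choice. An empty narrowed range
is an error, never a silent degenerate gate. Gate bounds are inclusive
throughout: the published intersection columns reuse boundary values, which
would self-exclude under exclusive bounds.

`applyFilters()` supports two modes. Per-classifier mode sets one boolean
flag per class and is the only mode used for confusion matrices, since
overlapping filters can legitimately select the same particle. Exclusive
mode, needed for abundance time series, assigns the first selecting class in
a configurable priority order (default: filter-set order) and labels
particles matching no filter `"unclassified"`; residual bins such as
`"Membrane"` and `"Undefined"` are treated as label-exclusion rules
downstream, not as image classes. Whether the reference instrument applies
filters sequentially or independently is unknown, so both behaviours are
available.

## Validation metrics

All metrics take population counts, not frequencies, and normalise
internally exactly where their formulas do:

* **Accuracy** `(TN + TP) / total` (`gateAccuracy()`), the reduction
  criterion.
* **Confusion counts** per classifier with precision `TP / (TP + FP)` and
  false discovery rate `FP / (TP + FP)` (complementary by construction),
  plus TPR/TNR and **balanced accuracy** `(TPR + TNR) / 2`, the
  imbalance-robust summary.
* **Hellinger distance** between the bin proportions of two datasets,
  `(1/sqrt(2)) sqrt(sum_k (sqrt(X_k/X) - sqrt(T_k/T))^2)` per filter set,
  with the `1/sqrt(2)` normalisation mapping disjoint support to 1. Both the
  per-filter-set values and their mean are returned, because the reference
  workflow reports per-classifier values while the formula averages over
  filter sets; both granularities are legitimate and the caller chooses.
  It is used as a train/test dataset-shift indicator: the per-classifier
  selection compositions on the training and test splits are compared.
* **SMAPE** per class, `mean_f |X - X'| / (X + X')`, reported as a
  percentage (matching how such summary tables print it); `0/0` terms
  contribute 0 so the metric is total.
* **Bray-Curtis dissimilarity** `sum |X - X'| / sum (X + X')` and
  **Kullback-Leibler divergence** `sum p (log p - log q)` between actual and
  predicted class compositions. KLD uses the natural log by default — the
  source formula writes `log` without a base, and with no raw dataset to
  adjudicate, the base is configurable. Bins with zero actual mass
  contribute 0 (the standard `0 log 0 = 0` limit); actual mass in a bin with
  zero forecast mass signals infinite divergence unless a pseudo-count is
  supplied explicitly.

Every metric is tested against an independently coded brute-force evaluation
of its printed formula on random count tables (tolerance 1e-12), plus its
analytic fixed points.

## Seasonal aggregation

`abundanceTimeseries()` groups exclusive assignments by mesocosm tank and
date (12 synthetic tanks A1-G3, 13 dates from 2019-05-23 to 2019-09-17,
assigned round-robin by the generator; dd/mm/yyyy input dates are
canonicalised to ISO-8601). Percentages are taken over the colonial classes
only; `"unclassified"` and the residual bins are counted separately and
excluded from the denominator. A sample with zero colonial particles keeps
its zero counts and flags percentages as NaN rather than dividing by zero.
`generateSeason()` lets tests write seasonal structure directly into the
generated data — for instance zeroing one morphospecies for a mid-season
window and checking that the abundance table shows the
disappearance/re-appearance pattern.

## Numerical and scale choices

Determinism is a contract: a `GenerationConfig` plus seed reproduces every
image, CSV byte and filter file; filter files round-trip bit-exactly using
17-significant-digit formatting. Headline checks run at the study scale of
150 particles per class for all 7 classes (about 1,050 rendered frames,
roughly three minutes of rendering); unit tests use table mode or a handful
of frames. The intergeneric worked example trains on diameter and intensity
only, where reduction typically leaves the *Cryptomonas* filter with the
single diameter gate, as in the published example. Range gates fitted from
n training particles have an expected fresh-sample coverage of
(n - 1)/(n + 1) per gate — about 0.92 at n = 25 — which bounds the true
positive rate of small-subset filters; balanced accuracies near 0.95-0.99
for well-separated classes are the realistic ceiling, not a bug.

## Command line

`inst/scripts/colonygate.R` is a thin Rscript wrapper exposing `generate`,
`extract`, `train`, `intersect`, `classify`, `evaluate`, `timeseries` and
`run` subcommands over the exported functions; `runPipeline()` is the same
driver as a function, writing a manifest, feature tables, the three filter
files, metric reports, the abundance table and a structured log per stage.

## Known limitations

* Absolute values of the signal features depend on the grayscale and Sobel
  conventions above; only within-pipeline comparisons are meaningful.
* The generator's colony geometry is a disk-union caricature; it moves every
  feature the classifiers use, but real colony texture, mucilage optics and
  focus variation are out of scope.
* Published headline numbers that depend on the original mesocosm image
  dataset (per-class precision tables, abundance figures) cannot be
  reproduced without that dataset; the package reproduces the printed
  worked-example filter ranges, the analytic fixed points of the metrics,
  and the qualitative intergeneric-vs-intrageneric ordering on synthetic
  data instead.
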