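---
title: "Quantifying tertiary lymphoid structures on H&E slides"
author: "tlsquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tertiary lymphoid structures on H&E slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsquant)
```

## The biomarker and its model

Tertiary lymphoid structures (TLSs) are organized aggregates of T (CD3+)
and B (CD20+) lymphocytes that form inside tumours and other chronically
inflamed tissue. Their burden carries prognostic information across many
solid cancers. `tlsquant` turns a hematoxylin–eosin (H&E) slide into one
number, the **TLS ratio**,

$$\mathrm{TLS\ ratio} \;=\; \frac{\sum_{\text{retained tiles}} |\,\mathrm{TLS} \cap \mathrm{tissue}\,|}{\sum_{\text{retained tiles}} |\,\mathrm{tissue}\,|},$$

averaged over slides per subject, and provides the survival statistics
usually applied to such a biomarker (maximally selected log-rank
cutpoint, Kaplan–Meier/log-rank, Cox proportional hazards with Harrell's
C, nested likelihood-ratio tests, Wilcoxon responder comparisons).

The quantification pipeline works on non-overlapping 512×512-pixel tiles
at 0.5 μm/pixel (the 20× scanning convention; 40× material is cropped at
1024×1024 and downscaled by area averaging). Three branches run per tile:

1. **Tissue branch.** Tile luminance (Rec. 601) is thresholded by Otsu's
   criterion; pixels darker than the threshold are tissue. Colour-rule
   filters remove blue, green and red pen-mark annotations before the
   mask is used. A tile enters the ratio only when its tissue area
   strictly exceeds 10% of the tile — 26,214 pixels for a 512×512 tile.
2. **Segmentation branch.** A segmenter maps the tile to a TLS
   probability map; pixels strictly above 0.5 become TLS, and the TLS
   mask is intersected with the tissue mask (so the ratio cannot exceed
   1, and TLS area is by construction tissue).
3. **Counting branch.** A nucleus detector counts lymphocytes whose
   centroids fall inside the tile's TLS area. When that count does not
   exceed 80 the tile's TLS area is zeroed — the filter exists to
   discard small TLS fragments — but its tissue still accrues to the
   denominator.

Ground truth for training and evaluation follows the mIHC convention: a
candidate lymphocyte aggregate qualifies as a TLS when it contains at
least 50 CD3+ or CD20+ cells; training tiles are curated to those with
more than 40% TLS area, split 7:1:2 into train/validation/test.

## Decisions where the procedure was genuinely open

Several boundary and orchestration details are not fixed by the
published description; the package pins them as follows.

* **Boundary conventions** are strict wherever a printed count implies
  it: retention requires `tissue_pixels > floor(0.10 × tile_area)`
  (making 26,214 the largest rejected count on a 512² tile), the
  probability threshold is a strict `> 0.5`, the lymphocyte filter a
  strict `> 80`, tile curation a strict `> 40%`, while TLS
  qualification is inclusive at `≥ 50` cells.
* **Edge tiles** that would extend past the slide are dropped, never
  padded — padding could only distort area ratios.
* **Otsu scope.** `otsu_tissue_mask()` thresholds a single tile, but
  `compute_slide_ratio()` computes the threshold once from the
  whole-slide histogram and applies it to every tile: a tile fully
  interior to tissue has no background mode in its own histogram, and
  per-tile Otsu would misclassify most of it. Tiles whose luminance
  range falls below 20 grey levels are treated as blank background
  (this generalizes the degenerate constant-tile case).
* **Pen rules** are pure per-pixel channel-threshold predicates with
  explicit constants in `tls_config()` — each requires a bright dominant
  channel plus suppressed competing channels, so hematoxylin purple,
  eosin pink, background and black are never flagged. The constants are
  frozen by golden tests.
* **Numerator intersection.** Predicted TLS is intersected with the
  tissue mask before accumulating; biologically TLS is tissue, and the
  intersection guarantees `ratio ≤ 1`.
* **Undefined ratios.** A slide with no retained tissue yields an
  undefined ratio (flagged, not an error); subjects average over their
  defined slides with a warning, because one blank slide should not
  zero a subject's biomarker.
* **Empty-mask metrics.** Dice and IoU score 1.0 when prediction and
  truth are both empty: a correct all-negative prediction should not be
  penalized. The identity `Dice = 2·IoU/(1 + IoU)` holds for every mask
  pair and is property-tested.
* **Bootstrap unit.** The 95% CI of the pixel-level AUC uses 500
  bootstrap replicates resampling *tiles*, not pixels: pixels within a
  tile are spatially dependent, so the tile is the exchangeable unit.
* **Survival details.** Cox models use Efron tie handling (the default
  of the R survival ecosystem); Wald 95% CIs are `exp(β ± 1.96·se)`;
  the cutpoint scan uses `minprop = 0.1` per side with ties broken
  towards the smaller cutpoint, and a fitted cutpoint can be applied
  unchanged to an external cohort; the Wilcoxon responder test is exact
  up to a combined n of 20 without ties and a tie-corrected normal
  approximation beyond. TNM stage enters models as a categorical factor
  with treatment contrasts.

## The trainable segmenter

The reference implementation of the segmentation branch is a deep
encoder–decoder; this package specifies only the contract — any map from
a 512×512×3 tile to a same-size probability field — and ships a
lightweight, CPU-friendly model that satisfies it:

* a **fixed multiscale encoder**: per pixel, stain darkness
  `1 − luminance/255`, a nucleus-density channel (indicator of darkness
  above 0.5, i.e. hematoxylin-dark nuclei, Gaussian-smoothed at scales
  of 2, 6 and 16 px for the `small` preset), and a smoothed blue-excess
  channel `(B − R)/255`;
* a **trainable decoder head**: a two-layer perceptron applied to the
  standardized feature vector on a stride-4 grid, bilinearly upsampled
  to tile resolution.

Dense aggregates of dark nuclei are exactly what the coarse-scale
nucleus-density channel responds to, which is also the visual definition
of a TLS on H&E — so the head has a nearly linearly separable problem to
learn. Training uses hand-written minibatch AdamW under the protocol in
`train_config()`: batch size 64 tiles, up to 100 epochs, early stopping
after 10 epochs without a new validation-loss minimum, compound soft-Dice
+ cross-entropy loss, and decoupled weight decay of 1e-4. The protocol's
default learning rate of 1e-4 suits deep backbones trained for many
thousands of steps; for this small head the desk-scale runs in the tests
and the acceptance script use 0.05 and at most 60 epochs, which reaches
a held-out synthetic Dice above 0.9 in a few minutes on one CPU. No data
augmentation is applied by default; the synthetic generator instead
varies staining directly.

The nucleus detector of the counting branch is likewise pluggable (any
function `tile → cell table`). The default is classical: per
non-overlapping 256×256 window, Gaussian-smoothed darkness, a darkness
threshold for nucleus candidates, local maxima as detections, offsets
applied per window, and duplicates within 4 px merged (keeping the
darker peak) so nuclei straddling window borders count once. The
lymphocyte flag is a smoothed-darkness rule: small dense lymphocyte
nuclei keep a high peak darkness, larger paler nuclei plateau lower.

## What the synthetic generator emulates — and what it does not

Every stage is testable without clinical material through
`generate_slide()` / `generate_cohort()`:

* tissue as a wobbled ellipse of eosin-pink texture on a bright
  background, sized to a target area fraction (an elliptical region can
  cover at most ~69% of the canvas; higher targets error out rather
  than clip);
* TLS regions as non-overlapping ellipses packed with 80–160 dark
  lymphocyte nuclei each (minimum separation 7 px), their areas summing
  to a target fraction of the tissue — so every region passes the
  50-cell rule by construction and the emitted cell table reproduces
  the ground-truth mask exactly;
* scattered stromal lymphocytes at a density of 400/mm² plus 25% as
  many larger, paler non-lymphocyte nuclei;
* per-slide stain variation as multiplicative jitter in an optical
  density–like colour space (emulating differing hematoxylin/eosin
  protocols without modelling chemistry);
* optional saturated pen strokes crossing the tissue edge;
* cohorts whose overall survival follows an exponential model with
  log-hazard `log(h₀) + β · ratio`, independent exponential censoring,
  and a logistic response model in the ratio — linked to the *true*
  ratio so that statistical tests can separate estimation error from
  sampling error.

Defaults (1024×1024 px at 0.5 μm/px, 60% tissue, 10% TLS fraction over
3 regions, stain jitter 0.05) were chosen once as a plausible desk-scale
stand-in for tumour sections with moderate TLS burden. Survival defaults
(baseline hazard 1/1000 per day, censoring 1/2000 per day, β = −2)
give realistic event rates with a protective TLS effect of the size the
biomarker literature reports.

The generator is deliberately not photorealistic: no germinal-centre
substructure, no stromal texture families, no nuclear pleomorphism, no
scanner artefacts beyond pen marks, and hard tissue/background edges.
Passing tests therefore demonstrate that the *machinery* — masking,
accumulation rules, metrics, statistics — is correct and that the
segmenter can learn density-defined aggregates; they do not certify
performance on clinical slides, where the reported Dice of a deep model
on real material is the relevant benchmark and is out of reach without
the original scans.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to exercise
every rule while staying comfortable on one CPU: ten 1024² slides for
the oracle-exactness check (the pipeline must match an independent
recomputation from ground truth to 1e-9 relative error, and does so
exactly); ~200 tiles from 22 slides for segmenter training with a 7:1:2
split; n = 400 cohorts for coefficient recovery (±3 SE); 500 null
replicates for log-rank and likelihood-ratio type-I error (expected in
[0.03, 0.07] at α = 0.05); and 20 replicates of the cutpoint scan
against an exhaustive `survdiff`-based search at n ≤ 50.

Floating-point choices worth knowing: area-average downscaling keeps
fractional means unrounded; the AUC uses average ranks (ties count one
half) with numeric accumulators (pixel counts overflow 32-bit integers
on full tiles); cutpoint ties are resolved to the smaller value with a
1e-9 comparison slack; Cox fits flag |β| > 15 as monotone likelihood
rather than returning a divergent estimate.

## Known limitations

* The default detector's lymphocyte flag is calibrated to the synthetic
  palette; real H&E requires either recalibrating `tls_config()$detector`
  or plugging in a learned nucleus model through the detector interface.
* Per-tile Otsu assumes a background mode; the slide-level threshold
  used by `compute_slide_ratio()` removes that assumption but still
  assumes bright background somewhere on the slide.
* The segmenter's stride-4 decoding blurs TLS boundaries by a few
  pixels; at typical TLS sizes (tens of thousands of pixels) the effect
  on the ratio is negligible, but very small aggregates are smoothed —
  which the 80-lymphocyte filter would discard anyway.
* TLS instance counting and maturity subtyping are out of scope.
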