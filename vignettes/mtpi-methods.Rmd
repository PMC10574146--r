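---
title: "Planning segmentation transfer learning with the maximum transfer potential index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning segmentation transfer learning with the maximum transfer potential index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A semantic-segmentation network trained on one imaging campaign often
degrades badly on the next one: vegetation classes photographed in a wet
season look different in a dry season, even though the scene geometry and
the label taxonomy are unchanged. Retraining from scratch wastes labelled
data and compute; naive fine-tuning requires choosing, by trial and error,
(a) how deep to freeze the pre-trained network and (b) how many new
labelled samples to collect.

The **maximum transfer potential index (MTPI)** procedure answers both
questions *before* any fine-tuning run. For every transfer point `x` (the
index of the deepest frozen activation layer, counted from the input), it
computes a transfer potential index

\[ \mathrm{TPI}(x) = \frac{\mathrm{TPI}_{WKs}(x)}{\mathrm{TPI}_{TP}(x)}, \]

where

* `TPI_WKs(x)` is the **accuracy potential**: the weighted Cohen kappa of a
  per-pixel classification built directly from layer `x`'s feature maps on
  the *new* dataset (the "TPI mapping"). It estimates how class-
  discriminative the frozen features already are, with no retraining.
* `TPI_TP(x)` is the **time-cost level**: the trainable-parameter fraction
  `LS_x / LS_0` binned into `Nlevel` (default 10) discrete levels,
  `min(Nlevel, floor(LS_x/LS_0 * Nlevel) + 1)`. `LS_x` counts the
  parameters that remain trainable when layers `1..x` are frozen.

The chosen freezing depth is `TP0 = argmax_x TPI(x)` (ties toward the
deepest, i.e. cheapest, point), and the transfer dataset size follows the
linear rule `TDS0 = round(k_pre * LS_TP0)` with
`k_pre = TDS_pre / LS_pre`, the samples-per-parameter ratio that was
demonstrably sufficient during pre-training.

Datasets are screened first: if the pre-trained network already achieves
WKs at or above 0.8 on a new dataset, it is kept as-is ("skip"); below 0.6
transfer training is triggered; the 0.6-0.8 band is undefined by the
protocol and flagged to the operator as "borderline".

### Choices where the printed formulas are ambiguous

Three places in the common write-ups of these metrics print forms that
contradict their own narrative; the package implements the standard form
and keeps the literal variant behind a flag:

* the cost level is computed from the *trainable* fraction `LS_x/LS_0`
  (`form = "fraction"`), so cost falls as freezing deepens and the TPI
  curve "rises then levels off"; the frozen-fraction variant is available
  as `form = "literal"`;
* kappa uses the Cohen denominator `1 - Pe` (`denominator = "pe"`); the
  `(Po - Pe)/(1 - Po)` variant is available as `denominator = "po"`;
* the weighted precision/recall/F1/IoU use prevalence weights `p_i`
  (`average = "weighted"`); the uniform `1/C` macro average is available
  as `average = "macro"`. In the recall denominator the package uses
  `TPP + FNP` (the definition of recall); cost-level binning uses
  `floor`, with the result clamped into `{1..Nlevel}`.

The TPI mapping itself is specified in the source material only by
example pictures, so the package documents its rule explicitly: on a
calibration subset, each feature channel is assigned to the class that
maximises its standardised in-class activation (mean inside the class
minus mean outside, over the channel's standard deviation); a class's
score map is the mean of its assigned channels, bilinearly upsampled to
label resolution if needed; the per-pixel class is the argmax (ties to
the lower class index). A least-squares 1x1 linear probe is implemented
as the alternative (`probe_config(rule = "linear")`). Negative kappa is
clipped to 0 in `TPI_WKs`, whose declared range is 0..1.

## The synthetic study system

Nothing in the package requires aerial imagery. All experiments run on a
seedable simulator of 4-class vegetation scenes (tree, shrub, grass, and
non-vegetated area NVA; palette blue/green/red/magenta).

* **Labels** come from thresholding Gaussian-smoothed white-noise fields,
  one per class, with offsets calibrated iteratively toward the requested
  area mixture — this produces contiguous, canopy-patch-like regions with
  a controllable correlation length (`blob_scale`).
* **Images** are the per-class mean colour plus a per-class oriented
  sinusoidal texture (grass finest, NVA nearly flat) and white pixel
  noise.
* **The season shift** is a photometric map applied in HSV space to the
  vegetation classes only (NVA is unshifted, mirroring the observation
  that bare ground survives a season change): hue rotation,
  saturation/brightness gains, and a texture-contrast stretch of V about
  the class mean. The identity shift is bit-exact, and labels are never
  touched by any photometric operation.

The default shift (versioned in
`inst/extdata/config/default_shift.yaml`) is **brightness-led**: a strong
brightness/saturation reduction with a small hue rotation. This choice is
deliberate. A multiplicative intensity change approximately commutes with
convolution-plus-ReLU, so the *information* in the frozen features
survives the shift — retraining only deep layers can recover it — while
the network's fixed classification head, whose decision boundaries are
anchored to source-domain activations scales, collapses. That is exactly
the regime the screening protocol presumes: the un-adapted network drops
below the transfer threshold (WKs < 0.6) although a cheap deep-layer
transfer can restore most of the accuracy. A strong hue rotation
(90-140 degrees), by contrast, folds class colours onto one another at
the first layer; no amount of deep retraining can undo a shallow
distortion, so frozen-feature transfer of *any* depth is then
structurally capped well below full fine-tuning. The shift magnitudes
were fixed once, during generator calibration, so that a source-trained
network screens as "skip" (WKs > 0.8) on its own domain and "transfer"
(WKs < 0.6) on the shifted domain, and were not revisited afterwards.

What the simulator does **not** emulate: spatial autocorrelation of real
canopies beyond second order, mixed pixels and shadows, georeferencing
artefacts, within-class phenology gradients, or label noise. Passing the
package's experiments therefore demonstrates that the MTPI machinery is
implemented coherently — not that the index is validated on real UAV
data.

## The toy network

The trainable model is a small fully-convolutional encoder: `depth` 3x3
convolution + ReLU stages at constant resolution followed by a 1x1
classification head. Activation layers are the transfer points; `x = 0`
freezes nothing and `x = -1` freezes everything but the head. Frozen
parameters are bit-identical after training, by construction, and
`LS_x` accounting is exact (`layer_sizes()` is tested against a
brute-force parameter-group walk).

Channel widths (default `c(16, 12, 9, 7, 12)`) taper through the trunk
and widen again at the last stage. The taper concentrates parameters in
the early stages — as in backbone-heavy segmentation networks, where the
bulk of capacity sits below the transfer band — which is what makes the
cost levels informative (deep transfer points are cheap, shallow ones
expensive). The wider final stage gives the head a richer feature basis,
which matters because the MTPI condition frequently selects a deep
transfer point: the quality of a deep transfer is then limited by what a
linear head can decode from the last frozen features.

Numerical choices, all visible in `train_config()` / `net_spec()`:
inputs are scaled to centred `[-0.5, 0.5]` (uncentred `[0, 1]` inputs
drove entire deep layers into the dead-ReLU regime during calibration);
He-style seeded initialisation; plain momentum SGD (lr 0.02, momentum
0.9) with a global gradient-norm clip of 5, which stopped the occasional
mid-training collapse of plain-ReLU stages; class-weighted cross-entropy
with inverse-frequency weights normalised to sum to C; convergence is
declared when the mean loss over the last `conv_window` iterations
improves on the previous window by less than `conv_tol` (relative).
Argmax ties in predictions break toward the lower class index.
Normalisation statistics do not arise (the toy nets carry none); for
architectures that have them, the stricter reading — frozen layers keep
frozen statistics — is the intended contract.

## Desk-scale study conditions

The shipped configuration (`inst/extdata/config/toy_default.yaml`) fixes
the problem sizes used throughout the tests and the acceptance script:
64x64 scenes (the 224-pixel minimum of the full-scale protocol is
relaxed at desk scale; the simulator accepts 48 and up), a source survey
of 600 scenes split 4:1:1, a shifted target survey of 120 scenes, 900
pre-training iterations and 400 transfer iterations at batch size 2.
These sizes were chosen once so that a full pipeline run — pre-train,
screen, scan, transfer, sweep — completes on a single CPU core in a few
minutes while leaving the qualitative structure of the full-scale
protocol intact: the pre-trained network reaches WKs above 0.95 on its
own domain, and every transfer point remains exercised.

The sweep harness compares cells by iterations-to-convergence, so its
cells use a deliberately coarse stopping rule (relative windowed loss
improvement below 5%, capped at 250 iterations): within the desk-scale
budget, small-batch SGD on the shallow cells keeps improving by more
than a fraction of a percent per window indefinitely, and a tight
tolerance would censor every cell at the cap. The condition-versus-full
fine-tuning comparison instead runs both arms to a fixed 400-iteration
budget, which favours neither arm. Throughout, `x = -1` (only the head
trainable) is ordered as the deepest transfer point.

At full scale the protocol's augmentation step expands each dataset
six-fold (2,500 samples to 15,000; four datasets to 60,000) with seven
methods — symmetry, panning (±5%), HSV jitter (x0.9–1.1 per channel),
scaling (x0.9–1.1), rotation (±5°), Gaussian noise, and cropping — each
variant composing 1–3 methods drawn uniformly (the composition recipe is
unspecified upstream; drawing uniformly is this package's choice, as is
including the original among the six outputs). Geometric methods move
image and label through one recorded affine map (image bilinear, label
nearest-neighbour; exposed regions fill with NVA), so congruence is
checkable exactly by replaying the transform; photometric methods never
touch the label. The Gaussian noise variance 0.1 is interpreted on
[0,1]-scaled intensities, matching the convention of the common image
toolboxes. The desk-scale pipeline trains on raw scenes — at 64 pixels
the augmented variants add little beyond the simulator's own noise — but
the augmentation module is exercised at full 400x400 scale by the test
suite.

## What the acceptance experiments show

* The five weighted metrics agree with brute-force counting oracles to
  1e-10 on random confusion matrices; perfect prediction yields 1
  everywhere and the uniform matrix yields WKs = 0.
* The augmentation pipeline expands 2,500 synthetic 400x400 samples to
  exactly 15,000 (and four surveys to 60,000), every output 400x400,
  with image/label congruence verified by transform replay on every
  augmented pair.
* After any transfer run, frozen parameters are bit-identical to the
  checkpoint and trainable counts equal `LS_x`, which is non-increasing
  in depth.
* `TPI_TP` stays in `{1..10}`, non-increasing with depth; `TPI` equals
  the ratio recomputed independently; a hand-built net whose first-layer
  channels are exact class indicators attains `TPI_WKs = 1`.
* End to end, under the shipped conditions: the source-trained net
  screens "skip" on source and "transfer" on the shifted target; the TPI
  curve rises steeply while the cost level falls, then levels off and
  fluctuates across the deep, level-1 transfer points; transfer at
  (TP0, TDS0) trains a small fraction of the parameters and lands near
  full fine-tuning; in the sweep harness, deeper freezing converges in
  fewer iterations and larger transfer sets reach higher final WKs.

## Known limitations

* The toy networks are orders of magnitude smaller than the
  architectures the index was designed for; the TP/LS machinery is
  architecture-agnostic, but the *shape* of a toy TPI curve (five points)
  is far coarser than a 57-layer catalog.
* The standardised channel-to-class probe is a deliberately simple
  reading of the "feature mapping" idea; it underestimates the accuracy
  potential of wide layers (the linear-probe alternative is closer but
  heavier). Both are labelled interpretations, selectable in
  `probe_config()`.
* The linear TDS rule inherits its stated assumption — sample need
  proportional to trainable parameters — and is applied unchanged; with
  very deep transfer points it can prescribe a single-digit sample
  count, which the package floors at 1 and caps at the available data
  with a warning.
* The screening thresholds (0.8 / 0.6) are protocol constants, not
  estimated quantities; the band between them is surfaced as
  "borderline" rather than resolved.
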