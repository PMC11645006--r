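---
title: "canopy3d: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{canopy3d: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early water or nutrient stress shows up in a potted crop's *geometry* before
it shows up in its color: one of the first morphological symptoms is a decline
of the foliage, i.e. the leaves sit a few centimeters lower (farther from a
top-view camera). canopy3d detects that decline from a **single top-view RGB
image**, with no depth sensor at inference time, by chaining five stages:

1. **Plant recognition.** A CNN classifies 32×32 RGB sections Φ as
   plant (υ₁) or no-plant (υ₂) and is applied as a sliding window that paints
   each window's central pixel ρ with the predicted label — an object-level
   classifier turned into a semantic segmenter, which also turns a few images
   into a large patch training set.
2. **Leaf detection.** The image is partitioned into SLIC superpixels
   (defaults: 999 desired superpixels, 9 iterations, smoothing 5). With φᵢ
   the pixel count of superpixel ψᵢ and γᵢ its count of plant-labelled
   pixels, the gate S(ϑᵢ) = 1 iff φᵢ = γᵢ keeps exactly the superpixels made
   entirely of plant pixels; everything else is discarded.
3. **Depth inference.** A second CNN with the same patch interface regresses
   the *mean 8-bit depth code* under each 32×32 section, trained from paired
   RGB/depth records; slid over the image it yields a dense depth-code map.
4. **3D reconstruction.** Codes convert to meters via Z = k·z/255 (k = depth
   range of the training sensor, default 4 m), and each leaf pixel
   back-projects through the pinhole model X = x·Z/f, Y = y·Z/f. A leaf's
   point cloud is summarised by its moments
   m₍p,q,g₎ = Σ Xᵖ Yᵠ Zᵍ (orders 0/1) and the centroid
   C = (m₁₀₀, m₀₁₀, m₀₀₁)/m₀₀₀.
5. **Stress classification.** Up to 15 leaf-centroid heights (ordered by
   pixel-projection count w, descending) form a fixed 15-vector fed to a
   feed-forward network with layers 15–128–64–32–64–128–2, ReLU hidden
   activations and two sigmoid outputs; the stressed-class sigmoid is the
   score and 0.5 the decision threshold.

Evaluation machinery includes the standard confusion metrics, ROC AUC, the
Polygon Area Metric (PAM: shoelace area of the hexagon whose six radii are
sensitivity, specificity, Jaccard, accuracy, F1 and AUC, normalized by
3√3/2 ≈ 2.59807), seeded k-fold cross-validation, method-comparison deltas,
and the moisture ratio MR = (Mₜ−Mₑ)/(M₀−Mₑ) used to validate stress grouping
by leaf drying curves.

## The synthetic world

The original paired RGB/depth datasets are not publicly available, so the
package ships a seeded generator (`generate_scene()`, `generate_dataset()`)
that emulates their *statistical structure*: 640×480 paired RGB + 8-bit depth
records in eight irrigation groups A–H (250 mL doses at 1/5/2/3-day
intervals, water or water+NPK), with unstressed foliage at 0.65–0.74 m from
the camera and stressed foliage at 0.75–0.80 m. Scenes are rosettes of flat
elliptical leaves over a textured soil plane at 0.85 m; each leaf's distance
Z is uniform in its group's band and encoded as z = round(255·Z/k).

Two deliberate modelling choices:

* **Brightness–distance coupling.** Leaf brightness (HSV value) falls off
  linearly with camera distance (≈ −1.1 per meter over the working band,
  with only ±2% per-leaf jitter). This is the monocular cue that makes
  single-image depth *identifiable* in the synthetic family — the stand-in
  for the real-world cue that declined (stressed) leaves sit lower and
  darker. Without an appearance–depth coupling no monocular method could
  work, so a green test establishes that the pipeline recovers depth *when a
  learnable cue exists*, not that such cues exist in any particular field
  image.
* **Depth-code orientation.** The conversion Z = k·z/255 makes the code grow
  with distance, and the generator follows it literally (its worked example:
  z = 128, k = 4 m → Z ≈ 2 m). Sensors that encode near-bright are supported
  through `invert_depth_code` at the file interface; package-internal maps
  are always code-grows-with-distance.

What the generator does **not** emulate: photorealistic leaf texture,
self-shadowing, growth over the 15-day protocol, NPK chemistry, or any
correlation between stress and leaf *color* (by construction, geometry is the
only stress signal — which is exactly the claim under test).

## Numerical and design choices

* **Patch networks in base R.** No deep-learning framework is assumed: the
  package implements conv/batch-norm/ReLU/max-pool/dense layers, Adam, and
  fused sigmoid+BCE/MSE losses over BLAS matmuls. Training is
  bit-reproducible for a fixed seed. The full VGG16-style encoder (13 conv,
  13 batch-norm, 5 max-pool) is available and shape-checked; tests train the
  *reduced* encoders (below) so the suite runs on one CPU in minutes.
* **Two reduced encoders.** Per-pixel *classification* must localize the
  window's central pixel, and a stack of max-pools destroys that
  information: with three conv/pool blocks the center-pixel painting rule
  saturated at ~3% interior error on two-color toys regardless of training.
  The reduced segmentation encoder therefore uses three conv blocks with a
  *single* early pool (interior F1 ≥ 0.99 on toys). The depth regressor
  predicts a window *mean*, which benefits from aggregation, so it defaults
  to the fully pooled 3-block variant; with the localizing encoder instead,
  class separation of reconstructed leaf heights degraded ~3-fold.
* **Border rule.** The first design (border pixels copy the nearest fully
  interior window center) proved wrong at desk scale: on 96×96 scenes the
  border band is ~54% of the image, label smearing capped whole-scene pixel
  F1 at ~0.84, and smeared "plant" strips at soil depth poisoned the purity
  gate. The default is now edge-replication padding (`border = "pad"`), so
  every pixel is classified on a full window; the original rule remains as
  `border = "nearest"`. Stride-skipped pixels take the nearest evaluated
  center under either rule.
* **Patch labels.** A training patch takes the ground-truth class of its
  central pixel (consistent with inference painting the center); a
  majority-vote rule is available (`label_rule = "majority"`).
* **Purity gate and merging.** The gate is the strict φᵢ = γᵢ rule — a
  single mislabelled pixel discards the superpixel, and single-pixel
  superpixels are gated like any other (no minimum-size filter). The
  pipeline then merges adjacent kept superpixels into 4-connected leaf
  regions (`merge_leaf_regions()`, `merge_regions = TRUE`): kept superpixels
  are leaf *sections*, and pooling them into per-leaf regions stabilises the
  15-slot feature vector (without merging, the 15 largest *sections* crowd
  out information from the rest of the plant). Set `merge_regions = FALSE`
  for section-level reconstruction.
* **SLIC.** CIELAB features with the standard distance
  d² = d²_Lab + (m/S)²·d²_xy, 2S×2S search windows, and connectivity
  enforcement by connected-component relabelling (fragments below a quarter
  of the expected superpixel size merge into their longest-border
  neighbour). The achieved superpixel count may differ from the desired one
  and is recorded.
* **Sigmoid and decision.** The logistic 1/(1+e^(−y)) is used (the variant
  with a minus sign in the denominator is unbounded near zero and read as a
  typo); the hard 0/1 step appears only as the 0.5 decision threshold after
  the smooth sigmoid, keeping training differentiable.
* **Moments.** The moment definition with w inside the sum would make
  m₀₀₀ = w² and cancel out of the centroid anyway; the package computes the
  plain sum of monomials, making the centroid the coordinate mean.
* **RMS.** Reported per axis as the square root of the mean squared
  matched-pair difference (the radical is restored; the printed formula
  omits it), with the "Average" the arithmetic mean of the three per-axis
  values, in meters. Centroid correspondence defaults to positional pairing;
  greedy nearest-neighbour matching in (X, Y) with a gating radius is
  available, with unmatched counts reported.
* **Undefined metrics.** Zero-denominator metrics are `NA` and flagged,
  never silently zero. PAM uses the exact normalizer 3√3/2 internally; the
  truncated 2.59807 appears only in reporting.
* **15-neuron input.** "Fifteen centroids" cannot fill fifteen neurons with
  three coordinates each; the default mode feeds the centroid *heights* (Z)
  of up to 15 leaves (stress manifests as foliage decline), and
  `full_centroids` packs (X, Y, Z) of the 5 largest leaves instead. The pad
  value (default 0) must lie outside plausible heights.

## Scaled-down testing, and what green means

The acceptance suite runs the whole system at desk scale: 96×96 scenes,
reduced encoders, sliding-window stride 4, 150 desired superpixels, and
training budgets of a few epochs — chosen so the suite fits a single-CPU
budget; every one of these knobs is configuration, not a constant. The
end-to-end check trains the stress DNN on features the *pipeline itself*
produces on training scenes (as in the original protocol, where the
classifier consumes the method's own reconstruction), then requires ≥95%
agreement with the 0.745 m threshold oracle on 100 fresh scenes. The
depth-separation check uses the minimum-error single threshold between the
two predicted height distributions, which is invariant to the shared
soil-penumbra bias that 32-pixel windows induce around leaves much smaller
than real foliage.

A green suite establishes: the arithmetic of every printed formula; exact
equivalence of the gating, moment and sliding-window implementations with
brute-force oracles; metric round-trips through the code/PNG interfaces
within one-code quantization (k/255 m); and parameter recovery in the stated
synthetic world. It does not establish performance on real field imagery,
robustness to lighting or occlusion, or transfer across crops.

## Known limitations

* Monocular depth here leans on a single photometric cue; real canopies
  offer richer but also more confounded cues.
* The purity gate inherits segmentation errors: a systematically optimistic
  segmenter keeps impure superpixels whose depth mixes soil and leaf.
* Superpixels smaller than a leaf fragment it; merged regions can also fuse
  touching leaves (true leaf-instance splitting is out of scope).
* At desk scale the 32-px window is large relative to synthetic leaves, so
  window-mean depth regression is biased toward soil; the bias is shared
  across classes and absorbed by training the classifier on pipeline
  features, but absolute heights read high by a few code units.
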