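---
title: "Segmenting mass regions in tomosynthesis-like volumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting mass regions in tomosynthesis-like volumes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dbtseg` implements a complete computer-aided pipeline for segmenting mass
regions in digital-breast-tomosynthesis-like (DBT-like) grayscale slice
stacks: contrast enhancement, patch-based training of a dilated fully
convolutional network (FCN) under a Dice loss, dense per-pixel two-class
prediction, connected-component postprocessing, and pixel- plus lesion-level
evaluation. This vignette records the model, its assumptions, and every
design decision that was genuinely open, so a maintainer can see why the
package behaves the way it does.

## The segmentation model

Each volume is processed slice by slice. A slice is a discrete image
$f$, and the network is built from the $d$-dilated convolution

$$(f *_d r)(\mathbf p) = \sum_{\mathbf s + d\,\mathbf t = \mathbf p} f(\mathbf s)\, r(\mathbf t),$$

where $r$ is a $(2k+1)^2$ filter on the support $[-k,k]^2$ and $d \ge 1$
spaces the kernel taps $d$ pixels apart. With $d = 1$ this is ordinary
discrete convolution. Stacking dilated layers grows the receptive field
exponentially while every layer preserves the spatial resolution — no
pooling, no upsampling, so the dense output has exactly the input's shape.

The default architecture (`architecture_spec()`) is eight layers: seven
$3\times3$ convolutions with dilations $1, 1, 2, 4, 8, 16, 1$ and 32
channels, each followed by batch normalization and ReLU, then a final
$1\times1$ convolution to 2 channels (mass / background) with neither batch
normalization nor nonlinearity. The one-axis receptive field is
$1 + \sum_i d_i (k_i - 1) = 1 + 2(1+1+2+4+8+16+1) = 67$ pixels
(`receptive_field()`), and the package verifies this against an empirical
perturbation-footprint oracle in its tests. Class probabilities come from a
two-class softmax; the decision rule is $p \ge 0.5$ by default and the
threshold is swept for ROC/FROC analysis.

Two numerical conventions matter:

* **Convolution vs cross-correlation.** The exported `dilated_conv2d()` is
  the literal convolution sum above. The network layers use the
  framework-standard cross-correlation — equivalent for learning because the
  weights are free parameters — and the tests assert the exact equivalence
  via kernel flipping.
* **Padding.** Zero "same" padding of $d\,k$ pixels per border keeps every
  layer's output at the input resolution.

## Training

**Loss.** The cost is built on the $f_\alpha$ overlap measure
$$f_\alpha(S, T) = \frac{(1+\alpha^2)\sum_i s_i t_i}{\sum_i s_i + \sum_i t_i},$$
with $\alpha = 1$ (the Dice coefficient) by default; the minimized loss is
$1 - f_\alpha$. This form is implemented exactly as written; note it omits
the $\alpha^2$ weighting that the classical $F_\alpha$ carries in its
denominator — at $\alpha = 1$ the two coincide, and the printed form is kept
deliberately. The measure is undefined (0/0) when prediction and truth are
both empty; training therefore adds a smoothing constant (default
$10^{-6}$) to numerator and denominator, while the strict form (which
raises an error) remains available for formula-level testing. The loss is
pooled over all pixels of a minibatch rather than per patch: tiny masses
make per-patch Dice extremely high-variance, and batch-global pooling is
the stabler choice.

**Patch sampling.** Slices are scanned by a sliding window (origins at
multiples of the stride, window fully inside the slice); a patch is positive
iff the mask is 1 at its central pixel, defined as offset
$\lfloor P/2 \rfloor$ from the origin on each axis — an even-sized patch
has no exact centre, so the floor convention is stated once and used
everywhere. Negatives include patches far from any mass: background regions
carry the information the classifier needs to reject confounders. Because
mass pixels are a small minority, each epoch draws an equal number of
patches per class (with replacement when a class is small), then expands the
draw by rotations of 90°, 180° and 270° — reflections are deliberately not
used, and rotation happens *after* balancing so every epoch sees four
orientations of the same balanced draw. Translation augmentation is
meaningless here (a shifted patch is just another sliding-window patch,
possibly with a different label).

**Optimization.** Adagrad at learning rate 0.01, the method's stated
setting. Weights use He-style initialization; biases start at zero; batch
normalization starts at scale 1 / shift 0 with running statistics (momentum
0.1) used at inference. Everything is seeded: weight init, per-epoch
sampling (epoch seeds derived from the master seed by a fixed 31-bit
recurrence), and hence the whole training trajectory — two runs with the
same seed are bit-identical.

**Scale profiles.** The full-scale profile (`default_config("paper")`)
is patch 256, stride 28, batch 150, 1000 epochs, and a per-class epoch draw
of 18 750 (which after 4-fold rotation expansion is exactly 1000 batches of
150). That schedule is far beyond a CPU session, so the package ships a
desk profile (`default_config("desk")`): patch 64, stride 16, batch 16, 20
epochs, 12 patches per class per epoch (6 minibatches after augmentation).
The desk profile is the package's own scaling choice; the method parameters
($\alpha$, $\delta$, the 50-voxel rule, the learning rate, the
architecture) are identical in both profiles.

## Preprocessing

Masses are low-contrast bright structures on textured tissue. Enhancement
has two stages, both per slice:

1. **White top-hat**: the slice minus its morphological opening with a disc.
   This extracts bright structures smaller than the disc and flattens the
   smooth background. The disc radius is configurable (desk default 30 px,
   full-scale default 50 px at 0.1 mm/px — larger than the largest in-plane
   mass radius, so whole masses survive the opening); no authoritative
   radius exists, so it is exposed rather than hard-coded. The enhanced
   image is `input + top-hat`, rescaled to $[0,1]$ — the standard
   contrast-enhancement use of the white top-hat.
2. **RBF constraint matrix**: candidate mass centres are detected on the
   top-hat response as per-slice local maxima above a per-volume percentile,
   thinned to a minimum separation (highest response wins). Each slice then
   gets $M(\mathbf p) = \max_c \exp(-\lVert\mathbf p - \mathbf c\rVert^2 /
   (2\sigma^2))$ with $\sigma = \delta / \text{pixel spacing}$ and
   $\delta = 5$ mm by default; the enhanced slice is multiplied by $M$.
   The Gaussian is used because it is the canonical isotropic radial basis
   function parameterized by a variance. Candidates are combined by
   pointwise maximum (keeps $M \le 1$ and treats candidates independently);
   slices with no candidate receive a configurable floor (default 1 =
   pass-through, so an empty slice is not suppressed). The constraint is
   applied identically at training and inference time; both the top-hat and
   the constraint can be disabled in config.

The candidate-detection rule itself (percentile + minimum separation) is
the package's design: some such localizer must exist for the constraint
matrix to be centred on anything, and exposing it entirely in config means
it can be bypassed or replaced. In-plane pixel pitch is required metadata
(default 0.1 mm/px, 1 mm slice spacing) rather than read from TIFF tags:
the δ-to-pixels conversion must never be silently wrong.

## Postprocessing

Heatmap → mask in three deterministic steps: threshold (inclusive at the
boundary), removal of 3D connected components with **strictly fewer than
50 voxels** (26-connectivity by default — the most inclusive choice, since
the rule is stated over volumes without a connectivity; 6/18 and a
per-slice 2D mode are available), then per-slice binary median smoothing
(3×3 window, zero padding; the median of an odd binary window is the
majority vote). Cluster removal precedes smoothing, matching the stated
order of operations; smoothing can legitimately shrink a surviving
component below 50 voxels and no re-filtering is applied.

## Evaluation

Pixel level: the confusion counts give ACC, SEN and SPE; a metric with an
empty denominator raises an error rather than returning NaN. ROC AUC is
computed by trapezoidal integration over all score thresholds, which equals
the Mann–Whitney rank statistic (asserted to $10^{-9}$ in tests); it is
pooled over all voxels of the evaluated set, consistent with the pixel-wise
ACC definition.

Lesion level (FROC): at each threshold of a decreasing sweep, every volume
is postprocessed by the deployed pipeline, and predicted components are
matched to ground-truth lesion instances. A lesion is *identified* when at
least one predicted-component voxel overlaps it; a component overlapping no
lesion is one false positive. TPR is pooled over lesions; FPV is false
positives per volume. Any-voxel overlap is the default match rule because
no authoritative rule exists; overlap-fraction and centroid-inside-lesion
variants sit behind `match_rule`. Postprocessing runs *inside* the sweep so
the curve describes the deployed system, not raw thresholding.

Cross-validation splits volumes (never patches) into near-equal folds;
`crossval_report()` aggregates per-fold metrics as mean ± sample SD.

## The synthetic phantom

Clinical DBT data is private, so the package carries a seeded generator
(`phantom_spec()`, `generate_phantom()`) that emulates the statistical
structure the method assumes, not breast anatomy:

* **Background**: Gaussian-blurred white noise (in-plane σ 6 px), lightly
  coupled across slices, scaled into a mid-gray band (default
  $[0.25, 0.65]$). The band emulates the limited dynamic range of
  soft-tissue backgrounds; full-range texture would bury a low-contrast
  mass under background variation larger than the mass signal itself.
* **Lesions**: soft-edged ellipsoids (raised-cosine margin over ±25% of the
  radius) rather than hard spheres — real masses have diffuse margins, and
  hard edges would make the task trivially easy and mask bugs. The
  intensity elevation is `contrast × mean background` (default contrast
  0.35), i.e. masses are consistently bright structures; the ground-truth
  mask is the half-maximum surface of the profile. Placement is uniform
  with non-overlap and boundary margins, with a bounded retry count and a
  loud failure when the volume is too small.
* **Noise**: the clean image is scaled to expected photon counts (default
  5000 at unit intensity), Poisson-sampled voxelwise, and rescaled to
  $[0, 1]$ — matching the Poisson character of low-dose imaging without
  modelling detector physics.
* **Desk geometry**: 16 slices of 128×128 px at 0.1 mm/px and 1 mm slice
  spacing, mass diameters 2–5 mm (so in-plane extents of 20–50 px), 1–3
  masses per volume. The full-scale geometry (≈69 slices of 1200×901,
  masses up to ~38 mm) is reachable through the same spec.

What passing tests on phantoms do **not** show: robustness to
reconstruction artifacts, spiculated or calcified morphology, pectoral
muscle and skin line, inter-scanner intensity variation, or annotation
noise. The phantom establishes that the implementation can learn and
recover what it is designed to recover; it says nothing about clinical
performance.

## The bundled end-to-end experiment

`run_phantom_experiment(seed)` generates 12 phantom volumes, preprocesses
all of them, trains the default network on the first 9 at the desk profile,
and scores the held-out 3: per-volume Dice of the final masks, pooled pixel
ACC/SEN/SPE/AUC, and the FROC operating point at a 4-FPV budget, alongside
the same scores for the untrained initialization as a floor reference.
These problem sizes are the package's chosen desk-scale study conditions;
`scripts/acceptance.R` re-runs exactly this experiment and writes the
numbers as JSON.

## Known limitations

* Training on CPU in R is practical only at desk scale; the full-scale
  schedule is supported in configuration but expects hours of compute.
* Batch normalization statistics are learned on balanced, zero-padded
  patches and applied to full slices at inference; at patch sizes near the
  receptive field this train/test mismatch is visible, and the desk profile
  simply trains through it. Larger patches reduce the mismatch.
* The 1-based indexing convention of R is used throughout (origins
  `1 + i·stride`); the patch-count formula is unaffected.
* `read_volume()` treats 8- and 16-bit TIFF pages as integer data (returned
  on their native scale, bit-exact round trip) and 32-bit pages as float;
  32-bit integer TIFFs are not supported.
* Lesion instances are tracked by the generator (`lesion_ids`); masks
  re-read from TIFF lose instance identity and must be re-labelled with
  `label_components()` before FROC analysis.
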