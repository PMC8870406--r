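---
title: "Methods: phase-image simulation, gland detection and core diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-image simulation, gland detection and core diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimscreen)
```

## The screening problem

Colorectal screening by histopathology rests on gland morphology: normal
colon mucosa shows ring-shaped epithelial glands with smooth, regular
boundaries around open lumens, while adenocarcinoma shows irregular,
eroded, partially fused glands. Spatial light interference microscopy
(SLIM) measures the specimen-induced optical pathlength per pixel — a
quantitative phase map in radians — without any stain, so the contrast is
an intrinsic tissue property that transfers across instruments.
`slimscreen` implements the full computational chain on such images:

1. four-frame phase-shifting simulation and retrieval (`simulate_frames()`,
   `retrieve_phase()`), plus mosaic stitching (`stitch_tiles()`);
2. synthetic tissue-microarray (TMA) cores with exact ground truth
   (`generate_dataset()`, `render_core()`);
3. gland instance detection and classification (`classical_segment()`,
   `train_detector()`, `detect()`);
4. core-level diagnosis by a 90% gland-vote rule (`classify_core()`);
5. three-level evaluation: detection, classification and diagnosis
   confusion matrices with per-class precision/recall/F1 reports
   (`report()`), confidence sweeps and ROC/AUC.

## Optics: the four-frame interferometric model

At every pixel the image field is the sum of an unscattered component
$U_0$ and a scattered component $U_1$ lagging by $\Delta\phi$, with
amplitude ratio $\beta = |U_1|/|U_0|$. Shifting the unscattered component
by $k\pi/2$ ($k = 0,1,2,3$) gives intensities

$$I_k = |U_0|^2\left(1 + \beta^2 + 2\beta\cos(\Delta\phi + k\pi/2)\right).$$

Retrieval inverts this algebra exactly: $\Delta\phi =
\operatorname{atan2}(I_3 - I_1,\, I_0 - I_2)$; the modulation envelope
$G = \sqrt{(I_0-I_2)^2 + (I_3-I_1)^2} = 4|U_0|^2\beta$ and frame mean
$S = \tfrac14\sum_k I_k = |U_0|^2(1+\beta^2)$ make $|U_0|^2$ and
$|U_1|^2$ the two roots of $x^2 - Sx + (G/4)^2 = 0$; the unscattered
component dominates in transparent tissue and takes the larger root. The
specimen phase is then
$\phi = \operatorname{atan2}(\beta\sin\Delta\phi,\, 1+\beta\cos\Delta\phi)$.

Numerical choices: the discriminant is clamped at zero (it is
$(|U_0|^2(1-\beta^2))^2$ analytically, but roundoff can push it slightly
negative as $\beta \to 1$); pixels with $G < 10^{-12}\,S$ carry no
interference signal and are flagged rather than divided, with $\phi = 0$;
no phase unwrapping is attempted — synthetic phase is constrained to
$(-\pi, \pi]$. On noiseless frames the retrieval is exact to machine
precision for any $\beta \in (0, 1)$, which the test suite uses as the
central optics oracle. Detector noise is additive Gaussian truncated at
zero (a shot-noise approximation); a Poisson mode is available behind a
flag.

Mosaic tiles are assembled at known offsets (no registration) with linear
feathering: per-tile weights ramp linearly across the overlap zone and are
normalized, so wherever all contributing tiles agree the mosaic equals the
common value exactly, and `stitch` after `split` is the identity.

## The synthetic TMA generator

The generator emulates the statistical structure of a real colorectal TMA
so that every downstream stage is testable without patient data. The
reference geometry is a ~1 mm circular core; the default desk-scale image
is 512 × 512 px at an implied 2 px/µm, and every morphological parameter
scales with image size.

A gland boundary is a radial Fourier perturbation of a circle: harmonics
2–8 receive Gaussian amplitudes $\propto 0.85\,k^{-1.1}$ scaled by a
single `irregularity` knob in $[0,1]$ (harmonic 2 supplies ellipticity,
the higher orders the lobed malignant look). The radius profile is
renormalized so its mean equals `base_radius` exactly; `irregularity = 0`
is an exact circle. Class presets:

| parameter | normal | cancer |
|---|---|---|
| irregularity | U(0.03, 0.15) | U(0.45, 0.85) |
| lumen radius fraction | U(0.40, 0.55) | U(0.12, 0.35) |
| peak epithelial phase (rad) | U(1.3, 2.2) | U(1.0, 1.8) |
| base radius (fraction of side) | U(0.055, 0.10) | U(0.055, 0.10) |

Cancer rings additionally receive a multiplicative erosion texture
(clipped at 0.45–1.1 of the nominal amplitude) so their edges are fainter
and less continuous. Stroma is low-pass-filtered Gaussian noise
(correlation length 8 px, mean 0.35 rad, sd 0.10 rad) inside a circular
footprint of radius 0.47 × side; outside it the mounting medium sits near
zero phase. Glands are placed by dart throwing with center spacing at
least 1.12 × the sum of base radii; 4–12 glands per core are drawn by
default (the density this scale supports; full-scale cores carry 2–30).
Each instance mask is the rasterized boundary polygon minus its lumen;
pixels claimed by an earlier gland are trimmed from later ones, and a
gland overlapping beyond 25% of its ring aborts that layout (dataset
materialization then redraws the layout deterministically from the next
derived seed).

The generator is deliberately not photorealistic: it has no crypts,
goblet-cell texture, mucin pools, tissue folds, staining artifacts or
imaging halo. Passing tests therefore demonstrate that the pipeline's
contracts hold on geometry with the right statistical signature
(separable boundary roughness, touching instances, textured background),
not that any fixed performance level transfers to patient tissue.

### Splits

`generate_dataset()` partitions cores with a class-**balanced** rule by
default: train and validation take `round(total * fraction / 2)` cores
per class and test absorbs each class's remainder. With 127 cancer + 131
normal cores at fractions (0.76, 0.12, 0.12) this yields 98/98 train,
15/15 validation and 14/18 test — totals 196/30/32 — i.e. the canonical
composition arises from the stated fractions alone, which is why balanced
is the default rather than per-class proportional allocation (also
available, as is an explicit per-class `composition` override). Whether
an unbalanced test remainder like 14/18 is a deliberate choice or the
arithmetic consequence of balancing the training data cannot be decided
from the composition itself; the package provides both modes and asserts
neither intent. Realized split sizes can deviate from the requested
fractions by up to ~2 cores (the balanced test split absorbs both
remainders).

## Gland detection

### The classical reference segmenter

A deterministic morphological pipeline serves as the reference detector
and test oracle: Gaussian smoothing → epithelial-phase thresholding →
morphological closing → hole filling → watershed splitting on the
distance map → size filter. Two guards make thresholding robust: Otsu's
threshold is computed **within tissue only** (pixels above a 0.1 rad
floor), so the near-zero background outside the core footprint cannot
drive the split; and if the resulting epithelium-to-stroma contrast is
below 0.3 rad the image is declared gland-free (stroma texture alone
never reaches the contrast of real rings). The morphological scales
default to image-size-proportional values (smoothing sigma side/205,
closing radius side/73, watershed tolerance side/51 — 2.5 / 7 / 10 at the
512 px reference), so one parameter set serves any rendering scale.

Each instance is classified by the boundary-roughness statistic
$P^2 / (4\pi A)$ of its hole-filled mask, with the perimeter measured as
the Euclidean length of the 8-connected contour chain: a digitized disk
scores ≈ 1.1, rough lobed boundaries score well above. Instances above
the cutoff 1.35 are called cancer. Scores are the logistic-transformed
margin from the cutoff (slope 10), so confidently smooth or confidently
rough glands score near 1 and borderline shapes near 0.5 — giving the
0.70/0.80/0.90 confidence thresholds real bite. The pipeline is fully
deterministic: identical inputs give byte-identical outputs.

### The trainable two-stage detector

The trainable detector keeps the two-stage anchor-based architecture's
*contract* at desk scale: stage 1 proposes candidate regions (the
morphological machinery run at three permissive threshold offsets, pooled
and de-duplicated); stage 2 scores each candidate with a small MLP over
eight rotation/flip-invariant region descriptors (log area, roughness,
lumen fraction, phase mean/sd, eccentricity, radial coefficient of
variation, relative phase) and a 3-way softmax over background / cancer /
normal. Candidates are labeled by mask IoU against ground truth (≥ 0.5
adopts the matched class, < 0.1 is background, the band between is
excluded), the standard proposal-assignment rule. Training is SGD with
learning rate 0.001, momentum 0.9, weight decay $10^{-4}$ and batch size
1, in the two-phase schedule — `epochs_heads_only` epochs updating only
the softmax head on a frozen hidden layer, then `epochs_all_layers`
epochs updating everything. Per-epoch validation loss is logged and a
checkpoint kept per epoch, so later epochs can be compared
(`detector_at_epoch()`). Anchor generation itself (`generate_anchors()`,
5 scales × 3 ratios = 15 boxes per point, box of scale $s$ and ratio $r$
sized $s\sqrt r \times s/\sqrt r$) is exposed and tested as the
region-proposal geometry.

Augmentation (`augmentation_policy()`) applies horizontal/vertical flips
with probability 0.5 each, a right-angle rotation drawn uniformly from
{none, 90°, 180°, 270°}, and Gaussian blur with sigma ~ U(0, 5) on the
image only; the identical geometric transform is applied to every mask,
preserving instance count and areas. Masks are kept full image size
throughout (no mini-mask resizing, which loses pixels on small objects).

A GPU-scale deep backbone is deliberately out of scope: the reproducible
object here is the training contract (schedule, optimizer, assignment
rule, determinism under a seed, trained-beats-untrained), not any
particular set of weights. Detection scores are per-instance classifier
confidences thresholded after non-maximum suppression (box IoU 0.3);
since detections are sorted by score and greedy matching proceeds in
score order, the detections at a higher confidence threshold are always a
prefix of those at a lower one — the basis of the monotone capture
fractions in the confidence sweep.

## Core diagnosis

`classify_core()` implements the gland-vote rule: a core is cancer when
at least 90% of its glands are cancer, normal when at least 90% are
normal. Conventions the rule itself leaves open are fixed as follows and
exposed as flags: "90%+" is read inclusively (a fraction of exactly 0.90
qualifies; `inclusive = FALSE` gives the strict reading); cores in
neither bucket — mixed fractions strictly between 10% and 90%, or cores
with zero detected glands — receive an explicit `indeterminate` label
rather than a forced binary call; and detections classified into neither
gland class are excluded from the fraction's denominator. The rule is
symmetric under label swap and depends only on the multiset of labels.

## Evaluation

A prediction counts as detecting a ground-truth gland when their mask IoU
reaches 0.5 (the instance-detection convention); matching is greedy,
one-to-one, by descending prediction score. The detection confusion
matrix adds a stroma/background pseudo-class: missed glands fall in its
column, false detections on non-gland tissue in its row — stroma is
evaluation territory, never a trained class. Dropping that row and column
restricts the matrix to detected glands, which is exactly the
classification report. Per-class precision, recall and F1 follow the
usual definitions with empty-column precision set to 0; accuracy is the
trace over the total; macro averages are unweighted, weighted averages
support-weighted. All metrics are held at full precision and rounded to
two decimals only at presentation.

`roc_auc()` integrates the ROC curve trapezoidally with tied scores
grouped at a single threshold, which equals the midrank Mann–Whitney
concordance probability; the tests verify this against an $O(n^2)$
pairwise oracle and against an independent ROC implementation. Capture
fractions at the 0.70/0.80/0.90 confidence thresholds and per-epoch
checkpoint comparison are both provided; whether a published per-epoch
figure shows ROC curves or capture rates is ambiguous when the numbers
coincide, so the package offers both readings and asserts neither.

## Problem sizes and reproducibility

All randomness flows from one top-level seed through derived child seeds
(each kept below $2^{31}$); identical seeds give bit-identical phase
maps, masks, manifests and training histories. The test suite and the
acceptance script run at deliberate desk scales, chosen as the package's
own working sizes: a frozen 20-core set at 512² for the classical
detector's IoU-0.5 regression floor (≥ 80%), 60 cores at 256² with a
5 + 15 epoch schedule for the trained-vs-untrained comparison, 50 seeded
field models for the optics oracle, and $n \le 2000$ score vectors for
the AUC checks.

## Known limitations

* The synthetic task is easier than patient tissue: class-pure cores,
  no dysplasia/hyperplasia morphologies, no halo or shade-off artifacts,
  no inter-patient variability. Absolute performance numbers on it are
  properties of the generator, not clinical claims.
* The trainable detector's proposal stage is shared with the classical
  segmenter, so its recall ceiling is the proposal recall; it
  demonstrates the training contract, not a state-of-the-art detector.
* TIFF output stores samples in [0, 1] with a fixed linear phase mapping
  (quantization ~1.5 nrad) and a JSON sidecar for pixel size; VIA
  annotations carry outer boundaries only, with lumens recoverable from
  the label-image TIFFs.
* Phase unwrapping, SLM calibration and halo correction are out of scope.
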