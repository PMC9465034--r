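---
title: "Methods: pest monitoring from light-trap imagery to outbreak warnings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pest monitoring from light-trap imagery to outbreak warnings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestwatch)
```

`pestwatch` is a desk-scale implementation of an automated pest-monitoring
chain for phototactic insects (moths attracted to a trap lamp): frames of a
falling insect are captured against a fixed background, the background is
removed by a per-pixel Gaussian-mixture model, the insect body is cropped
and identified by one of three classifiers, and daily identification counts
feed a rule-based outbreak warning engine. No field imagery ships with the
package: a synthetic-data module generates every input with exact ground
truth, which is what makes the downstream stages testable.

## The synthetic scene model

`render_sequence()` composites three layers per frame: a gray background
with per-pixel Gaussian noise (default mean 160, noise standard deviation 8
on the 0--255 scale, matching a dimly LED-lit capture channel), a single
elliptical body moving along a supplied trajectory, and transient clutter
blobs (3--10 px, alive for 1--2 frames, spawning with probability 0.05 per
frame) that emulate debris and small non-target insects. The body is
blurred (sigma 1 px by default) *after* the ground-truth mask is recorded,
so masks are exact by construction. `parabolic_trajectory()` starts the
body just above the frame: the insect enters the view while falling, and
the background model therefore sees object-free frames first, as the real
device does between captures.

`make_insect_dataset()` renders CIFAR-style labelled image sets. The three
default classes stand in for the cotton bollworm moth (tan, striped), the
corn borer moth (pale yellow, slender) and *Spodoptera litura* (dark brown,
broad). Classes differ in colour, elongation, size and stripe period, and a
nearest-centroid classifier on mean RGB alone already separates them —
deliberately so: the synthetic task certifies that the training machinery
works, not that the network could cope with visually confusable field
moths. That is the main feature of real data this generator does not
emulate, and accuracy numbers on it must be read accordingly. A fourth
"non-target" class (random blobs, heavy noise) emulates captures of debris
and unknown insects; `color_shift` and `background_mean` shift the body
colours and illumination to mimic the lab-to-field domain gap.

`make_count_series()` produces daily trap counts as deterministic geometric
growth `round(base * growth^day)`, optionally Poisson-sampled around that
mean — the natural count-noise model, and the noiseless mode keeps the
closed forms exact for testing.

## Background subtraction and capture QC

Each pixel-channel maintains a mixture of K = 5 Gaussians updated online:
an observation within 2.5 standard deviations of a component moves that
component toward it with learning rate alpha = 0.01; otherwise the
least-likely component (smallest weight/sd) is replaced. Components sorted
by weight/sd whose cumulative weight reaches T = 0.7 form the background;
a pixel is foreground when any channel fails to match a background
component. The method itself fixes none of these constants, so the usual
adaptive-mixture conventions are adopted and everything is exposed in
`bg_config()`. Masks pass one 3-by-3 morphological opening then closing
(the smallest useful cleanup; larger elements would erase small insects),
and the first 30 frames are burn-in: the mixture needs history before
foreground is meaningful.

`classify_capture()` reproduces the six-way audit of capture quality:
`out_of_view` (no foreground, or the main blob touches the border),
`background_not_removed` (residual foreground beyond the main blob above
1% of the frame), `blurred` (mean gradient magnitude along the main blob's
boundary below `b_min`), `removable_noise` (all secondary blobs under
s_min = 20 px), `nonremovable_noise`, else `clean`. The original screening
was done by eye; these thresholds make it explicit and configurable. The
default `b_min = 10` was set from the sharpness statistic's behaviour on
rendered sequences: sharp bodies at the generator's default blur score
well above it and clearly defocused ones well below, with margin on both
sides (the test suite exercises both regimes). `select_clean()` then
performs the
seeded 400-to-300 per-sample screening used to assemble the lab dataset.

## Dataset construction

`crop_roi()` cuts the 140 x 140 window centred on the mask centroid,
expanding the border by edge replication when the body sits near the frame
edge. `augment()` applies the online training augmentation: rotation by a
random multiple of 90 degrees, horizontal shear with factor uniform in
[0, 0.5] (the "staggered by 0.5" transform is not defined precisely
anywhere; an affine shear with edge-replication fill is the interpretation
used here, and it is configurable), and independent horizontal/vertical
flips. Augmentation happens online during training only — never on
validation or test images.

`split_dataset()` is stratified with largest-remainder rounding, ties
resolved toward train then validation: this reproduces 6300/1350/1350 for
9,000 images at 7:1.5:1.5 and 852/284/284 for 1,420 at 6:2:2 exactly.
`build_dataset2_1()` downsamples the oversized fourth (non-target) class of
the field set to 70 images; whether that rebalancing preceded or followed
the 6:2:2 split is ambiguous, and this package rebalances first, then
splits. `filling_mix()` pads the field set's three target classes with lab
images up to the fourth class's size; `symmetric_mix()` doubles every class
with equal lab/field halves (the fourth class drawing its second half from
an external pool disjoint from the field set). Every image carries a stable
identifier and the mixers refuse to duplicate one within a split.

## The 30-feature descriptor and selection

The classical classifiers use a 30-dimensional descriptor per masked ROI:
9 colour values (mean, sd, skewness per RGB channel over body pixels), 16
texture values (contrast, correlation, energy, homogeneity of the
symmetric, whole-matrix-normalized gray co-occurrence matrix at 0/45/90/135
degrees; 16 gray levels, distance 1), and 5 shape values (area, perimeter,
circularity, eccentricity, extent). The identity of the original 30
features is not recoverable from the source material; this 9+16+5
decomposition is the package's concrete, documented stand-in, with the
order fixed in `feature_names()`. The perimeter uses a Crofton-corrected
edge count (staircase length times pi/4, minus pi for the half-pixel
circumscription of the pixel-square boundary), which is unbiased for
smooth convex bodies — a digital disk scores circularity 1 within 2%.

`select_features()` fits a gradient-boosted tree ensemble with log-loss
(200 trees, depth 3, learning rate 0.1 — none of these are given by the
method description; these are conventional values) and keeps features whose
gain importance reaches the mean importance. With all-zero importances the
selection is empty rather than "everything", since a threshold of zero
would otherwise select all features vacuously.

## Classifiers

**PSO-SVM.** A Gaussian-kernel SVM whose `gamma` and `C` are tuned by a
global-best particle swarm (30 particles, inertia 0.72, cognitive and
social coefficients 1.49, 100 iterations, log10-scaled ranges
gamma in [1e-3, 1e2], C in [1e-2, 1e3]; only the iteration count is
prescribed by the method, the rest are standard PSO settings). The fitness
is 10-fold cross-validated accuracy; since a fitness of 1 cannot be
improved, the search stops early at perfect cross-validation. The SVM fit
itself is delegated to `e1071`; the swarm is implemented here.

**BPNN.** A single-hidden-layer network (sigmoid hidden units, softmax
output) trained by minibatch SGD with exponential learning-rate decay
`lr0 * rate^(t/steps)`, cross-entropy loss with an L2 penalty, weights
initialized from N(0, 1/n_in). The literal `1/n_in` scale is unusually
small — the printed formula may have lost a square root — so
`init_sd = "inv_sqrt"` is available. The empirical hidden-width formula as
printed (`h = m + n + a`) contradicts the stated `h = 3` for 11 inputs and
3 outputs, so the hidden width is exposed directly with default 3.

**Residual network.** The 56-layer full pre-activation residual classifier
is implemented from scratch in C++ (single precision, im2col + GEMM
convolutions, hand-written batch-normalization backward, Adam): stem
convolution, three stages of nine units with widths 16/32/64, each unit
BN -> ReLU -> conv -> BN -> ReLU -> conv with an identity skip, 1x1
projections only at the two stage boundaries, then BN -> ReLU -> global
average pooling -> softmax. Weighted layers count as stem + 54 unit
convolutions + classifier = 56; projections are excluded by the usual
convention. Because every in-stage skip is an identity, the activation
entering any deep unit equals a shallow activation plus the summed branch
outputs — `resnet_unit_trace()` exposes the per-unit activations and the
test suite checks the identity numerically, alongside finite-difference
validation of the analytic gradients.

Training follows the published recipe (batch 16, Adam at 1e-3, online
augmentation, best-on-validation checkpoint with ties to the earlier
epoch); widths follow the CIFAR-scale convention the architecture family
was defined on. Two scheduling observations keep desk runs honest and
fast: a validation error of zero can never be displaced under the
tie-to-earlier rule, so training stops there with a bit-identical result;
and `patience` implements conventional early stopping for everything else.
The full 200-epoch schedule remains the default configuration.

**Transfer update.** `transfer_update()` copies every trunk parameter (and
the BN running statistics) bitwise, discards the classifier head, and
re-creates it for the new class count. Nothing is frozen — all parameters
train on the new data, matching the description that the base model's
parameters continued to change.

## Evaluation and the warning engine

`eval_metrics()` reports the confusion matrix, per-class precision, recall
and F1 (harmonic mean), and overall accuracy (trace over total). A class
with zero support has its recall reported as `NA` and flagged, never
silently zeroed.

The warning engine groups daily counts into 7-day cycles (pest emergence
takes about a week). Cycle 1 tracks each day's increasing rate IR against
the cardinal count — defined here as day 1's count, configurable to a
historical baseline. From cycle 2 the day-on-day rate DIR and the
cycle-on-cycle rate CIR (same weekday, previous cycle) take over, per the
source procedure. Any defined rate in (0, 100]% raises blue, (100, 300]%
orange, above 300% red. Cycle-level grading combines the pest-density band
with the pest-increasing-rate band (PIR: cycle total against the first
cycle's total); the published table does not say how the two bands combine,
so the engine takes the maximum — conservative for crop protection — and
reports both sub-levels. Bands are right-closed, matching the "at most 5"
first band; the published rate row lists ">300%" for both levels 4 and 5,
which cannot partition, so level 5 is read as above 500% (the lookup is
configurable). Zero-baseline rates are flagged rather than invented: a
positive count over a zero baseline raises at least orange; negative rates
never warn. Pest density per cycle is the mean daily count (insects per
trap-day), a choice the package documents rather than inherits.

## Numerical choices and problem sizes

Images are 0--255 double arrays in R and are scaled to [-0.5, 0.5] floats
inside the network. The network trains in single precision; test
reproducibility tolerances are set accordingly (exact seeds give identical
epoch histories up to float accumulation order, which is deterministic on
one thread). GLCM correlation of a degenerate single-level matrix is
defined as 1. The test suite and the acceptance script use desk-scale
problem sizes chosen so each check exercises the full code path in minutes:
900-image 32 px training sets (the smallest CIFAR-like size at which the
56-layer network is meaningfully deep), 20 sequences of 500 frames at
200 x 200 px for subtraction quality, and toy class-size vectors taken
from the published dataset arithmetic for the bookkeeping rules.

## Known limitations

The synthetic classes are far more separable than field imagery; absolute
accuracies here say nothing about field accuracy. The background model
assumes a static camera and background; ghosting after long stationarity
is not modelled away. The feature list and several training constants are
stated package choices where the source material is silent, as flagged
above; all are configurable rather than baked in.
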