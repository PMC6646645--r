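---
title: "From gaze traces to segmentation masks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gaze traces to segmentation masks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Training data for semantic segmentation of medical images is expensive:
every image needs a per-pixel mask, conventionally drawn by hand by an
expert. Eye tracking offers a cheaper channel. A reader who visually traces
the border of a lesion produces, at 60 Hz, a cloud of gaze samples hugging
that border; the convex hull of the in-window samples is already a usable
segmentation mask. `gazemask` implements that pipeline end to end and, more
importantly, implements the evaluation needed to decide whether such
gaze-derived (ET) masks can replace hand-annotated (HA) masks as training
labels: paired Dice comparisons, trimmed means, cluster-size-threshold
ROC/AUC, and TOST equivalence testing on twin networks trained from each
mask source.

Because real gaze recordings over clinical images are not shipped with the
package, a synthetic module generates lesion phantoms with exact ground
truth and simulates the tracing behaviour itself. Every claim the package
makes is therefore testable offline, at the price of simulation realism
(discussed at the end).

## Gaze recordings and trace extraction

A recording is an ordered table of `(t, x, y, valid)` samples at a nominal
60 Hz. Coordinates are image pixels, origin at the top-left pixel center,
`x` = column, `y` = row, both 0-based; times are seconds. Two policies are
deliberate:

* **Invalid samples are kept but flagged.** Tracker dropouts break fixation
  runs but do not shift indices; traces simply skip them.
* **Off-frame samples are clamped to the frame and flagged**, not dropped,
  so a trace that grazes the image edge stays continuous under tracker
  jitter.

The boundary trace for a structure is defined by a closed time window
`[t_start, t_stop]`: every *valid* sample with `t_start <= t <= t_stop`,
in time order. Everything outside the window -- the initial search, glances
elsewhere -- is excluded by construction. Windows come from an explicit
per-structure table, standing in for the manual video review that would
otherwise identify them.

Fixation detection is provided for analysis and QC (masks are built from
raw in-window samples, because the trace is the record of where gaze
actually was, and centroiding would thin the boundary cloud). The detector
is dispersion-threshold identification (I-DT): a fixation is a maximal run
of consecutive valid samples whose bounding-box half-diagonal stays within
the dispersion radius (default 25 px) and whose duration reaches the
minimum (default 0.1 s). I-DT was chosen because it is the standard
parameter-light identification scheme and is trivially checkable against
an exhaustive brute-force run search, which the test suite does.

## Mask rasterization

ET masks are the convex hull of the trace points; HA masks are filled
polygons (the digital analogue of a clicked region-of-interest polygon);
images without a target get the zero matrix.

The membership rule is fixed and oracle-checkable: **a pixel is set iff its
center lies inside or on the closed region** (even-odd rule for general
polygons). Degenerate traces stay total rather than silently empty: a
single point sets its nearest pixel; a collinear point set rasterizes as a
one-pixel-wide segment between its extremes. Hull masks are invariant to
point order and duplicates. One consequence of the center-in-closed-hull
rule worth knowing: a trace point that is itself a hull vertex can round to
a pixel whose center falls just outside the hull; such a pixel is
(correctly, per the rule) unset.

Self-intersecting polygons are rejected rather than filled, since an
even-odd fill of a bow-tie is almost never what an annotator intended.

Images and masks are brought to the network's square input size with
bilinear interpolation for images and nearest-neighbour for masks, so masks
stay exactly binary. Aspect ratio is intentionally not preserved (the
conventional square-resize before training). Masks are computed at the
image's native resolution first and resized afterwards: annotation happens
at display resolution, and rounding a hull on a coarse grid first would
discard boundary detail the tracer actually produced.

## The segmentation network

The harness trains a U-net-style encoder-decoder with two 3x3
convolutions per block, ReLU activations, 2x2 max pooling, and a decoder
using nearest-neighbour upsampling followed by convolutions over the
concatenated skip connection, ending in a 1x1 output convolution and a
sigmoid. Weights start Glorot-normal with mean zero. The loss is the
negative soft Dice coefficient with smoothing constant 1 added to numerator
and denominator (so empty masks are well-defined: a perfect prediction
scores -1 within the smoothing tolerance, a fully wrong one approaches 0).
Optimization is Adam. The convolution forward/backward passes are im2col +
BLAS matrix products in compiled code; the backward pass is verified
against finite differences in the test suite.

Two configurations are exposed:

* `trainConfig()` -- the desk scale used throughout the tests: 64x64
  inputs, 2 pooling levels, 8 base filters (11 convolutional layers),
  batch 8, 50 epochs, Adam step 1e-3, 20 test images. This trains in a few
  minutes on one CPU, which is what makes the full twin-arm experiment a
  runnable test. The step length matters: 1e-5 is tuned for a 600-epoch
  schedule and barely moves a network in 50 epochs, so the desk default
  uses 1e-3.
* `paperTrainConfig()` -- the full-scale protocol: 256x256 inputs, 4
  levels, 16 base filters (19 convolutional layers counting the output),
  600 epochs, Adam step 1e-5, 50 test images. Expect hours of CPU time.

Splitting holds the test set out of the *lesion* images only; normal
images all stay on the training side, where their role is teaching the
network specificity. The remainder splits 80/20 train/validation. With 356
lesion images and 50 test images this reproduces the canonical 245/61/50
partition. Everything -- split, initialization, shuffling -- derives from
one seed, and the two experiment arms share split, seed and initial
weights, so the mask source is the only difference between them.

Prediction returns raw probability maps; binarization (at 0.5, a
convention, since the loss is symmetric around neither class) and any
cluster filtering belong to the evaluation stage.

## Evaluation statistics

**Dice.** `2|A∩B| / (|A|+|B|)`; two empty masks agree perfectly (1),
exactly one empty gives 0. The gold standard throughout the experiment is
the HA mask -- a deliberately strict choice for the ET arm, which is never
compared against its own training labels.

**Trimmed mean.** Drops `floor(n*f)` smallest and largest values per side
(default f = 0.1, exposed in config; the summary should survive a few
catastrophic test images without hiding the typical case).

**Cluster-size ROC.** Post-processing predictions by deleting small
connected components is the standard defence against scattered false
positives; sweeping the area threshold yields an ROC. Components are
8-connected (the usual choice for blob post-processing in 2-D). For each
threshold s, every predicted component smaller than s pixels is deleted,
surviving pixels are pooled across the test images, and (FPR, TPR) is
computed against the gold masks. Both rates are non-increasing in s, so the
curve runs from the raw-prediction point down to (0,0). Two completion
points define the AUC: (0,0) (everything deleted) and a horizontal
extension from the loosest-threshold point to FPR = 1, reflecting that no
threshold can predict *more* than the raw prediction. This makes the AUC
attain 1 for a perfect predictor and 0 for an empty one, the two anchor
cases it must satisfy.

**TOST.** Failing to reject "no difference" does not show equivalence, so
the arms are compared with two one-sided paired t tests against symmetric
bounds (-SESOI, +SESOI), SESOI = 0.1 on the Dice scale, alpha = 0.05. The
reported decision p value is the maximum of the two one-sided p values.
Degenerate zero-variance differences (e.g. literally identical vectors)
have no t statistic; the report then uses p = 0 when the mean difference
is strictly inside the bounds, p = 1 strictly outside, and p = 0.5 exactly
on a bound.

## The synthetic study

`phantomSpec()` describes contrast-enhancing lesion phantoms on noisy
backgrounds: a 256x256 frame, an elliptical (convex) or smooth-blob
(harmonically perturbed, possibly non-convex) lesion of radius 20-50 px,
background intensity 0.35, lesion 0.75, pixel noise sd 0.08, Gaussian edge
blur sigma 1.5, and up to two small bright distractor spots per image. The
distractors exist to make specificity non-trivial: they give a trained
network something to falsely segment, which is exactly the failure mode
cluster-size thresholding addresses. Lesion presence defaults to 0.84,
roughly five lesion images per normal, the mix used by the study design
this emulates.

`scanpathSpec()` describes the tracing behaviour: 60 Hz sampling, 1 s of
off-lesion search before the trace (detection latency), 4 s on the
boundary (a medium lesion takes a few seconds to trace at a comfortable
angular speed), isotropic Gaussian jitter of sd 2 px, 10% of the boundary
replaced by straight chord cuts (the corner-cutting a fatigued tracer
produces), counterclockwise traversal, and half a second of drift away
after the trace. The simulated gaze follows the lesion's *visible edge* --
the outline of the boundary pixels, half a pixel outside their centers --
because that is what a human traces; at zero noise the pipeline then
recovers convex truth masks with Dice above 0.99, a property the test
suite asserts over 50 phantoms.

Simulated hand annotations subsample the analytic lesion boundary to 16
vertices and perturb them with 1 px Gaussian noise, approximating a human
clicking a coarse polygon; so ET-vs-HA comparisons have realistic nonzero
disagreement on both sides.

Phantoms, scanpaths and annotations are all generated at the native
256x256 resolution; the training stage then resizes to the 64x64 network
input. The order matters: jitter is a property of gaze on the display, and
simulating it directly on a 64x64 grid would quadruple its relative
magnitude and misrepresent the annotation noise the experiment is about.

Every image derives its own sub-seeds from one master seed, so a dataset
regenerates bit-identically.

**Problem sizes.** The test suite and the acceptance script use: 100
lesion + 20 normal phantoms for the twin-arm experiment (20 test images),
50 phantoms for zero-noise recovery, 100 phantoms per jitter level for the
monotonicity check, and a 6-image corpus for file-level reproducibility
checks. These sizes keep the full suite in the minutes range on one CPU
while leaving each property comfortably away from sampling noise.

## What the simulation does and does not show

The generator reproduces the *mechanics* of gaze annotation: sampling
rate, detection latency, boundary jitter, corner cutting, coarse hand
polygons, class mix, and the resolution pipeline. Passing tests therefore
show that the pipeline is correct and that the equivalence methodology
behaves as designed under controlled noise.

It does not reproduce real anatomy (phantom backgrounds are smooth noise,
not brains), real lesion appearance variability, calibration drift,
saccade dynamics, pupil-size artefacts, multi-lesion images, or
reader-to-reader variability (one simulated "reader" with fixed
parameters). Published headline numbers from comparable human studies were
measured on non-deposited web-scraped images and are not reproducible
here; the package asserts *properties* (arms within 0.1 trimmed-mean Dice,
TOST equivalence, AUCs within 0.05 of each other) rather than those exact
values.

## Numerical and degenerate-input choices

* Rasterization boundary handling uses a relative epsilon on the
  point-to-edge cross product; points on an edge are always inside.
* Hull degeneracies (1 point, collinear sets) produce the nearest pixel /
  a 1-px segment, never an empty mask.
* Dice of two empty masks is 1; one empty, 0. The Dice loss epsilon is 1.0.
* Timestamps must be strictly increasing; ties are rejected at parse time
  with the offending row number.
* Constant images cannot be normalized and raise an error rather than
  returning NaNs.
* TOST zero-variance branches are defined above; n < 3 pairs is an error.
* Cluster thresholds must be ascending; the threshold-0 point is the raw
  prediction.
* All RNG flows through explicit seeds; the RNG state of the caller is
  saved and restored around every seeded operation.

## Known limitations

Convex hulls cannot represent concave lesions; the simulator's blob
phantoms quantify the resulting over-coverage (precision below recall on
average) but the pipeline offers no concave refinement by design. The
desk-scale network is far smaller than production segmentation models and
is meant for methodology testing, not deployment. The CLI
(`inst/cli/gaze2mask.R`) wraps the same functions documented here and adds
nothing semantically.
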