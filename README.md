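# gazemask

Segmentation masks from eye-tracking gaze traces — and the statistics to
decide whether they can replace hand annotation.

## The problem

Convolutional segmentation networks need large sets of per-pixel masks,
conventionally drawn by hand by an expert — slow, expensive work done
outside clinical routine. An alternative: let the expert *look*. A reader
who visually traces a lesion's border under a 60 Hz eye tracker produces a
stream of timestamped gaze points hugging that border; the convex hull of
the in-window points is already a segmentation mask. `gazemask` is for
researchers in medical image analysis and visual-attention research who
want to build such eye-tracking (ET) masks from gaze logs and to test,
quantitatively, whether networks trained on ET masks are equivalent to
networks trained on hand-annotated (HA) masks.

## What is inside

For a gaze recording $\{(t_j, x_j, y_j)\}$ and a per-structure window
$[t_{\mathrm{start}}, t_{\mathrm{stop}}]$, the boundary trace is the
ordered set of valid gaze points with
$t_{\mathrm{start}} \le t_j \le t_{\mathrm{stop}}$; the ET mask sets every
pixel whose center lies in the closed convex hull of the trace. HA masks
are filled annotation polygons; images without a target get the zero
matrix. Two U-nets with shared initialization, split and seed are trained
with the negative soft-Dice loss

$$\mathcal{L} = -\frac{2\sum_i p_i y_i + \varepsilon}{\sum_i p_i + \sum_i y_i + \varepsilon},$$

one on ET masks, one on HA masks, and compared on a shared test set
against the HA gold standard with:

* the Dice similarity coefficient $\mathrm{DSC} = 2|A\cap B|/(|A|+|B|)$
  and two-sided trimmed means of per-image DSC;
* an ROC built by deleting 8-connected predicted components below a sweep
  of area thresholds (AUC by trapezoid);
* TOST equivalence testing: two one-sided paired t tests against
  $\pm$SESOI bounds (SESOI = 0.1 on the DSC scale), decision p value =
  max of the two one-sided p values.

A synthetic module generates contrast-enhancing lesion phantoms with exact
ground truth and simulates the tracing behaviour itself (60 Hz sampling,
detection latency, boundary jitter, corner-cutting shortcuts, coarse
hand-annotation polygons), so the entire experiment runs with no external
data. Fixation detection (dispersion-threshold I-DT) is included for
analysing the gaze stream itself.

## A worked example

```r
library(gazemask)
dir <- file.path(tempdir(), "demo")

# a small synthetic corpus: 8 lesion phantoms + 2 normals at 256x256
man <- generateDataset(8, 2, phantomSpec(), scanpathSpec(), dir, seed = 42)

# how well do the gaze-derived masks agree with the hand annotations?
round(maskAgreement(file.path(dir, "manifest.csv")), 3)
#> [1] 0.885

# one image's pipeline, step by step
rec <- readGazeLog(file.path(dir, man$gaze_log[1]), 256, 256)
rec
#> GazeRecording: 330 samples (330 valid) @ 60 Hz, frame 256x256, t in [0.000, 5.483] s

win <- TimeWindow(man$image[1], as.numeric(man$t_start[1]),
                  as.numeric(man$t_stop[1]))
tr <- extractTrace(rec, win)
tr
#> BoundaryTrace 'img0001.png': 240 points

et <- convexHullMask(tr, c(256, 256))
et
#> BinaryMask 256 x 256, 3292 foreground pixels

truth <- readMaskPNG(file.path(dir, man$truth_mask[1]))
round(diceCoef(et, truth), 3)
#> [1] 0.903

detectFixations(rec)
#> FixationSequence: 9 fixations (dispersion 25 px, min duration 0.1 s)
```

The 330 samples are 1 s of off-lesion search, 4 s tracing the border, and
half a second of drift away; only the 240 in-window points enter the mask.
The hull recovers the phantom at DSC 0.90 under the default 2 px of gaze
jitter and 10% corner cutting — and with no noise at all the recovery
exceeds 0.99, a property the test suite asserts.

The full twin-arm experiment is one call (minutes of CPU time):

```r
generateDataset(100, 20, phantomSpec(), scanpathSpec(), "run", seed = 1)
rep <- runExperiment("run/manifest.csv", cfg = trainConfig(seed = 1L))
rep   # trimmed-mean DSC per arm, both AUCs, the TOST verdict
```

A command-line front end wrapping the same functions lives at
`inst/cli/gaze2mask.R`
(`gaze2mask simulate|maskgen|train|evaluate|experiment --config run.yaml`).

## Documentation

The methods vignette (`vignettes/gaze-to-mask.Rmd`) documents the model
and its assumptions, every tunable parameter with units and defaults, the
simulator's scope and limits, and the numerical conventions (degenerate
hulls, empty-mask Dice, TOST zero-variance branches, the ROC completion
rule).
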