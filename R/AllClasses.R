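# S4 classes for the gaze-to-mask pipeline. Coordinates are image-pixel
# coordinates throughout: origin at the top-left pixel center, x = column,
# y = row, both 0-based; times are seconds.

#' Binary segmentation mask
#'
#' A 2-D raster of \{0,1\} values aligned to an image, the unit exchanged
#' between every stage of the pipeline. On disk masks are stored as 8-bit
#' grayscale PNG with values \{0,255\}; in memory they are \{0,1\}.
#'
#' @slot grid numeric matrix with values exactly 0 or 1.
#' @export
setClass("BinaryMask", representation(grid = "matrix"), validity = function(object) {
  if (!is.numeric(object@grid)) return("grid must be numeric")
  if (!all(object@grid %in% c(0, 1))) return("grid values must be exactly 0 or 1")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param grid numeric matrix of 0/1 values.
#' @return a \code{BinaryMask}.
#' @export
BinaryMask <- function(grid) {
  storage.mode(grid) <- "double"
  new("BinaryMask", grid = grid)
}

#' Extract the 0/1 matrix from a BinaryMask
#' @param x a \code{BinaryMask}.
#' @return numeric matrix.
#' @export
maskMatrix <- function(x) as_mask_matrix(x)

#' @describeIn BinaryMask-class mask dimensions (rows, cols)
#' @param x a \code{BinaryMask}.
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@grid))

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d, %d foreground pixels\n",
              nrow(object@grid), ncol(object@grid), sum(object@grid)))
})

#' Gaze recording
#'
#' Ordered, timestamped gaze samples in image-pixel coordinates, as sampled
#' by a remote eye tracker (nominally at 60 Hz). Samples with a lost tracker
#' lock are kept but flagged invalid; off-frame samples are clamped to the
#' frame and flagged.
#'
#' @slot samples data.frame with columns \code{t} (seconds, strictly
#'   increasing), \code{x}, \code{y} (pixels), \code{valid} (0/1) and
#'   \code{clamped} (logical).
#' @slot rateHz nominal sampling rate.
#' @slot frameWidth,frameHeight image frame size in pixels.
#' @export
setClass("GazeRecording",
  representation(samples = "data.frame", rateHz = "numeric",
                 frameWidth = "integer", frameHeight = "integer"),
  validity = function(object) {
    s <- object@samples
    need <- c("t", "x", "y", "valid", "clamped")
    if (!all(need %in% names(s))) return("samples must have t,x,y,valid,clamped")
    if (nrow(s) > 1 && any(diff(s$t) <= 0))
      return("timestamps must be strictly increasing")
    if (any(!is.finite(s$t))) return("timestamps must be finite")
    v <- s$valid == 1
    if (any(v & (!is.finite(s$x) | !is.finite(s$y))))
      return("valid samples must have finite x,y")
    if (object@rateHz <= 0) return("rateHz must be positive")
    TRUE
  })

setMethod("show", "GazeRecording", function(object) {
  s <- object@samples
  cat(sprintf("GazeRecording: %d samples (%d valid) @ %g Hz, frame %dx%d, t in [%.3f, %.3f] s\n",
              nrow(s), sum(s$valid == 1), object@rateHz,
              object@frameWidth, object@frameHeight,
              if (nrow(s)) min(s$t) else NA, if (nrow(s)) max(s$t) else NA))
})

#' Access the sample table of a GazeRecording
#' @param rec a \code{GazeRecording}.
#' @return data.frame of samples.
#' @export
gazeSamples <- function(rec) rec@samples

#' Per-structure annotation time window
#'
#' The closed interval [tStart, tStop] during which the reader's gaze was
#' tracing one structure's border; everything outside the window (search,
#' off-lesion fixations) is excluded from the boundary trace.
#'
#' @slot structureId identifier of the traced structure.
#' @slot tStart,tStop window bounds in seconds, 0 <= tStart <= tStop.
#' @export
setClass("TimeWindow",
  representation(structureId = "character", tStart = "numeric", tStop = "numeric"),
  validity = function(object) {
    if (!is.finite(object@tStart) || !is.finite(object@tStop))
      return("window bounds must be finite")
    if (object@tStart < 0) return("tStart must be non-negative")
    if (object@tStart > object@tStop) return("tStart must be <= tStop")
    TRUE
  })

#' Construct a TimeWindow
#' @param structureId identifier.
#' @param tStart,tStop bounds in seconds.
#' @return a \code{TimeWindow}.
#' @export
TimeWindow <- function(structureId, tStart, tStop) {
  new("TimeWindow", structureId = as.character(structureId),
      tStart = as.numeric(tStart), tStop = as.numeric(tStop))
}

setMethod("show", "TimeWindow", function(object) {
  cat(sprintf("TimeWindow '%s': [%.3f, %.3f] s\n",
              object@structureId, object@tStart, object@tStop))
})

#' Boundary trace
#'
#' The time-ordered (x, y) gaze points recorded while one structure's border
#' was being traced; the raw material from which a convex-hull mask is built.
#'
#' @slot structureId identifier of the traced structure.
#' @slot points n x 2 matrix with columns x, y (pixels, time order).
#' @export
setClass("BoundaryTrace",
  representation(structureId = "character", points = "matrix"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 2) return("points must be an n x 2 matrix")
    if (nrow(p) < 1) return("trace must contain at least one point")
    if (any(!is.finite(p))) return("trace points must be finite")
    TRUE
  })

BoundaryTrace <- function(structureId, points) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y")
  new("BoundaryTrace", structureId = as.character(structureId), points = points)
}

setMethod("show", "BoundaryTrace", function(object) {
  cat(sprintf("BoundaryTrace '%s': %d points\n",
              object@structureId, nrow(object@points)))
})

#' Access the point matrix of a BoundaryTrace
#' @param trace a \code{BoundaryTrace}.
#' @return n x 2 matrix (x, y).
#' @export
tracePoints <- function(trace) trace@points

#' Fixation sequence
#'
#' Fixations detected by dispersion-threshold identification (I-DT):
#' maximal runs of consecutive valid samples whose bounding-box
#' half-diagonal stays within the dispersion radius and whose duration
#' reaches the minimum. Provided for analysis and QC; masks are built from
#' raw in-window samples, not fixation centroids.
#'
#' @slot fixations data.frame with columns x, y (centroid), onset, duration.
#' @slot dispersionPx,minDurS parameters used for detection.
#' @export
setClass("FixationSequence",
  representation(fixations = "data.frame", dispersionPx = "numeric",
                 minDurS = "numeric"))

setMethod("show", "FixationSequence", function(object) {
  cat(sprintf("FixationSequence: %d fixations (dispersion %g px, min duration %g s)\n",
              nrow(object@fixations), object@dispersionPx, object@minDurS))
})

#' Access the fixation table of a FixationSequence
#' @param x a \code{FixationSequence}.
#' @return data.frame with centroid x, y, onset, duration.
#' @export
fixations <- function(x) x@fixations

#' Annotated phantom image
#'
#' A grayscale phantom with its ground-truth lesion mask. For label
#' "normal" the truth mask is the zero matrix. The analytic lesion boundary
#' polygon (if any) is kept so that simulated hand annotations can perturb
#' its vertices.
#'
#' @slot image grayscale matrix in [0,1].
#' @slot truthMask a \code{BinaryMask}.
#' @slot label "lesion" or "normal".
#' @slot boundary k x 2 matrix of boundary polygon vertices (0 rows if none).
#' @export
setClass("AnnotatedImage",
  representation(image = "matrix", truthMask = "BinaryMask",
                 label = "character", boundary = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@image), dim(object@truthMask@grid)))
      return("image and truth mask dimensions differ")
    if (!object@label %in% c("lesion", "normal"))
      return("label must be 'lesion' or 'normal'")
    if (object@label == "normal" && sum(object@truthMask@grid) != 0)
      return("a normal image must have an all-zero truth mask")
    TRUE
  })

setMethod("show", "AnnotatedImage", function(object) {
  cat(sprintf("AnnotatedImage (%s): %d x %d, truth area %d px\n",
              object@label, nrow(object@image), ncol(object@image),
              sum(object@truthMask@grid)))
})

#' ROC curve over cluster-size thresholds
#'
#' Pixel-pooled (FPR, TPR) operating points obtained by deleting
#' 8-connected predicted components below a sweep of area thresholds,
#' scored against hand-annotation masks as the gold standard.
#'
#' @slot thresholds area cutoffs in pixels (ascending).
#' @slot fpr,tpr operating points per threshold.
#' @slot auc trapezoidal area under the curve.
#' @slot counts data.frame of pooled tp, fp, fn, tn per threshold.
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric", counts = "data.frame"),
  validity = function(object) {
    if (any(object@fpr < -1e-12 | object@fpr > 1 + 1e-12) ||
        any(object@tpr < -1e-12 | object@tpr > 1 + 1e-12))
      return("FPR and TPR must lie in [0,1]")
    TRUE
  })

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d thresholds, AUC = %.4f\n",
              length(object@thresholds), object@auc))
})

#' AUC of a RocCurve
#' @param x a \code{RocCurve}.
#' @return numeric AUC.
#' @export
aucValue <- function(x) x@auc

#' Operating points of a RocCurve
#' @param x a \code{RocCurve}.
#' @return data.frame with threshold, fpr, tpr.
#' @export
rocPoints <- function(x) data.frame(threshold = x@thresholds, fpr = x@fpr, tpr = x@tpr)

#' TOST equivalence report
#'
#' Result of the paired two one-sided test: the mean paired difference, the
#' symmetric equivalence bounds (+/- SESOI), the decision p value (maximum
#' of the two one-sided p values) and the verdict at level alpha.
#'
#' @slot deltaLower,deltaUpper equivalence bounds.
#' @slot sesoi smallest effect size of interest.
#' @slot alpha test level.
#' @slot meanDiff mean paired difference.
#' @slot pLower,pUpper the two one-sided p values.
#' @slot pValue decision p value, max(pLower, pUpper).
#' @slot equivalent TRUE iff pValue < alpha.
#' @slot n number of pairs.
#' @export
setClass("EquivalenceReport",
  representation(deltaLower = "numeric", deltaUpper = "numeric",
                 sesoi = "numeric", alpha = "numeric", meanDiff = "numeric",
                 pLower = "numeric", pUpper = "numeric", pValue = "numeric",
                 equivalent = "logical", n = "integer"),
  validity = function(object) {
    if (xor(object@equivalent, object@pValue < object@alpha))
      return("equivalent must equal (pValue < alpha)")
    TRUE
  })

setMethod("show", "EquivalenceReport", function(object) {
  cat(sprintf("TOST equivalence (n = %d, SESOI = %g, alpha = %g)\n",
              object@n, object@sesoi, object@alpha))
  cat(sprintf("  mean difference: %.4f in (-%g, %g)\n",
              object@meanDiff, object@sesoi, object@sesoi))
  cat(sprintf("  p = %.4g -> %s\n", object@pValue,
              if (object@equivalent) "equivalent" else "not equivalent"))
})

#' Decision p value of an EquivalenceReport
#' @param x an \code{EquivalenceReport}.
#' @return numeric p value.
#' @export
pValue <- function(x) x@pValue

#' Equivalence verdict of an EquivalenceReport
#' @param x an \code{EquivalenceReport}.
#' @return logical.
#' @export
isEquivalent <- function(x) x@equivalent
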