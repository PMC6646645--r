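# The twin-arm experiment: train one U-net on ET masks and one on HA masks
# of the same dataset, predict on a shared test split, and compare the arms
# with trimmed-mean Dice, cluster-size ROC/AUC and TOST equivalence.

#' Experiment report
#'
#' Everything the ET-versus-HA comparison produces: paired per-test-image
#' Dice scores of both arms against the hand-annotation gold standard,
#' trimmed means, the TOST equivalence verdict, both ROC curves, and the
#' mask-agreement summary (mean Dice between ET and HA masks themselves).
#'
#' @slot dicePairs data.frame: image, dsc_et, dsc_ha per test image.
#' @slot trimFrac trim fraction used for the summary means.
#' @slot trimmedMeanET,trimmedMeanHA trimmed-mean test Dice per arm.
#' @slot tost an \linkS4class{EquivalenceReport} on the paired Dice vectors.
#' @slot rocET,rocHA \linkS4class{RocCurve} per arm.
#' @slot maskAgreement mean Dice between ET and HA masks over lesion images.
#' @slot historyET,historyHA per-epoch training histories.
#' @slot split the train/val/test row indices used (shared by both arms).
#' @slot seed master seed of the run.
#' @export
setClass("ExperimentReport",
  representation(dicePairs = "data.frame", trimFrac = "numeric",
                 trimmedMeanET = "numeric", trimmedMeanHA = "numeric",
                 tost = "EquivalenceReport", rocET = "RocCurve",
                 rocHA = "RocCurve", maskAgreement = "numeric",
                 historyET = "data.frame", historyHA = "data.frame",
                 split = "list", seed = "integer"))

setMethod("show", "ExperimentReport", function(object) {
  cat("ET-versus-HA segmentation experiment\n")
  cat(sprintf("  test images: %d\n", nrow(object@dicePairs)))
  cat(sprintf("  mask agreement (ET vs HA): mean DSC %.3f\n",
              object@maskAgreement))
  cat(sprintf("  trimmed-mean test DSC: ET %.3f, HA %.3f (trim %g)\n",
              object@trimmedMeanET, object@trimmedMeanHA, object@trimFrac))
  cat(sprintf("  AUC: ET %.3f, HA %.3f\n", object@rocET@auc, object@rocHA@auc))
  cat(sprintf("  TOST: p = %.4g -> %s\n", object@tost@pValue,
              if (object@tost@equivalent) "equivalent" else "not equivalent"))
})

#' Access the paired per-image Dice table of an ExperimentReport
#' @param x an \linkS4class{ExperimentReport}.
#' @return data.frame with image, dsc_et, dsc_ha.
#' @export
dicePairs <- function(x) x@dicePairs

#' Mean Dice agreement between ET and HA masks of a dataset
#'
#' The direct mask-to-mask comparison (no network involved): mean Dice
#' between the gaze-derived and hand-annotated masks over all lesion
#' images of a dataset.
#'
#' @param manifest manifest data.frame or path to manifest.csv.
#' @param dir directory the manifest paths are relative to.
#' @return mean Dice coefficient.
#' @export
maskAgreement <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- read.csv(manifest, check.names = FALSE)
  }
  if (is.null(dir)) dir <- "."
  rows <- which(manifest$label == "lesion")
  if (!length(rows)) stop("manifest contains no lesion images")
  mean(vapply(rows, function(i) {
    et <- readMaskPNG(file.path(dir, manifest$et_mask[i]))
    ha <- readMaskPNG(file.path(dir, manifest$ha_mask[i]))
    diceCoef(et, ha)
  }, 0))
}

#' Run the full ET-versus-HA experiment on a dataset
#'
#' Trains twin U-nets -- one on eye-tracking masks, one on hand-annotation
#' masks -- with the same split, seed and initial weights, so the mask
#' source is the only difference between arms. Both arms predict the shared
#' test split; predictions are binarized at 0.5 and scored against the HA
#' masks as the gold standard. Reports paired Dice scores, trimmed means,
#' cluster-size-threshold ROC/AUC per arm, and the TOST equivalence verdict
#' on the paired Dice vectors.
#'
#' @param manifest manifest data.frame or path to manifest.csv.
#' @param dir directory the manifest paths are relative to.
#' @param cfg a \linkS4class{TrainConfig} shared by both arms.
#' @param trimFrac trim fraction for the summary means (default 0.1/side).
#' @param sesoi equivalence margin for TOST (default 0.1).
#' @param alpha TOST level (default 0.05).
#' @param thresholds cluster-size sweep for the ROC curves.
#' @param verbose print training progress.
#' @return an \linkS4class{ExperimentReport}.
#' @export
runExperiment <- function(manifest, dir = NULL, cfg = trainConfig(),
                          trimFrac = 0.1, sesoi = 0.1, alpha = 0.05,
                          thresholds = c(0, 2, 5, 10, 20, 40, 80, 160),
                          verbose = FALSE) {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- read.csv(manifest, check.names = FALSE)
  }
  if (is.null(dir)) dir <- "."
  split <- splitDataset(manifest, cfg)
  if (verbose) message("training arm 1/2 (ET masks)")
  modET <- trainUnet(manifest, "et", cfg, dir = dir, split = split,
                     verbose = verbose)
  if (verbose) message("training arm 2/2 (HA masks)")
  modHA <- trainUnet(manifest, "ha", cfg, dir = dir, split = split,
                     verbose = verbose)
  s <- cfg@inputSize
  testImgs <- lapply(split$test, function(i)
    readImagePNG(file.path(dir, manifest$image[i])))
  goldMasks <- lapply(split$test, function(i) {
    msk <- readMaskPNG(file.path(dir, manifest$ha_mask[i]))
    img <- readImagePNG(file.path(dir, manifest$image[i]))
    resizePair(img, msk, c(s, s))$mask
  })
  predET <- predictUnet(modET, testImgs)
  predHA <- predictUnet(modHA, testImgs)
  binET <- lapply(predET, function(p) BinaryMask((p >= 0.5) + 0))
  binHA <- lapply(predHA, function(p) BinaryMask((p >= 0.5) + 0))
  nT <- length(split$test)
  dscET <- vapply(seq_len(nT), function(i) diceCoef(binET[[i]], goldMasks[[i]]), 0)
  dscHA <- vapply(seq_len(nT), function(i) diceCoef(binHA[[i]], goldMasks[[i]]), 0)
  pairs <- data.frame(image = manifest$image[split$test],
                      dsc_et = dscET, dsc_ha = dscHA)
  tost <- tostEquivalence(dscET, dscHA, sesoi = sesoi, alpha = alpha)
  rocET <- sizeThresholdROC(binET, goldMasks, thresholds)
  rocHA <- sizeThresholdROC(binHA, goldMasks, thresholds)
  agree <- maskAgreement(manifest, dir)
  new("ExperimentReport", dicePairs = pairs, trimFrac = trimFrac,
      trimmedMeanET = trimmedMean(dscET, trimFrac),
      trimmedMeanHA = trimmedMean(dscHA, trimFrac),
      tost = tost, rocET = rocET, rocHA = rocHA, maskAgreement = agree,
      historyET = modET@history, historyHA = modHA@history,
      split = split, seed = cfg@seed)
}
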