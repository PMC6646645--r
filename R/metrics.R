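# Evaluation statistics: Dice coefficient, trimmed means,
# cluster-size-threshold ROC/AUC, and TOST equivalence testing.

#' Dice similarity coefficient between two binary masks
#'
#' DSC = 2|A intersect B| / (|A| + |B|). Two empty masks are defined to
#' agree perfectly (DSC 1); exactly one empty mask gives 0.
#'
#' @param a,b \linkS4class{BinaryMask} objects or 0/1 matrices of equal shape.
#' @return DSC in [0,1].
#' @export
diceCoef <- function(a, b) {
  ma <- as_mask_matrix(a, "a"); mb <- as_mask_matrix(b, "b")
  if (!identical(dim(ma), dim(mb)))
    stop("mask shapes differ: ", paste(dim(ma), collapse = "x"), " vs ",
         paste(dim(mb), collapse = "x"))
  sa <- sum(ma); sb <- sum(mb)
  if (sa + sb == 0) return(1)
  2 * sum(ma * mb) / (sa + sb)
}

#' Two-sided trimmed mean
#'
#' Drops floor(n * trimFrac) smallest and largest values and averages the
#' rest; a robust summary for DSC distributions with occasional failures.
#'
#' @param values non-empty numeric vector.
#' @param trimFrac fraction trimmed from each tail, in [0, 0.5).
#' @return numeric.
#' @export
trimmedMean <- function(values, trimFrac = 0.1) {
  if (length(values) == 0) stop("cannot take the trimmed mean of nothing")
  if (trimFrac < 0 || trimFrac >= 0.5) stop("trimFrac must be in [0, 0.5)")
  mean(values, trim = trimFrac)
}

#' Label connected components of a mask
#'
#' @param mask \linkS4class{BinaryMask} or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
labelClusters <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- as_mask_matrix(mask)
  storage.mode(m) <- "integer"
  cpp_label_components(m, as.integer(connectivity))
}

# Remove 8-connected components with area < minSize pixels.
filter_clusters <- function(m, labels, minSize) {
  if (minSize <= 0) return(m)
  if (max(labels) == 0) return(m)
  areas <- tabulate(labels[labels > 0])
  drop <- which(areas < minSize)
  if (length(drop)) m[labels %in% drop] <- 0
  m
}

#' ROC over cluster-size thresholds
#'
#' For each area threshold s, every 8-connected component of each predicted
#' mask with fewer than s pixels is deleted; surviving predicted pixels are
#' pooled across images and scored against the truth masks (TPR = TP/(TP+FN),
#' FPR = FP/(FP+TN)). Because raising s can only shrink the predicted set,
#' both rates are non-increasing in s. The curve is completed with (0,0)
#' (everything deleted) and a horizontal extension from the loosest
#' threshold's point to FPR = 1 (no further pixels can be predicted beyond
#' the raw prediction), and the AUC is the trapezoidal area under it.
#'
#' @param predMasks,truthMasks paired lists of \linkS4class{BinaryMask}
#'   objects (or 0/1 matrices) of matching shapes.
#' @param thresholds non-negative, ascending area cutoffs in pixels
#'   (include 0 for the unfiltered prediction).
#' @return a \linkS4class{RocCurve}.
#' @export
sizeThresholdROC <- function(predMasks, truthMasks,
                             thresholds = c(0, 2, 5, 10, 20, 40, 80, 160)) {
  if (length(predMasks) != length(truthMasks))
    stop("prediction and truth lists must be paired")
  if (any(thresholds < 0) || is.unsorted(thresholds))
    stop("thresholds must be non-negative and ascending")
  pm <- lapply(predMasks, as_mask_matrix)
  tm <- lapply(truthMasks, as_mask_matrix)
  for (i in seq_along(pm))
    if (!identical(dim(pm[[i]]), dim(tm[[i]])))
      stop("shape mismatch between prediction and truth at image ", i)
  labs <- lapply(pm, labelClusters)
  counts <- data.frame(threshold = thresholds, tp = 0, fp = 0, fn = 0, tn = 0)
  for (k in seq_along(thresholds)) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(pm)) {
      p <- filter_clusters(pm[[i]], labs[[i]], thresholds[k])
      tr <- tm[[i]]
      tp <- tp + sum(p * tr)
      fp <- fp + sum(p * (1 - tr))
      fn <- fn + sum((1 - p) * tr)
      tn <- tn + sum((1 - p) * (1 - tr))
    }
    counts[k, 2:5] <- c(tp, fp, fn, tn)
  }
  tpr <- ifelse(counts$tp + counts$fn > 0,
                counts$tp / (counts$tp + counts$fn), 0)
  fpr <- ifelse(counts$fp + counts$tn > 0,
                counts$fp / (counts$fp + counts$tn), 0)
  # loosest threshold = smallest s (largest surviving prediction)
  kmin <- which.min(thresholds)
  fx <- c(0, fpr, 1)
  fy <- c(0, tpr, tpr[kmin])
  ord <- order(fx, fy)
  fx <- fx[ord]; fy <- fy[ord]
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  new("RocCurve", thresholds = as.numeric(thresholds), fpr = fpr, tpr = tpr,
      auc = auc, counts = counts)
}

#' Paired TOST equivalence test
#'
#' Tests whether the mean paired difference d = a - b lies within the
#' symmetric equivalence bounds (-sesoi, +sesoi) via two one-sided paired t
#' tests (H0: mean d <= -sesoi, H0: mean d >= +sesoi). The decision p value
#' is the maximum of the two one-sided p values; equivalence is declared
#' when it is below alpha. With zero variance the t statistic is undefined:
#' a mean strictly inside the bounds is reported equivalent with p = 0,
#' strictly outside with p = 1, and exactly on a bound with p = 0.5.
#'
#' @param dscA,dscB paired numeric vectors of equal length n >= 3.
#' @param sesoi smallest effect size of interest (> 0); default 0.1.
#' @param alpha test level; default 0.05.
#' @return an \linkS4class{EquivalenceReport}.
#' @export
tostEquivalence <- function(dscA, dscB, sesoi = 0.1, alpha = 0.05) {
  if (length(dscA) != length(dscB)) stop("vectors must be paired")
  n <- length(dscA)
  if (n < 3) stop("TOST needs at least 3 pairs")
  if (sesoi <= 0) stop("sesoi must be positive")
  d <- dscA - dscB
  m <- mean(d)
  s <- sd(d)
  if (!is.finite(s) || s < 1e-12) {
    p <- if (abs(m) < sesoi) 0 else if (abs(m) > sesoi) 1 else 0.5
    pl <- pu <- p
  } else {
    pl <- t.test(d, mu = -sesoi, alternative = "greater")$p.value
    pu <- t.test(d, mu = sesoi, alternative = "less")$p.value
    p <- max(pl, pu)
  }
  new("EquivalenceReport", deltaLower = -sesoi, deltaUpper = sesoi,
      sesoi = sesoi, alpha = alpha, meanDiff = m, pLower = pl, pUpper = pu,
      pValue = p, equivalent = p < alpha, n = as.integer(n))
}
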