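# Synthetic study generator: contrast-enhancing lesion phantoms on noisy
# backgrounds, plus simulated boundary-tracing gaze recordings, so the whole
# ET-versus-HA experiment runs with no external data.

#' Phantom specification
#'
#' Parameters of the lesion-phantom generator. Phantoms emulate
#' postcontrast images of round, contrast-enhancing lesions: a noisy
#' background with smooth low-frequency structure, an elliptical or
#' smooth-blob lesion of elevated intensity with blurred edges, and a few
#' small bright distractor spots that give a trained network something to
#' falsely segment (the role cluster-size thresholding exists for).
#'
#' @slot size integer c(rows, cols) of the frame.
#' @slot shape "ellipse" (convex) or "blob" (radius modulated by low-order
#'   harmonics; possibly non-convex).
#' @slot radiusRange lesion radius range in pixels (>= 3).
#' @slot bgMean,lesionMean background / lesion mean intensity in [0,1].
#' @slot noiseSd pixel noise standard deviation.
#' @slot blurSigma Gaussian blur applied to the lesion profile (edge softness).
#' @slot presenceProb probability the phantom contains a lesion.
#' @slot maxDistractors maximum number of small bright distractor spots.
#' @slot seed default RNG seed.
#' @export
setClass("PhantomSpec",
  representation(size = "integer", shape = "character",
                 radiusRange = "numeric", bgMean = "numeric",
                 lesionMean = "numeric", noiseSd = "numeric",
                 blurSigma = "numeric", presenceProb = "numeric",
                 maxDistractors = "integer", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(object@size < 16)) return("frame must be at least 16 x 16")
  if (any(object@radiusRange < 3)) return("lesion radii must be >= 3 px")
  if (object@bgMean < 0 || object@bgMean > 1 ||
      object@lesionMean < 0 || object@lesionMean > 1)
    return("intensities must lie in [0,1]")
  if (object@presenceProb < 0 || object@presenceProb > 1)
    return("presenceProb must lie in [0,1]")
  if (!object@shape %in% c("ellipse", "blob"))
    return("shape must be 'ellipse' or 'blob'")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe a 256 x 256 frame with a convex elliptical lesion of
#' radius 20-50 px, background intensity 0.35, lesion intensity 0.75 and
#' noise sd 0.08; lesion presence probability 0.84 mirrors a study mix of
#' roughly five lesion images per normal.
#'
#' @param size frame c(rows, cols); default c(256, 256).
#' @param shape "ellipse" or "blob".
#' @param radiusRange c(min, max) lesion radius in px.
#' @param bgMean,lesionMean,noiseSd,blurSigma intensity model parameters.
#' @param presenceProb lesion presence probability.
#' @param maxDistractors max bright distractor spots per image.
#' @param seed default RNG seed.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(size = c(256, 256), shape = "ellipse",
                        radiusRange = c(20, 50), bgMean = 0.35,
                        lesionMean = 0.75, noiseSd = 0.08, blurSigma = 1.5,
                        presenceProb = 0.84, maxDistractors = 2L, seed = 1L) {
  new("PhantomSpec", size = as.integer(size), shape = shape,
      radiusRange = as.numeric(radiusRange), bgMean = bgMean,
      lesionMean = lesionMean, noiseSd = noiseSd, blurSigma = blurSigma,
      presenceProb = presenceProb, maxDistractors = as.integer(maxDistractors),
      seed = as.integer(seed))
}

#' Scanpath specification
#'
#' Parameters of the simulated boundary-tracing scanpath: a 60 Hz gaze
#' stream that first wanders off-lesion for the detection latency, then
#' follows the lesion contour at constant arc speed (optionally cutting
#' corners by replacing arcs with straight chords, the shortcut behaviour
#' seen in fatigued tracing), with isotropic Gaussian fixation jitter.
#'
#' @slot rateHz sampling rate (default 60).
#' @slot latencyS off-lesion search time before the trace starts (s).
#' @slot traceS time spent on the boundary (s).
#' @slot jitterPx isotropic gaze noise sd (px).
#' @slot shortcutFrac fraction of the boundary replaced by chord cuts, [0,1).
#' @slot direction "ccw" or "cw" traversal.
#' @slot seed default RNG seed.
#' @export
setClass("ScanpathSpec",
  representation(rateHz = "numeric", latencyS = "numeric", traceS = "numeric",
                 jitterPx = "numeric", shortcutFrac = "numeric",
                 direction = "character", seed = "integer"))

setValidity("ScanpathSpec", function(object) {
  if (object@rateHz <= 0) return("rateHz must be positive")
  if (object@jitterPx < 0) return("jitterPx must be >= 0")
  if (object@shortcutFrac < 0 || object@shortcutFrac >= 1)
    return("shortcutFrac must be in [0,1)")
  if (object@latencyS < 0 || object@traceS <= 0)
    return("latencyS must be >= 0 and traceS > 0")
  if (!object@direction %in% c("ccw", "cw"))
    return("direction must be 'ccw' or 'cw'")
  TRUE
})

#' Construct a ScanpathSpec
#'
#' Defaults: 60 Hz sampling, 1 s detection latency, 4 s on the boundary
#' (a medium lesion takes a few seconds to trace), 2 px jitter, 10% corner
#' cutting, counterclockwise traversal.
#'
#' @param rateHz sampling rate.
#' @param latencyS detection latency (s).
#' @param traceS on-boundary tracing time (s).
#' @param jitterPx gaze jitter sd (px).
#' @param shortcutFrac fraction of boundary chord-cut.
#' @param direction "ccw" or "cw".
#' @param seed default RNG seed.
#' @return a \linkS4class{ScanpathSpec}.
#' @export
scanpathSpec <- function(rateHz = 60, latencyS = 1, traceS = 4, jitterPx = 2,
                         shortcutFrac = 0.1, direction = "ccw", seed = 1L) {
  new("ScanpathSpec", rateHz = rateHz, latencyS = latencyS, traceS = traceS,
      jitterPx = jitterPx, shortcutFrac = shortcutFrac, direction = direction,
      seed = as.integer(seed))
}

# Analytic lesion boundary polygon (x, y), 0-based pixel coordinates.
lesion_polygon <- function(spec, nv = 72) {
  S <- spec@size
  rmax <- spec@radiusRange[2]
  margin <- rmax + 4
  if (2 * margin >= min(S)) stop("lesion radius range too large for the frame")
  cy <- runif(1, margin, S[1] - 1 - margin)
  cx <- runif(1, margin, S[2] - 1 - margin)
  phi <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  if (spec@shape == "ellipse") {
    a <- runif(1, spec@radiusRange[1], spec@radiusRange[2])
    b <- runif(1, spec@radiusRange[1], spec@radiusRange[2])
    th <- runif(1, 0, pi)
    x <- cx + a * cos(phi) * cos(th) - b * sin(phi) * sin(th)
    y <- cy + a * cos(phi) * sin(th) + b * sin(phi) * cos(th)
  } else {
    r0 <- runif(1, spec@radiusRange[1], spec@radiusRange[2])
    amp <- runif(3, 0.05, 0.18) * sample(c(-1, 1), 3, replace = TRUE)
    psi <- runif(3, 0, 2 * pi)
    r <- r0 * (1 + amp[1] * cos(2 * phi + psi[1]) +
                 amp[2] * cos(3 * phi + psi[2]) +
                 amp[3] * cos(4 * phi + psi[3]))
    r <- pmax(r, 3)
    x <- cx + r * cos(phi)
    y <- cy + r * sin(phi)
  }
  cbind(x = x, y = y)
}

#' Generate a lesion phantom with ground-truth mask
#'
#' Deterministic given the seed: the same seed yields a bit-identical image
#' and mask. The truth mask is exactly the rasterized lesion polygon; a
#' normal phantom (no lesion) has an all-zero truth mask.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed RNG seed; defaults to the spec's.
#' @return an \linkS4class{AnnotatedImage}.
#' @export
generatePhantom <- function(spec, seed = spec@seed) {
  stopifnot(is(spec, "PhantomSpec"))
  S <- spec@size
  with_seed(seed, {
    lesion <- runif(1) < spec@presenceProb
    if (lesion) {
      poly <- lesion_polygon(spec)
      truth <- polygonMask(poly, S)
    } else {
      poly <- matrix(numeric(0), 0, 2)
      truth <- zeroMask(S)
    }
    # smooth anatomical background + pixel noise
    lowfreq <- as.matrix(EBImage::gblur(matrix(rnorm(prod(S)), S[1], S[2]),
                                        sigma = max(8, min(S) / 16)))
    img <- spec@bgMean + 0.6 * lowfreq + matrix(rnorm(prod(S), 0, spec@noiseSd),
                                                S[1], S[2])
    # bright distractor spots (small, below lesion size)
    nd <- if (spec@maxDistractors > 0)
      sample(0:spec@maxDistractors, 1) else 0L
    if (nd > 0) {
      for (k in seq_len(nd)) {
        dr <- runif(1, 1.5, 3)
        dcy <- runif(1, dr + 1, S[1] - 2 - dr)
        dcx <- runif(1, dr + 1, S[2] - 2 - dr)
        yy <- matrix(0:(S[1] - 1), S[1], S[2])
        xx <- matrix(0:(S[2] - 1), S[1], S[2], byrow = TRUE)
        spot <- exp(-(((yy - dcy)^2 + (xx - dcx)^2) / (2 * dr^2)))
        img <- img + (spec@lesionMean - spec@bgMean) * spot
      }
    }
    if (lesion) {
      profile <- as.matrix(EBImage::gblur(maskMatrix(truth),
                                          sigma = spec@blurSigma))
      img <- img + (spec@lesionMean - spec@bgMean) * profile
    }
    img <- clamp(img, 0, 1)
    new("AnnotatedImage", image = img, truthMask = truth,
        label = if (lesion) "lesion" else "normal", boundary = poly)
  })
}

# Ordered boundary contour of a mask as 0-based (x, y) points on the
# region's visible edge: boundary-pixel centers pushed half a pixel along
# the outward normal (a tracer follows the edge itself, not pixel centers).
mask_contour <- function(m) {
  oc <- EBImage::ocontour(m)
  if (length(oc) == 0) stop("mask has no foreground; nothing to trace")
  cont <- oc[[which.max(vapply(oc, nrow, 0L))]]
  # EBImage's first coordinate runs along the matrix's first dimension (rows)
  P <- cbind(x = cont[, 2], y = cont[, 1])
  n <- nrow(P)
  if (n >= 3) {
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    tang <- P[nxt, , drop = FALSE] - P[prv, , drop = FALSE]
    len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
    nrm <- cbind(-tang[, 2], tang[, 1]) / len
    ctr <- colMeans(P)
    outward <- rowSums(nrm * sweep(P, 2, ctr)) # flip normals pointing inward
    nrm <- nrm * ifelse(outward >= 0, 1, -1)
    P <- P + 0.5 * nrm
  }
  P
}

# Piecewise-linear position along a closed contour at arc parameter s in [0,1).
contour_interp <- function(P, cum, s) {
  s <- s %% 1
  target <- s * cum[length(cum)]
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- clamp(i, 1, nrow(P) - 1)
  seg <- cum[i + 1] - cum[i]
  f <- if (seg > 0) (target - cum[i]) / seg else 0
  P[i, ] + f * (P[i + 1, ] - P[i, ])
}

#' Simulate a boundary-tracing gaze recording
#'
#' Emits \code{latencyS} seconds of off-lesion search samples, then
#' \code{traceS} seconds of samples following the truth-mask contour at
#' constant arc speed (with \code{shortcutFrac} of the boundary replaced by
#' straight chord cuts) plus Gaussian jitter, then a short drift away after
#' the trace. Returns the recording together with the ground-truth
#' \linkS4class{TimeWindow} covering exactly the on-boundary samples.
#'
#' @param truth a non-empty \linkS4class{BinaryMask}.
#' @param spec a \linkS4class{ScanpathSpec}.
#' @param seed RNG seed; defaults to the spec's.
#' @param structureId id recorded in the returned window.
#' @return list with elements \code{recording} and \code{window}.
#' @export
simulateScanpath <- function(truth, spec, seed = spec@seed,
                             structureId = "lesion") {
  stopifnot(is(spec, "ScanpathSpec"))
  m <- as_mask_matrix(truth)
  if (sum(m) == 0) stop("truth mask is empty; nothing to trace")
  S <- dim(m)
  with_seed(seed, {
    P <- mask_contour(m)
    P <- rbind(P, P[1, , drop = FALSE]) # close the ring
    # traversal direction: signed shoelace area (y grows downward, so
    # on-screen counterclockwise corresponds to negative area)
    n <- nrow(P)
    area2 <- sum(P[-n, 1] * P[-1, 2] - P[-1, 1] * P[-n, 2])
    wantNeg <- spec@direction == "ccw"
    if ((area2 > 0) == wantNeg) P <- P[n:1, , drop = FALSE]
    seglen <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-n, , drop = FALSE])^2))
    cum <- c(0, cumsum(seglen))
    nOn <- max(2L, round(spec@traceS * spec@rateHz))
    nLat <- round(spec@latencyS * spec@rateHz)
    nTail <- round(0.5 * spec@rateHz)
    s0 <- runif(1)
    sk <- s0 + (seq_len(nOn) - 1) / nOn
    # chord-cut intervals in arc parameter
    cuts <- NULL
    if (spec@shortcutFrac > 0) {
      ncut <- sample(1:3, 1)
      w <- rexp(ncut)
      lens <- spec@shortcutFrac * w / sum(w)
      starts <- sort(runif(ncut))
      ends <- numeric(ncut)
      prev <- -Inf
      for (k in seq_len(ncut)) {
        a <- max(starts[k], prev)
        b <- min(a + lens[k], 1)
        starts[k] <- a; ends[k] <- b; prev <- b
      }
      cuts <- cbind(starts, ends)
    }
    posOf <- function(s) {
      s <- s %% 1
      if (!is.null(cuts)) {
        for (k in seq_len(nrow(cuts))) {
          if (s >= cuts[k, 1] && s < cuts[k, 2]) {
            pa <- contour_interp(P, cum, cuts[k, 1])
            pb <- contour_interp(P, cum, cuts[k, 2])
            f <- (s - cuts[k, 1]) / (cuts[k, 2] - cuts[k, 1])
            return(pa + f * (pb - pa))
          }
        }
      }
      contour_interp(P, cum, s)
    }
    onPts <- t(vapply(sk, posOf, numeric(2)))
    if (spec@jitterPx > 0)
      onPts <- onPts + matrix(rnorm(2 * nOn, 0, spec@jitterPx), ncol = 2)
    # latency: drift from a frame corner toward the first boundary point
    first <- onPts[1, ]
    pts <- onPts
    if (nLat > 0) {
      corner <- c(sample(c(2, S[2] - 3), 1), sample(c(2, S[1] - 3), 1))
      f <- (seq_len(nLat) - 1) / nLat
      lat <- cbind(corner[1] + f * (first[1] - corner[1]),
                   corner[2] + f * (first[2] - corner[2]))
      lat <- lat + matrix(rnorm(2 * nLat, 0, max(spec@jitterPx, 3)), ncol = 2)
      pts <- rbind(lat, pts)
    }
    if (nTail > 0) {
      last <- onPts[nOn, ]
      ctr <- c(S[2] / 2, S[1] / 2)
      f <- seq_len(nTail) / nTail
      tail_ <- cbind(last[1] + f * (ctr[1] - last[1]),
                     last[2] + f * (ctr[2] - last[2]))
      tail_ <- tail_ + matrix(rnorm(2 * nTail, 0, max(spec@jitterPx, 3)),
                              ncol = 2)
      pts <- rbind(pts, tail_)
    }
    nTot <- nrow(pts)
    t <- (seq_len(nTot) - 1) / spec@rateHz
    x <- clamp(pts[, 1], 0, S[2] - 1)
    y <- clamp(pts[, 2], 0, S[1] - 1)
    clamped <- x != pts[, 1] | y != pts[, 2]
    samples <- data.frame(t = t, x = x, y = y, valid = 1, clamped = clamped)
    rec <- new("GazeRecording", samples = samples, rateHz = spec@rateHz,
               frameWidth = as.integer(S[2]), frameHeight = as.integer(S[1]))
    win <- TimeWindow(structureId, t[nLat + 1], t[nLat + nOn])
    list(recording = rec, window = win)
  })
}

# Free-viewing gaze over a normal image (no structure to trace).
wander_scanpath <- function(S, spec, seed) {
  with_seed(seed, {
    nTot <- round((spec@latencyS + spec@traceS) * spec@rateHz)
    nTot <- max(nTot, 10)
    steps <- matrix(rnorm(2 * nTot, 0, 8), ncol = 2)
    pts <- apply(steps, 2, cumsum)
    pts[, 1] <- S[2] / 2 + pts[, 1] - mean(pts[, 1])
    pts[, 2] <- S[1] / 2 + pts[, 2] - mean(pts[, 2])
    t <- (seq_len(nTot) - 1) / spec@rateHz
    x <- clamp(pts[, 1], 0, S[2] - 1)
    y <- clamp(pts[, 2], 0, S[1] - 1)
    samples <- data.frame(t = t, x = x, y = y, valid = 1,
                          clamped = x != pts[, 1] | y != pts[, 2])
    new("GazeRecording", samples = samples, rateHz = spec@rateHz,
        frameWidth = as.integer(S[2]), frameHeight = as.integer(S[1]))
  })
}

# Simulated hand annotation: subsample the analytic boundary to a handful of
# vertices (a human clicks a coarse polygon) and perturb them slightly.
simulate_ha_mask <- function(boundary, shape, vertexSd = 1, nVertices = 16,
                             seed = 1) {
  if (nrow(boundary) == 0) return(zeroMask(shape))
  idx <- round(seq(1, nrow(boundary), length.out = nVertices + 1))[-(nVertices + 1)]
  base <- boundary[idx, , drop = FALSE]
  with_seed(seed, {
    for (try in 1:8) {
      v <- base + matrix(rnorm(2 * nrow(base), 0, vertexSd), ncol = 2)
      ok <- tryCatch({polygonMask(v, shape)}, error = function(e) NULL)
      if (!is.null(ok)) return(ok)
    }
    polygonMask(base, shape)
  })
}

#' Generate a complete synthetic ET-versus-HA dataset on disk
#'
#' Writes, for each phantom: the image PNG, the ground-truth mask, the ET
#' mask (obtained by running the actual gaze pipeline: simulated scanpath ->
#' windowed trace -> convex hull), the simulated hand-annotation mask
#' (perturbed truth polygon), and the gaze log CSV; plus a windows table and
#' a manifest. Normal images get all-zero ET/HA/truth masks and a
#' free-viewing gaze log with no annotation window. Fully seeded: the same
#' master seed reproduces every file bit for bit.
#'
#' @param nLesion,nNormal number of lesion / normal phantoms.
#' @param phantom a \linkS4class{PhantomSpec}.
#' @param scan a \linkS4class{ScanpathSpec}.
#' @param outDir output directory (created if needed).
#' @param haVertexSd hand-annotation vertex noise sd in px (default 1).
#' @param haVertices number of hand-annotation polygon vertices.
#' @param seed master seed; per-image sub-seeds are derived from it.
#' @return the manifest data.frame, invisibly (also written as
#'   \code{manifest.csv}: columns image, label, gaze_log, t_start, t_stop,
#'   et_mask, ha_mask, truth_mask).
#' @export
generateDataset <- function(nLesion, nNormal, phantom = phantomSpec(),
                            scan = scanpathSpec(), outDir,
                            haVertexSd = 1, haVertices = 16, seed = 1) {
  if (!dir.exists(outDir))
    if (!dir.create(outDir, recursive = TRUE))
      stop("cannot create output directory ", outDir)
  nTot <- nLesion + nNormal
  seeds <- matrix(derive_seeds(seed, 3 * nTot), ncol = 3)
  labels <- rep(c("lesion", "normal"), c(nLesion, nNormal))
  rows <- vector("list", nTot)
  winrows <- list()
  for (i in seq_len(nTot)) {
    id <- sprintf("img%04d", i)
    pspec <- phantom
    pspec@presenceProb <- if (labels[i] == "lesion") 1 else 0
    ph <- generatePhantom(pspec, seed = seeds[i, 1])
    writeImagePNG(ph@image, file.path(outDir, paste0(id, ".png")))
    writeMaskPNG(ph@truthMask, file.path(outDir, paste0(id, "_truth.png")))
    if (labels[i] == "lesion") {
      sim <- simulateScanpath(ph@truthMask, scan, seed = seeds[i, 2],
                              structureId = id)
      writeGazeLog(sim$recording, file.path(outDir, paste0(id, "_gaze.csv")))
      tr <- extractTrace(sim$recording, sim$window)
      et <- convexHullMask(tr, dim(ph@image))
      ha <- simulate_ha_mask(ph@boundary, dim(ph@image), haVertexSd,
                             haVertices, seed = seeds[i, 3])
      tS <- sim$window@tStart; tE <- sim$window@tStop
      winrows[[length(winrows) + 1]] <- data.frame(
        structure_id = id, image = paste0(id, ".png"),
        t_start = sprintf("%.9f", tS), t_stop = sprintf("%.9f", tE))
    } else {
      rec <- wander_scanpath(dim(ph@image), scan, seeds[i, 2])
      writeGazeLog(rec, file.path(outDir, paste0(id, "_gaze.csv")))
      et <- zeroMask(dim(ph@image))
      ha <- zeroMask(dim(ph@image))
      tS <- NA; tE <- NA
    }
    writeMaskPNG(et, file.path(outDir, paste0(id, "_et.png")))
    writeMaskPNG(ha, file.path(outDir, paste0(id, "_ha.png")))
    rows[[i]] <- data.frame(
      image = paste0(id, ".png"), label = labels[i],
      gaze_log = paste0(id, "_gaze.csv"),
      t_start = if (is.na(tS)) "" else sprintf("%.9f", tS),
      t_stop = if (is.na(tE)) "" else sprintf("%.9f", tE),
      et_mask = paste0(id, "_et.png"), ha_mask = paste0(id, "_ha.png"),
      truth_mask = paste0(id, "_truth.png"))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  windows <- if (length(winrows)) do.call(rbind, winrows) else
    data.frame(structure_id = character(0), image = character(0),
               t_start = character(0), t_stop = character(0))
  write.csv(windows, file.path(outDir, "windows.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}
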