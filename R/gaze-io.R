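# Reading/writing gaze logs and annotation windows, fixation detection, and
# time-windowed boundary-trace extraction.

#' Read a gaze log CSV
#'
#' Parses a timestamped gaze recording with header \code{t,x,y,valid}
#' (t in seconds, x/y in pixels, valid 0/1 tracker lock). Timestamps must be
#' strictly increasing. Invalid samples are kept but flagged; samples
#' falling outside the image frame are clamped to the frame bounds and
#' flagged as clamped rather than dropped, so traces stay continuous under
#' tracker jitter at image edges.
#'
#' @param path CSV file path.
#' @param frameWidth,frameHeight image frame size in pixels.
#' @param rateHz nominal sampling rate (default 60 Hz).
#' @return a \linkS4class{GazeRecording}.
#' @export
readGazeLog <- function(path, frameWidth, frameHeight, rateHz = 60) {
  if (!file.exists(path)) stop("gaze log not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), c("t", "x", "y", "valid")))
    stop("gaze log header must be exactly 't,x,y,valid' in ", path)
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  valid <- num$valid
  bad <- which(!is.finite(num$t) | !is.finite(valid) |
               (valid == 1 & (!is.finite(num$x) | !is.finite(num$y))))
  if (length(bad))
    stop(sprintf("malformed gaze log row at line %d of %s",
                 bad[1] + 1L, path)) # +1 for the header line
  if (any(!valid %in% c(0, 1)))
    stop("'valid' column must be 0 or 1 in ", path)
  if (length(num$t) > 1) {
    drop <- which(diff(num$t) <= 0)
    if (length(drop))
      stop(sprintf("non-monotone timestamp at row %d of %s", drop[1] + 1L, path))
  }
  x <- num$x
  y <- num$y
  cx <- clamp(x, 0, frameWidth - 1)
  cy <- clamp(y, 0, frameHeight - 1)
  clamped <- (valid == 1) & (cx != x | cy != y)
  clamped[is.na(clamped)] <- FALSE
  samples <- data.frame(t = num$t, x = cx, y = cy, valid = valid,
                        clamped = clamped)
  new("GazeRecording", samples = samples, rateHz = rateHz,
      frameWidth = as.integer(frameWidth), frameHeight = as.integer(frameHeight))
}

#' Write a gaze recording to CSV
#'
#' Inverse of \code{\link{readGazeLog}}; writes the \code{t,x,y,valid}
#' columns with fixed decimal formatting so that rewriting and re-reading
#' is stable.
#'
#' @param rec a \linkS4class{GazeRecording}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeGazeLog <- function(rec, path) {
  s <- rec@samples
  df <- data.frame(t = sprintf("%.9f", s$t),
                   x = sprintf("%.6f", s$x),
                   y = sprintf("%.6f", s$y),
                   valid = as.integer(s$valid))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table of per-structure annotation windows
#'
#' CSV with header \code{structure_id,image,t_start,t_stop}. Rows with
#' missing t_start/t_stop (images with nothing to trace) are allowed.
#'
#' @param path CSV path.
#' @return data.frame with those four columns.
#' @export
readTimeWindows <- function(path) {
  if (!file.exists(path)) stop("windows table not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("structure_id", "image", "t_start", "t_stop")
  if (!all(need %in% names(df)))
    stop("windows table must have columns structure_id,image,t_start,t_stop")
  has <- !is.na(df$t_start) & !is.na(df$t_stop)
  if (any(has & (df$t_start < 0 | df$t_start > df$t_stop)))
    stop("windows must satisfy 0 <= t_start <= t_stop")
  df
}

#' Detect fixations by dispersion-threshold identification (I-DT)
#'
#' A fixation is a maximal run of consecutive valid samples whose
#' bounding-box half-diagonal stays within \code{dispersionPx} and whose
#' duration (last minus first timestamp) is at least \code{minDurS}. The
#' scan is greedy left to right: each run is extended as far as the
#' dispersion criterion allows; runs too short to qualify advance the start
#' by one sample. Invalid samples break runs. The fixation centroid is the
#' mean of its member samples.
#'
#' @param rec a \linkS4class{GazeRecording} with at least 2 valid samples.
#' @param dispersionPx dispersion radius in pixels (default 25).
#' @param minDurS minimum duration in seconds (default 0.1).
#' @return a \linkS4class{FixationSequence}.
#' @export
detectFixations <- function(rec, dispersionPx = 25, minDurS = 0.1) {
  stopifnot(dispersionPx > 0, minDurS > 0)
  s <- rec@samples
  vidx <- which(s$valid == 1)
  if (length(vidx) < 2)
    stop("recording has fewer than 2 valid samples")
  # segments of consecutive valid samples
  breaks <- c(0, which(diff(vidx) > 1), length(vidx))
  out <- list()
  for (seg in seq_len(length(breaks) - 1)) {
    idx <- vidx[(breaks[seg] + 1):breaks[seg + 1]]
    tt <- s$t[idx]; xx <- s$x[idx]; yy <- s$y[idx]
    n <- length(idx)
    i <- 1L
    while (i <= n) {
      xmin <- xx[i]; xmax <- xx[i]; ymin <- yy[i]; ymax <- yy[i]
      j <- i
      while (j < n) {
        nxmin <- min(xmin, xx[j + 1]); nxmax <- max(xmax, xx[j + 1])
        nymin <- min(ymin, yy[j + 1]); nymax <- max(ymax, yy[j + 1])
        if (sqrt((nxmax - nxmin)^2 + (nymax - nymin)^2) / 2 > dispersionPx) break
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
        j <- j + 1L
      }
      dur <- tt[j] - tt[i]
      if (dur >= minDurS) {
        out[[length(out) + 1]] <- data.frame(
          x = mean(xx[i:j]), y = mean(yy[i:j]), onset = tt[i], duration = dur)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  fx <- if (length(out)) do.call(rbind, out) else
    data.frame(x = numeric(0), y = numeric(0), onset = numeric(0),
               duration = numeric(0))
  new("FixationSequence", fixations = fx, dispersionPx = dispersionPx,
      minDurS = minDurS)
}

#' Extract the boundary trace for one annotation window
#'
#' Returns, in time order, the (x, y) of every valid sample whose timestamp
#' lies in the closed interval [tStart, tStop]. Samples before tStart and
#' after tStop -- the reader searching the image or looking elsewhere -- are
#' excluded by construction.
#'
#' @param rec a \linkS4class{GazeRecording}.
#' @param win a \linkS4class{TimeWindow}.
#' @return a \linkS4class{BoundaryTrace}.
#' @export
extractTrace <- function(rec, win) {
  s <- rec@samples
  inwin <- s$t >= win@tStart & s$t <= win@tStop
  if (!any(inwin))
    stop(sprintf("window [%g, %g] does not overlap recording (t in [%g, %g])",
                 win@tStart, win@tStop, min(s$t), max(s$t)))
  keep <- inwin & s$valid == 1
  if (!any(keep))
    stop("all samples inside the window are invalid; trace would be empty")
  BoundaryTrace(win@structureId, cbind(x = s$x[keep], y = s$y[keep]))
}

#' Write a boundary trace to CSV
#'
#' Columns \code{structure_id,seq,x,y}; round-trips losslessly with
#' \code{\link{readTrace}}.
#'
#' @param trace a \linkS4class{BoundaryTrace}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTrace <- function(trace, path) {
  p <- trace@points
  if (nrow(p) < 1) stop("refusing to write an empty trace")
  df <- data.frame(structure_id = trace@structureId, seq = seq_len(nrow(p)),
                   x = sprintf("%.17g", p[, 1]), y = sprintf("%.17g", p[, 2]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read boundary traces from CSV
#'
#' @param path CSV written by \code{\link{writeTrace}} (may hold several
#'   structures).
#' @return named list of \linkS4class{BoundaryTrace} objects.
#' @export
readTrace <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("structure_id", "seq", "x", "y")
  if (!all(need %in% names(df)))
    stop("trace file must have columns structure_id,seq,x,y")
  by_id <- split(df, df$structure_id)
  out <- lapply(by_id, function(d) {
    d <- d[order(d$seq), ]
    BoundaryTrace(d$structure_id[1], cbind(x = d$x, y = d$y))
  })
  out[unique(df$structure_id)]
}
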