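# Rasterizing boundary traces and polygon annotations into binary masks,
# plus PNG I/O and image/mask resizing.
#
# Membership rule: a pixel is set iff its center (integer x = col-1,
# y = row-1) lies inside or on the closed region. Degenerate point sets are
# total: one point -> its nearest pixel; collinear points -> a 1-px segment.

#' Rasterize the convex hull of a boundary trace
#'
#' The mask is 1 at every pixel whose center lies inside or on the convex
#' hull of the trace points. A single-point trace sets exactly its nearest
#' pixel; a collinear trace sets a one-pixel-wide segment between its
#' extreme points. Points outside the grid are clamped to it first. The
#' result is invariant to point order and duplicate points.
#'
#' @param trace a \linkS4class{BoundaryTrace}, or an n x 2 matrix of (x, y).
#' @param shape integer c(rows, cols) of the target grid.
#' @return a \linkS4class{BinaryMask}.
#' @export
convexHullMask <- function(trace, shape) {
  pts <- if (is(trace, "BoundaryTrace")) trace@points else as.matrix(trace)
  if (nrow(pts) < 1) stop("trace must contain at least one point")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  x <- clamp(pts[, 1], 0, nc - 1)
  y <- clamp(pts[, 2], 0, nr - 1)
  uniq <- !duplicated(cbind(x, y))
  x <- x[uniq]; y <- y[uniq]
  if (length(x) == 1) {
    g <- matrix(0, nr, nc)
    g[round(y) + 1, round(x) + 1] <- 1
    return(BinaryMask(g))
  }
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  if (length(h) >= 3 && polygon_area(hx, hy) > 1e-9) {
    g <- cpp_fill_polygon(hx, hy, nr, nc)
  } else {
    # collinear: rasterize the farthest pair as a segment
    dd <- as.matrix(dist(cbind(x, y)))
    far <- which(dd == max(dd), arr.ind = TRUE)[1, ]
    g <- cpp_raster_segment(x[far[1]], y[far[1]], x[far[2]], y[far[2]], nr, nc)
  }
  BinaryMask(g + 0)
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Do any two non-adjacent edges of the closed polygon intersect?
is_simple_polygon <- function(x, y) {
  n <- length(x)
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  seg_intersect <- function(i, j) {
    a <- c(x[i], y[i]); b <- c(x[i %% n + 1], y[i %% n + 1])
    c_ <- c(x[j], y[j]); d <- c(x[j %% n + 1], y[j %% n + 1])
    o1 <- orient(a[1], a[2], b[1], b[2], c_[1], c_[2])
    o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
    o3 <- orient(c_[1], c_[2], d[1], d[2], a[1], a[2])
    o4 <- orient(c_[1], c_[2], d[1], d[2], b[1], b[2])
    if (o1 != o2 && o3 != o4) return(TRUE)
    # collinear overlap
    onseg <- function(p, q, r) {
      orient(p[1], p[2], q[1], q[2], r[1], r[2]) == 0 &&
        r[1] <= max(p[1], q[1]) + 1e-12 && r[1] >= min(p[1], q[1]) - 1e-12 &&
        r[2] <= max(p[2], q[2]) + 1e-12 && r[2] >= min(p[2], q[2]) - 1e-12
    }
    onseg(a, b, c_) || onseg(a, b, d) || onseg(c_, d, a) || onseg(c_, d, b)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n # edge n is adjacent to edge 1
    if (i + 2 > jmax) next
    for (j in (i + 2):jmax) {
      if (seg_intersect(i, j)) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize a simple polygon into a binary mask
#'
#' Even-odd fill of the closed polygon, boundary pixels included -- the
#' digital analogue of a hand-drawn region-of-interest polygon. Refuses
#' self-intersecting polygons.
#'
#' @param vertices ordered k x 2 matrix of (x, y) vertices, k >= 3.
#' @param shape integer c(rows, cols) of the target grid.
#' @return a \linkS4class{BinaryMask}.
#' @export
polygonMask <- function(vertices, shape) {
  v <- as.matrix(vertices)
  # drop consecutive duplicates (closed-ring repeats included)
  keep <- c(TRUE, rowSums(abs(diff(v))) > 1e-12)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) > 1 && all(abs(v[1, ] - v[nrow(v), ]) < 1e-12))
    v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3) stop("polygon needs at least 3 distinct vertices")
  if (!is_simple_polygon(v[, 1], v[, 2]))
    stop("polygon is self-intersecting")
  g <- cpp_fill_polygon(v[, 1], v[, 2], as.integer(shape[1]),
                        as.integer(shape[2]))
  BinaryMask(g + 0)
}

#' All-zero mask
#'
#' The mask of an image with nothing to segment.
#'
#' @param shape integer c(rows, cols).
#' @return a \linkS4class{BinaryMask} of zeros.
#' @export
zeroMask <- function(shape) {
  BinaryMask(matrix(0, as.integer(shape[1]), as.integer(shape[2])))
}

#' Resize an image together with its mask
#'
#' The image is resampled with bilinear interpolation, the mask with
#' nearest-neighbour so its values stay in \{0,1\}. Aspect ratio is not
#' preserved: both are stretched to the target shape (masks and images are
#' conventionally brought to a common square size before training).
#'
#' @param img grayscale matrix.
#' @param mask a \linkS4class{BinaryMask} (or 0/1 matrix) aligned to img.
#' @param target integer c(rows, cols), at least 8 x 8.
#' @return list with elements \code{image} and \code{mask}.
#' @export
resizePair <- function(img, mask, target) {
  m <- as_mask_matrix(mask)
  stopifnot(identical(dim(img), dim(m)))
  tr <- as.integer(target[1]); tc <- as.integer(target[2])
  if (tr < 8 || tc < 8) stop("target size must be at least 8 x 8")
  if (nrow(img) == 0) stop("empty input image")
  if (identical(dim(img), c(tr, tc)))
    return(list(image = img, mask = BinaryMask(m)))
  ri <- as.matrix(EBImage::resize(img, w = tr, h = tc))
  rm <- as.matrix(EBImage::resize(m, w = tr, h = tc, filter = "none"))
  list(image = ri, mask = BinaryMask(round(rm)))
}

#' Read a grayscale image from PNG
#'
#' Multi-channel PNGs are collapsed to their first channel.
#'
#' @param path PNG path.
#' @return matrix in [0,1].
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

#' Write a grayscale image to 8-bit PNG
#' @param img matrix in [0,1] (clamped).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' On-disk masks use \{0,255\}; any nonzero intensity maps to 1.
#'
#' @param path PNG path.
#' @return a \linkS4class{BinaryMask}.
#' @export
readMaskPNG <- function(path) {
  a <- readImagePNG(path)
  BinaryMask((a > 0.5) + 0)
}

#' Write a binary mask to 8-bit PNG (values 0/255 on disk)
#' @param mask a \linkS4class{BinaryMask} or 0/1 matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(as_mask_matrix(mask), path)
  invisible(path)
}
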