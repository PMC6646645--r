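# Independent brute-force oracles and fixture builders used across tests.
# These deliberately recompute results by the most literal method available
# and never call the package's rasterization or scanning code paths.

# Per-pixel even-odd ray casting over a whole grid, boundary included via a
# point-to-segment distance test. Vectorized over pixel centers.
oracle_fill <- function(xs, ys, nr, nc) {
  px <- rep(0:(nc - 1), each = nr)
  py <- rep(0:(nr - 1), times = nc)
  inside <- rep(FALSE, nr * nc)
  onb <- rep(FALSE, nr * nc)
  n <- length(xs)
  j <- n
  for (i in seq_len(n)) {
    dx <- xs[i] - xs[j]; dy <- ys[i] - ys[j]
    L2 <- dx^2 + dy^2
    if (L2 > 0) {
      tt <- ((px - xs[j]) * dx + (py - ys[j]) * dy) / L2
      tt <- pmin(pmax(tt, 0), 1)
      qx <- xs[j] + tt * dx; qy <- ys[j] + tt * dy
      onb <- onb | ((px - qx)^2 + (py - qy)^2 < 1e-16)
      cross <- ((ys[j] <= py & ys[i] > py) | (ys[i] <= py & ys[j] > py))
      xi <- xs[j] + (py - ys[j]) / (ys[i] - ys[j]) * (xs[i] - xs[j])
      flip <- cross & (px < xi)
      flip[is.na(flip)] <- FALSE
      inside <- xor(inside, flip)
    } else {
      onb <- onb | (abs(px - xs[i]) < 1e-9 & abs(py - ys[i]) < 1e-9)
    }
    j <- i
  }
  matrix(as.numeric(inside | onb), nr, nc)
}

# Exhaustive maximal-run fixation search: for each candidate start, grow the
# run one sample at a time recomputing the bounding box from scratch.
oracle_fixations <- function(t, x, y, valid, disp, mindur) {
  out <- list()
  n <- length(t)
  i <- 1L
  while (i <= n) {
    if (valid[i] != 1) { i <- i + 1L; next }
    j <- i
    while (j < n && valid[j + 1] == 1) {
      rng_x <- range(x[i:(j + 1)]); rng_y <- range(y[i:(j + 1)])
      if (sqrt(diff(rng_x)^2 + diff(rng_y)^2) / 2 > disp) break
      j <- j + 1L
    }
    if (t[j] - t[i] >= mindur) {
      out[[length(out) + 1]] <- data.frame(
        x = mean(x[i:j]), y = mean(y[i:j]), onset = t[i],
        duration = t[j] - t[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(x = numeric(0), y = numeric(0), onset = numeric(0),
               duration = numeric(0))
}

# 8-connected component sizes via igraph over the pixel adjacency graph.
oracle_component_sizes <- function(m) {
  idx <- which(m == 1)
  if (!length(idx)) return(integer(0))
  co <- arrayInd(idx, dim(m))
  key <- paste(co[, 1], co[, 2], sep = ",")
  lookup <- seq_along(idx)
  names(lookup) <- key
  edges <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- paste(co[, 1] + dr, co[, 2] + dc, sep = ",")
    hit <- which(nb %in% key)
    if (length(hit))
      edges <- c(edges, rbind(lookup[key[hit]], lookup[nb[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  sort(as.integer(table(igraph::components(g)$membership)), decreasing = TRUE)
}

# Build a GazeRecording directly from vectors (test fixture, no file I/O).
make_recording <- function(t, x, y, valid = rep(1, length(t)),
                           frame = c(512, 512), rateHz = 60) {
  new("GazeRecording",
      samples = data.frame(t = t, x = x, y = y, valid = valid,
                           clamped = FALSE),
      rateHz = rateHz, frameWidth = as.integer(frame[1]),
      frameHeight = as.integer(frame[2]))
}

# Random simple star-shaped polygon: one vertex per angular sector of a
# full circle, so every ray from the center crosses exactly one edge.
random_star_polygon <- function(nv, cx, cy, rmin, rmax) {
  ang <- (seq_len(nv) - 1) * 2 * pi / nv +
    runif(nv, 0.05, 0.95) * (2 * pi / nv)
  r <- runif(nv, rmin, rmax)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

write_gaze_csv <- function(path, t, x, y, valid = rep(1, length(t))) {
  writeLines(c("t,x,y,valid",
               sprintf("%.9f,%.6f,%.6f,%d", t, x, y, as.integer(valid))),
             path)
}
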