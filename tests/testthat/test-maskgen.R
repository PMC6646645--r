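# Convex-hull and polygon rasterization, resizing, and PNG round trips.

test_that("convex hull rasterization handles canonical and degenerate inputs", {
  m <- convexHullMask(rbind(c(2, 2), c(2, 10), c(10, 10), c(10, 2)), c(16, 16))
  expect_equal(sum(maskMatrix(m)), 81) # closed 9x9 block, boundary included

  m1 <- convexHullMask(matrix(c(5, 5), 1), c(16, 16))
  g <- maskMatrix(m1)
  expect_equal(sum(g), 1)
  expect_equal(g[6, 6], 1) # pixel (x=5, y=5) is row 6, col 6

  # collinear points rasterize to a 1-px segment between the extremes
  seg <- convexHullMask(rbind(c(1, 1), c(5, 5), c(9, 9)), c(12, 12))
  expect_equal(sum(maskMatrix(seg)), 9)

  th <- seq(0, 2 * pi, length.out = 201)[-201]
  mc <- convexHullMask(cbind(50 + 30 * cos(th), 50 + 30 * sin(th)), c(100, 100))
  expect_lt(abs(sum(maskMatrix(mc)) - pi * 30^2) / (pi * 30^2), 0.02)
})

test_that("hull masks are invariant to point order and duplicates and cover the trace", {
  set.seed(5)
  pts <- cbind(runif(40, 3, 28), runif(40, 3, 28))
  a <- maskMatrix(convexHullMask(pts, c(32, 32)))
  b <- maskMatrix(convexHullMask(pts[sample(40), ], c(32, 32)))
  d <- maskMatrix(convexHullMask(rbind(pts, pts[rep(1, 5), ]), c(32, 32)))
  expect_identical(a, b)
  expect_identical(a, d)
  # superset property: every trace point's nearest pixel is set, except
  # where rounding pushes a hull-vertex point to a pixel whose center falls
  # outside the closed hull (the membership rule is center-in-closed-hull)
  h <- chull(pts[, 1], pts[, 2])
  for (i in seq_len(nrow(pts))) {
    px <- round(pts[i, 1]); py <- round(pts[i, 2])
    centerInHull <- oracle_fill(pts[h, 1], pts[h, 2], 32, 32)[py + 1, px + 1]
    expect_equal(a[py + 1, px + 1], centerInHull)
    if (centerInHull == 0) # only near-boundary points may be missed
      expect_lt(min(sqrt((pts[h, 1] - px)^2 + (pts[h, 2] - py)^2)), 1)
  }
})

test_that("hull and polygon rasterization agree with the ray-casting oracle", {
  set.seed(17)
  for (case in 1:25) {
    nr <- sample(12:64, 1); nc <- sample(12:64, 1)
    npt <- sample(3:25, 1)
    pts <- cbind(runif(npt, 0, nc - 1), runif(npt, 0, nr - 1))
    got <- maskMatrix(convexHullMask(pts, c(nr, nc)))
    h <- chull(pts[, 1], pts[, 2])
    want <- oracle_fill(pts[h, 1], pts[h, 2], nr, nc)
    expect_identical(got, want)

    poly <- random_star_polygon(sample(4:10, 1), nc / 2, nr / 2,
                                min(nr, nc) / 6, min(nr, nc) / 2.5)
    gotp <- maskMatrix(polygonMask(poly, c(nr, nc)))
    wantp <- oracle_fill(poly[, 1], poly[, 2], nr, nc)
    expect_identical(gotp, wantp)
  }
})

test_that("rasterized hulls are convex up to the pixel grid", {
  set.seed(23)
  for (case in 1:10) {
    nr <- sample(16:64, 1); nc <- sample(16:64, 1)
    pts <- cbind(runif(12, 1, nc - 2), runif(12, 1, nr - 2))
    g <- maskMatrix(convexHullMask(pts, c(nr, nc)))
    on <- which(g == 1, arr.ind = TRUE)
    if (nrow(on) < 4) next
    cx <- on[, 2] - 1; cy <- on[, 1] - 1
    h <- chull(cx, cy)
    off <- which(g == 0, arr.ind = TRUE)
    inside <- oracle_fill(cx[h], cy[h], nr, nc)
    # no unset pixel center strictly interior: allow boundary-touching ones
    strict <- inside == 1 & g == 0
    if (any(strict)) {
      bad <- which(strict, arr.ind = TRUE)
      for (k in seq_len(nrow(bad))) {
        px <- bad[k, 2] - 1; py <- bad[k, 1] - 1
        dmin <- min(sqrt((cx[h] - px)^2 + (cy[h] - py)^2))
        expect_lt(dmin, 1.5) # only boundary grazing allowed
      }
    } else succeed()
  }
})

test_that("polygon masks match brute-force fill and reject self-intersection", {
  tri <- rbind(c(0, 0), c(0, 8), c(8, 0))
  got <- maskMatrix(polygonMask(tri, c(10, 10)))
  expect_identical(got, oracle_fill(tri[, 1], tri[, 2], 10, 10))

  # convexity identity: a convex polygon fills the same as its hull
  set.seed(31)
  ang <- sort(runif(8, 0, 2 * pi))
  conv <- cbind(15 + 9 * cos(ang), 15 + 9 * sin(ang))
  expect_identical(maskMatrix(polygonMask(conv, c(32, 32))),
                   maskMatrix(convexHullMask(conv, c(32, 32))))

  bow <- rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4))
  expect_error(polygonMask(bow, c(10, 10)), "self-intersect")
  expect_error(polygonMask(rbind(c(0, 0), c(1, 1)), c(10, 10)), "3")
})

test_that("zero masks are empty, shaped, and maximally dissimilar to anything", {
  z <- zeroMask(c(7, 9))
  expect_equal(sum(maskMatrix(z)), 0)
  expect_equal(dim(z), c(7L, 9L))
  m <- zeroMask(c(7, 9)); mm <- maskMatrix(m); mm[3, 3] <- 1
  expect_equal(diceCoef(z, BinaryMask(mm)), 0)
  expect_equal(diceCoef(z, zeroMask(c(7, 9))), 1)
})

test_that("resizing keeps masks binary and geometry approximately scaled", {
  big <- matrix(0, 512, 512)
  big[207:306, 207:306] <- 1 # centered 100x100 block
  img <- matrix(runif(512 * 512), 512, 512)
  rp <- resizePair(img, BinaryMask(big), c(256, 256))
  rm <- maskMatrix(rp$mask)
  expect_true(all(rm %in% c(0, 1)))
  expect_equal(dim(rm), c(256L, 256L))
  expect_lt(abs(sum(rm) - 2500), 250) # ~50x50 block
  on <- which(rm == 1, arr.ind = TRUE)
  expect_lt(abs(mean(on[, 1]) - 128.5), 3)
  expect_lt(abs(mean(on[, 2]) - 128.5), 3)

  same <- resizePair(img, BinaryMask(big), c(512, 512))
  expect_identical(same$image, img)
  expect_identical(maskMatrix(same$mask), big)

  z <- resizePair(img, zeroMask(c(512, 512)), c(64, 64))
  expect_equal(sum(maskMatrix(z$mask)), 0)
  expect_error(resizePair(img, BinaryMask(big), c(4, 4)), "8 x 8")
})

test_that("images and masks round-trip through PNG at 8-bit precision", {
  d <- withr::local_tempdir()
  img <- matrix(runif(32 * 32), 32, 32)
  writeImagePNG(img, file.path(d, "i.png"))
  back <- readImagePNG(file.path(d, "i.png"))
  expect_lt(max(abs(back - img)), 1 / 255)
  m <- BinaryMask(matrix(rbinom(64, 1, 0.4), 8, 8))
  writeMaskPNG(m, file.path(d, "m.png"))
  expect_identical(maskMatrix(readMaskPNG(file.path(d, "m.png"))),
                   maskMatrix(m))
})
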