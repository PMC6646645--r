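# Gaze log parsing, fixation detection, and windowed trace extraction.

test_that("gaze logs parse, keep order, and report nominal sampling gaps", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(f, t = c(0, 1/60, 2/60), x = c(10, 11, 12), y = c(5, 5, 6))
  rec <- readGazeLog(f, frameWidth = 100, frameHeight = 80)
  s <- gazeSamples(rec)
  expect_equal(nrow(s), 3)
  expect_equal(s$x, c(10, 11, 12))
  expect_equal(diff(s$t), rep(1/60, 2), tolerance = 1e-6)
})

test_that("malformed and non-monotone gaze logs are rejected with locations", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,valid", "0.0,1,2,1", "0.5,oops,3,1"), f)
  expect_error(readGazeLog(f, 100, 100), "line 3")
  writeLines(c("t,x,y,valid", "0.0,1,2,1", "0.5,3,3,1", "0.4,4,4,1"), f)
  expect_error(readGazeLog(f, 100, 100), "row 3")
  writeLines(c("time,x,y,valid", "0.0,1,2,1"), f)
  expect_error(readGazeLog(f, 100, 100), "header")
})

test_that("off-frame samples are clamped and flagged, not dropped", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(f, t = c(0, 0.1), x = c(-5, 50), y = c(10, 120))
  rec <- readGazeLog(f, frameWidth = 100, frameHeight = 100)
  s <- gazeSamples(rec)
  expect_equal(nrow(s), 2)
  expect_equal(s$x[1], 0)
  expect_equal(s$y[2], 99)
  expect_equal(s$clamped, c(TRUE, TRUE))
})

test_that("dispersion-threshold fixation detection matches its definition", {
  # 30 samples at one exact point over 0.5 s -> one fixation of 0.5 s
  t <- seq(0, 0.5, length.out = 30)
  rec <- make_recording(t, rep(40, 30), rep(60, 30))
  fx <- fixations(detectFixations(rec, dispersionPx = 10, minDurS = 0.1))
  expect_equal(nrow(fx), 1)
  expect_equal(fx$x, 40)
  expect_equal(fx$duration, 0.5)

  # two stationary clusters 100 px apart, each held 0.3 s
  t2 <- seq(0, 0.6, length.out = 40)
  x2 <- c(rep(10, 20), rep(110, 20))
  rec2 <- make_recording(t2, x2, rep(50, 40))
  fx2 <- fixations(detectFixations(rec2, dispersionPx = 10, minDurS = 0.1))
  orc <- oracle_fixations(t2, x2, rep(50, 40), rep(1, 40), 10, 0.1)
  expect_equal(nrow(fx2), 2)
  expect_equal(fx2$x, c(10, 110))
  expect_equal(fx2, orc)

  # continuous fast sweep: no sample pair stays within dispersion long enough
  t3 <- seq(0, 1, length.out = 61)
  rec3 <- make_recording(t3, 20 * (0:60), rep(50, 61), frame = c(2000, 200))
  fx3 <- fixations(detectFixations(rec3, dispersionPx = 10, minDurS = 0.1))
  expect_equal(nrow(fx3), 0)
})

test_that("fixation detection agrees with exhaustive brute-force search", {
  set.seed(42)
  for (case in 1:30) {
    n <- sample(20:200, 1)
    t <- cumsum(runif(n, 0.01, 0.03))
    # piecewise-stationary gaze with saccades and dropouts
    k <- sample(2:6, 1)
    cx <- runif(k, 0, 300); cy <- runif(k, 0, 300)
    seg <- sort(sample(seq_len(n - 1), k - 1))
    lab <- rep(seq_len(k), diff(c(0, seg, n)))
    x <- cx[lab] + rnorm(n, 0, 3)
    y <- cy[lab] + rnorm(n, 0, 3)
    valid <- as.numeric(runif(n) > 0.05)
    if (sum(valid) < 2) valid[1:2] <- 1
    rec <- make_recording(t, x, y, valid, frame = c(400, 400))
    got <- fixations(detectFixations(rec, dispersionPx = 12, minDurS = 0.08))
    want <- oracle_fixations(t, x, y, valid, 12, 0.08)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("trace extraction keeps exactly the valid samples in the closed window", {
  rec <- make_recording(0:10, 10 * (0:10), rep(5, 11), frame = c(200, 50))
  tr <- extractTrace(rec, TimeWindow("m1", 3, 7))
  expect_equal(nrow(tracePoints(tr)), 5)
  expect_equal(tracePoints(tr)[, "x"], c(30, 40, 50, 60, 70))

  one <- extractTrace(rec, TimeWindow("m1", 5, 5))
  expect_equal(nrow(tracePoints(one)), 1)

  expect_error(extractTrace(rec, TimeWindow("m1", 20, 30)), "overlap")

  rec2 <- make_recording(0:10, 10 * (0:10), rep(5, 11),
                         valid = c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1, 1),
                         frame = c(200, 50))
  expect_error(extractTrace(rec2, TimeWindow("m1", 3, 7)), "invalid")
})

test_that("trace extraction is an idempotent order-preserving subsequence filter", {
  set.seed(7)
  for (case in 1:20) {
    n <- sample(50:300, 1)
    t <- cumsum(runif(n, 0.005, 0.05))
    x <- runif(n, 0, 99); y <- runif(n, 0, 99)
    valid <- as.numeric(runif(n) > 0.1)
    if (sum(valid) == 0) valid[1] <- 1
    rec <- make_recording(t, x, y, valid, frame = c(100, 100))
    a <- runif(1, min(t), max(t)); b <- runif(1, a, max(t))
    naive <- which(t >= a & t <= b & valid == 1)
    if (!length(naive)) {
      expect_error(extractTrace(rec, TimeWindow("s", a, b)))
      next
    }
    tr <- tracePoints(extractTrace(rec, TimeWindow("s", a, b)))
    expect_equal(tr[, "x"], x[naive])
    expect_equal(tr[, "y"], y[naive])
  }
})

test_that("disjoint windows partition a recording without double counting", {
  set.seed(11)
  n <- 200
  t <- cumsum(runif(n, 0.01, 0.03))
  rec <- make_recording(t, runif(n, 0, 63), runif(n, 0, 63),
                        valid = as.numeric(runif(n) > 0.1), frame = c(64, 64))
  cuts <- sort(runif(3, min(t), max(t)))
  bounds <- rbind(c(min(t), cuts[1]), c(cuts[1] + 1e-9, cuts[2]),
                  c(cuts[2] + 1e-9, cuts[3]), c(cuts[3] + 1e-9, max(t)))
  total <- 0
  for (i in seq_len(nrow(bounds))) {
    tr <- tryCatch(extractTrace(rec, TimeWindow("s", bounds[i, 1], bounds[i, 2])),
                   error = function(e) NULL)
    if (!is.null(tr)) total <- total + nrow(tracePoints(tr))
  }
  expect_equal(total, sum(gazeSamples(rec)$valid == 1))
})

test_that("traces round-trip losslessly through CSV, empty traces refused", {
  set.seed(3)
  big <- new("BoundaryTrace", structureId = "m7",
             points = cbind(x = runif(10000, 0, 511), y = runif(10000, 0, 511)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrace(big, f)
  back <- readTrace(f)[["m7"]]
  expect_identical(unname(tracePoints(back)[, 1]), unname(big@points[, 1]))
  expect_identical(unname(tracePoints(back)[, 2]), unname(big@points[, 2]))
  expect_error(new("BoundaryTrace", structureId = "e",
                   points = matrix(numeric(0), 0, 2)))
})
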