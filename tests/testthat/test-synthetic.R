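# Phantom generation and scanpath simulation.

test_that("phantom generation is seed-deterministic and respects presence", {
  ps <- phantomSpec(size = c(64, 64), radiusRange = c(8, 16))
  p1 <- generatePhantom(ps, seed = 5)
  p2 <- generatePhantom(ps, seed = 5)
  expect_identical(p1@image, p2@image)
  expect_identical(maskMatrix(p1@truthMask), maskMatrix(p2@truthMask))
  expect_false(identical(p1@image, generatePhantom(ps, seed = 6)@image))

  psn <- phantomSpec(size = c(64, 64), radiusRange = c(8, 16), presenceProb = 0)
  pn <- generatePhantom(psn, seed = 5)
  expect_equal(sum(maskMatrix(pn@truthMask)), 0)
  expect_equal(pn@label, "normal")
})

test_that("elliptical truth masks have the analytic area", {
  # fixed radii: a = b = 20 -> area pi * 20 * 20
  ps <- phantomSpec(size = c(256, 256), radiusRange = c(20, 20),
                    presenceProb = 1)
  for (s in 1:5) {
    p <- generatePhantom(ps, seed = s)
    expect_lt(abs(sum(maskMatrix(p@truthMask)) - pi * 400) / (pi * 400), 0.05)
  }
})

test_that("scanpaths include the detection latency and are seed-deterministic", {
  ps <- phantomSpec(size = c(128, 128), radiusRange = c(15, 25),
                    presenceProb = 1)
  p <- generatePhantom(ps, seed = 2)
  ss <- scanpathSpec(latencyS = 1.0)
  sim <- simulateScanpath(p@truthMask, ss, seed = 3)
  s <- gazeSamples(sim$recording)
  expect_gte(sum(s$t < sim$window@tStart), 60) # >= 1 s at 60 Hz before start
  sim2 <- simulateScanpath(p@truthMask, ss, seed = 3)
  expect_identical(gazeSamples(sim$recording), gazeSamples(sim2$recording))
  expect_equal(sim$window@tStart, sim2$window@tStart)
  expect_error(simulateScanpath(zeroMask(c(32, 32)), ss), "empty")
})

test_that("a noiseless trace of a convex lesion recovers the truth mask", {
  ps <- phantomSpec(presenceProb = 1) # 256 x 256, ellipse
  ss <- scanpathSpec(jitterPx = 0, shortcutFrac = 0)
  for (s in 1:5) {
    p <- generatePhantom(ps, seed = 50 + s)
    sim <- simulateScanpath(p@truthMask, ss, seed = 60 + s)
    et <- convexHullMask(extractTrace(sim$recording, sim$window), dim(p@image))
    expect_gte(diceCoef(et, p@truthMask), 0.99)
  }
})

test_that("corner cutting on non-convex blobs biases hull masks toward over-coverage", {
  ps <- phantomSpec(size = c(256, 256), shape = "blob", presenceProb = 1)
  ss <- scanpathSpec(jitterPx = 0, shortcutFrac = 0.1)
  prec <- rec <- numeric(30)
  for (i in 1:30) {
    p <- generatePhantom(ps, seed = 300 + i)
    sim <- simulateScanpath(p@truthMask, ss, seed = 400 + i)
    et <- maskMatrix(convexHullMask(extractTrace(sim$recording, sim$window),
                                    dim(p@image)))
    tr <- maskMatrix(p@truthMask)
    prec[i] <- sum(et * tr) / sum(et)
    rec[i] <- sum(et * tr) / sum(tr)
  }
  expect_lt(mean(prec), mean(rec))
})

test_that("dataset generation writes a consistent, reproducible corpus", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ps <- phantomSpec(size = c(64, 64), radiusRange = c(8, 16))
  ss <- scanpathSpec()
  man <- generateDataset(4, 2, ps, ss, d1, seed = 21)
  expect_equal(nrow(man), 6)
  expect_equal(sum(man$label == "normal"), 2)
  for (i in which(man$label == "normal")) {
    expect_equal(sum(maskMatrix(readMaskPNG(file.path(d1, man$et_mask[i])))), 0)
    expect_equal(sum(maskMatrix(readMaskPNG(file.path(d1, man$ha_mask[i])))), 0)
  }
  # every referenced file exists
  for (col in c("image", "gaze_log", "et_mask", "ha_mask", "truth_mask"))
    expect_true(all(file.exists(file.path(d1, man[[col]]))))
  # re-running with the same master seed is file-identical
  generateDataset(4, 2, ps, ss, d2, seed = 21)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("ET masks rebuilt from the gaze CSVs match the dataset's masks", {
  d <- withr::local_tempdir()
  ps <- phantomSpec(size = c(64, 64), radiusRange = c(8, 16))
  man <- generateDataset(3, 0, ps, scanpathSpec(), d, seed = 33)
  orig <- lapply(man$et_mask, function(f) maskMatrix(readMaskPNG(file.path(d, f))))
  status <- cmdMaskgen(d)
  expect_true(all(status$status == "ok"))
  for (i in seq_len(nrow(man))) {
    rebuilt <- maskMatrix(readMaskPNG(file.path(d, man$et_mask[i])))
    expect_gte(diceCoef(rebuilt, orig[[i]]), 0.999)
  }
})
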