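# Dice, trimmed means, cluster-size ROC, and TOST equivalence.

test_that("Dice coefficient matches hand counts and conventions", {
  a <- matrix(0, 5, 5); a[1:2, 1:2] <- 1 # |A| = 4
  b <- matrix(0, 5, 5); b[1:2, 1:3] <- 1 # |B| = 6, overlap 3... adjust
  b[2, 2] <- 0                            # |B| = 5, overlap 3
  b[4, 4] <- 1                            # |B| = 6
  expect_equal(sum(a), 4); expect_equal(sum(b), 6)
  expect_equal(sum(a * b), 3)
  expect_equal(diceCoef(a, b), 0.6)

  expect_equal(diceCoef(a, a), 1)
  dis <- matrix(0, 5, 5); dis[5, 5] <- 1
  expect_equal(diceCoef(a, dis), 0)
  expect_equal(diceCoef(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_equal(diceCoef(matrix(0, 3, 3), matrix(1, 3, 3)), 0)
  expect_error(diceCoef(matrix(0, 3, 3), matrix(0, 4, 4)), "shape")
})

test_that("Dice is symmetric, bounded, and monotone in overlap", {
  set.seed(2)
  for (i in 1:20) {
    a <- matrix(rbinom(100, 1, 0.4), 10, 10)
    b <- matrix(rbinom(100, 1, 0.4), 10, 10)
    d <- diceCoef(a, b)
    expect_equal(d, diceCoef(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
  }
  # growing the intersection with |A|, |B| fixed raises DSC
  a <- matrix(0, 6, 6); a[1:3, 1:3] <- 1
  b1 <- matrix(0, 6, 6); b1[4:6, 4:6] <- 1        # overlap 0
  b2 <- matrix(0, 6, 6); b2[2:4, 2:4] <- 1        # overlap 4
  b3 <- matrix(0, 6, 6); b3[1:3, 1:3] <- 1        # overlap 9
  expect_true(diceCoef(a, b1) < diceCoef(a, b2))
  expect_true(diceCoef(a, b2) < diceCoef(a, b3))
})

test_that("trimmed mean implements sort-and-drop and its edge cases", {
  x <- c(1, 2, 3, 4, 100)
  sorted <- sort(x)
  drop <- floor(length(x) * 0.2)
  oracle <- mean(sorted[(drop + 1):(length(x) - drop)])
  expect_equal(oracle, 3)
  expect_equal(trimmedMean(x, 0.2), 3)
  expect_equal(trimmedMean(x, 0), mean(x))
  expect_equal(trimmedMean(rep(7.5, 11), 0.3), 7.5)
  set.seed(4)
  for (i in 1:10) {
    v <- rnorm(sample(5:40, 1))
    tf <- runif(1, 0, 0.45)
    tm <- trimmedMean(v, tf)
    expect_gte(tm, min(v)); expect_lte(tm, max(v))
  }
  expect_error(trimmedMean(numeric(0)), "nothing")
  expect_error(trimmedMean(1:3, 0.5), "trimFrac")
})

test_that("connected-component labeling agrees with the igraph oracle", {
  skip_if_not_installed("igraph")
  # diagonal touching: one component under 8-connectivity, two under 4
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
  expect_equal(max(labelClusters(m, 8)), 1)
  expect_equal(max(labelClusters(m, 4)), 2)
  set.seed(9)
  for (i in 1:15) {
    mm <- matrix(rbinom(400, 1, runif(1, 0.2, 0.6)), 20, 20)
    lab <- labelClusters(mm)
    sizes <- sort(as.integer(table(lab[lab > 0])), decreasing = TRUE)
    expect_identical(sizes, oracle_component_sizes(mm))
  }
})

test_that("cluster-size ROC reproduces the worked two-blob example", {
  truth <- matrix(0, 10, 10); truth[2:4, 2:4] <- 1            # 9-px blob
  pred <- truth; pred[8, 8] <- 1; pred[8, 9] <- 1             # + 2-px false blob
  roc <- sizeThresholdROC(list(pred), list(truth), thresholds = c(0, 3))
  cts <- roc@counts
  expect_equal(cts$tp[cts$threshold == 0], 9)
  expect_equal(cts$fp[cts$threshold == 0], 2)
  expect_equal(cts$tp[cts$threshold == 3], 9)
  expect_equal(cts$fp[cts$threshold == 3], 0)
  # oracle: component sizes of the prediction are 9 and 2
  expect_identical(oracle_component_sizes(pred), c(9L, 2L))
})

test_that("perfect and empty predictions bound the ROC at 1 and 0", {
  set.seed(12)
  truths <- lapply(1:4, function(i) {
    m <- matrix(0, 16, 16); m[4:9, 4:9] <- 1; m
  })
  roc1 <- sizeThresholdROC(truths, truths, thresholds = c(0, 5, 30))
  expect_equal(roc1@auc, 1)
  expect_equal(roc1@tpr, c(1, 1, 1))
  expect_equal(roc1@fpr, c(0, 0, 0))
  zeros <- lapply(truths, function(m) m * 0)
  roc0 <- sizeThresholdROC(zeros, truths, thresholds = c(0, 5))
  expect_equal(roc0@auc, 0)
  expect_equal(roc0@tpr, c(0, 0))
})

test_that("ROC rates are non-increasing in the size threshold", {
  set.seed(19)
  for (rep in 1:5) {
    preds <- lapply(1:3, function(i) {
      m <- matrix(0, 24, 24)
      for (k in 1:4) {
        r <- sample(3:20, 1); c <- sample(3:20, 1); w <- sample(1:4, 1)
        m[r:min(24, r + w), c:min(24, c + w)] <- 1
      }
      m
    })
    truths <- lapply(1:3, function(i) {
      m <- matrix(0, 24, 24); m[6:14, 6:14] <- 1; m
    })
    roc <- sizeThresholdROC(preds, truths, thresholds = c(0, 2, 4, 8, 16, 32))
    expect_true(all(diff(roc@tpr) <= 1e-12))
    expect_true(all(diff(roc@fpr) <= 1e-12))
  }
})

test_that("TOST declares equivalence for identical vectors and not at the margin", {
  set.seed(6)
  a <- runif(50, 0.6, 0.9)
  rep1 <- tostEquivalence(a, a, sesoi = 0.1, alpha = 0.05)
  expect_true(isEquivalent(rep1))
  expect_equal(rep1@meanDiff, 0)
  expect_equal(pValue(rep1), 0) # zero-variance branch, mean inside bounds

  # identical-but-noisy pairing: nonzero spread, zero mean difference
  b <- a + rnorm(50, 0, 0.01)
  rep1b <- tostEquivalence(a, b, sesoi = 0.1, alpha = 0.05)
  expect_true(isEquivalent(rep1b))

  # mean difference exactly at +sesoi with tiny symmetric spread: the upper
  # one-sided t is 0, so p -> 0.5 by the closed form
  eps <- rep(c(-1e-8, 1e-8), 25)
  rep2 <- tostEquivalence(a + 0.1 + eps, a, sesoi = 0.1, alpha = 0.05)
  expect_false(isEquivalent(rep2))
  expect_lt(abs(pValue(rep2) - 0.5), 0.02)

  # huge spread: no power, no equivalence
  set.seed(8)
  rep3 <- tostEquivalence(rnorm(20, 0, 5), rnorm(20, 0, 5), sesoi = 0.1)
  expect_false(isEquivalent(rep3))
  expect_error(tostEquivalence(1:2, 2:3), "3")
})

test_that("TOST p-value is non-increasing in the equivalence margin", {
  set.seed(13)
  a <- runif(30, 0.5, 0.9)
  b <- a + rnorm(30, 0.03, 0.05)
  ps <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(s)
    pValue(tostEquivalence(a, b, sesoi = s)), 0)
  expect_true(all(diff(ps) <= 1e-12))
})
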