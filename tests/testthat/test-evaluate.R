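# Brute-force one-vs-rest oracle for the diagnostic metrics, independent of
# classMetrics: expand the matrix to per-map label pairs and count.
oracleMetrics <- function(counts) {
  truth <- pred <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    truth <- c(truth, rep(i, counts[i, j]))
    pred <- c(pred, rep(j, counts[i, j]))
  }
  out <- matrix(NA_real_, 3, 4)
  for (c in 1:3) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    tn <- sum(truth != c & pred != c)
    r <- function(num, den) if (den == 0) NA_real_ else
      floor(1000 * num / den + 0.5) / 10
    out[c, ] <- c(r(tp, tp + fn), r(tn, tn + fp), r(tp, tp + fp),
                  r(tn, tn + fn))
  }
  out
}

dnnCounts <- matrix(c(10, 0, 0,
                      4, 5, 1,
                      2, 5, 3), 3, 3, byrow = TRUE)
cnnCounts <- matrix(c(10, 0, 0,
                      5, 4, 1,
                      3, 4, 3), 3, 3, byrow = TRUE)

test_that("confusion matrices count published-vs-predicted pairs", {
  cm <- confusionMatrix3(rep(0, 10), rep(0, 10))
  expect_equal(unname(cmCounts(cm)[1, ]), c(10, 0, 0))
  expect_true(all(cmCounts(confusionMatrix3(integer(0), integer(0))) == 0))
  expect_error(confusionMatrix3(0:1, 0L), "length")

  # the packaged 30-map benchmark reproduces both published matrices
  b <- experimentalBenchmark()
  expect_equal(unname(cmCounts(
    confusionMatrix3(b$published_class, b$dnn_predicted))), dnnCounts)
  expect_equal(unname(cmCounts(
    confusionMatrix3(b$published_class, b$cnn_predicted))), cnnCounts)
})

test_that("combined agreement reproduces the published percentages", {
  expect_equal(combinedAgreement(dnnCounts), 60.0)
  expect_equal(combinedAgreement(cnnCounts), 56.7)
  expect_equal(combinedAgreement(diag(c(5, 5, 5))), 100.0)
  expect_error(combinedAgreement(matrix(0, 3, 3)), "undefined|empty")
})

test_that("class metrics reproduce the published per-class table", {
  dnn <- classMetrics(dnnCounts)
  expect_equal(dnn$sensitivity, c(100.0, 50.0, 30.0))
  expect_equal(dnn$specificity, c(70.0, 75.0, 95.0))
  expect_equal(dnn$ppv, c(62.5, 50.0, 75.0))
  expect_equal(dnn$npv, c(100.0, 75.0, 73.1))
  cnn <- classMetrics(cnnCounts)
  expect_equal(cnn$sensitivity, c(100.0, 40.0, 30.0))
  expect_equal(cnn$specificity, c(60.0, 80.0, 95.0))
  expect_equal(cnn$ppv, c(55.6, 50.0, 75.0))
  expect_equal(cnn$npv, c(100.0, 72.7, 73.1))
  # diagonal-only matrix: all metrics 100
  d <- classMetrics(diag(c(4, 4, 4)))
  expect_true(all(as.matrix(d[, -1]) == 100))
})

test_that("class metrics agree with a brute-force count on random matrices", {
  set.seed(10)
  for (i in 1:25) {
    counts <- matrix(rpois(9, 4), 3, 3)
    got <- as.matrix(classMetrics(counts)[, -1])
    dimnames(got) <- NULL
    expect_equal(got, oracleMetrics(counts))
  }
})

test_that("soft-membership metrics reduce to crisp counting", {
  set.seed(11)
  truth <- sample(0:2, 40, TRUE)
  pred <- sample(0:2, 40, TRUE)
  U <- diag(3)[truth + 1, ]
  V <- diag(3)[pred + 1, ]
  soft <- classMetricsSoft(U, V)
  crisp <- classMetrics(confusionMatrix3(truth, pred))
  expect_equal(soft[, -1], crisp[, -1])
})

test_that("undefined ratios surface as NA, never 0 or 100", {
  # nothing predicted as class 3 (low) -> PPV(low) undefined
  counts <- matrix(c(5, 1, 0,
                     2, 4, 0,
                     1, 5, 0), 3, 3, byrow = TRUE)
  m <- classMetrics(counts)
  expect_true(is.na(m$ppv[3]))
  expect_false(is.na(m$npv[3]))
})

test_that("agreement equals the row-sum-weighted mean of sensitivities", {
  set.seed(12)
  for (i in 1:10) {
    counts <- matrix(rpois(9, 5) + 1, 3, 3)
    sens <- vapply(1:3, function(c) counts[c, c] / sum(counts[c, ]), 0)
    weighted <- sum(sens * rowSums(counts)) / sum(counts)
    expect_equal(combinedAgreement(counts), roundHalfUp(100 * weighted, 1))
  }
})

test_that("categorical accuracy counts in-mask matches", {
  a <- array(sample(0:9, 64, TRUE), c(4, 4, 4))
  expect_equal(categoricalAccuracy(a, a), 1.0)
  b <- a
  b[1:2, , ] <- (a[1:2, , ] + 1) %% 10   # exactly half wrong
  expect_equal(categoricalAccuracy(b, a), 0.5)
  # permutation invariance over voxels
  p <- sample(64)
  expect_equal(categoricalAccuracy(as.vector(b)[p], as.vector(a)[p]),
               0.5)
  # background exclusion via mask
  mask <- array(TRUE, c(4, 4, 4)); mask[1:2, , ] <- FALSE
  expect_equal(categoricalAccuracy(b, a, mask), 1.0)
  expect_error(categoricalAccuracy(b, a, mask & FALSE), "empty")
  # random 10-class predictions hover at chance
  set.seed(13)
  n <- 1e6
  acc <- categoricalAccuracy(sample(0:9, n, TRUE), sample(0:9, n, TRUE))
  expect_lt(abs(acc - 0.1), 0.002)
})

test_that("boundary scan of the analytic thresholds finds 5.0 and 10.5", {
  # the bare three-class thresholds (<5 high, 5-10 medium, >10 low) as
  # the "model": change points fall where the 0.5 A grid first crosses them
  res <- boundaryScan(function(m, r) threeClassLabel(r), box = 32,
                      nAtoms = 150, seed = 50)
  expect_equal(nrow(res$scan), 28L)
  expect_equal(res$scan$resolution, seq(1.5, 15, 0.5))
  expect_equal(res$boundaries, c(5.0, 10.5))
  # constant-output model: no change points
  const <- boundaryScan(function(m, r) 1L, resolutions = seq(2, 6, 1),
                        box = 16, nAtoms = 20, seed = 5)
  expect_equal(length(const$boundaries), 0L)
})
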