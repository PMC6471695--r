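# Closed-form parameter counts written out independently of countParams.
dnnParamFormula <- function(E, h1 = 1000, h2 = 100) {
  (E^3 * h1 + h1) + (h1 * h2 + h2) + (h2 * 3 + 3)
}

test_that("DNN parameter counts match the closed form at any edge", {
  expect_equal(countParams(buildDNN(64)), 262245403)
  expect_equal(countParams(buildDNN(8)), 613403)
  for (E in c(4, 16, 32)) {
    expect_equal(countParams(buildDNN(E)), dnnParamFormula(E))
  }
  expect_error(buildDNN(1), ">= 2")
})

test_that("CNN shapes and parameter arithmetic are exact", {
  spec <- buildCNN3D(64)
  sh <- inferShapes(spec)
  # after the three conv/pool blocks: 8^3 spatial with 128 channels
  post <- sh[[6]]
  expect_equal(post$edge, 8L)
  expect_equal(post$channels, 128)
  # first conv: 32 * (7^3 * 1) + 32
  expect_equal(sh[[1]]$fanIn * spec@layers[[1]]$filters +
                 spec@layers[[1]]$filters, 11008)
  # full count: convs + dense(1024) on 8^3*128 + logits
  manual <- 11008 +
    (64 * 5^3 * 32 + 64) +
    (128 * 5^3 * 64 + 128) +
    (1024 * 8^3 * 128 + 1024) +
    (3 * 1024 + 3)
  expect_equal(countParams(spec), manual)
  expect_error(buildCNN3D(60), "divisible")
})

test_that("U-Net shapes: root at 1^3, ten-channel voxel output", {
  spec <- buildUNet3D(16)
  sh <- inferShapes(spec)
  rootConv <- sh[[17]]  # first conv after the four pools
  expect_equal(rootConv$edge, 1L)
  expect_equal(rootConv$channels, 1024)
  last <- sh[[length(sh)]]
  expect_equal(last$edge, 16L)
  expect_equal(last$channels, 10L)
  expect_error(buildUNet3D(8), "power of two")
  # desk-scale variant keeps the topology, shrinks the widths
  small <- buildUNet3D(16, baseFilters = 2)
  expect_equal(inferShapes(small)[[17]]$channels, 32)
})

test_that("softmax outputs are probabilities and ties break low", {
  set.seed(20)
  spec <- buildDNN(8, hidden = c(12, 6))
  w <- cryores:::initNetwork(spec)
  X <- array(runif(3 * 8^3), c(3, 8, 8, 8))
  fwd <- cryores:::forwardNetwork(spec, w, X)
  P <- cryores:::softmaxCols(fwd$outs[[length(spec@layers)]])
  expect_equal(colSums(P), rep(1, 3))
  expect_true(all(P >= 0))
  # argmax tie-break: equal logits resolve to the lowest class index
  tied <- matrix(c(0.5, 0.5, 0), 3, 1)
  expect_equal(max.col(t(tied), ties.method = "first") - 1L, 0L)
})

test_that("analytic gradients match finite differences through the CNN", {
  set.seed(42)
  spec <- buildCNN3D(8, filters = c(2, 3, 4), denseUnits = 5)
  w <- cryores:::initNetwork(spec)
  X <- array(rnorm(3 * 8^3), c(3, 8, 8, 8))
  y <- c(0L, 1L, 2L)
  lossOf <- function(w) {
    fwd <- cryores:::forwardNetwork(spec, w, X)
    cryores:::globalLoss(fwd$outs[[length(spec@layers)]], y)$loss
  }
  fwd <- cryores:::forwardNetwork(spec, w, X)
  lr <- cryores:::globalLoss(fwd$outs[[length(spec@layers)]], y)
  g <- cryores:::backwardNetwork(spec, w, X, fwd, lr$dZ)
  eps <- 1e-6
  for (li in c(1, 3, 5, 8, 9)) {
    for (trial in 1:3) {
      i <- sample(length(w[[li]]$W), 1)
      wp <- w; wp[[li]]$W[i] <- wp[[li]]$W[i] + eps
      wm <- w; wm[[li]]$W[i] <- wm[[li]]$W[i] - eps
      num <- (lossOf(wp) - lossOf(wm)) / (2 * eps)
      expect_equal(g[[li]]$W[i], num, tolerance = 1e-4)
    }
  }
})

test_that("analytic gradients match finite differences through the U-Net", {
  set.seed(7)
  spec <- buildUNet3D(16, baseFilters = 1)
  w <- cryores:::initNetwork(spec)
  X <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  y <- array(sample(0:9, 2 * 16^3, TRUE), c(2, 16, 16, 16))
  y[1, 1:4, , ] <- -1   # background voxels must not contribute
  yv <- as.vector(aperm(y, c(2, 3, 4, 1)))
  lossOf <- function(w) {
    fwd <- cryores:::forwardNetwork(spec, w, X)
    cryores:::voxelLoss(fwd$outs[[length(spec@layers)]], yv, -1)$loss
  }
  fwd <- cryores:::forwardNetwork(spec, w, X)
  lr <- cryores:::voxelLoss(fwd$outs[[length(spec@layers)]], yv, -1)
  g <- cryores:::backwardNetwork(spec, w, X, fwd, lr$dZ)
  eps <- 1e-6
  convs <- which(vapply(spec@layers, function(l) l$type == "conv3", TRUE))
  for (li in convs[c(1, 5, 9, 11, 14, 19)]) {
    i <- sample(length(w[[li]]$W), 1)
    wp <- w; wp[[li]]$W[i] <- wp[[li]]$W[i] + eps
    wm <- w; wm[[li]]$W[i] <- wm[[li]]$W[i] - eps
    num <- (lossOf(wp) - lossOf(wm)) / (2 * eps)
    expect_equal(g[[li]]$W[i], num, tolerance = 5e-3)
  }
})

test_that("training traces, early stopping and determinism behave", {
  set.seed(1)
  # separable toy set: constant-0 maps vs constant-1 maps
  X <- array(0, c(8, 8, 8, 8)) ; X[5:8, , , ] <- 1
  y <- c(rep(0L, 4), rep(1L, 4))
  spec <- buildDNN(8, hidden = c(8, 4))
  cfgShort <- TrainConfig(batchSize = 4, maxEpochs = 1, patience = 0,
                          seed = 3)
  tr <- trainNetwork(spec, X, y, X, y, cfgShort)
  expect_equal(nrow(tr@trace), 1L)

  cfg <- TrainConfig(batchSize = 4, maxEpochs = 50, patience = 10, seed = 3)
  t1 <- trainNetwork(spec, X, y, X, y, cfg)
  expect_equal(t1@trace$val_acc[t1@bestEpoch], 1.0)
  # never runs more than `patience` epochs past the best validation loss
  expect_lte(nrow(t1@trace), t1@bestEpoch + cfg@patience)
  # same seed twice: identical traces
  t2 <- trainNetwork(spec, X, y, X, y, cfg)
  expect_identical(t1@trace, t2@trace)
  # label/architecture mismatch fails before training
  expect_error(
    trainNetwork(spec, X, array(0, c(8, 8, 8, 8)), X, y, cfg),
    "label kind")
  expect_error(
    trainNetwork(buildUNet3D(16, baseFilters = 1), X, y, X, y,
                 TrainConfig(loss = "categorical_ce")),
    "label kind")
})

test_that("prediction validates input shapes", {
  set.seed(2)
  spec <- buildDNN(8, hidden = c(6, 3))
  X <- array(runif(4 * 8^3), c(4, 8, 8, 8))
  y <- c(0L, 1L, 2L, 0L)
  net <- trainNetwork(spec, X, y, X, y,
                      TrainConfig(batchSize = 4, maxEpochs = 2,
                                  patience = 2, seed = 1))
  p <- predictNetwork(net, X)
  expect_length(p, 4L)
  expect_true(all(p %in% 0:2))
  probs <- predictNetwork(net, X, type = "prob")
  expect_equal(rowSums(probs), rep(1, 4))
  expect_error(predictNetwork(net, array(0, c(1, 4, 4, 4))), "shape|edge")
  # a bare 3D array is promoted to a batch of one
  expect_length(predictNetwork(net, X[1, , , ]), 1L)
})
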