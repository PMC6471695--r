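# Forward/backward orchestration for the three architectures.
#
# Volumetric activations travel as (channels x nvox*N) matrices with
# attributes edge/N (x-fastest voxel order within each sample block);
# flattened activations as (features x N) matrices. Activation gradients
# are computed from the outputs (possible for ReLU/ELU/tanh), so no
# pre-activation caches are kept.

volFeature <- function(X) {
  # (N, E, E, E) array -> (1, nvox*N) matrix
  d <- dim(X)
  m <- matrix(as.vector(aperm(X, c(2, 3, 4, 1))), nrow = 1)
  attr(m, "edge") <- d[2]
  attr(m, "N") <- d[1]
  m
}

featVol <- function(v, edge, N) {
  # per-voxel vector (nvox*N) -> (N, E, E, E) array
  aperm(array(v, c(edge, edge, edge, N)), c(4, 1, 2, 3))
}

applyActivation <- function(Z, act) {
  switch(act,
    relu = pmax(Z, 0),
    elu = {
      neg <- which(Z < 0)   # which() drops NaNs: divergence propagates
      Z[neg] <- expm1(Z[neg])
      Z
    },
    tanh = tanh(Z),
    linear = Z,
    softmax = Z,   # handled by the loss / predictor
    stop("unknown activation: ", act))
}

activationGradFromOutput <- function(A, act) {
  switch(act,
    relu = (A > 0) * 1,
    elu = {
      g <- A + 1
      g[which(A > 0)] <- 1
      g
    },
    tanh = 1 - A^2,
    linear = 1,
    softmax = 1,
    stop("unknown activation: ", act))
}

initNetwork <- function(spec) {
  # He-normal fan-in initialization for ReLU/ELU layers, Glorot otherwise;
  # draws come from the active R RNG stream so training is seed-reproducible
  shapes <- inferShapes(spec)
  weights <- vector("list", length(spec@layers))
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    if (!ly$type %in% c("dense", "conv3")) next
    sh <- shapes[[i]]
    nOut <- if (ly$type == "dense") sh$units else ly$filters
    fanIn <- sh$fanIn
    sd <- if (ly$activation %in% c("relu", "elu")) sqrt(2 / fanIn) else
      sqrt(2 / (fanIn + nOut))
    weights[[i]] <- list(
      W = matrix(stats::rnorm(nOut * fanIn, sd = sd), nOut, fanIn),
      b = rep(0, nOut))
  }
  weights
}

forwardNetwork <- function(spec, weights, X, training = FALSE) {
  nLayers <- length(spec@layers)
  outs <- vector("list", nLayers)
  caches <- vector("list", nLayers)
  tagIndex <- list()
  cur <- volFeature(X)
  N <- attr(cur, "N")
  for (i in seq_len(nLayers)) {
    ly <- spec@layers[[i]]
    cur <- switch(ly$type,
      flatten = {
        edge <- attr(cur, "edge")
        m <- cur
        dim(m) <- c(nrow(cur) * edge^3, N)
        m
      },
      dense = {
        Z <- weights[[i]]$W %*% cur + weights[[i]]$b
        A <- applyActivation(Z, ly$activation)
        if (training && !is.null(ly$dropout) && ly$dropout > 0) {
          keep <- 1 - ly$dropout
          mask <- (matrix(stats::runif(length(A)), nrow(A)) < keep) / keep
          caches[[i]]$mask <- mask
          A <- A * mask
        }
        A
      },
      conv3 = {
        edge <- attr(cur, "edge")
        Z <- cr_conv3_fwd(cur, weights[[i]]$W, weights[[i]]$b, edge,
                          ly$kernel, N)
        A <- applyActivation(Z, ly$activation)
        attr(A, "edge") <- edge
        A
      },
      pool3 = {
        edge <- attr(cur, "edge")
        r <- cr_maxpool_fwd(cur, edge, N)
        caches[[i]]$idx <- r$idx
        caches[[i]]$nvoxIn <- edge^3
        Y <- r$Y
        attr(Y, "edge") <- edge %/% 2L
        Y
      },
      upsample3 = {
        edge <- attr(cur, "edge")
        Y <- cr_upsample_fwd(cur, edge, N)
        attr(Y, "edge") <- edge * 2L
        Y
      },
      sdrop = {
        edge <- attr(cur, "edge")
        A <- cur
        if (training && ly$rate > 0) {
          keep <- 1 - ly$rate
          cmask <- (matrix(stats::runif(nrow(cur) * N), nrow(cur)) < keep) /
            keep
          mask <- cmask[, rep(seq_len(N), each = edge^3), drop = FALSE]
          caches[[i]]$mask <- mask
          A <- cur * mask
        }
        attr(A, "edge") <- edge
        A
      },
      concat = {
        edge <- attr(cur, "edge")
        skip <- outs[[tagIndex[[ly$skip]]]]
        caches[[i]]$skipChannels <- nrow(skip)
        Y <- rbind(skip, cur)
        attr(Y, "edge") <- edge
        Y
      })
    if (!is.null(ly$tag)) tagIndex[[ly$tag]] <- i
    outs[[i]] <- cur
  }
  list(outs = outs, caches = caches, tagIndex = tagIndex, N = N)
}

backwardNetwork <- function(spec, weights, X, fwd, dTop) {
  nLayers <- length(spec@layers)
  outs <- fwd$outs
  caches <- fwd$caches
  N <- fwd$N
  skipOf <- integer(0)
  for (i in seq_len(nLayers)) {
    ly <- spec@layers[[i]]
    if (ly$type == "concat") skipOf[i] <- fwd$tagIndex[[ly$skip]]
  }
  grads <- vector("list", nLayers)   # grad wrt each layer's output
  gradsW <- vector("list", nLayers)
  grads[[nLayers]] <- dTop
  inputOf <- function(i) if (i == 1L) volFeature(X) else outs[[i - 1L]]
  addGrad <- function(g, i, d) {
    if (is.null(g[[i]])) g[[i]] <- d else g[[i]] <- g[[i]] + d
    g
  }
  for (i in rev(seq_len(nLayers))) {
    ly <- spec@layers[[i]]
    dOut <- grads[[i]]
    if (is.null(dOut)) next
    Xin <- inputOf(i)
    dIn <- switch(ly$type,
      flatten = {
        m <- dOut
        dim(m) <- c(nrow(Xin), ncol(Xin))
        m
      },
      dense = {
        if (!is.null(caches[[i]]$mask)) dOut <- dOut * caches[[i]]$mask
        dZ <- dOut * activationGradFromOutput(outs[[i]], ly$activation)
        gradsW[[i]] <- list(W = dZ %*% t(Xin), b = rowSums(dZ))
        t(weights[[i]]$W) %*% dZ
      },
      conv3 = {
        edge <- attr(outs[[i]], "edge")
        dZ <- dOut * activationGradFromOutput(outs[[i]], ly$activation)
        r <- cr_conv3_bwd(Xin, weights[[i]]$W, dZ, edge, ly$kernel, N)
        gradsW[[i]] <- list(W = r$dW, b = as.vector(r$db))
        r$dX
      },
      pool3 = cr_maxpool_bwd(dOut, caches[[i]]$idx, caches[[i]]$nvoxIn, N),
      upsample3 = cr_upsample_bwd(dOut, attr(outs[[i]], "edge"), N),
      sdrop = if (is.null(caches[[i]]$mask)) dOut else
        dOut * caches[[i]]$mask,
      concat = {
        cs <- caches[[i]]$skipChannels
        grads <- addGrad(grads, skipOf[i], dOut[seq_len(cs), , drop = FALSE])
        dOut[-seq_len(cs), , drop = FALSE]
      })
    if (i > 1L) grads <- addGrad(grads, i - 1L, dIn)
    grads[i] <- list(NULL)  # release; plain [[<- NULL would shift the list
  }
  gradsW
}

softmaxCols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max), `-`)
  E <- exp(Z)
  sweep(E, 2, colSums(E), `/`)
}

# Sparse softmax cross-entropy on integer global labels (0-based).
globalLoss <- function(logits, y) {
  P <- softmaxCols(logits)
  n <- length(y)
  idx <- cbind(y + 1L, seq_len(n))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dZ = dZ / n, P = P)
}

# Categorical cross-entropy over voxels; background-sentinel voxels carry
# zero weight in both loss and gradient.
voxelLoss <- function(logits, y, background) {
  P <- softmaxCols(logits)
  w <- as.numeric(y != background)
  tot <- sum(w)
  if (tot == 0) stop("no in-mask voxels in batch")
  yi <- ifelse(w > 0, y, 0)
  idx <- cbind(yi + 1L, seq_along(y))
  loss <- -sum(w * log(pmax(P[idx], 1e-12))) / tot
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  dZ <- sweep(dZ, 2, w / tot, `*`)
  list(loss = loss, dZ = dZ, P = P)
}

makeOptimizer <- function(config, weights) {
  if (config@optimizer == "sgd") {
    list(step = function(weights, grads) {
      for (i in seq_along(weights)) {
        if (is.null(grads[[i]])) next
        weights[[i]]$W <- weights[[i]]$W - config@learningRate * grads[[i]]$W
        weights[[i]]$b <- weights[[i]]$b - config@learningRate * grads[[i]]$b
      }
      weights
    })
  } else {
    state <- new.env()
    state$t <- 0
    state$m <- state$v <- lapply(weights, function(w)
      if (is.null(w)) NULL else list(W = w$W * 0, b = w$b * 0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    list(step = function(weights, grads) {
      state$t <- state$t + 1
      corr1 <- 1 - b1^state$t
      corr2 <- 1 - b2^state$t
      for (i in seq_along(weights)) {
        if (is.null(grads[[i]])) next
        for (p in c("W", "b")) {
          g <- grads[[i]][[p]]
          state$m[[i]][[p]] <- b1 * state$m[[i]][[p]] + (1 - b1) * g
          state$v[[i]][[p]] <- b2 * state$v[[i]][[p]] + (1 - b2) * g^2
          weights[[i]][[p]] <- weights[[i]][[p]] - config@learningRate *
            (state$m[[i]][[p]] / corr1) /
            (sqrt(state$v[[i]][[p]] / corr2) + eps)
        }
      }
      weights
    })
  }
}

labelsMatchArchitecture <- function(spec, y) {
  if (spec@architecture %in% c("dnn", "cnn3d"))
    is.atomic(y) && is.null(dim(y))
  else
    is.array(y) && length(dim(y)) == 4L
}

evalNetwork <- function(spec, weights, X, y, background = -1,
                        chunk = 16L) {
  n <- dim(X)[1]
  totLoss <- 0; totAcc <- 0; totW <- 0
  for (s in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    fwd <- forwardNetwork(spec, weights, X[s, , , , drop = FALSE],
                          training = FALSE)
    logits <- fwd$outs[[length(spec@layers)]]
    if (spec@architecture %in% c("dnn", "cnn3d")) {
      r <- globalLoss(logits, y[s])
      pred <- max.col(t(r$P), ties.method = "first") - 1L
      totLoss <- totLoss + r$loss * length(s)
      totAcc <- totAcc + sum(pred == y[s])
      totW <- totW + length(s)
    } else {
      edge <- spec@inputEdge
      yv <- as.vector(aperm(y[s, , , , drop = FALSE], c(2, 3, 4, 1)))
      r <- voxelLoss(logits, yv, background)
      w <- yv != background
      pred <- max.col(t(r$P), ties.method = "first") - 1L
      totLoss <- totLoss + r$loss * sum(w)
      totAcc <- totAcc + sum(pred[w] == yv[w])
      totW <- totW + sum(w)
    }
  }
  list(loss = totLoss / totW, acc = totAcc / totW)
}

#' Train a network
#'
#' Minibatch training with the configured optimizer and loss; after every
#' epoch the validation loss and accuracy are recorded, the weights with
#' the smallest validation loss are retained, and training stops once the
#' validation loss has not improved for \code{patience} epochs (or at
#' \code{maxEpochs}). Fully reproducible given the config seed: weight
#' initialization, shuffling and dropout all draw from one seeded stream.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param trainX,valX rank-4 arrays (N, E, E, E) of inputs.
#' @param trainY,valY integer class vectors (0..2) for the global
#'   classifiers, or rank-4 label arrays (values 0..9 or the background
#'   sentinel) for the U-Net.
#' @param config a \linkS4class{TrainConfig}; the loss must match the
#'   architecture ("sparse_ce" for dnn/cnn3d, "categorical_ce" for unet3d).
#' @param background label sentinel excluded from loss and accuracy.
#' @param verbose print one line per epoch.
#' @return A \linkS4class{TrainedNetwork} holding the best-epoch weights
#'   and the per-epoch validation trace.
#' @export
trainNetwork <- function(spec, trainX, trainY, valX, valY, config,
                         background = -1, verbose = FALSE) {
  stopifnot(is(spec, "NetworkSpec"), is(config, "TrainConfig"))
  if (!labelsMatchArchitecture(spec, trainY) ||
      !labelsMatchArchitecture(spec, valY))
    stop("label kind does not match the architecture (global classifiers ",
         "take integer class vectors; the U-Net takes voxel label cubes)")
  wantLoss <- if (spec@architecture == "unet3d") "categorical_ce" else
    "sparse_ce"
  if (config@loss != wantLoss)
    stop("architecture ", spec@architecture, " requires the ", wantLoss,
         " loss")
  if (dim(trainX)[1] == 0L || dim(valX)[1] == 0L)
    stop("training and validation sets must be non-empty")
  set.seed(config@seed)
  weights <- initNetwork(spec)
  opt <- makeOptimizer(config, weights)
  nTrain <- dim(trainX)[1]
  trace <- data.frame(epoch = integer(0), val_loss = numeric(0),
                      val_acc = numeric(0))
  best <- Inf; bestEpoch <- 0L; bestWeights <- weights
  voxel <- spec@architecture == "unet3d"
  for (epoch in seq_len(config@maxEpochs)) {
    perm <- sample.int(nTrain)
    for (s in split(perm, ceiling(seq_along(perm) / config@batchSize))) {
      Xb <- trainX[s, , , , drop = FALSE]
      fwd <- forwardNetwork(spec, weights, Xb, training = TRUE)
      logits <- fwd$outs[[length(spec@layers)]]
      lr <- if (voxel) {
        yv <- as.vector(aperm(trainY[s, , , , drop = FALSE], c(2, 3, 4, 1)))
        voxelLoss(logits, yv, background)
      } else {
        globalLoss(logits, trainY[s])
      }
      grads <- backwardNetwork(spec, weights, Xb, fwd, lr$dZ)
      if (is.finite(config@clipNorm)) {
        gn <- sqrt(sum(vapply(grads, function(g)
          if (is.null(g)) 0 else sum(g$W^2) + sum(g$b^2), 0)))
        if (is.finite(gn) && gn > config@clipNorm) {
          sc <- config@clipNorm / gn
          grads <- lapply(grads, function(g)
            if (is.null(g)) NULL else list(W = g$W * sc, b = g$b * sc))
        }
      }
      weights <- opt$step(weights, grads)
    }
    ev <- evalNetwork(spec, weights, valX, valY, background)
    trace <- rbind(trace, data.frame(epoch = epoch, val_loss = ev$loss,
                                     val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %3d  val_loss %.4f  val_acc %.4f",
                      epoch, ev$loss, ev$acc))
    if (is.finite(ev$loss) && ev$loss < best - 1e-12) {
      best <- ev$loss; bestEpoch <- epoch; bestWeights <- weights
    }
    if (epoch - bestEpoch >= config@patience) break
  }
  new("TrainedNetwork", spec = spec, weights = bestWeights, trace = trace,
      bestEpoch = bestEpoch)
}

#' Predict with a trained network
#'
#' Global classifiers return the argmax class (0 = high, 1 = medium,
#' 2 = low; ties resolve to the lowest index). The U-Net returns per-voxel
#' argmax classes as a rank-4 array. \code{type = "prob"} returns softmax
#' probabilities instead.
#'
#' @param trained a \linkS4class{TrainedNetwork}.
#' @param X rank-4 input array (N, E, E, E); a single 3D array or
#'   \linkS4class{DensityMap} is promoted to a batch of one.
#' @param type "class" or "prob".
#' @return Integer classes (vector or rank-4 array) or probabilities.
#' @export
predictNetwork <- function(trained, X, type = c("class", "prob")) {
  type <- match.arg(type)
  stopifnot(is(trained, "TrainedNetwork"))
  spec <- trained@spec
  if (is(X, "DensityMap")) X <- mapData(X)
  if (length(dim(X)) == 3L) {
    X <- array(X, c(1L, dim(X)))
  }
  if (!identical(as.integer(dim(X)[2:4]), rep(spec@inputEdge, 3L)))
    stop("input shape ", paste(dim(X)[2:4], collapse = "x"),
         " does not match the network input edge ", spec@inputEdge)
  n <- dim(X)[1]
  edge <- spec@inputEdge
  global <- spec@architecture %in% c("dnn", "cnn3d")
  outClass <- if (global) integer(n) else array(0L, dim(X))
  outProb <- NULL
  for (s in split(seq_len(n), ceiling(seq_len(n) / 16))) {
    fwd <- forwardNetwork(spec, trained@weights, X[s, , , , drop = FALSE],
                          training = FALSE)
    P <- softmaxCols(fwd$outs[[length(spec@layers)]])
    if (global) {
      if (type == "prob") {
        if (is.null(outProb)) outProb <- matrix(0, n, spec@nClasses)
        outProb[s, ] <- t(P)
      }
      outClass[s] <- max.col(t(P), ties.method = "first") - 1L
    } else {
      cls <- max.col(t(P), ties.method = "first") - 1L
      outClass[s, , , ] <- featVol(cls, edge, length(s))
      if (type == "prob") {
        if (is.null(outProb))
          outProb <- array(0, c(n, edge, edge, edge, spec@nClasses))
        for (k in seq_len(spec@nClasses))
          outProb[s, , , , k] <- featVol(P[k, ], edge, length(s))
      }
    }
  }
  if (type == "prob") outProb else outClass
}
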