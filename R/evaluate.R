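#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention under
#' which the package's reported percentages match hand-rounded tables;
#' R's \code{round} rounds half to even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

classNames3 <- c("high", "medium", "low")

#' Build a 3x3 confusion matrix of resolution classes
#'
#' Counts maps by (published, predicted) class pair; rows are the published
#' (true) class, columns the predicted class, both ordered
#' high/medium/low. Accepts integer codes 0/1/2 or the class names.
#'
#' @param truth,predicted equal-length vectors of classes.
#' @return A \linkS4class{ConfusionMatrix3}.
#' @export
confusionMatrix3 <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  norm <- function(x) {
    if (is.numeric(x)) {
      if (!all(x %in% 0:2)) stop("class codes must be 0, 1 or 2")
      factor(classNames3[x + 1L], levels = classNames3)
    } else {
      x <- tolower(as.character(x))
      if (!all(x %in% classNames3)) stop("unknown class name")
      factor(x, levels = classNames3)
    }
  }
  counts <- unclass(table(norm(truth), norm(predicted)))
  counts <- matrix(as.numeric(counts), 3, 3,
                   dimnames = list(published = classNames3,
                                   predicted = classNames3))
  new("ConfusionMatrix3", counts = counts)
}

#' Combined agreement of a confusion matrix
#'
#' Percentage of maps whose predicted class equals the published class:
#' 100 * trace / total, reported to one decimal (half-up).
#'
#' @param cm a \linkS4class{ConfusionMatrix3} (or plain 3x3 matrix).
#' @return agreement percentage, one decimal.
#' @export
combinedAgreement <- function(cm) {
  counts <- if (is(cm, "ConfusionMatrix3")) cm@counts else cm
  total <- sum(counts)
  if (total == 0) stop("undefined metric: empty confusion matrix")
  roundHalfUp(100 * sum(diag(counts)) / total, 1)
}

#' Per-class sensitivity, specificity, PPV and NPV
#'
#' Computes the four diagnostic measures for each resolution class from a
#' 3x3 confusion matrix using partial-class-membership counting, which for
#' crisp (0/1) labels reduces to one-vs-rest TP/FP/TN/FN counts:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN). Percentages are rounded half-up to one decimal.
#' Undefined ratios (zero denominators) are returned as NA, never as 0 or
#' 100.
#'
#' @param cm a \linkS4class{ConfusionMatrix3} (or plain 3x3 matrix).
#' @return data.frame with columns \code{class}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv} (percentages).
#' @export
classMetrics <- function(cm) {
  counts <- if (is(cm, "ConfusionMatrix3")) cm@counts else cm
  n <- sum(counts)
  out <- data.frame(class = classNames3, sensitivity = NA_real_,
                    specificity = NA_real_, ppv = NA_real_,
                    npv = NA_real_)
  pct <- function(num, den) if (den == 0) NA_real_ else
    roundHalfUp(100 * num / den, 1)
  for (c in 1:3) {
    tp <- counts[c, c]
    fn <- sum(counts[c, -c])
    fp <- sum(counts[-c, c])
    tn <- n - tp - fn - fp
    out$sensitivity[c] <- pct(tp, tp + fn)
    out$specificity[c] <- pct(tn, tn + fp)
    out$ppv[c] <- pct(tp, tp + fp)
    out$npv[c] <- pct(tn, tn + fn)
  }
  out
}

#' Diagnostic metrics from soft class memberships
#'
#' The general partial-class-membership form of [classMetrics()]: rows of
#' \code{truthM}/\code{predM} are per-sample membership vectors (each
#' summing to 1). With product-weighted counts TP_c = sum(u_c v_c),
#' FP_c = sum((1-u_c) v_c), FN_c = sum(u_c (1-v_c)), TN_c = the remainder,
#' crisp 0/1 memberships reproduce [classMetrics()] exactly.
#'
#' @param truthM,predM n x k membership matrices.
#' @return data.frame as in [classMetrics()] with one row per class.
#' @export
classMetricsSoft <- function(truthM, predM) {
  stopifnot(identical(dim(truthM), dim(predM)))
  k <- ncol(truthM)
  nm <- if (k == 3) classNames3 else paste0("class", seq_len(k) - 1)
  out <- data.frame(class = nm, sensitivity = NA_real_,
                    specificity = NA_real_, ppv = NA_real_, npv = NA_real_)
  pct <- function(num, den) if (den == 0) NA_real_ else
    roundHalfUp(100 * num / den, 1)
  for (c in seq_len(k)) {
    u <- truthM[, c]; v <- predM[, c]
    tp <- sum(u * v)
    fp <- sum((1 - u) * v)
    fn <- sum(u * (1 - v))
    tn <- sum((1 - u) * (1 - v))
    out$sensitivity[c] <- pct(tp, tp + fn)
    out$specificity[c] <- pct(tn, tn + fp)
    out$ppv[c] <- pct(tp, tp + fp)
    out$npv[c] <- pct(tn, tn + fn)
  }
  out
}

#' Voxel-wise categorical accuracy
#'
#' Fraction of in-mask voxels whose predicted class equals the label class.
#'
#' @param pred,truth arrays (or vectors) of identical shape holding class
#'   codes.
#' @param mask optional logical/0-1 array selecting the voxels to score;
#'   by default all voxels count.
#' @return accuracy in [0, 1].
#' @export
categoricalAccuracy <- function(pred, truth, mask = NULL) {
  if (!identical(dim(pred), dim(truth)) ||
      length(pred) != length(truth))
    stop("pred and truth must have identical shape")
  if (is.null(mask)) mask <- rep(TRUE, length(pred))
  m <- as.logical(mask)
  if (sum(m) == 0) stop("undefined metric: empty mask")
  mean(pred[m] == truth[m])
}

#' Resolution-boundary scan of a trained global classifier
#'
#' Simulates one map per grid resolution (a distinct seeded synthetic
#' structure per resolution), preprocesses it like the training data
#' (min-max normalization), runs the classifier, and reports the predicted
#' class per resolution together with the change points — the resolutions
#' at which the prediction first switches class. The default grid is
#' 1.5 to 15.0 A in 0.5 A steps (28 maps).
#'
#' @param model either a \linkS4class{TrainedNetwork} or a function
#'   \code{f(map, resolution)} returning a class code 0/1/2 (useful for
#'   analytic reference classifiers, e.g. the bare three-class thresholds).
#' @param resolutions strictly increasing grid (default seq(1.5, 15, 0.5)).
#' @param box,voxelSize simulation geometry (match the classifier's input).
#' @param nAtoms atoms per synthetic structure.
#' @param seed base seed; structure for grid entry i uses seed + i.
#' @return list with \code{scan} (data.frame resolution/class) and
#'   \code{boundaries} (resolutions where the class changes).
#' @export
boundaryScan <- function(model, resolutions = seq(1.5, 15, by = 0.5),
                         box = 64, voxelSize = 1, nAtoms = 300, seed = 100) {
  if (is.unsorted(resolutions, strictly = TRUE))
    stop("resolutions must be strictly increasing")
  classify <- if (is(model, "TrainedNetwork")) {
    if (model@bestEpoch < 1L) stop("model has not been trained")
    function(m, r) predictNetwork(model, mapData(m))
  } else if (is.function(model)) {
    model
  } else stop("model must be a TrainedNetwork or a function")
  cls <- integer(length(resolutions))
  for (i in seq_along(resolutions)) {
    struct <- makeSyntheticModel(nAtoms, extent = 0.6 * box * voxelSize,
                                 seed = seed + i)
    m <- suppressWarnings(simulateMap(struct, resolutions[i], box = box,
                                      voxelSize = voxelSize))
    cls[i] <- classify(minMaxNormalize(m), resolutions[i])
  }
  change <- which(diff(cls) != 0) + 1L
  list(scan = data.frame(resolution = resolutions, class = cls),
       boundaries = resolutions[change])
}

#' Cross-evaluation accuracy grid
#'
#' Evaluates every model on every labelled evaluation set and tabulates the
#' voxel-wise categorical accuracies: rows are evaluation sets, columns are
#' models. Incompatible pairs yield NA in their cell (with a warning)
#' rather than aborting the grid.
#'
#' @param models named list of \linkS4class{TrainedNetwork}s.
#' @param evalSets named list; each element a list with rank-4 \code{inputs}
#'   and \code{labels} arrays (background sentinel allowed).
#' @param background label sentinel excluded from scoring.
#' @return numeric matrix (sets x models) of accuracies.
#' @export
crossEvaluate <- function(models, evalSets, background = -1) {
  grid <- matrix(NA_real_, length(evalSets), length(models),
                 dimnames = list(names(evalSets), names(models)))
  for (i in seq_along(evalSets)) {
    for (j in seq_along(models)) {
      grid[i, j] <- tryCatch({
        pred <- predictNetwork(models[[j]], evalSets[[i]]$inputs)
        labs <- evalSets[[i]]$labels
        categoricalAccuracy(pred, labs, mask = labs != background)
      }, error = function(e) {
        warning("cross-evaluation cell (", i, ",", j, ") failed: ",
                conditionMessage(e))
        NA_real_
      })
    }
  }
  grid
}
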