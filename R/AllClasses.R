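#' @import methods
NULL

#' DensityMap: a 3D scalar density grid
#'
#' The universal volume currency of the package: a three-dimensional scalar
#' grid together with its sampling rate (Angstrom per voxel, per axis) and
#' the Angstrom offset of the grid corner. Data are indexed logically as
#' \code{[x, y, z]}; voxel centres sit at \code{origin + (i + 0.5) * voxelSize}
#' for 0-based index \code{i}.
#'
#' @slot data 3D numeric array, dimensions \code{(nx, ny, nz)}.
#' @slot voxelSize numeric length-3, Angstrom per voxel along x, y, z.
#' @slot origin numeric length-3, Angstrom offset of the grid corner.
#' @export
setClass("DensityMap",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("data must be a 3D array")
    if (any(dim(d) < 1L)) return("all three dimensions must be >= 1")
    if (length(object@voxelSize) != 3L) return("voxelSize must have length 3")
    if (any(!is.finite(object@voxelSize)) || any(object@voxelSize <= 0))
      return("voxelSize must be positive and finite")
    if (length(object@origin) != 3L) return("origin must have length 3")
    if (any(!is.finite(d))) return("data values must be finite")
    TRUE
  }
)

#' Construct a DensityMap
#'
#' @param data 3D numeric array.
#' @param voxelSize Angstrom per voxel; a scalar is recycled to all axes.
#' @param origin Angstrom offset of the grid corner (length 3).
#' @return A \linkS4class{DensityMap}.
#' @examples
#' m <- DensityMap(array(0, c(8, 8, 8)))
#' dim(mapData(m))
#' @export
DensityMap <- function(data, voxelSize = 1, origin = c(0, 0, 0)) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("DensityMap", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' AtomicModel: atom positions with per-atom weights
#'
#' A minimal atomic model: Cartesian coordinates in Angstrom and a positive
#' scalar weight per atom (1 by default, optionally the atomic number). An
#' empty model (zero atoms) is legal and rasterizes to an all-zero map.
#'
#' @slot positions numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @slot weights positive numeric vector, one entry per atom.
#' @slot elements character vector of element symbols (may be empty).
#' @export
setClass("AtomicModel",
  representation(positions = "matrix", weights = "numeric",
                 elements = "character"),
  validity = function(object) {
    p <- object@positions
    if (ncol(p) != 3L) return("positions must have 3 columns")
    if (any(!is.finite(p))) return("positions must be finite")
    if (length(object@weights) != nrow(p))
      return("weights length must equal the number of atoms")
    if (any(object@weights <= 0)) return("weights must be > 0")
    TRUE
  }
)

#' Construct an AtomicModel
#'
#' @param positions n x 3 numeric matrix of coordinates in Angstrom.
#' @param weights per-atom positive weights; scalar recycled. Default 1.
#' @param elements optional element symbols.
#' @return An \linkS4class{AtomicModel}.
#' @export
AtomicModel <- function(positions = matrix(numeric(0), 0, 3), weights = 1,
                        elements = character(0)) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L && nrow(positions) == 0L)
    positions <- matrix(numeric(0), 0, 3)
  n <- nrow(positions)
  if (length(weights) == 1L) weights <- rep(as.numeric(weights), n)
  new("AtomicModel", positions = positions, weights = as.numeric(weights),
      elements = as.character(elements))
}

#' LabeledVolume: a density map paired with a resolution label
#'
#' Couples a \linkS4class{DensityMap} with either one global resolution class
#' (0 = high, 1 = medium, 2 = low) or a per-voxel class volume with values in
#' 0..9 plus a background sentinel for voxels outside the structure mask.
#'
#' @slot map the \linkS4class{DensityMap}.
#' @slot globalClass integer global class, or NA when labels are voxel-wise.
#' @slot voxelLabels numeric array of per-voxel classes (same dimensions as
#'   the map) or a zero-length array when the label is global.
#' @slot background the sentinel value marking out-of-mask voxels.
#' @export
setClass("LabeledVolume",
  representation(map = "DensityMap", globalClass = "integer",
                 voxelLabels = "array", background = "numeric"),
  validity = function(object) {
    hasVox <- length(object@voxelLabels) > 0L
    if (!hasVox && is.na(object@globalClass))
      return("either a global class or voxel labels must be present")
    if (hasVox) {
      if (!identical(dim(object@voxelLabels), dim(object@map@data)))
        return("voxelLabels dimensions must match the map")
      v <- object@voxelLabels
      ok <- v == object@background | (v >= 0 & v <= 9 & v == floor(v))
      if (!all(ok))
        return("voxel labels must be classes 0..9 or the background sentinel")
    } else if (!(object@globalClass %in% 0:2)) {
      return("global class must be 0 (high), 1 (medium) or 2 (low)")
    }
    TRUE
  }
)

#' Construct a LabeledVolume
#'
#' @param map a \linkS4class{DensityMap}.
#' @param globalClass integer 0/1/2 global resolution class (or NA).
#' @param voxelLabels per-voxel class array (or NULL for a global label).
#' @param background sentinel value for out-of-mask voxels (default -1).
#' @return A \linkS4class{LabeledVolume}.
#' @export
LabeledVolume <- function(map, globalClass = NA_integer_, voxelLabels = NULL,
                          background = -1) {
  if (is.null(voxelLabels)) voxelLabels <- array(numeric(0), c(0, 0, 0))
  new("LabeledVolume", map = map, globalClass = as.integer(globalClass),
      voxelLabels = voxelLabels, background = as.numeric(background))
}

#' PatchBatch: a stack of cubic patches with parallel labels
#'
#' Rank-4 stacks of N cubic input patches and (optionally) parallel label
#' patches, plus the provenance needed to reassemble whole-map predictions:
#' the source map dimensions and the 0-based voxel offset of every retained
#' cube. Cubes whose input values are all zero are removed upstream.
#'
#' @slot inputs numeric array (N, c, c, c).
#' @slot labels numeric array (N, c, c, c) or zero-length when unlabeled.
#' @slot offsets integer N x 3 matrix of 0-based cube corner offsets.
#' @slot sourceDim integer length-3 dimensions of the source volume.
#' @slot background sentinel used when reassembling removed cubes.
#' @export
setClass("PatchBatch",
  representation(inputs = "array", labels = "array", offsets = "matrix",
                 sourceDim = "integer", background = "numeric"),
  validity = function(object) {
    di <- dim(object@inputs)
    if (length(di) != 4L) return("inputs must be a rank-4 array")
    if (length(unique(di[2:4])) != 1L) return("patches must be cubic")
    if (length(object@labels) > 0L &&
        !identical(dim(object@labels), di))
      return("labels must parallel inputs in shape")
    if (nrow(object@offsets) != di[1L])
      return("one offset row per cube required")
    TRUE
  }
)

#' ConfusionMatrix3: published-vs-predicted counts for three classes
#'
#' A 3 x 3 contingency table of map counts; rows are the published (true)
#' resolution class and columns the predicted class, ordered
#' high / medium / low.
#'
#' @slot counts 3 x 3 non-negative integer matrix.
#' @export
setClass("ConfusionMatrix3",
  representation(counts = "matrix"),
  validity = function(object) {
    cm <- object@counts
    if (!identical(dim(cm), c(3L, 3L)) && !identical(dim(cm), c(3, 3)))
      return("counts must be 3 x 3")
    if (any(cm < 0) || any(cm != floor(cm)))
      return("counts must be non-negative integers")
    TRUE
  }
)

#' NetworkSpec: a declarative network architecture
#'
#' Describes one of the three architectures (dense network, 3D convolutional
#' network, 3D U-Net) as an ordered list of layer descriptions. Shapes and
#' trainable-parameter counts are derived from the description without
#' allocating weights, so the full-size published architectures can be
#' reasoned about cheaply while training uses desk-scale widths.
#'
#' @slot architecture one of "dnn", "cnn3d", "unet3d".
#' @slot inputEdge cubic input edge length in voxels.
#' @slot inputChannels input channel count (1 for density maps).
#' @slot layers list of layer descriptions.
#' @slot nClasses 3 for the global classifiers, 10 for the U-Net.
#' @export
setClass("NetworkSpec",
  representation(architecture = "character", inputEdge = "integer",
                 inputChannels = "integer", layers = "list",
                 nClasses = "integer"),
  validity = function(object) {
    if (!object@architecture %in% c("dnn", "cnn3d", "unet3d"))
      return("unknown architecture")
    if (object@inputEdge < 2L) return("input edge must be >= 2")
    expected <- if (object@architecture == "unet3d") 10L else 3L
    if (object@nClasses != expected)
      return(sprintf("%s must have %d output classes",
                     object@architecture, expected))
    TRUE
  }
)

#' TrainConfig: optimizer and schedule settings for training
#'
#' @slot optimizer "sgd" (constant-rate gradient descent) or "adam".
#' @slot learningRate positive learning rate.
#' @slot batchSize minibatch size (>= 1).
#' @slot loss "sparse_ce" (integer global labels) or "categorical_ce"
#'   (one-hot voxel labels with background excluded).
#' @slot patience epochs without validation-loss improvement before stopping.
#' @slot maxEpochs hard epoch cap.
#' @slot clipNorm global gradient-norm ceiling per update (Inf = off).
#' @slot seed integer seed governing initialization and shuffling.
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", learningRate = "numeric",
                 batchSize = "integer", loss = "character",
                 patience = "integer", maxEpochs = "integer",
                 clipNorm = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learning rate must be > 0")
    if (object@batchSize < 1L) return("batch size must be >= 1")
    if (object@patience < 0L) return("patience must be >= 0")
    if (!object@optimizer %in% c("sgd", "adam")) return("unknown optimizer")
    TRUE
  }
)

#' Construct a TrainConfig
#'
#' Defaults follow the global-classifier configuration: constant-rate
#' gradient descent at 0.01 with sparse softmax cross-entropy.
#'
#' @param optimizer "sgd" or "adam".
#' @param learningRate learning rate (default 0.01).
#' @param batchSize minibatch size (default 150).
#' @param loss "sparse_ce" or "categorical_ce".
#' @param patience early-stopping patience in epochs (default 50).
#' @param maxEpochs maximum number of epochs.
#' @param clipNorm if finite, each update's gradients are rescaled so
#'   their global L2 norm does not exceed this value — the standard guard
#'   against the sudden mid-training explosions cross-entropy training is
#'   prone to (default 5).
#' @param seed integer seed.
#' @return A \linkS4class{TrainConfig}.
#' @export
TrainConfig <- function(optimizer = "sgd", learningRate = 0.01,
                        batchSize = 150, loss = "sparse_ce", patience = 50,
                        maxEpochs = 100, clipNorm = 5, seed = 1) {
  new("TrainConfig", optimizer = optimizer,
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), loss = loss,
      patience = as.integer(patience), maxEpochs = as.integer(maxEpochs),
      clipNorm = as.numeric(clipNorm), seed = as.integer(seed))
}

#' TrainedNetwork: weights plus the training trace
#'
#' @slot spec the \linkS4class{NetworkSpec} that was trained.
#' @slot weights list of per-layer weight matrices (the best-epoch weights).
#' @slot trace data.frame with one row per epoch: \code{epoch},
#'   \code{val_loss}, \code{val_acc}.
#' @slot bestEpoch epoch index with the smallest validation loss.
#' @export
setClass("TrainedNetwork",
  representation(spec = "NetworkSpec", weights = "list", trace = "data.frame",
                 bestEpoch = "integer"),
  validity = function(object) {
    tr <- object@trace
    if (nrow(tr) > 0L) {
      if (!all(c("epoch", "val_loss", "val_acc") %in% names(tr)))
        return("trace must have epoch, val_loss, val_acc columns")
      if (object@bestEpoch != which.min(tr$val_loss))
        return("bestEpoch must be the argmin of the validation loss")
    }
    TRUE
  }
)
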