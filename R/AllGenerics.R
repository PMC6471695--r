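#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' \code{mapData} returns the 3D array of a \linkS4class{DensityMap};
#' \code{voxelSize} and \code{mapOrigin} its sampling rate and corner offset.
#' \code{atomPositions}/\code{atomWeights}/\code{nAtoms} access an
#' \linkS4class{AtomicModel}; \code{patchInputs}/\code{patchLabels}/
#' \code{patchOffsets} a \linkS4class{PatchBatch}; \code{cmCounts} the count
#' table of a \linkS4class{ConfusionMatrix3}.
#'
#' @param x the object.
#' @return The slot value.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))

#' @rdname accessors
#' @export
setGeneric("atomPositions", function(x) standardGeneric("atomPositions"))

#' @rdname accessors
#' @export
setGeneric("atomWeights", function(x) standardGeneric("atomWeights"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("patchInputs", function(x) standardGeneric("patchInputs"))

#' @rdname accessors
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))

#' @rdname accessors
#' @export
setGeneric("patchOffsets", function(x) standardGeneric("patchOffsets"))

#' @rdname accessors
#' @export
setGeneric("cmCounts", function(x) standardGeneric("cmCounts"))

#' @rdname accessors
#' @export
setMethod("mapData", "DensityMap", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSize", "DensityMap", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("mapOrigin", "DensityMap", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("atomPositions", "AtomicModel", function(x) x@positions)

#' @rdname accessors
#' @export
setMethod("atomWeights", "AtomicModel", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("nAtoms", "AtomicModel", function(x) nrow(x@positions))

#' @rdname accessors
#' @export
setMethod("patchInputs", "PatchBatch", function(x) x@inputs)

#' @rdname accessors
#' @export
setMethod("patchLabels", "PatchBatch", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("patchOffsets", "PatchBatch", function(x) x@offsets)

#' @rdname accessors
#' @export
setMethod("cmCounts", "ConfusionMatrix3", function(x) x@counts)

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("DensityMap %d x %d x %d voxels, %s A/voxel, origin (%s) A\n",
              d[1], d[2], d[3],
              paste(format(object@voxelSize, digits = 4), collapse = ", "),
              paste(format(object@origin, digits = 4), collapse = ", ")))
  r <- range(object@data)
  cat(sprintf("  density range [%.4g, %.4g]\n", r[1], r[2]))
})

setMethod("show", "AtomicModel", function(object) {
  cat(sprintf("AtomicModel with %d atoms\n", nrow(object@positions)))
  if (nrow(object@positions) > 0) {
    bb <- apply(object@positions, 2, range)
    cat(sprintf("  bounding box %.1f x %.1f x %.1f A\n",
                diff(bb[, 1]), diff(bb[, 2]), diff(bb[, 3])))
  }
})

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@map@data)
  if (length(object@voxelLabels) > 0L) {
    inmask <- sum(object@voxelLabels != object@background)
    cat(sprintf(
      "LabeledVolume %d x %d x %d, voxel-wise labels (%d in-mask voxels)\n",
      d[1], d[2], d[3], inmask))
  } else {
    cls <- c("high", "medium", "low")[object@globalClass + 1L]
    cat(sprintf("LabeledVolume %d x %d x %d, global class %d (%s)\n",
                d[1], d[2], d[3], object@globalClass, cls))
  }
})

setMethod("show", "PatchBatch", function(object) {
  d <- dim(object@inputs)
  cat(sprintf("PatchBatch: %d cubes of %d x %d x %d (%s), source %s\n",
              d[1], d[2], d[3], d[4],
              if (length(object@labels) > 0L) "labeled" else "unlabeled",
              paste(object@sourceDim, collapse = " x ")))
})

setMethod("show", "ConfusionMatrix3", function(object) {
  cat("ConfusionMatrix3 (rows: published, cols: predicted)\n")
  print(object@counts)
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec '%s': input %d^3 x %d, %d layers, %d classes\n",
              object@architecture, object@inputEdge, object@inputChannels,
              length(object@layers), object@nClasses))
  cat(sprintf("  trainable parameters: %s\n",
              format(countParams(object), big.mark = ",")))
})

setMethod("show", "TrainedNetwork", function(object) {
  cat(sprintf("TrainedNetwork '%s': %d epochs, best epoch %d",
              object@spec@architecture, nrow(object@trace),
              object@bestEpoch))
  if (nrow(object@trace) > 0L)
    cat(sprintf(" (val loss %.4f, val acc %.3f)",
                object@trace$val_loss[object@bestEpoch],
                object@trace$val_acc[object@bestEpoch]))
  cat("\n")
})
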