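#' Min-max normalize a density map to [0, 1]
#'
#' Linear rescaling so the output spans exactly 0..1 for any non-constant
#' input. A constant map normalizes to all zeros (and then counts as
#' "empty" for downstream empty-cube removal). Idempotent on non-constant
#' maps.
#'
#' @param map a \linkS4class{DensityMap}.
#' @return The normalized \linkS4class{DensityMap}.
#' @export
minMaxNormalize <- function(map) {
  stopifnot(is(map, "DensityMap"))
  d <- map@data
  lo <- min(d); hi <- max(d)
  map@data <- if (hi > lo) (d - lo) / (hi - lo) else array(0, dim(d))
  map
}

#' Three-class global resolution label
#'
#' Maps a resolution in Angstrom to the global class code: high (0) below
#' 5 A, medium (1) from 5 to 10 A inclusive, low (2) above 10 A.
#'
#' @param resolution resolution in Angstrom (> 0); vectorized.
#' @return Integer class code(s) 0/1/2.
#' @examples
#' threeClassLabel(c(2.5, 7.5, 12.5))  # 0 1 2
#' @export
threeClassLabel <- function(resolution) {
  if (any(resolution <= 0)) stop("resolution must be > 0")
  ifelse(resolution < 5, 0L, ifelse(resolution <= 10, 1L, 2L))
}

#' Ten-bin voxel resolution class
#'
#' Bins a continuous resolution into the ten classes used for voxel-wise
#' classification: 0 for (0-2 A), 1 for (2-3 A), ..., 8 for (9-10 A) and 9
#' for everything from 10 A up. Bins are half-open \code{[lo, hi)}; the last
#' bin is \code{[10, Inf)}.
#'
#' @param resolution resolution in Angstrom (> 0); vectorized.
#' @return Integer bin index/indices in 0..9.
#' @examples
#' binResolution10(c(2.5, 12.5, 1.999))  # 1 9 0
#' @export
binResolution10 <- function(resolution) {
  if (any(resolution <= 0)) stop("resolution must be > 0")
  as.integer(pmin(pmax(floor(resolution) - 1, 0), 9))
}

#' Central crop or trailing zero-pad to a fixed cube
#'
#' Standardizes variable-size experimental volumes for the fixed-input
#' global classifiers: per axis, dimensions larger than the target are
#' centrally cropped; dimensions smaller than the target are padded by
#' appending \code{padValue} at the trailing end. (This is deliberately a
#' different protocol from [padToPow2()], which pads symmetrically.)
#'
#' @param map a \linkS4class{DensityMap}.
#' @param target output edge length (default 64).
#' @param padValue value for padded voxels (default 0; use the background
#'   sentinel when transforming label volumes).
#' @return A \linkS4class{DensityMap} of exactly \code{target^3} voxels.
#' @export
centralCropOrPad <- function(map, target = 64, padValue = 0) {
  stopifnot(is(map, "DensityMap"))
  d <- dim(map@data)
  out <- array(padValue, rep(as.integer(target), 3L))
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    if (d[i] >= target) {
      off <- floor((d[i] - target) / 2)
      src[[i]] <- (off + 1):(off + target)
      dst[[i]] <- 1:target
    } else {
      src[[i]] <- 1:d[i]
      dst[[i]] <- 1:d[i]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- map@data[src[[1]], src[[2]], src[[3]]]
  DensityMap(out, voxelSize = map@voxelSize, origin = map@origin)
}

#' Apply a binary mask to a map
#'
#' Voxels where the mask is 0 are set to zero; mask-1 voxels pass through
#' unchanged. Used to remove experimental noise outside the structure.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param mask binary array (or \linkS4class{DensityMap}) of identical
#'   dimensions with values in {0, 1}.
#' @return The masked \linkS4class{DensityMap}.
#' @export
applyMask <- function(map, mask) {
  stopifnot(is(map, "DensityMap"))
  if (is(mask, "DensityMap")) mask <- mask@data
  if (!identical(dim(mask), dim(map@data)))
    stop("mask dimensions must match the map")
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0 or 1")
  map@data <- map@data * mask
  map
}

#' Derive a binary structure mask by thresholding
#'
#' Voxels with density strictly above \code{level} are inside the mask.
#' The default level 0 matches simulated maps, whose truncated Gaussians
#' leave exact zeros outside the structure.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param level threshold (default 0).
#' @return A 0/1 array of the map's dimensions.
#' @export
thresholdMask <- function(map, level = 0) {
  stopifnot(is(map, "DensityMap"))
  array(as.numeric(map@data > level), dim(map@data))
}

#' Pad a volume to the nearest power-of-two cube
#'
#' Each output dimension is the smallest power of two greater than or equal
#' to the largest input dimension (so the output is a cube and 16^3
#' partitioning always divides it). Padding is split evenly between the
#' front and back of each axis; when the total pad is odd, the leftover
#' voxel goes to the front or the back by a seeded coin flip, so an (input,
#' label) pair padded with the same seed stays in voxel-wise register.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param seed integer seed for the odd-voxel coin flips.
#' @param padValue value for padded voxels (default 0; use the background
#'   sentinel for label volumes).
#' @return The padded \linkS4class{DensityMap}.
#' @export
padToPow2 <- function(map, seed, padValue = 0) {
  stopifnot(is(map, "DensityMap"))
  d <- dim(map@data)
  p <- 2L^as.integer(ceiling(log2(max(d))))
  set.seed(as.integer(seed))
  flip <- stats::runif(3) < 0.5
  tot <- p - d
  front <- tot %/% 2L + ifelse(tot %% 2L == 1L & flip, 1L, 0L)
  out <- array(padValue, rep(p, 3L))
  idx <- lapply(1:3, function(i) (front[i] + 1):(front[i] + d[i]))
  out[idx[[1]], idx[[2]], idx[[3]]] <- map@data
  DensityMap(out, voxelSize = map@voxelSize, origin = map@origin)
}

#' Partition a volume into 16^3 cubes with empty-cube removal
#'
#' Divides a volume (dimensions divisible by \code{cube}, guaranteed after
#' [padToPow2()]) into non-overlapping cubes, drops every cube whose input
#' values are all zero (within \code{zeroTol}; exact zero by default, valid
#' because simulation and masking produce exact zeros), removes the paired
#' label cube in lockstep, and records each retained cube's 0-based corner
#' offset for later reassembly.
#'
#' @param input a \linkS4class{DensityMap} (or 3D array).
#' @param labels optional per-voxel label array of identical dimensions.
#' @param cube cube edge (default 16).
#' @param zeroTol values with absolute value <= zeroTol count as zero
#'   (default 0, i.e. exact); useful for noisy experimental maps.
#' @param background sentinel recorded for reassembly (default -1).
#' @return A \linkS4class{PatchBatch}.
#' @export
partitionPatches <- function(input, labels = NULL, cube = 16, zeroTol = 0,
                             background = -1) {
  x <- if (is(input, "DensityMap")) input@data else input
  d <- dim(x)
  if (any(d %% cube != 0))
    stop("volume dimensions (", paste(d, collapse = "x"),
         ") are not divisible by the cube edge ", cube)
  if (!is.null(labels) && !identical(dim(labels), d))
    stop("labels dimensions must match the input")
  nb <- d %/% cube
  grid <- as.matrix(expand.grid(x = 0:(nb[1] - 1), y = 0:(nb[2] - 1),
                                z = 0:(nb[3] - 1))) * cube
  keep <- logical(nrow(grid))
  for (j in seq_len(nrow(grid))) {
    o <- grid[j, ]
    blk <- x[(o[1] + 1):(o[1] + cube), (o[2] + 1):(o[2] + cube),
             (o[3] + 1):(o[3] + cube)]
    keep[j] <- any(abs(blk) > zeroTol)
  }
  n <- sum(keep)
  inputs <- array(0, c(n, cube, cube, cube))
  labs <- if (is.null(labels)) array(numeric(0), c(0, 0, 0, 0)) else
    array(0, c(n, cube, cube, cube))
  offs <- matrix(0L, n, 3)
  jj <- 0L
  for (j in which(keep)) {
    jj <- jj + 1L
    o <- grid[j, ]
    rng <- lapply(1:3, function(i) (o[i] + 1):(o[i] + cube))
    inputs[jj, , , ] <- x[rng[[1]], rng[[2]], rng[[3]]]
    if (!is.null(labels)) labs[jj, , , ] <- labels[rng[[1]], rng[[2]], rng[[3]]]
    offs[jj, ] <- as.integer(o)
  }
  new("PatchBatch", inputs = inputs, labels = labs, offsets = offs,
      sourceDim = as.integer(d), background = as.numeric(background))
}

#' Reassemble per-cube predictions into a whole volume
#'
#' Inverse of [partitionPatches()]: places each cube (the batch's labels by
#' default, or supplied predictions) at its recorded offset; positions of
#' removed (empty) cubes are filled with the background sentinel.
#'
#' @param batch a \linkS4class{PatchBatch}.
#' @param predictions optional rank-4 array parallel to the batch; defaults
#'   to the batch's label cubes.
#' @return A 3D array of the source volume's dimensions.
#' @export
reassemblePatches <- function(batch, predictions = NULL) {
  stopifnot(is(batch, "PatchBatch"))
  if (is.null(predictions)) predictions <- batch@labels
  di <- dim(batch@inputs)
  if (!identical(dim(predictions), di))
    stop("predictions must parallel the batch (shape ",
         paste(di, collapse = "x"), ")")
  cube <- di[2]
  out <- array(batch@background, batch@sourceDim)
  seen <- array(FALSE, batch@sourceDim %/% cube)
  for (j in seq_len(di[1])) {
    o <- batch@offsets[j, ]
    cell <- o %/% cube + 1L
    if (seen[cell[1], cell[2], cell[3]])
      stop("offset collision at ", paste(o, collapse = ","))
    seen[cell[1], cell[2], cell[3]] <- TRUE
    out[(o[1] + 1):(o[1] + cube), (o[2] + 1):(o[2] + cube),
        (o[3] + 1):(o[3] + cube)] <- predictions[j, , , ]
  }
  out
}

#' Reproducible three-way dataset split
#'
#' Uniformly and randomly splits ids into training/validation/test subsets
#' with the given ratios. Subset sizes are \code{round(ratio * n)} for the
#' validation and test sets with the remainder assigned to training; the
#' three subsets are disjoint and cover the input. Deterministic given the
#' seed.
#'
#' @param ids vector of ids (any type).
#' @param ratios three fractions summing to 1 (default 60/20/20).
#' @param seed integer seed.
#' @return list with elements \code{train}, \code{validation}, \code{test}.
#' @examples
#' splitDataset(1:10, c(0.6, 0.2, 0.2), seed = 1)
#' @export
splitDataset <- function(ids, ratios = c(0.6, 0.2, 0.2), seed = 1) {
  if (length(ratios) != 3L || any(ratios < 0) || any(ratios > 1) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three fractions in [0,1] summing to 1")
  n <- length(ids)
  if (n == 0L)
    return(list(train = ids, validation = ids, test = ids))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  nVal <- round(ratios[2] * n)
  nTest <- round(ratios[3] * n)
  nTrain <- n - nVal - nTest
  list(train = ids[perm[seq_len(nTrain)]],
       validation = ids[perm[nTrain + seq_len(nVal)]],
       test = ids[perm[nTrain + nVal + seq_len(nTest)]])
}

#' Size of a simulated training corpus
#'
#' The number of maps obtained by simulating every selected structure at
#' every training resolution — a counting function, so corpus bookkeeping
#' never requires materializing the maps.
#'
#' @param nStructures number of atomic structures.
#' @param resolutions vector of training resolutions (default
#'   2.5/7.5/12.5 A).
#' @return \code{nStructures * length(resolutions)}.
#' @examples
#' simulatedCorpusSize(12671)  # 38013
#' @export
simulatedCorpusSize <- function(nStructures,
                                resolutions = c(2.5, 7.5, 12.5)) {
  as.numeric(nStructures) * length(resolutions)
}
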