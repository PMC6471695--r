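#' Local-resolution phantom: a map with voxel-wise ground-truth classes
#'
#' Builds a density volume whose resolution varies by region, together with
#' the matching per-voxel class volume, emulating the kind of supervision a
#' local-resolution estimator (MonoRes/ResMap-style) would provide — but
#' with labels that are exact by construction. A shared structure is
#' rendered independently at every region's resolution and the renders are
#' composited region by region, so each voxel's density carries exactly its
#' region's resolution signature. In-mask voxels (density > 0 after
#' compositing; the Gaussian truncation keeps far voxels exactly zero) are
#' labelled with the ten-bin class of their region's resolution via
#' [binResolution10()]; everything else gets the background sentinel.
#'
#' Regions are axis-aligned slabs of equal thickness along x, or concentric
#' spheres about the box centre (last region = remainder of the box).
#'
#' @param resolutions vector of region resolutions in Angstrom (one region
#'   per entry, all > 0).
#' @param layout "slabs" or "spheres".
#' @param box cubic box edge in voxels (default 32).
#' @param voxelSize Angstrom/voxel (default 1).
#' @param model optional \linkS4class{AtomicModel}; by default a synthetic
#'   random-walk structure spanning ~70% of the box is generated from
#'   \code{seed}.
#' @param nAtoms atom count for the default synthetic structure.
#' @param seed integer seed (structure generation).
#' @param background label sentinel for out-of-mask voxels (default -1).
#' @return A \linkS4class{LabeledVolume} with voxel-wise labels.
#' @examples
#' ph <- makeLocalResPhantom(c(2.5, 12.5), box = 32, seed = 7)
#' table(ph@voxelLabels)
#' @export
makeLocalResPhantom <- function(resolutions, layout = c("slabs", "spheres"),
                                box = 32, voxelSize = 1, model = NULL,
                                nAtoms = 8 * box, seed = 1,
                                background = -1) {
  layout <- match.arg(layout)
  if (any(resolutions <= 0)) stop("region resolutions must be > 0")
  k <- length(resolutions)
  if (is.null(model))
    model <- makeSyntheticModel(nAtoms, extent = 0.7 * box * voxelSize,
                                seed = seed)
  renders <- lapply(resolutions, function(R)
    suppressWarnings(simulateMap(model, R, box = box,
                                 voxelSize = voxelSize)))
  dims <- rep(as.integer(box), 3L)
  region <- regionIndexVolume(dims, k, layout)
  data <- array(0, dims)
  for (r in seq_len(k)) {
    sel <- region == r
    data[sel] <- mapData(renders[[r]])[sel]
  }
  labels <- array(background, dims)
  inmask <- data > 0
  for (r in seq_len(k)) {
    sel <- inmask & region == r
    labels[sel] <- binResolution10(resolutions[r])
  }
  LabeledVolume(DensityMap(data, voxelSize = voxelSize),
                voxelLabels = labels, background = background)
}

# Assign every voxel of a (cubic) grid to one of k regions.
regionIndexVolume <- function(dims, k, layout) {
  if (layout == "slabs") {
    edges <- round(seq(0, dims[1], length.out = k + 1))
    xi <- findInterval(seq_len(dims[1]) - 0.5, edges,
                       rightmost.closed = TRUE)
    return(array(rep(xi, times = dims[2] * dims[3]), dims))
  }
  # concentric spheres: radii chosen for roughly equal-volume shells inside
  # the inscribed sphere; region k is the remainder of the box
  ctr <- (dims + 1) / 2
  x <- seq_len(dims[1]) - ctr[1]
  y <- seq_len(dims[2]) - ctr[2]
  z <- seq_len(dims[3]) - ctr[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  rmax <- min(dims) / 2
  radii <- rmax * ((seq_len(k - 1)) / k)^(1 / 3)
  reg <- array(k, dims)
  for (r in rev(seq_len(k - 1))) reg[r2 <= radii[r]^2] <- r
  reg
}
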