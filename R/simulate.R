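#' @useDynLib cryores, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Continuum Gaussian width for resolution R: with kernel
# g(r) = exp(-r^2 / (2 sigma^2)), the Fourier transform is
# exp(-2 pi^2 sigma^2 s^2); requiring amplitude 1/2 at s = 1/R gives
# 2 pi^2 sigma^2 / R^2 = ln 2.
analyticSigma <- function(resolution) {
  resolution * sqrt(log(2) / 2) / pi
}

#' Simulate a density map from an atomic model
#'
#' Renders each atom as a mass-normalized 3D Gaussian whose resolution R is
#' defined in Fourier space: the map's rotationally averaged Fourier
#' amplitude falls to one-half of its zero-frequency value at spatial
#' frequency \code{s = 1/R}. The Gaussian spectrum is imposed exactly on
#' the sampling grid: atoms are first rasterized with a narrow, well-sampled
#' auxiliary Gaussian (circularly wrapped, i.e. with the periodic semantics
#' of the DFT), and the spectrum is then reshaped to
#' \code{exp(-R^2 ln(2) |k|^2)} by Fourier multiplication. Point-sampling a
#' real-space Gaussian instead would alias badly whenever the width
#' (\code{sigma = R sqrt(ln 2 / 2) / pi}, about 0.47 voxel at R = 2.5 A and
#' 1 A/voxel) drops below the voxel size, and the half-amplitude contract
#' would be unattainable on the grid.
#'
#' After synthesis, voxels farther than \code{cutoff} from every atom are
#' set to exactly zero, which keeps downstream empty-cube removal well
#' defined. The default cutoff is \code{max(5 sigma, 10 voxels)}: 5 sigma
#' keeps the discarded Gaussian mass negligible, while the 10-voxel floor
#' preserves the (slightly ringing) band-limited kernel and its tail well
#' enough that the spectral contract still holds to about a percent even
#' for single-atom maps. By default the model's centre of mass is
#' translated to the box centre.
#'
#' @param model an \linkS4class{AtomicModel}; an empty model yields an
#'   all-zero map.
#' @param resolution target resolution R in Angstrom (> 0).
#' @param box edge length of the cubic simulation box in voxels (default 64).
#' @param voxelSize sampling rate in Angstrom/voxel (default 1).
#' @param center translate the model's centre of mass to the box centre
#'   (default TRUE).
#' @param cutoffSigma support cutoff in target standard deviations
#'   (default 5; the effective cutoff never falls below 10 voxels).
#' @return A \linkS4class{DensityMap}.
#' @examples
#' m <- makeSyntheticModel(50, extent = 20, seed = 1)
#' vol <- simulateMap(m, resolution = 7.5, box = 32)
#' @export
simulateMap <- function(model, resolution, box = 64, voxelSize = 1,
                        center = TRUE, cutoffSigma = 5) {
  stopifnot(is(model, "AtomicModel"))
  if (resolution <= 0) stop("resolution must be > 0")
  if (box < 8) stop("box must be >= 8 voxels")
  if (voxelSize <= 0) stop("voxelSize must be > 0")
  vox <- rep(voxelSize, 3L)
  dims <- rep(as.integer(box), 3L)
  if (nAtoms(model) == 0L)
    return(DensityMap(array(0, dims), voxelSize = vox))
  sigma <- analyticSigma(resolution)
  if (sigma < min(vox))
    warning(sprintf(
      "resolution %.3g A is near/below the sampling limit for %.3g A ",
      resolution, min(vox)),
      "voxels; the rendered Gaussian is narrower than one voxel")
  pos <- atomPositions(model)
  if (center) {
    com <- colMeans(pos)
    pos <- sweep(pos, 2, com, `-`)
    pos <- sweep(pos, 2, dims * vox / 2, `+`)
  }
  lim <- dims * vox
  bad <- which(pos[, 1] < 0 | pos[, 1] > lim[1] |
               pos[, 2] < 0 | pos[, 2] > lim[2] |
               pos[, 3] < 0 | pos[, 3] > lim[3])
  if (length(bad) > 0L)
    stop(sprintf(
      "atom(s) %s fall outside the %d^3-voxel box after centering ",
      paste(utils::head(bad, 5), collapse = ", "), box),
      "(box extent ", paste(format(lim), collapse = " x "), " A); ",
      "use a larger box or a smaller model")
  # auxiliary rasterization width: wide enough to sample without aliasing,
  # narrow enough that the Fourier reshape never amplifies noise unduly
  sigmaR <- 1.2 * max(vox)
  arr <- cr_rasterize_gauss(pos, atomWeights(model), dims, vox,
                            sigmaR, 6 * sigmaR, TRUE)
  aTgt <- 2 * pi^2 * sigma^2
  aAux <- 2 * pi^2 * sigmaR^2
  k2 <- frequencyGrid2(dims, vox)
  Fm <- stats::fft(arr) * exp((aAux - aTgt) * k2)
  arr <- Re(stats::fft(Fm, inverse = TRUE)) / prod(dims)
  cutoff <- max(cutoffSigma * sigma, 10 * max(vox))
  arr[!cr_support_mask(pos, dims, vox, cutoff)] <- 0
  DensityMap(array(arr, dims), voxelSize = vox)
}

# |k|^2 on the DFT frequency grid (1/Angstrom^2), with negative frequencies
# wrapped.
frequencyGrid2 <- function(dims, vox) {
  fr <- lapply(1:3, function(i) {
    f <- (seq_len(dims[i]) - 1) / (dims[i] * vox[i])
    nyq <- 1 / (2 * vox[i])
    ifelse(f > nyq, f - 2 * nyq, f)
  })
  outer(outer(fr[[1]]^2, fr[[2]]^2, `+`), fr[[3]]^2, `+`)
}

#' Generate a protein-like synthetic atomic model
#'
#' A self-avoiding-ish random walk with ~1.5 Angstrom steps (the scale of
#' covalent-bond spacing, so synthetic maps have protein-like packing),
#' confined to a cube of the given extent. Deterministic given the seed, so
#' desk-scale corpora need no structure downloads.
#'
#' @param nAtoms number of atoms (>= 0).
#' @param extent edge of the bounding cube in Angstrom.
#' @param seed integer seed.
#' @param step step length in Angstrom (default 1.5).
#' @return An \linkS4class{AtomicModel} with unit weights.
#' @export
makeSyntheticModel <- function(nAtoms, extent, seed, step = 1.5) {
  if (nAtoms < 0) stop("nAtoms must be >= 0")
  if (extent <= 0) stop("extent must be > 0")
  if (nAtoms == 0L) return(AtomicModel())
  set.seed(as.integer(seed))
  half <- extent / 2
  pos <- matrix(0, nAtoms, 3)
  for (i in seq_len(nAtoms)[-1]) {
    repeat {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1, ] + step * u
      if (all(abs(cand) <= half)) break
    }
    pos[i, ] <- cand
  }
  AtomicModel(pos, weights = 1)
}

#' Rotationally averaged Fourier amplitude of a map
#'
#' Computes \code{|FFT|} of the volume and averages it over spherical shells
#' of spatial frequency, giving the amplitude spectrum used by the
#' resolution contract of [simulateMap()].
#'
#' @param map a \linkS4class{DensityMap}.
#' @param nShells number of radial shells (default: half the smallest grid
#'   dimension).
#' @return data.frame with columns \code{s} (shell-centre spatial frequency,
#'   1/Angstrom) and \code{amplitude}.
#' @export
radialAmplitude <- function(map, nShells = NULL) {
  stopifnot(is(map, "DensityMap"))
  d <- dim(map@data)
  if (is.null(nShells)) nShells <- floor(min(d) / 2)
  Fm <- abs(stats::fft(map@data))
  fr <- lapply(1:3, function(i) {
    f <- (seq_len(d[i]) - 1) / (d[i] * map@voxelSize[i])
    nyq <- 1 / (2 * map@voxelSize[i])
    ifelse(f > nyq, f - 2 * nyq, f)
  })
  s2 <- outer(fr[[1]]^2, fr[[2]]^2, `+`)
  s <- sqrt(outer(as.vector(s2), fr[[3]]^2, `+`))
  smax <- min(1 / (2 * map@voxelSize))
  edges <- seq(0, smax, length.out = nShells + 1)
  shell <- findInterval(as.vector(s), edges, rightmost.closed = TRUE)
  keep <- shell >= 1 & shell <= nShells
  amp <- tapply(as.vector(Fm)[keep], shell[keep], mean)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(s = mid, amplitude = NA_real_)
  out$amplitude[as.integer(names(amp))] <- as.numeric(amp)
  # the DC term is the first shell's zero-frequency sample
  out$amplitude[1] <- Fm[1, 1, 1]
  out[!is.na(out$amplitude), , drop = FALSE]
}

#' Half-amplitude crossing frequency of a map's radial spectrum
#'
#' The spatial frequency at which the rotationally averaged Fourier
#' amplitude first falls to one-half of its zero-frequency value, located by
#' linear interpolation between shells. For a single-atom simulated map this
#' equals \code{1/resolution} by construction.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param nShells passed to [radialAmplitude()].
#' @return crossing frequency in 1/Angstrom, or NA when the spectrum never
#'   falls below half within Nyquist.
#' @export
halfCrossingFrequency <- function(map, nShells = NULL) {
  ra <- radialAmplitude(map, nShells)
  a0 <- abs(sum(mapData(map)))  # |F(0)|, the DC amplitude
  half <- a0 / 2
  below <- which(ra$amplitude < half)
  if (length(below) == 0L) return(NA_real_)
  j <- below[1]
  if (j == 1L) return(ra$s[1])
  s0 <- ra$s[j - 1]; s1 <- ra$s[j]
  a1 <- ra$amplitude[j - 1]; a2 <- ra$amplitude[j]
  if (a1 > 0 && a2 > 0)  # log-linear interpolation suits smooth decay
    s0 + (log(half) - log(a1)) / (log(a2) - log(a1)) * (s1 - s0)
  else
    s0 + (half - a1) / (a2 - a1) * (s1 - s0)
}
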