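#' Read an MRC2014 density volume
#'
#' Parses the 1024-byte MRC header and the data block of a standard MRC2014
#' file (modes 0, 1, 2 and 6 are accepted; data are promoted to double).
#' The file's axis-order words (MAPC/MAPR/MAPS) are honoured: data are
#' permuted so that the returned array is always indexed logically as
#' \code{[x, y, z]}, whatever the file order was.
#'
#' Voxel size is taken as cell dimension / sampling grid (CELLA / MX..MZ);
#' the origin is read from the MRC2014 ORIGIN words.
#'
#' @param path path to an MRC file.
#' @return A \linkS4class{DensityMap}.
#' @seealso [writeMRC()]
#' @export
readMRC <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("malformed MRC file (header): file shorter than the 1024-byte ",
         "header: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  # re-read the float words from the raw header bytes
  seek(con, 0)
  raw <- readBin(con, "raw", n = 1024)
  fl <- function(word) readBin(raw[((word - 1) * 4 + 1):(word * 4)],
                               "numeric", size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (any(c(nx, ny, nz) < 1L) || any(c(nx, ny, nz) > 1e5))
    stop("malformed MRC file (NX/NY/NZ): nonpositive or absurd dimensions")
  if (!mode %in% c(0L, 1L, 2L, 6L))
    stop("malformed MRC file (MODE): unsupported mode ", mode)
  mx <- hdr[8]; my <- hdr[9]; mz <- hdr[10]
  cella <- c(fl(11), fl(12), fl(13))
  mapc <- hdr[17]; mapr <- hdr[18]; maps <- hdr[19]
  if (!setequal(c(mapc, mapr, maps), 1:3))
    stop("malformed MRC file (MAPC/MAPR/MAPS): axis words must be a ",
         "permutation of 1,2,3")
  nsymbt <- hdr[24]
  origin <- c(fl(50), fl(51), fl(52))
  # sampling intervals default to 1 A when the cell is unset
  grid <- c(mx, my, mz)
  vox <- ifelse(grid > 0 & cella > 0, cella / grid, 1)
  nvox <- as.numeric(nx) * ny * nz
  bytes <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)[as.character(mode)]
  if (sz < 1024 + nsymbt + nvox * bytes)
    stop("malformed MRC file (data block): file truncated")
  seek(con, 1024 + nsymbt)
  vals <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = "little")),
    `1` = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    `2` = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    `6` = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = FALSE, endian = "little")))
  # file order: column axis fastest, then row, then section
  arr <- array(vals, dim = c(nx, ny, nz))
  axes <- c(mapc, mapr, maps)          # axes[i] = xyz axis along file dim i
  if (!identical(axes, 1:3)) {
    perm <- match(1:3, axes)
    arr <- aperm(arr, perm)
    vox <- vox[perm]
  }
  DensityMap(arr, voxelSize = vox, origin = origin)
}

#' Write a DensityMap as an MRC2014 volume
#'
#' Writes mode-2 (float32) MRC2014 with MAPC/MAPR/MAPS = 1/2/3, the cell set
#' to grid dimensions times voxel size, and the origin in the MRC2014 ORIGIN
#' words, so the file round-trips through [readMRC()] and opens in common
#' viewers.
#'
#' @param map a \linkS4class{DensityMap}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMRC <- function(map, path) {
  stopifnot(is(map, "DensityMap"))
  d <- dim(map@data)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) {
    # float32 via raw conversion
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  vals <- as.vector(map@data)
  wi(d)                                # NX NY NZ
  wi(2L)                               # MODE 2 = float32
  wi(c(0L, 0L, 0L))                    # NXSTART..
  wi(d)                                # MX MY MZ
  wf(d * map@voxelSize)                # CELLA
  wf(c(90, 90, 90))                    # CELLB
  wi(1:3)                              # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wi(1L)                               # ISPG (volume)
  wi(0L)                               # NSYMBT
  wi(rep(0L, 3))                       # EXTRA words 25-27
  wi(20140L)                           # NVERSION (word 28)
  wi(rep(0L, 21))                      # EXTRA words 29-49
  wf(map@origin)                       # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)     # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(vals))                  # RMS
  wi(0L)                               # NLABL
  writeBin(raw(800), con)              # labels
  wf(vals)
  invisible(path)
}
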