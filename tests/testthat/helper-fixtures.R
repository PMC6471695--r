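# Shared in-code fixtures.

# A minimal three-atom model placed off-centre (tests centering too).
threeAtomModel <- function() {
  AtomicModel(matrix(c(10, 12, 11,
                       13, 10, 12,
                       11, 14, 13), 3, 3, byrow = TRUE))
}

# Write a tiny PDB file and return its path.
writeTinyPDB <- function(coords, dir = tempdir()) {
  path <- tempfile("model", fileext = ".pdb", tmpdir = dir)
  lines <- c("HEADER    TEST", "REMARK synthetic fixture")
  for (i in seq_len(nrow(coords))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, i, coords[i, 1], coords[i, 2], coords[i, 3]))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Independent radial-spectrum oracle: plain loops over the FFT grid,
# written without reusing the package's radialAmplitude machinery.
oracleHalfCrossing <- function(arr, voxel = 1) {
  n <- dim(arr)[1]
  Fm <- abs(fft(arr))
  f1 <- (0:(n - 1)) / (n * voxel)
  f1[f1 > 1 / (2 * voxel)] <- f1[f1 > 1 / (2 * voxel)] - 1 / voxel
  amp <- numeric(0); ss <- numeric(0)
  width <- 1 / (n * voxel)
  nb <- floor(n / 2)
  sums <- numeric(nb); cnts <- numeric(nb)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    s <- sqrt(f1[i]^2 + f1[j]^2 + f1[k]^2)
    b <- floor(s / width) + 1
    if (b >= 1 && b <= nb) {
      sums[b] <- sums[b] + Fm[i, j, k]
      cnts[b] <- cnts[b] + 1
    }
  }
  avg <- sums / pmax(cnts, 1)
  half <- Fm[1, 1, 1] / 2
  ctr <- (seq_len(nb) - 0.5) * width
  below <- which(avg < half & cnts > 0)
  j <- below[1]
  s0 <- ctr[j - 1]; s1 <- ctr[j]
  a1 <- avg[j - 1]; a2 <- avg[j]
  exp(log(s0) + (log(half) - log(a1)) / (log(a2) - log(a1)) *
        (log(s1) - log(s0)))
}
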