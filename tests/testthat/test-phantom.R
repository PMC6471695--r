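test_that("a single-region phantom labels every in-mask voxel class 1", {
  ph <- makeLocalResPhantom(2.5, box = 32, seed = 2)
  lab <- ph@voxelLabels
  inmask <- lab != ph@background
  expect_gt(sum(inmask), 0)
  expect_true(all(lab[inmask] == 1))
  expect_identical(dim(lab), dim(mapData(ph@map)))
})

test_that("two half-box regions carry exactly classes {1, 9}", {
  ph <- makeLocalResPhantom(c(2.5, 12.5), layout = "slabs", box = 32,
                            seed = 4)
  lab <- ph@voxelLabels
  left <- lab[1:16, , ]; right <- lab[17:32, , ]
  expect_true(all(left[left != -1] == 1))
  expect_true(all(right[right != -1] == 9))
  expect_setequal(unique(as.vector(lab[lab != -1])), c(1, 9))
})

test_that("blurrier regions hold less high-frequency power", {
  ph <- makeLocalResPhantom(c(2.5, 12.5), layout = "slabs", box = 32,
                            seed = 6)
  d <- mapData(ph@map)
  bandPower <- function(x) {
    Fm <- abs(fft(x))^2
    n <- dim(x)[1]
    f <- (0:(n - 1)) / n; f[f > 0.5] <- f[f > 0.5] - 1
    s <- sqrt(outer(outer(f^2, f^2, `+`), f^2, `+`))
    sum(Fm[s > 0.25]) / sum(Fm)
  }
  sharp <- d[1:16, , ]; dim(sharp) <- c(16, 32, 32)
  blurry <- d[17:32, , ]; dim(blurry) <- c(16, 32, 32)
  # compare cubic sub-blocks to keep the FFT isotropic
  expect_gt(bandPower(d[1:16, 9:24, 9:24]), bandPower(d[17:32, 9:24, 9:24]))
})

test_that("phantom labels are invariant to the density scale", {
  ph1 <- makeLocalResPhantom(c(2.5, 12.5), box = 32, seed = 8)
  m <- makeSyntheticModel(8 * 32, extent = 0.7 * 32, seed = 8)
  heavy <- AtomicModel(atomPositions(m), weights = 50)
  ph2 <- makeLocalResPhantom(c(2.5, 12.5), box = 32, model = heavy,
                             seed = 8)
  expect_identical(ph1@voxelLabels, ph2@voxelLabels)
})

test_that("nonpositive region resolutions are rejected", {
  expect_error(makeLocalResPhantom(c(2.5, -1), box = 32, seed = 1), "> 0")
})

test_that("sphere layouts tile the box", {
  reg <- cryores:::regionIndexVolume(c(16L, 16L, 16L), 3, "spheres")
  expect_setequal(unique(as.vector(reg)), 1:3)
  slab <- cryores:::regionIndexVolume(c(16L, 16L, 16L), 4, "slabs")
  expect_equal(unique(as.vector(slab[1:4, , ])), 1)
  expect_equal(unique(as.vector(slab[13:16, , ])), 4)
})
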