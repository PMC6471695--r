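test_that("min-max normalization spans [0,1] and is idempotent", {
  m <- DensityMap(array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2)))
  n <- minMaxNormalize(m)
  expect_equal(sort(unique(as.vector(mapData(n)))), c(0, 0.5, 1))
  expect_equal(mapData(minMaxNormalize(n)), mapData(n))
  # constant map -> all zeros
  expect_true(all(mapData(minMaxNormalize(
    DensityMap(array(3, c(2, 2, 2))))) == 0))
  # any non-constant map spans exactly [0,1]
  set.seed(5)
  r <- minMaxNormalize(DensityMap(array(rnorm(27), c(3, 3, 3))))
  expect_equal(range(mapData(r)), c(0, 1))
})

test_that("three-class labels follow the 5/10 Angstrom boundaries", {
  expect_equal(threeClassLabel(c(2.5, 7.5, 12.5)), c(0L, 1L, 2L))
  expect_equal(threeClassLabel(c(4.999, 5, 10, 10.001)),
               c(0L, 1L, 1L, 2L))
  expect_error(threeClassLabel(0), "> 0")
})

test_that("ten-bin classes use half-open bins with [10, Inf) last", {
  expect_equal(binResolution10(2.5), 1L)
  expect_equal(binResolution10(12.5), 9L)
  expect_equal(binResolution10(1.999), 0L)
  expect_equal(binResolution10(c(2, 3, 9.999, 10, 250)),
               c(1L, 2L, 8L, 9L, 9L))
  # monotone non-decreasing in resolution
  rs <- sort(runif(50, 0.1, 20))
  expect_true(all(diff(binResolution10(rs)) >= 0))
  expect_error(binResolution10(-1), "> 0")
})

test_that("central crop keeps the middle region; small maps pad trailing", {
  big <- DensityMap(array(seq_len(128^3), c(128, 128, 128)))
  cr <- centralCropOrPad(big, 64)
  expect_equal(dim(mapData(cr)), rep(64L, 3))
  expect_equal(mapData(cr), mapData(big)[33:96, 33:96, 33:96])

  small <- DensityMap(array(1, c(45, 45, 45)))
  pd <- centralCropOrPad(small, 64)
  expect_equal(dim(mapData(pd)), rep(64L, 3))
  expect_true(all(mapData(pd)[1:45, 1:45, 1:45] == 1))
  expect_true(all(mapData(pd)[46:64, , ] == 0))
  expect_true(all(mapData(pd)[, 46:64, ] == 0))

  same <- DensityMap(array(rnorm(64^3), c(64, 64, 64)))
  expect_equal(mapData(centralCropOrPad(same, 64)), mapData(same))
})

test_that("masking zeroes exactly the masked voxels", {
  set.seed(2)
  m <- DensityMap(array(rnorm(4^3), c(4, 4, 4)))
  ones <- array(1, c(4, 4, 4))
  expect_equal(mapData(applyMask(m, ones)), mapData(m))
  expect_true(all(mapData(applyMask(m, ones * 0)) == 0))
  half <- ones; half[1:2, , ] <- 0
  masked <- applyMask(m, half)
  expect_true(all(mapData(masked)[1:2, , ] == 0))
  expect_equal(mapData(masked)[3:4, , ], mapData(m)[3:4, , ])
  expect_error(applyMask(m, array(1, c(3, 3, 3))), "dimensions")
  expect_error(applyMask(m, ones * 2), "0 or 1")
})

test_that("power-of-two padding is reproducible and splits pads evenly", {
  m64 <- DensityMap(array(1, c(64, 64, 64)))
  expect_equal(dim(mapData(padToPow2(m64, seed = 1))), rep(64L, 3))
  m100 <- DensityMap(array(1, c(100, 100, 100)))
  expect_equal(dim(mapData(padToPow2(m100, seed = 1))), rep(128L, 3))

  m45 <- DensityMap(array(rnorm(45^3), c(45, 45, 45)))
  a <- padToPow2(m45, seed = 9)
  b <- padToPow2(m45, seed = 9)
  expect_identical(mapData(a), mapData(b))
  expect_equal(dim(mapData(a)), rep(64L, 3))
  # per-axis pads are (9,10) or (10,9)
  occ <- which(mapData(a) != 0, arr.ind = TRUE)
  for (ax in 1:3) {
    front <- min(occ[, ax]) - 1L
    back <- 64L - max(occ[, ax])
    expect_true(all(sort(c(front, back)) == c(9L, 10L)))
  }
  # label volumes can pad with the background sentinel
  lab <- padToPow2(DensityMap(array(3, c(45, 45, 45))), seed = 9,
                   padValue = -1)
  expect_equal(sort(unique(as.vector(mapData(lab)))), c(-1, 3))
})

test_that("partitioning tiles the volume and removes empty cubes", {
  full <- DensityMap(array(1, c(64, 64, 64)))
  lab <- array(5, c(64, 64, 64))
  pb <- partitionPatches(full, lab)
  expect_equal(dim(patchInputs(pb))[1], 64L)   # (64/16)^3

  empty <- DensityMap(array(0, c(32, 32, 32)))
  expect_equal(dim(patchInputs(partitionPatches(empty)))[1], 0L)

  oct <- array(0, c(32, 32, 32))
  oct[17:32, 1:16, 17:32] <- rnorm(16^3)
  pb1 <- partitionPatches(DensityMap(oct), array(1, c(32, 32, 32)))
  expect_equal(dim(patchInputs(pb1))[1], 1L)
  expect_equal(unname(patchOffsets(pb1)[1, ]), c(16L, 0L, 16L))
  expect_error(partitionPatches(DensityMap(array(1, c(20, 20, 20)))),
               "divisible")
})

test_that("partition then reassemble is exact on non-empty cubes", {
  set.seed(4)
  x <- array(rnorm(32^3), c(32, 32, 32))
  x[1:16, 1:16, 1:16] <- 0               # one empty cube
  lab <- array(sample(0:9, 32^3, TRUE), c(32, 32, 32))
  pb <- partitionPatches(DensityMap(x), lab)
  expect_equal(dim(patchInputs(pb))[1], 7L)
  back <- reassemblePatches(pb)
  expect_equal(back[17:32, , ], lab[17:32, , ])
  expect_true(all(back[1:16, 1:16, 1:16] == -1))
  # removed cubes come back as background only where they were removed
  half <- x; half[1:16, , ] <- 0
  hb <- reassemblePatches(partitionPatches(DensityMap(half), lab))
  expect_true(all(hb[1:16, , ] == -1))
  expect_equal(hb[17:32, , ], lab[17:32, , ])
})

test_that("dataset splits are disjoint, covering and size-exact", {
  s <- splitDataset(1:10, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(s), c(train = 6L, validation = 2L, test = 2L))
  s2 <- splitDataset(1:100, c(0.72, 0.08, 0.20), seed = 1)
  expect_equal(lengths(s2), c(train = 72L, validation = 8L, test = 20L))
  expect_equal(sort(unlist(s2, use.names = FALSE)), 1:100)
  expect_identical(splitDataset(1:100, seed = 7),
                   splitDataset(1:100, seed = 7))
  # property: disjoint covering for assorted ratios and sizes
  for (n in c(1, 7, 33)) {
    for (r in list(c(0.5, 0.25, 0.25), c(0.9, 0.05, 0.05))) {
      sp <- splitDataset(seq_len(n), r, seed = n)
      all3 <- unlist(sp, use.names = FALSE)
      expect_equal(sort(all3), seq_len(n))
      expect_equal(length(all3), length(unique(all3)))
    }
  }
  expect_equal(lengths(splitDataset(integer(0))),
               c(train = 0L, validation = 0L, test = 0L))
})

test_that("the simulated corpus size is structures times resolutions", {
  expect_equal(simulatedCorpusSize(12671), 38013)
  expect_equal(simulatedCorpusSize(5, c(2.5, 7.5)), 10)
})

test_that("preprocessing keeps (input, label) pairs in register", {
  ph <- makeLocalResPhantom(c(2.5, 12.5), box = 32, seed = 3)
  lab <- ph@voxelLabels
  stages <- list(
    function(m, l) list(minMaxNormalize(m), l),
    function(m, l) list(centralCropOrPad(m, 32),
                        mapData(centralCropOrPad(DensityMap(l), 32,
                                                 padValue = -1))),
    function(m, l) list(padToPow2(m, seed = 5),
                        mapData(padToPow2(DensityMap(l), seed = 5,
                                          padValue = -1))))
  m <- ph@map
  for (st in stages) {
    out <- st(m, lab)
    m <- out[[1]]; lab <- out[[2]]
    expect_identical(dim(mapData(m)), dim(lab))
  }
})
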