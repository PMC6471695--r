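test_that("empty model simulates to an all-zero map", {
  m <- simulateMap(AtomicModel(), 7.5, box = 16)
  expect_true(all(mapData(m) == 0))
  expect_equal(dim(mapData(m)), c(16L, 16L, 16L))
})

test_that("a single centred atom gives a symmetric map peaking centrally", {
  one <- AtomicModel(matrix(c(5, 9, 7), 1, 3))
  m <- mapData(suppressWarnings(simulateMap(one, 5, box = 32)))
  peak <- which(m == max(m), arr.ind = TRUE)[1, ]
  # centre of an even box falls between voxels 16 and 17 on each axis
  expect_true(all(peak %in% 16:17))
  # mirror symmetry about the box centre (indices i and 33 - i)
  expect_equal(m, m[32:1, , ], tolerance = 1e-10)
  expect_equal(m, m[, 32:1, ], tolerance = 1e-10)
  expect_equal(m, m[, , 32:1], tolerance = 1e-10)
})

test_that("rotationally averaged spectrum halves at s = 1/R", {
  one <- AtomicModel(matrix(c(32, 32, 32), 1, 3))
  for (R in c(2.5, 7.5, 12.5)) {
    m <- suppressWarnings(simulateMap(one, R, box = 64))
    sStar <- oracleHalfCrossing(mapData(m))
    expect_lt(abs(sStar - 1 / R) * R, 0.02)
  }
})

test_that("maps are exactly zero beyond the support cutoff", {
  one <- AtomicModel(matrix(c(32, 32, 32), 1, 3))
  m <- mapData(suppressWarnings(simulateMap(one, 2.5, box = 64)))
  expect_gt(mean(m == 0), 0.9)
  expect_identical(m[1, 1, 1], 0)
})

test_that("simulation is linear in atom weights", {
  mod <- threeAtomModel()
  mod2 <- AtomicModel(atomPositions(mod), weights = 2)
  a <- mapData(simulateMap(mod, 7.5, box = 32))
  b <- mapData(simulateMap(mod2, 7.5, box = 32))
  expect_equal(b, 2 * a, tolerance = 1e-12)
})

test_that("larger R strictly reduces power above any fixed band", {
  mod <- threeAtomModel()
  for (band in c(0.15, 0.25, 0.35)) {
    pw <- vapply(c(2.5, 7.5, 12.5), function(R) {
      ra <- radialAmplitude(simulateMap(mod, R, box = 32) |>
                              suppressWarnings())
      sum(ra$amplitude[ra$s > band]^2)
    }, 0)
    expect_true(all(diff(pw) < 0))
  }
})

test_that("atoms outside the box are reported", {
  far <- AtomicModel(matrix(c(0, 0, 0, 100, 100, 100), 2, 3, byrow = TRUE))
  expect_error(suppressWarnings(simulateMap(far, 7.5, box = 16)),
               "outside")
})

test_that("sub-voxel Gaussian widths trigger a sampling warning", {
  one <- AtomicModel(matrix(8, 1, 3))
  expect_warning(simulateMap(one, 1.6, box = 16), "sampling|voxel")
  expect_silent(simulateMap(one, 7.5, box = 16))
})

test_that("synthetic models are deterministic protein-like walks", {
  expect_equal(nAtoms(makeSyntheticModel(0, 40, seed = 1)), 0L)
  a <- makeSyntheticModel(500, extent = 40, seed = 3)
  b <- makeSyntheticModel(500, extent = 40, seed = 3)
  expect_identical(atomPositions(a), atomPositions(b))
  expect_false(identical(
    atomPositions(a), atomPositions(makeSyntheticModel(500, 40, seed = 4))))
  # consecutive steps are 1.5 A; the walk stays inside the extent
  d <- sqrt(rowSums(diff(atomPositions(a))^2))
  expect_equal(d, rep(1.5, 499), tolerance = 1e-12)
  bb <- apply(atomPositions(a), 2, function(x) diff(range(x)))
  expect_true(all(bb <= 40))
})
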