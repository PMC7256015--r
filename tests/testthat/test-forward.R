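# Forward model: line integrals, polychromatic expected counts, Poisson
# sampling.

test_that("the central ray through a uniform disk equals chord x density", {
  # water disk, diameter 24 voxels = 0.6 cm, density 1 g/mL -> A = 0.6 g/cm^2
  ph <- disk_phantom(n = 64, water_radius_vox = 12)
  geom <- ct_geometry(n_views = 4, n_detectors = 96)
  A <- project_material(ph, geom, "water")
  center <- (geom$n_detectors + 1) / 2   # between detectors 48 and 49
  chord <- mean(A[1, floor(center):ceiling(center)])
  expect_lt(abs(chord - 0.6), 0.01 * 0.6)
})

test_that("projection is linear and zero maps project to zero", {
  geom <- ct_geometry(30, 96)
  ph0 <- voxel_phantom(64, 250)
  expect_true(all(project_material(ph0, geom, "water") == 0))
  ph1 <- disk_phantom(64, 10)
  ph2 <- disk_phantom(64, 20)
  ph12 <- voxel_phantom(64, 250)
  ph12$maps$water <- ph1$maps$water + ph2$maps$water
  expect_equal(project_material(ph12, geom, "water"),
               project_material(ph1, geom, "water") +
                 project_material(ph2, geom, "water"),
               tolerance = 1e-12)
})

test_that("expected counts equal the blank at zero attenuation and decrease with path", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  blank <- blank_counts(s, b, flux = 1e4)
  A0 <- list(water = matrix(0, 2, 2))
  lam0 <- expected_counts(A0, s, b, flux = 1e4)
  for (k in seq_len(b$n_bins)) {
    expect_equal(unname(lam0[, , k]), matrix(blank[k], 2, 2), tolerance = 1e-9)
  }
  lam1 <- expected_counts(list(water = matrix(2, 1, 1)), s, b, 1e4)
  lam2 <- expected_counts(list(water = matrix(4, 1, 1)), s, b, 1e4)
  expect_true(all(lam1 > lam2))
  expect_true(all(lam1 < blank + 1e-9))
  expect_error(expected_counts(list(water = matrix(-1, 1, 1)), s, b, 1e4),
               "negative")
})

test_that("expected counts match an independently coded spectral sum", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  A <- list(water = matrix(3, 1, 1), gold = matrix(0.004, 1, 1))
  lam <- as.numeric(expected_counts(A, s, b, flux = 5e4))
  oracle <- oracle_expected_counts(list(water = 3, gold = 0.004), s, b, 5e4)
  expect_equal(lam, unname(oracle), tolerance = 1e-10)
})

test_that("gold's K-edge boosts attenuation in bin [83,98) relative to [53,78)", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  w <- 2   # g/cm^2 water background path
  lam0 <- oracle_expected_counts(list(water = w, gold = 0), s, b, 1e5)
  lam1 <- oracle_expected_counts(list(water = w, gold = 0.01), s, b, 1e5)
  drop_frac <- 1 - lam1 / lam0
  expect_gt(drop_frac[4], drop_frac[2])   # [83,98) vs [53,78)
  # and the same ordering through the package path
  p0 <- as.numeric(expected_counts(list(water = matrix(w, 1, 1)), s, b, 1e5))
  p1 <- as.numeric(expected_counts(list(water = matrix(w, 1, 1),
                                        gold = matrix(0.01, 1, 1)), s, b, 1e5))
  dd <- 1 - p1 / p0
  expect_gt(dd[4], dd[2])
})

test_that("iodine attenuates the low bin proportionally more than the top bin", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  lam0 <- oracle_expected_counts(list(water = 2, iodine = 0), s, b, 1e5)
  lam1 <- oracle_expected_counts(list(water = 2, iodine = 0.01), s, b, 1e5)
  drop_frac <- 1 - lam1 / lam0
  expect_gt(drop_frac[1], drop_frac[5])
})

test_that("bins are additive: per-bin counts sum to the single-bin total", {
  s <- build_source_spectrum(120, 2.5)
  b5 <- energy_bin_set()
  b1 <- energy_bin_set(30, upper_kev = 120)
  A <- list(water = matrix(c(0, 1, 2.5, 4), 2, 2))
  lam5 <- expected_counts(A, s, b5, 1e4)
  lam1 <- expected_counts(A, s, b1, 1e4)
  expect_equal(apply(lam5, c(1, 2), sum), lam1[, , 1], tolerance = 1e-9)
})

test_that("Poisson sampling is seeded, mean-correct and dispersion ~1", {
  expect_true(all(sample_poisson(array(0, c(3, 3)), seed = 1) == 0))
  lam <- array(1e4, c(100, 100))
  x1 <- sample_poisson(lam, seed = 9)
  x2 <- sample_poisson(lam, seed = 9)
  expect_identical(x1, x2)
  m <- mean(x1)
  expect_lt(abs(m - 1e4), 3 * sqrt(1e4 / length(lam)))
  disp <- var(as.numeric(x1)) / m
  expect_gt(disp, 0.9); expect_lt(disp, 1.1)
  expect_error(sample_poisson(array(-1, c(2, 2)), 1), ">= 0")
})

test_that("an acquisition bundles counts, blank and geometry consistently", {
  cfg <- small_config()
  ph <- disk_phantom()
  sino <- acquire(ph, cfg, seed = 4)
  expect_identical(dim(sino$counts),
                   c(cfg$geometry$n_views, cfg$geometry$n_detectors,
                     cfg$bins$n_bins))
  expect_true(all(sino$counts >= 0))
  expect_true(all(sino$blank > 0))
  expect_equal(sum(sino$blank), cfg$flux, tolerance = 1e-9)
  # air rays carry roughly blank-level counts
  edge <- sino$counts[1, 2, ]
  expect_lt(abs(sum(edge) - cfg$flux), 4 * sqrt(cfg$flux))
})
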