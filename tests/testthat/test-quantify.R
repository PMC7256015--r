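# ROI segmentation, mass/cell quantification, detection limits.

test_that("segmentation of an empty image yields an empty ROI", {
  img <- matrix(0, 64, 64)
  roi <- segment_roi(img, background_box(64))
  expect_false(any(roi))
})

test_that("segmentation recovers the pellet footprint within 10%", {
  # full default geometry: the 2 sigma rule needs a realistic noise floor
  cfg <- acquisition_config()
  ph <- build_pellet(0.5e6)
  img <- reconstruct_materials(decompose_sinogram(acquire(ph, cfg, seed = 8)),
                               cfg$n)
  roi <- segment_roi(img$maps$gold, background_box(cfg$n))
  truth <- attr(ph, "pellet_mask")
  expect_lt(abs(sum(roi) - sum(truth)) / sum(truth), 0.10)
  # the ROI sits on the pellet, not elsewhere
  expect_gt(sum(roi & truth) / sum(roi), 0.8)
})

test_that("pure-noise images produce ROIs covering under 1% of voxels", {
  set.seed(55)
  cover <- replicate(20, {
    img <- matrix(rnorm(64 * 64, sd = 10), 64, 64)
    mean(segment_roi(img, background_box(64)))
  })
  expect_lt(mean(cover), 0.01)
})

test_that("ROI mass is concentration times volume, negatives included", {
  img <- matrix(0, 64, 64)
  roi <- matrix(FALSE, 64, 64)
  roi[1:10, 1:10] <- TRUE
  img[roi] <- 2
  q <- roi_mass(img, roi, voxel_size_um = 250)
  expect_equal(q$mass_ug, 2 * 100 * 1.5625e-2, tolerance = 1e-12)
  expect_equal(q$roi_volume_ul, 100 * 1.5625e-2)
  expect_identical(q$roi_voxels, 100L)
  # negative voxels are summed as-is
  img[1, 1] <- -2
  expect_equal(roi_mass(img, roi, 250)$mass_ug, 2 * 98 * 1.5625e-2,
               tolerance = 1e-12)
  # empty ROI
  q0 <- roi_mass(img, matrix(FALSE, 64, 64), 250)
  expect_equal(q0$mass_ug, 0)
  expect_equal(q0$est_cells, 0)
})

test_that("cell number estimation is mass over per-cell load", {
  expect_equal(estimate_cells(128, 128), 1e6)
  expect_equal(estimate_cells(0, 128), 0)
  expect_equal(estimate_cells(7.4, 128), 57812.5)  # the failure animal's mass
  expect_error(estimate_cells(10, 0), "positive")
})

test_that("quantified mass increases strictly along the printed pellet series", {
  cfg <- small_config()
  cells <- c(0, 0.125e6, 0.25e6, 0.5e6, 1e6)
  masses <- vapply(cells, function(cc) {
    ph <- build_pellet(cc, n = cfg$n, voxel_size_um = cfg$voxel_size_um)
    img <- reconstruct_materials(decompose_sinogram(acquire(ph, cfg)), cfg$n)
    roi <- segment_roi(img$maps$gold, background_box(cfg$n))
    roi_mass(img$maps$gold, roi, cfg$voxel_size_um)$mass_ug
  }, 0)
  expect_true(all(diff(masses) > 0))
  # noiseless quantification of the 1e6-cell pellet lands within 5% of 128 ug
  expect_lt(abs(masses[5] - 128), 0.05 * 128)
})

test_that("the analytic detection limit follows k sigma V over load", {
  expect_equal(analytic_detection_limit(10, k = 4), 4882.8125)
  # doubling the per-cell load halves the limit
  expect_equal(analytic_detection_limit(10, per_cell_load_pg = 256),
               analytic_detection_limit(10) / 2)
  expect_error(analytic_detection_limit(10, k = 0), "positive")
  expect_error(detection_limit(small_config(), k = 0), "positive")
  expect_error(detection_limit(small_config(), n_replicates = 5), "20")
})

test_that("the empirical detection scan flags a limit beyond the grid", {
  # tiny geometry, grid far below the reachable limit: must flag, not error
  cfg <- small_config(n = 33, n_views = 24, n_detectors = 49)
  dl <- detection_limit(cfg, n_replicates = 20, cell_grid = c(10, 20),
                        seed = 2, bg_diameter_mm = 6)
  expect_false(dl$converged)
  expect_true(is.na(dl$empirical_cells))
  expect_identical(nrow(dl$rates), 2L)
  expect_gt(dl$sigma_bg_mg_ml, 0)
})
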