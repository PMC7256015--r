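# Filtered back-projection and Hounsfield conversion.

test_that("FBP is linear and maps zero to zero", {
  geom <- ct_geometry(40, 96)
  z <- matrix(0, 40, 96)
  expect_true(all(fbp(z, geom, 64) == 0))
  set.seed(1)
  a <- matrix(runif(40 * 96), 40, 96)
  b <- matrix(runif(40 * 96), 40, 96)
  expect_equal(fbp(a + b, geom, 64), fbp(a, geom, 64) + fbp(b, geom, 64),
               tolerance = 1e-10)
  expect_error(fbp(matrix(0, 10, 10), geom, 64), "dimensions")
})

test_that("a uniform disk round-trips through projection and FBP within 5%", {
  # oracle route: forward-project the known disk at dense views, reconstruct,
  # compare interior mean (1-voxel eroded) with the known concentration
  n <- 100
  ph <- disk_phantom(n = n, water_radius_vox = 40, contrast = "gold",
                     contrast_mg_ml = 4, contrast_radius_vox = 20)
  geom <- ct_geometry(n_views = 720, n_detectors = 144)
  A <- project_material(ph, geom, "gold")
  rec <- fbp(A, geom, n) * 1000
  interior <- spcct:::.disk_mask(n, 19)
  expect_lt(abs(mean(rec[interior]) - 4), 0.05 * 4)
})

test_that("project -> decompose -> FBP recovers uniform concentrations within 5%", {
  cfg <- small_config()
  ph <- disk_phantom(n = cfg$n, water_radius_vox = 24, contrast = "gold",
                     contrast_mg_ml = 4, contrast_radius_vox = 8)
  img <- reconstruct_materials(decompose_sinogram(acquire(ph, cfg)), cfg$n)
  interior <- spcct:::.disk_mask(cfg$n, 7)
  expect_lt(abs(mean(img$maps$gold[interior]) - 4), 0.05 * 4)
  water_in <- spcct:::.disk_mask(cfg$n, 20) & !spcct:::.disk_mask(cfg$n, 10)
  expect_lt(abs(mean(img$maps$water[water_in]) - 1000), 0.05 * 1000)
})

test_that("Hounsfield conversion anchors air at -1000 and water at 0", {
  muw <- 0.2
  expect_equal(to_hounsfield(muw, muw), 0)
  expect_equal(to_hounsfield(0, muw), -1000)
  expect_equal(to_hounsfield(2 * muw, muw), 1000)
  expect_error(to_hounsfield(0.1, 0), "positive")
})

test_that("conventional images read ~0 HU in water and ~-1000 HU in air", {
  cfg <- small_config()
  ph <- disk_phantom(n = cfg$n, water_radius_vox = 24)
  hu <- reconstruct_conventional(acquire(ph, cfg, seed = 21), cfg$n)
  water_in <- spcct:::.disk_mask(cfg$n, 18)
  air <- !spcct:::.disk_mask(cfg$n, 30)
  expect_lt(abs(mean(hu[water_in])), 30)
  expect_lt(abs(mean(hu[air]) + 1000), 40)
})

bicolor_disk_phantom <- function(n, conc_mg_ml) {
  ph <- voxel_phantom(n, 250)
  ph$maps$water[spcct:::.disk_mask(n, 26)] <- 1.0
  au <- matrix(0, n, n); au[spcct:::.disk_mask(n, 6, cx = -12)] <- conc_mg_ml
  io <- matrix(0, n, n); io[spcct:::.disk_mask(n, 6, cx = 12)] <- conc_mg_ml
  ph$maps$gold <- au; ph$maps$iodine <- io
  ph
}

test_that("material images show each agent only at its own location", {
  cfg <- small_config(flux = 1e5)   # decisive contrast-to-noise
  n <- cfg$n
  ph <- bicolor_disk_phantom(n, 40)
  sino <- acquire(ph, cfg, seed = 33)
  img <- reconstruct_materials(decompose_sinogram(sino), n)
  gold_region <- spcct:::.disk_mask(n, 5, cx = -12)
  iod_region <- spcct:::.disk_mask(n, 5, cx = 12)
  bg <- spcct:::.disk_mask(n, 5, cy = 16)
  sd_gold_bg <- sd(img$maps$gold[bg])
  sd_iod_bg <- sd(img$maps$iodine[bg])
  # each map shows its own agent well above the per-voxel noise ...
  expect_gt(mean(img$maps$gold[gold_region]), 2 * sd_gold_bg)
  expect_gt(mean(img$maps$iodine[iod_region]), 2 * sd_iod_bg)
  # ... and stays consistent with zero at the other agent's location
  expect_lt(abs(mean(img$maps$gold[iod_region])), 2 * sd_gold_bg)
  expect_lt(abs(mean(img$maps$iodine[gold_region])), 2 * sd_iod_bg)
})

test_that("conventional images cannot separate gold from iodine at matched mg/mL", {
  cfg <- small_config()
  n <- cfg$n
  sino <- acquire(bicolor_disk_phantom(n, 6), cfg, seed = 34)
  hu <- reconstruct_conventional(sino, n)
  gold_region <- spcct:::.disk_mask(n, 5, cx = -12)
  iod_region <- spcct:::.disk_mask(n, 5, cx = 12)
  m1 <- mean(hu[gold_region]); s1 <- sd(hu[gold_region])
  m2 <- mean(hu[iod_region]); s2 <- sd(hu[iod_region])
  # overlapping +/- 1 SD intervals: the agents are indistinguishable by HU
  expect_lt(abs(m1 - m2), s1 + s2)
  # while both enhance relative to plain water
  water_hu <- mean(hu[spcct:::.disk_mask(n, 5, cy = 16)])
  expect_gt(m1, water_hu)
  expect_gt(m2, water_hu)
})
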