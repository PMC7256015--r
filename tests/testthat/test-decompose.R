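# Per-ray maximum-likelihood material decomposition, calibration fitting,
# conventional sinogram.

test_that("noiseless rays are decomposed back to the exact truth", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  truth <- list(water = matrix(2, 1, 1), gold = matrix(0.002, 1, 1))
  y <- as.numeric(expected_counts(truth, s, b, flux = 1e5))
  blank <- blank_counts(s, b, 1e5)
  fit <- ml_decompose_ray(y, blank, s, b, basis = c("water", "gold"))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$A - c(2, 0.002))), 1e-6)   # g/cm^2, absolute
})

test_that("a blank ray decomposes to zero and an empty ray is flagged", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  blank <- blank_counts(s, b, 1e5)
  fit <- ml_decompose_ray(as.numeric(blank), blank, s, b)
  expect_true(fit$converged)
  expect_equal(unname(fit$A), c(0, 0, 0), tolerance = 1e-8)
  fit0 <- ml_decompose_ray(rep(0, 5), blank, s, b)
  expect_false(fit0$converged)
  expect_equal(unname(fit0$A), c(0, 0, 0))
})

test_that("ML decomposition equals brute-force likelihood grid search", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  flux <- 1e5
  blank <- blank_counts(s, b, flux)
  set.seed(202)
  n_rays <- 50
  for (r in seq_len(n_rays)) {
    truth <- c(water = runif(1, 0.5, 5), gold = runif(1, 0, 0.01))
    y <- oracle_expected_counts(list(water = truth[1], gold = truth[2]),
                                s, b, flux)
    fit <- ml_decompose_ray(unname(y), blank, s, b, basis = c("water", "gold"))
    gs <- grid_search_ml(unname(y), s, b, flux,
                         center = c(2.75, 0.005), halfwidth = c(2.5, 0.0055))
    expect_true(fit$converged)
    # coordinate agreement at the scale of the final lattice: along the
    # nearly flat diagonal ridge the best lattice point can sit a dozen
    # spacings from the continuum optimum, so allow 20 spacings (~2e-5
    # g/cm^2 for gold); the likelihood check below pins the optimum exactly
    expect_lt(abs(fit$A[1] - gs$A[1]), 20 * gs$resolution[1])
    expect_lt(abs(fit$A[2] - gs$A[2]), 20 * gs$resolution[2])
    # ... and the Newton solution is at least as likely as the lattice best
    e <- as.numeric(s$grid)
    mu <- sapply(c("water", "gold"), function(m)
      mass_attenuation_at(attenuation_table(m), e))
    W <- spcct:::.bin_weights(s, b, flux)
    lam_fit <- as.numeric(exp(-matrix(fit$A, 1) %*% t(mu)) %*% W)
    ll_fit <- sum(y * log(lam_fit)) - sum(lam_fit)
    expect_gte(ll_fit, gs$loglik - 1e-6 * abs(gs$loglik))
  }
})

test_that("the ML estimate is asymptotically unbiased at high flux", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  flux <- 1e6
  blank <- blank_counts(s, b, flux)
  lam <- oracle_expected_counts(list(water = 2, gold = 0.002), s, b, flux)
  set.seed(31)
  est <- replicate(500, {
    y <- rpois(5, lam)
    ml_decompose_ray(y, blank, s, b, basis = c("water", "gold"))$A[2]
  })
  expect_lt(abs(mean(est) - 0.002), 0.02 * 0.002)
})

test_that("decomposition noise scales as one over the square root of flux", {
  s <- build_source_spectrum(120, 2.5)
  b <- energy_bin_set()
  lam_of <- function(f) oracle_expected_counts(list(water = 2, gold = 0.002),
                                               s, b, f)
  sd_at <- function(f, seed) {
    blank <- blank_counts(s, b, f)
    lam <- lam_of(f)
    set.seed(seed)
    sd(replicate(300, {
      y <- rpois(5, lam)
      ml_decompose_ray(y, blank, s, b, basis = c("water", "gold"))$A[2]
    }))
  }
  ratio <- sd_at(1e4, 5) / sd_at(1e5, 6)
  expect_gt(ratio, sqrt(10) * 0.7)
  expect_lt(ratio, sqrt(10) * 1.4)
})

test_that("sinogram decomposition is basis-separable on noiseless phantoms", {
  cfg <- small_config()
  ph <- disk_phantom(contrast = "gold", contrast_mg_ml = 8)
  sino <- acquire(ph, cfg)                 # noiseless
  ms <- decompose_sinogram(sino)
  expect_true(all(ms$converged))
  # gold-only phantom: iodine sinogram is ~0 relative to the gold signal
  Amax <- max(ms$A$gold)
  expect_gt(Amax, 0)
  expect_lt(max(abs(ms$A$iodine)), 0.01 * Amax)
  # zero-attenuation sinogram decomposes to all-zero material sinograms
  empty <- acquire(voxel_phantom(cfg$n, cfg$voxel_size_um), cfg)
  ms0 <- decompose_sinogram(empty)
  expect_lt(max(abs(ms0$A$gold)), 1e-8)
  expect_lt(max(abs(ms0$A$water)), 1e-8)
  expect_error(decompose_sinogram(sino, basis = c("water", "kryptonite")),
               "attenuation")
})

test_that("fitted calibration reproduces spectrum-weighted bin coefficients", {
  cfg <- small_config(flux = 1e5)
  tubes <- c(build_calibration_series(c(0, 20, 40), "gold", 6,
                                      n = cfg$n, voxel_size_um = cfg$voxel_size_um),
             build_calibration_series(c(30, 60), "iodine", 6,
                                      n = cfg$n, voxel_size_um = cfg$voxel_size_um))
  scans <- lapply(tubes, acquire, config = cfg)      # noiseless
  cal <- fit_calibration(scans, tubes)
  eff <- effective_attenuation(cfg$spectrum, cfg$bins)
  for (m in c("water", "gold", "iodine")) {
    expect_equal(cal$coefficients[, m], eff[, m], tolerance = 0.02,
                 ignore_attr = TRUE)
  }
  # K-edge ordering: gold coefficient in bin [83,98) above bin [53,78)
  expect_gt(cal$coefficients[4, "gold"], cal$coefficients[2, "gold"])
  # degenerate design: a single concentration cannot be fitted
  expect_error(fit_calibration(scans[1], tubes[1]), "rank")
})

test_that("calibrated mode agrees with physics mode on noiseless data", {
  cfg <- small_config(flux = 1e5)
  tubes <- c(build_calibration_series(c(0, 20, 40), "gold", 6, n = cfg$n),
             build_calibration_series(c(30, 60), "iodine", 6, n = cfg$n))
  cal <- fit_calibration(lapply(tubes, acquire, config = cfg), tubes)
  ph <- disk_phantom(contrast = "gold", contrast_mg_ml = 8)
  sino <- acquire(ph, cfg)
  phys <- decompose_sinogram(sino, mode = "physics")
  calb <- decompose_sinogram(sino, mode = "calibrated", calibration = cal)
  central <- phys$A$gold > 0.5 * max(phys$A$gold)
  rel <- abs(calb$A$gold[central] - phys$A$gold[central]) / phys$A$gold[central]
  expect_lt(median(rel), 0.05)
  expect_error(decompose_sinogram(sino, mode = "calibrated"), "calibration")
})

test_that("calcium leaks into the iodine sinogram, not primarily into gold", {
  # skull-only phantom decomposed without calcium in the basis
  ph <- build_brain_slice(0, 0, 0, 0, skull = TRUE, n = 64, voxel_size_um = 500)
  cfg <- small_config(n = 64, voxel_size_um = 500)
  ms <- decompose_sinogram(acquire(ph, cfg))
  Aca <- project_material(ph, cfg$geometry, "calcium")
  sk <- Aca > 0.5 * max(Aca)
  iod_leak <- mean(ms$A$iodine[sk])
  au_leak <- mean(ms$A$gold[sk])
  expect_gt(iod_leak, 0)                       # skull appears in iodine
  expect_lt(abs(au_leak), iod_leak)            # and much less in gold
})

test_that("the conventional sinogram is the log total transmission", {
  cfg <- small_config()
  empty <- acquire(voxel_phantom(cfg$n, cfg$voxel_size_um), cfg)
  expect_equal(max(abs(conventional_sinogram(empty))), 0, tolerance = 1e-9)
  # transmission 1/e in every bin -> p = 1
  fake <- empty
  fake$counts <- empty$counts / exp(1)
  expect_equal(unique(round(as.numeric(conventional_sinogram(fake)), 9)), 1)
  # central ray through a water disk: within 3% of the polychromatic oracle
  ph <- disk_phantom(n = 64, water_radius_vox = 24)
  sino <- acquire(ph, cfg)
  p <- conventional_sinogram(sino)
  lam <- oracle_expected_counts(list(water = 24 * 2 * 0.025), cfg$spectrum,
                                cfg$bins, cfg$flux)
  p_oracle <- -log(sum(lam) / cfg$flux)
  center <- (cfg$geometry$n_detectors + 1) / 2
  p_central <- mean(p[1, floor(center):ceiling(center)])
  expect_lt(abs(p_central - p_oracle), 0.03 * p_oracle)
})
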