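# Experiment orchestration: validation, packaged designs, reproducible runs.

tiny_cfg <- function(type, seed = 1, params, voxel_size_um = 250) {
  experiment_config(type, seed = seed, n = 64, n_views = 48, n_detectors = 96,
                    voxel_size_um = voxel_size_um, params = params)
}

test_that("configuration validation names the offending field", {
  expect_error(experiment_config("pellets", seed = NULL,
                                 params = list(cell_counts = 0)), "seed")
  expect_error(experiment_config("nonsense", seed = 1), "type")
  expect_error(experiment_config("pellets", seed = 1, kvp = 90), "kvp")
  expect_error(experiment_config("pellets", seed = 1, flux = -5), "flux")
  expect_error(experiment_config("pellets", seed = 1, n_detectors = 10),
               "n_detectors")
  expect_error(experiment_config("pellets", seed = 1, filter = "shepp"),
               "filter")
})

test_that("builtin experiments reproduce the printed study designs", {
  pel <- builtin_experiments("pellets")
  expect_identical(pel$params$cell_counts, c(1e6, 0.5e6, 0.25e6, 0.125e6, 0))
  expect_identical(pel$params$per_cell_load_pg, 128)
  cal <- builtin_experiments("calibration")
  expect_identical(nrow(cal$params$tubes), 13L)
  expect_identical(cal$params$tubes$mM[cal$params$tubes$element == "gold"],
                   c(0, 10, 15, 20, 30, 40))
  expect_identical(cal$params$tubes$mM[cal$params$tubes$element == "iodine"],
                   c(0, 10, 15, 20, 30, 40, 60))
  expect_error(builtin_experiments("unknown"),
               "calibration.*pellets.*monocolor.*bicolor.*detection_limit")
})

test_that("configurations round-trip through YAML and JSON files", {
  cfg <- builtin_experiments("pellets", seed = 9)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_experiment_config(cfg, f)
    back <- read_experiment_config(f)
    expect_identical(back$type, cfg$type)
    expect_equal(back$seed, cfg$seed)
    expect_equal(back$thresholds_kev, cfg$thresholds_kev)
    expect_equal(back$params$cell_counts, cfg$params$cell_counts)
  }
})

test_that("identical configs give byte-identical tables", {
  cfg <- tiny_cfg("pellets",
                  params = list(cell_counts = c(0.5e6, 0),
                                per_cell_load_pg = 128,
                                packing_volume_per_cell_pl = 2.8))
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  run_experiment(cfg, d1)
  run_experiment(cfg, d2)
  t1 <- file.path(d1, "tables", "pellets.csv")
  t2 <- file.path(d2, "tables", "pellets.csv")
  expect_true(file.exists(t1))
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  rep <- jsonlite::fromJSON(file.path(d1, "report.json"))
  expect_true(nzchar(rep$config_hash))
  expect_equal(rep$seed, 1)
  expect_true(!is.null(rep$versions$spcct))
})

test_that("a bicolor run writes both gold and iodine artifacts", {
  cfg <- tiny_cfg("bicolor", voxel_size_um = 500,
                  params = list(design = "bicolor", doses = c(0.5e6, 0.25e6),
                                n_failures = 0, cell_volume_ul_ref = 1.4,
                                scaffold_iodine_ug = 125,
                                scaffold_volume_ul = 4.9))
  d <- file.path(tempdir(), "bic")
  rep <- run_experiment(cfg, d)
  tab <- read.csv(file.path(d, "tables", "quantification.csv"))
  expect_true(all(c("est_gold_ug", "est_iodine_ug") %in% names(tab)))
  expect_identical(nrow(tab), 2L * 3L)
  expect_true(file.exists(file.path(d, "sinograms",
                                    "bicolor-01_tp1_materials.nii.gz")))
  expect_true(is.numeric(rep$summary$agreement$bias_ug))
})
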