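# Orchestration: validated experiment configurations, packaged study
# designs, and end-to-end reproducible runs with a deterministic artifact
# layout.

.experiment_types <- c("calibration", "pellets", "monocolor", "bicolor",
                       "detection_limit")

# FNV-1a hash of a string; hex. Small stable hash for config fingerprints.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor only touches the low byte here
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by 16777619 = 2^24 + 403, exact in doubles
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Experiment configuration
#'
#' Bundles every stage's parameters into one serializable, validated
#' object. A seed is mandatory: all stochastic stages derive their streams
#' from it.
#'
#' @param type One of `"calibration"`, `"pellets"`, `"monocolor"`,
#'   `"bicolor"`, `"detection_limit"`.
#' @param seed Integer seed (mandatory).
#' @param kvp,filtration_mm_al,thresholds_kev,flux,n_views,n_detectors,n,voxel_size_um
#'   Acquisition parameters, see [acquisition_config()].
#' @param basis Decomposition basis materials.
#' @param mode Decomposition mode, `"physics"` or `"calibrated"`.
#' @param filter Reconstruction filter, `"ramp"` or `"hann"`.
#' @param roi_k ROI threshold multiplier for [segment_roi()].
#' @param detect_k Detectability factor for [detection_limit()].
#' @param params Named list of type-specific parameters (e.g.
#'   `concentrations_mM`, `cell_counts`, `n_animals`, `cell_grid`,
#'   `n_replicates`).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(type, seed = NULL,
                              kvp = 120, filtration_mm_al = 2.5,
                              thresholds_kev = c(30, 53, 78, 83, 98),
                              flux = spcct_default_flux(),
                              n_views = 360, n_detectors = 384,
                              n = 256, voxel_size_um = 250,
                              basis = c("water", "gold", "iodine"),
                              mode = "physics", filter = "ramp",
                              roi_k = 2, detect_k = 4,
                              params = list()) {
  cfg <- structure(list(type = type, seed = seed, kvp = kvp,
                        filtration_mm_al = filtration_mm_al,
                        thresholds_kev = thresholds_kev, flux = flux,
                        n_views = n_views, n_detectors = n_detectors,
                        n = n, voxel_size_um = voxel_size_um,
                        basis = basis, mode = mode, filter = filter,
                        roi_k = roi_k, detect_k = detect_k, params = params),
                   class = "experiment_config")
  validate_experiment_config(cfg)
}

#' Validate an experiment configuration
#'
#' Checks every field and fails with an error naming the offending field.
#'
#' @param cfg An [experiment_config()].
#' @return The config, invisibly validated.
#' @export
validate_experiment_config <- function(cfg) {
  fail <- function(field, why) stop(sprintf("invalid config field '%s': %s",
                                            field, why), call. = FALSE)
  if (!cfg$type %in% .experiment_types)
    fail("type", paste("must be one of", paste(.experiment_types, collapse = ", ")))
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    fail("seed", "a seed is mandatory for stochastic stages")
  if (!cfg$kvp %in% c(80, 100, 120)) fail("kvp", "must be 80, 100 or 120")
  if (cfg$filtration_mm_al < 0) fail("filtration_mm_al", "must be >= 0")
  if (any(diff(cfg$thresholds_kev) <= 0) || max(cfg$thresholds_kev) >= cfg$kvp)
    fail("thresholds_kev", "must be ascending and below kvp")
  if (!is.finite(cfg$flux) || cfg$flux <= 0) fail("flux", "must be positive")
  if (cfg$n_views < 2) fail("n_views", "need at least 2 views")
  if (cfg$n_detectors < ceiling(sqrt(2) * cfg$n))
    fail("n_detectors", "detector array must cover the grid diagonal")
  if (cfg$n < 32) fail("n", "grid too small")
  if (cfg$voxel_size_um <= 0) fail("voxel_size_um", "must be positive")
  if (length(cfg$basis) > length(cfg$thresholds_kev))
    fail("basis", "at most as many basis materials as bins")
  if (!cfg$mode %in% c("physics", "calibrated")) fail("mode", "unknown mode")
  if (!cfg$filter %in% c("ramp", "hann")) fail("filter", "unknown filter")
  if (cfg$roi_k <= 0) fail("roi_k", "must be positive")
  if (cfg$detect_k <= 0) fail("detect_k", "must be positive")
  invisible(cfg)
}

#' Read or write an experiment configuration file
#'
#' Configurations serialize to YAML or JSON (same schema: the fields of
#' [experiment_config()]); the format is chosen by file extension.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return For `read_experiment_config`, a validated
#'   [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  args <- lst[setdiff(names(lst), "params")]
  args$params <- as.list(lst$params)
  do.call(experiment_config, args)
}

#' @rdname read_experiment_config
#' @param cfg An [experiment_config()].
#' @export
write_experiment_config <- function(cfg, path) {
  validate_experiment_config(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(cfg), path)
  } else {
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                                null = "null"), path)
  }
  invisible(path)
}

#' Packaged study-design configurations
#'
#' Returns the configuration reproducing one of the built-in experiments:
#' `"calibration"` (13 tubes: gold 0/10/15/20/30/40 mM, iodine
#' 0/10/15/20/30/40/60 mM), `"pellets"` (cell pellets at 1e6, 0.5e6,
#' 0.25e6, 0.125e6 and 0 cells), `"monocolor"` (13-animal longitudinal
#' cohort), `"bicolor"` (9-animal dose-ranging cohort with iodine
#' scaffold), `"detection_limit"` (single-voxel inclusion scan).
#'
#' @param name Experiment name.
#' @param seed Integer seed.
#' @return An [experiment_config()].
#' @export
builtin_experiments <- function(name, seed = 1) {
  if (!name %in% .experiment_types)
    stop("unknown experiment '", name, "'; valid names: ",
         paste(.experiment_types, collapse = ", "))
  params <- switch(name,
    calibration = list(
      tubes = data.frame(
        element = c(rep("gold", 6), rep("iodine", 7)),
        mM = c(0, 10, 15, 20, 30, 40, 0, 10, 15, 20, 30, 40, 60)),
      tube_diameter_mm = 8),
    pellets = list(cell_counts = c(1e6, 0.5e6, 0.25e6, 0.125e6, 0),
                   per_cell_load_pg = 128,
                   packing_volume_per_cell_pl = 2.8),
    monocolor = list(design = "monocolor", cell_volume_ul_ref = 2.7),
    bicolor = list(design = "bicolor", cell_volume_ul_ref = 1.4,
                   scaffold_iodine_ug = 125, scaffold_volume_ul = 4.9),
    detection_limit = list(cell_grid = seq(1000, 10000, by = 250),
                           n_replicates = 20, per_cell_load_pg = 128))
  experiment_config(name, seed = seed, params = params)
}

.item_seed <- function(seed, i, j = 0) {
  (as.numeric(seed) * 48271 + i * 69621 + j * 16807) %% 2147483629
}

.acq_from_cfg <- function(cfg) {
  acquisition_config(kvp = cfg$kvp, filtration_mm_al = cfg$filtration_mm_al,
                     thresholds_kev = cfg$thresholds_kev, flux = cfg$flux,
                     n_views = cfg$n_views, n_detectors = cfg$n_detectors,
                     n = cfg$n, voxel_size_um = cfg$voxel_size_um)
}

# one phantom through acquire -> decompose -> reconstruct -> quantify
.pipeline_one <- function(phantom, cfg, acq, seed, write_prefix = NULL) {
  sino <- acquire(phantom, acq, seed = seed)
  msino <- decompose_sinogram(sino, basis = cfg$basis, mode = "physics")
  img <- reconstruct_materials(msino, n = cfg$n, filter = cfg$filter)
  if (!is.null(write_prefix)) {
    RNifti::writeNifti(RNifti::asNifti(sino$counts),
                       paste0(write_prefix, "_counts.nii.gz"))
    arr <- simplify2array(img$maps)
    RNifti::writeNifti(RNifti::asNifti(arr),
                       paste0(write_prefix, "_materials.nii.gz"))
  }
  list(sino = sino, msino = msino, image = img)
}

#' Run a packaged experiment end to end
#'
#' Executes the configured experiment and writes a deterministic artifact
#' directory: `sinograms/` and `images/` (NIfTI), `tables/` (CSV), and
#' `report.json` (config hash, seeds, package and R versions, summary
#' statistics). Identical configs produce identical tables.
#'
#' @param cfg An [experiment_config()] (see [builtin_experiments()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the report list.
#' @export
run_experiment <- function(cfg, out_dir) {
  validate_experiment_config(cfg)
  for (d in c("", "sinograms", "images", "tables"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  acq <- .acq_from_cfg(cfg)
  t0 <- Sys.time()
  summary_stats <- list()

  if (cfg$type == "calibration") {
    tubes <- cfg$params$tubes
    rows <- list()
    for (i in seq_len(nrow(tubes))) {
      el <- tubes$element[i]
      ph <- build_calibration_series(tubes$mM[i], el,
                                     tube_diameter_mm = cfg$params$tube_diameter_mm,
                                     n = cfg$n, voxel_size_um = cfg$voxel_size_um)[[1]]
      res <- .pipeline_one(ph, cfg, acq, .item_seed(cfg$seed, i),
                           file.path(out_dir, "sinograms", sprintf("tube%02d", i)))
      tube_mask <- phantom_map(ph, "water") > 0
      core <- EBImage::erode(tube_mask * 1, EBImage::makeBrush(5, "disc")) > 0
      est <- mean(res$image$maps[[el]][core])
      rows[[i]] <- data.frame(tube = i, element = el, molar_mM = tubes$mM[i],
                              true_mg_ml = molar_to_mass_concentration(tubes$mM[i], el),
                              est_mg_ml = est)
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "tables", "calibration.csv"),
                     row.names = FALSE)
    for (el in unique(tab$element)) {
      sub <- tab[tab$element == el, ]
      fit <- linreg(sub$true_mg_ml, sub$est_mg_ml)
      summary_stats[[paste0("linearity_", el)]] <-
        list(slope = fit$slope, r_squared = fit$r_squared)
    }
  } else if (cfg$type == "pellets") {
    ccounts <- cfg$params$cell_counts
    rows <- list()
    for (i in seq_along(ccounts)) {
      ph <- build_pellet(ccounts[i],
                         per_cell_load_pg = cfg$params$per_cell_load_pg,
                         packing_volume_per_cell_pl = cfg$params$packing_volume_per_cell_pl,
                         n = cfg$n, voxel_size_um = cfg$voxel_size_um)
      res <- .pipeline_one(ph, cfg, acq, .item_seed(cfg$seed, i),
                           file.path(out_dir, "sinograms", sprintf("pellet%d", i)))
      gold <- res$image$maps$gold
      roi <- segment_roi(gold, background_box(cfg$n), k = cfg$roi_k)
      q <- roi_mass(gold, roi, cfg$voxel_size_um, cfg$params$per_cell_load_pg)
      rows[[i]] <- data.frame(pellet = i, cells = ccounts[i],
                              true_gold_ug = attr(ph, "true_gold_ug"),
                              est_gold_ug = q$mass_ug,
                              roi_volume_ul = q$roi_volume_ul,
                              est_cells = q$est_cells)
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "tables", "pellets.csv"),
                     row.names = FALSE)
    fit <- linreg(tab$true_gold_ug, tab$est_gold_ug)
    summary_stats$pellet_linearity <- list(slope = fit$slope,
                                           intercept = fit$intercept,
                                           r_squared = fit$r_squared)
  } else if (cfg$type %in% c("monocolor", "bicolor")) {
    des <- study_design(cfg$params$design,
                        doses = cfg$params$doses,
                        n_failures = cfg$params$n_failures)
    cohort <- generate_cohort(des, seed = cfg$seed)
    utils::write.csv(cohort_table(cohort),
                     file.path(out_dir, "tables", "cohort.csv"),
                     row.names = FALSE)
    bicolor <- cfg$type == "bicolor"
    rows <- list()
    for (i in seq_len(nrow(cohort))) {
      delivered <- cohort$injected_cells[i] * cohort$delivery_efficiency[i]
      cell_vol <- cfg$params$cell_volume_ul_ref * delivered / 0.375e6
      for (tp in seq_along(cohort$days[[i]])) {
        ph <- build_brain_slice(
          cell_gold_ug = cohort$true_gold_per_timepoint_ug[[i]][tp],
          cell_volume_ul = cell_vol,
          scaffold_iodine_ug = if (bicolor) cfg$params$scaffold_iodine_ug else 0,
          scaffold_volume_ul = if (bicolor) cfg$params$scaffold_volume_ul else 0,
          skull = TRUE, n = cfg$n, voxel_size_um = cfg$voxel_size_um)
        pre <- if (tp == 1)
          file.path(out_dir, "sinograms", sprintf("%s_tp%d", cohort$id[i], tp))
        else NULL
        res <- .pipeline_one(ph, cfg, acq, .item_seed(cfg$seed, i, tp), pre)
        gold <- res$image$maps$gold
        # contralateral background box inside the head
        bgbox <- background_box(cfg$n, offset_vox = -round(cfg$n / 8))
        roi <- segment_roi(gold, bgbox, k = cfg$roi_k)
        q <- roi_mass(gold, roi, cfg$voxel_size_um, des$per_cell_load_pg)
        row <- data.frame(id = cohort$id[i], timepoint = tp,
                          day = cohort$days[[i]][tp],
                          true_gold_ug = cohort$true_gold_per_timepoint_ug[[i]][tp],
                          est_gold_ug = q$mass_ug,
                          roi_volume_ul = q$roi_volume_ul,
                          est_cells = q$est_cells,
                          icp_gold_ug = cohort$icp_gold_ug[i])
        if (bicolor) {
          iod <- res$image$maps$iodine
          roi_i <- segment_roi(iod, bgbox, k = cfg$roi_k)
          row$est_iodine_ug <- roi_mass(iod, roi_i, cfg$voxel_size_um)$mass_ug
        }
        rows[[length(rows) + 1]] <- row
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "tables", "quantification.csv"),
                     row.names = FALSE)
    last <- tab[tab$timepoint == max(tab$timepoint), ]
    rep <- agreement_report(last$est_gold_ug, last$icp_gold_ug)
    summary_stats$agreement <- list(
      bias_ug = rep$bland_altman$bias,
      loa = c(rep$bland_altman$loa_low, rep$bland_altman$loa_high),
      r_squared_all = rep$regression_all$r_squared,
      r_squared_no_outliers = rep$regression_no_outliers$r_squared,
      slope_all = rep$regression_all$slope)
  } else if (cfg$type == "detection_limit") {
    dl <- detection_limit(acq,
                          per_cell_load_pg = cfg$params$per_cell_load_pg,
                          k = cfg$detect_k,
                          n_replicates = cfg$params$n_replicates,
                          cell_grid = cfg$params$cell_grid,
                          seed = cfg$seed)
    utils::write.csv(dl$rates, file.path(out_dir, "tables", "detection_rates.csv"),
                     row.names = FALSE)
    summary_stats$detection_limit <- list(
      empirical_cells = dl$empirical_cells,
      analytic_cells = dl$analytic_cells,
      sigma_bg_mg_ml = dl$sigma_bg_mg_ml)
  }

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  report <- list(type = cfg$type,
                 config = unclass(cfg),
                 config_hash = .fnv1a(as.character(cfg_json)),
                 seed = cfg$seed,
                 versions = list(spcct = as.character(utils::packageVersion("spcct")),
                                 R = R.version.string),
                 elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 summary = summary_stats)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(out_dir, "report.json"))
  invisible(report)
}
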