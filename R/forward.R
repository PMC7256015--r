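# Multi-bin photon-counting acquisition: parallel-beam line integrals,
# polychromatic Beer-Lambert expected counts per energy bin, Poisson
# sampling, and blank scans.

#' Parallel-beam CT geometry
#'
#' 2D parallel-beam geometry with `n_views` evenly spaced over 180 degrees
#' and a linear detector whose pitch equals the reconstruction voxel size.
#' (The scanner's helical fan-beam geometry is replaced by parallel beam,
#' for which ramp-filtered back-projection is exact.)
#'
#' @param n_views Number of views over 180 degrees (default 360).
#' @param n_detectors Number of detector elements (default 384).
#' @param voxel_size_um Voxel size = detector pitch, um.
#' @return Object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_views = 360, n_detectors = 384,
                        voxel_size_um = 250) {
  if (n_views < 1 || n_detectors < 1) stop("empty geometry")
  structure(list(n_views = as.integer(n_views),
                 n_detectors = as.integer(n_detectors),
                 voxel_size_um = voxel_size_um,
                 angles = seq(0, pi, length.out = n_views + 1)[seq_len(n_views)]),
            class = "ct_geometry")
}

#' Project one material map into a line-integral sinogram
#'
#' Discrete Radon transform of a phantom concentration map: for each (view,
#' detector) ray, the path integral of mass density along the ray, in
#' g/cm^2. Linear in the phantom.
#'
#' @param phantom A [voxel_phantom()].
#' @param geometry A [ct_geometry()]; its voxel size must match the phantom.
#' @param material Map name (`"water"` is in g/mL; contrast maps in mg/mL).
#' @param step_frac Ray sampling step as a fraction of the voxel size.
#' @return Matrix `n_views x n_detectors` of line integrals, g/cm^2.
#' @export
project_material <- function(phantom, geometry, material, step_frac = 0.5) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(geometry, "ct_geometry"))
  if (abs(phantom$voxel_size_um - geometry$voxel_size_um) > 1e-9)
    stop("phantom and geometry voxel sizes differ")
  if (geometry$n_detectors < ceiling(sqrt(2) * phantom$n))
    warning("detector array does not cover the grid diagonal")
  m <- phantom_map(phantom, material)
  # g/mL == g/cm^3 for water; mg/mL -> 1e-3 g/cm^3 for contrast maps
  dens_scale <- if (material == "water") 1 else 1e-3
  vox_cm <- phantom$voxel_size_um * 1e-4
  p <- cpp_forward_project(m, geometry$angles, geometry$n_detectors,
                           pitch_vox = 1.0, step_vox = step_frac)
  p * vox_cm * dens_scale
}

#' Project all maps of a phantom
#'
#' @inheritParams project_material
#' @return Named list of sinogram matrices (g/cm^2), one per phantom map.
#' @export
project_phantom <- function(phantom, geometry, step_frac = 0.5) {
  sinos <- lapply(names(phantom$maps), function(nm)
    project_material(phantom, geometry, nm, step_frac))
  names(sinos) <- names(phantom$maps)
  sinos
}

# flux-scaled spectral bin weights: W[e,b] with sum(W) = flux, so that
# blank_b = colSums(W)
.bin_weights <- function(spectrum, bins, flux) {
  R <- bin_response_matrix(bins, spectrum$grid)
  W <- spectrum$fluence * R
  if (sum(W) <= 0) stop("no fluence inside the detector bins")
  W * flux / sum(W)
}

# E x M mass attenuation matrix on the spectrum grid
.mu_matrix <- function(spectrum, materials, tables = NULL) {
  e <- as.numeric(spectrum$grid)
  mu <- vapply(materials, function(m) {
    tb <- if (!is.null(tables) && !is.null(tables[[m]])) tables[[m]]
          else attenuation_table(m)
    mass_attenuation_at(tb, e)
  }, numeric(length(e)))
  colnames(mu) <- materials
  mu
}

#' Blank-scan expected counts per bin
#'
#' Expected photon counts with no object in the beam, per detector element
#' and energy bin. Flux is uniform across detector elements (no bowtie
#' filter), so the blank is a single vector of per-bin counts.
#'
#' @param spectrum A [build_source_spectrum()].
#' @param bins An [energy_bin_set()].
#' @param flux Total expected counts per detector element summed over bins.
#' @return Named numeric vector of per-bin blank counts.
#' @export
blank_counts <- function(spectrum, bins, flux) {
  W <- .bin_weights(spectrum, bins, flux)
  b <- colSums(W)
  names(b) <- paste0("bin", seq_along(b))
  b
}

#' Expected counts per energy bin for material line integrals
#'
#' Polychromatic Beer-Lambert model: for each ray,
#' `lambda_b = sum_E S(E) R_b(E) exp(-sum_m (mu/rho)_m(E) A_m)`, scaled so
#' the no-object value equals the blank. Strictly decreasing in every `A_m`
#' and bounded above by the blank.
#'
#' @param A Named list of line-integral matrices (g/cm^2), one per material;
#'   all the same dimension.
#' @param spectrum A [build_source_spectrum()].
#' @param bins An [energy_bin_set()].
#' @param flux Blank counts per detector element summed over bins.
#' @param tables Optional named list of [attenuation_table()]s overriding
#'   the embedded ones.
#' @return 3D array `n_views x n_detectors x n_bins` of expected counts.
#' @export
expected_counts <- function(A, spectrum, bins, flux, tables = NULL) {
  stopifnot(is.list(A), length(A) >= 1)
  if (any(vapply(A, function(a) any(a < -1e-12), TRUE)))
    stop("negative line integrals")
  dims <- dim(A[[1]])
  mu <- .mu_matrix(spectrum, names(A), tables)
  W <- .bin_weights(spectrum, bins, flux)
  nray <- prod(dims)
  Amat <- vapply(A, as.numeric, numeric(nray))      # rays x materials
  if (is.null(dim(Amat))) Amat <- matrix(Amat, nrow = nray)
  B <- bins$n_bins
  lam <- matrix(0, nray, B)
  chunk <- 20000L
  for (st in seq(1L, nray, by = chunk)) {
    en <- min(st + chunk - 1L, nray)
    Tr <- exp(-Amat[st:en, , drop = FALSE] %*% t(mu))  # rays x E transmission
    lam[st:en, ] <- Tr %*% W
  }
  array(lam, dim = c(dims, B))
}

#' Poisson photon-count sampling
#'
#' Independent Poisson draws around the expected counts; reproducible given
#' the seed.
#'
#' @param lambda Array of expected counts (any shape).
#' @param seed Integer seed.
#' @return Integer-valued array of counts, same shape as `lambda`.
#' @export
sample_poisson <- function(lambda, seed) {
  if (any(lambda < 0)) stop("expected counts must be >= 0")
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  counts <- stats::rpois(length(lambda), as.numeric(lambda))
  array(counts, dim = dim(lambda))
}

#' Acquisition configuration
#'
#' Bundles the source, detector binning, flux and geometry of one SPCCT
#' acquisition. Defaults reproduce the study settings: 120 kVp, thresholds
#' 30/53/78/83/98 keV, 250 um voxels; the default flux is calibrated so the
#' reconstructed gold-map background SD is ~10 mg/mL (tube current and
#' exposure time are absorbed into this single scalar).
#'
#' @param kvp Tube voltage (80, 100, 120).
#' @param filtration_mm_al Aluminum filtration, mm.
#' @param thresholds_kev Detector thresholds, keV.
#' @param flux Blank counts per detector element (summed over bins).
#' @param n_views,n_detectors Geometry, see [ct_geometry()].
#' @param n,voxel_size_um Reconstruction/phantom grid.
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(kvp = 120, filtration_mm_al = 2.5,
                               thresholds_kev = c(30, 53, 78, 83, 98),
                               flux = spcct_default_flux(),
                               n_views = 360, n_detectors = 384,
                               n = 256, voxel_size_um = 250) {
  spectrum <- build_source_spectrum(kvp, filtration_mm_al)
  bins <- energy_bin_set(thresholds_kev, upper_kev = kvp)
  structure(list(kvp = kvp, filtration_mm_al = filtration_mm_al,
                 spectrum = spectrum, bins = bins, flux = flux,
                 geometry = ct_geometry(n_views, n_detectors, voxel_size_um),
                 n = as.integer(n), voxel_size_um = voxel_size_um),
            class = "acquisition_config")
}

#' Default calibrated flux
#'
#' Blank counts per detector element (summed over the five bins) calibrated
#' once, with `scripts/calibrate_flux.R`, so that the reconstructed gold-map
#' background SD in a water object at the default geometry is ~10 mg/mL.
#'
#' @return Numeric scalar.
#' @export
spcct_default_flux <- function() 12000

#' Simulate one multi-bin acquisition of a phantom
#'
#' Projects every phantom map, evaluates the polychromatic expected counts
#' per bin, and draws Poisson counts.
#'
#' @param phantom A [voxel_phantom()].
#' @param config An [acquisition_config()].
#' @param seed Integer seed for the Poisson draw; with `seed = NULL` the
#'   acquisition is noiseless (expected counts returned unsampled).
#' @param noiseless If `TRUE`, return expected counts without Poisson noise.
#' @return Object of class `count_sinogram`: list with `counts` (array
#'   `n_views x n_detectors x n_bins`), `blank` (per-bin vector), `bins`,
#'   `geometry`, `spectrum`, `flux`, `seed`.
#' @export
acquire <- function(phantom, config = acquisition_config(), seed = NULL,
                    noiseless = is.null(seed)) {
  stopifnot(inherits(config, "acquisition_config"))
  A <- project_phantom(phantom, config$geometry)
  lam <- expected_counts(A, config$spectrum, config$bins, config$flux)
  counts <- if (noiseless) lam else sample_poisson(lam, seed)
  structure(list(counts = counts,
                 blank = blank_counts(config$spectrum, config$bins, config$flux),
                 bins = config$bins, geometry = config$geometry,
                 spectrum = config$spectrum, flux = config$flux,
                 seed = if (noiseless) NA_integer_ else seed,
                 noiseless = noiseless),
            class = "count_sinogram")
}

#' @export
print.count_sinogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<count_sinogram> %d views x %d detectors x %d bins (%s)\n",
              d[1], d[2], d[3],
              if (isTRUE(x$noiseless)) "noiseless" else sprintf("seed %s", x$seed)))
  invisible(x)
}
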