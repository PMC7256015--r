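# Step 2 of the image chain: filtered back-projection of material and
# conventional sinograms into images.

# ramp-filter a sinogram (views x detectors): zero-pad to the next power of
# two, multiply the FFT by |freq| (cycles/cm, optional Hann apodization),
# inverse FFT. Returns the filtered sinogram in (input units)/cm.
.filter_sinogram <- function(sino, pitch_cm, filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  nd <- ncol(sino)
  npad <- 2^ceiling(log2(2 * nd))
  freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * pitch_cm)
  resp <- abs(freq)
  if (filter == "hann") {
    nyq <- 1 / (2 * pitch_cm)
    resp <- resp * 0.5 * (1 + cos(pi * freq / nyq))
  }
  padded <- cbind(sino, matrix(0, nrow(sino), npad - nd))
  ft <- t(stats::mvfft(t(padded)))
  filt <- Re(t(stats::mvfft(t(ft * rep(resp, each = nrow(sino))),
                            inverse = TRUE))) / npad
  filt[, seq_len(nd), drop = FALSE]
}

#' Filtered back-projection
#'
#' Reconstructs a parallel-beam sinogram by ramp-filtered back-projection
#' (Ram-Lak filter; optional Hann apodization), zero-padding to the next
#' power of two and linear interpolation during back-projection. A linear
#' operator: line integrals in g/cm^2 reconstruct to densities in g/cm^3.
#'
#' @param sino Matrix `n_views x n_detectors` (line integrals).
#' @param geometry The [ct_geometry()] of the sinogram.
#' @param n Output grid side, voxels.
#' @param filter `"ramp"` (default) or `"hann"`.
#' @return `n x n` matrix in (input units)/cm.
#' @export
fbp <- function(sino, geometry, n, filter = c("ramp", "hann")) {
  stopifnot(inherits(geometry, "ct_geometry"))
  if (nrow(sino) != geometry$n_views || ncol(sino) != geometry$n_detectors)
    stop("sinogram dimensions do not match the geometry")
  if (geometry$n_views < 2) stop("need at least 2 views")
  pitch_cm <- geometry$voxel_size_um * 1e-4
  filt <- .filter_sinogram(sino, pitch_cm, filter)
  cpp_back_project(filt, geometry$angles, as.integer(n), pitch_vox = 1.0)
}

#' Reconstruct material sinograms into concentration maps
#'
#' Applies [fbp()] to every basis-material sinogram; g/cm^2 line integrals
#' become g/cm^3 densities, reported in mg/mL (so the water map reads
#' ~1000 mg/mL in water).
#'
#' @param msino A `material_sinogram` from [decompose_sinogram()].
#' @param n Output grid side, voxels.
#' @param filter FBP filter.
#' @return Object of class `material_image`: list with `maps` (named list
#'   of `n x n` mg/mL matrices), `voxel_size_um`, `basis`.
#' @export
reconstruct_materials <- function(msino, n, filter = c("ramp", "hann")) {
  stopifnot(inherits(msino, "material_sinogram"))
  maps <- lapply(msino$A, function(a)
    fbp(a, msino$geometry, n, filter) * 1000)   # g/cm^3 -> mg/mL
  structure(list(maps = maps, voxel_size_um = msino$geometry$voxel_size_um,
                 basis = msino$basis),
            class = "material_image")
}

#' @export
print.material_image <- function(x, ...) {
  cat(sprintf("<material_image> %s; %d x %d voxels @ %g um (mg/mL)\n",
              paste(x$basis, collapse = "/"),
              nrow(x$maps[[1]]), ncol(x$maps[[1]]), x$voxel_size_um))
  invisible(x)
}

#' Effective linear attenuation of water under the full beam
#'
#' Fluence-weighted mean of the water mass attenuation coefficient over the
#' detected part of the spectrum (all bins), times 1 g/cm^3. Fixes the
#' polychromatic Hounsfield convention of this implementation.
#'
#' @param spectrum A [build_source_spectrum()].
#' @param bins An [energy_bin_set()].
#' @return Linear attenuation coefficient of water, 1/cm.
#' @export
mu_water_effective <- function(spectrum, bins = energy_bin_set()) {
  eff <- effective_attenuation(spectrum, bins, "water")
  W <- .bin_weights(spectrum, bins, 1)
  sum(eff * colSums(W)) / sum(W)    # bin-weighted mean, rho_water = 1 g/cm^3
}

#' Convert an attenuation image to Hounsfield units
#'
#' `HU = 1000 (mu - mu_water) / mu_water`; air maps to -1000 HU and water
#' to 0 HU.
#'
#' @param mu_image Linear attenuation image, 1/cm.
#' @param mu_water Reference water attenuation, 1/cm (see
#'   [mu_water_effective()]).
#' @return Object of class `conventional_image`: list with `hu` matrix and
#'   `voxel_size_um` if supplied via attribute.
#' @export
to_hounsfield <- function(mu_image, mu_water) {
  if (mu_water <= 0) stop("mu_water must be positive")
  1000 * (mu_image - mu_water) / mu_water
}

#' Reconstruct the conventional (HU) image from a count sinogram
#'
#' Chains [conventional_sinogram()], [fbp()] and [to_hounsfield()].
#'
#' @param sino A `count_sinogram`.
#' @param n Output grid side, voxels.
#' @param filter FBP filter.
#' @return `n x n` matrix in Hounsfield units.
#' @export
reconstruct_conventional <- function(sino, n, filter = c("ramp", "hann")) {
  p <- conventional_sinogram(sino)
  mu <- fbp(p, sino$geometry, n, filter)
  to_hounsfield(mu, mu_water_effective(sino$spectrum, sino$bins))
}
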