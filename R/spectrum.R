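# Polychromatic source spectrum and energy-bin partition of the
# photon-counting detector.

#' Polychromatic X-ray source spectrum
#'
#' Kramers-shaped bremsstrahlung spectrum, `fluence(E) proportional to
#' (kVp - E)` for `E <= kVp`, hardened by an aluminum filtration layer
#' (`exp(-mu_Al(E) * rho_Al * d)`). Characteristic tungsten lines are
#' omitted; a measured tube spectrum can be loaded with
#' [read_source_spectrum()] instead. Fluence is on an arbitrary scale; the
#' acquisition flux parameter sets absolute counts.
#'
#' @param kvp Tube voltage in kVp: 80, 100 or 120.
#' @param filtration_mm_al Aluminum-equivalent filtration thickness, mm
#'   (default 2.5).
#' @param grid An [energy_grid()].
#' @return Object of class `source_spectrum`: list with `grid`, `fluence`
#'   (photons per keV per detector element, arbitrary scale) and `kvp`.
#' @export
#' @examples
#' s <- build_source_spectrum(120, 2.5)
#' mean_energy(s)
build_source_spectrum <- function(kvp = 120, filtration_mm_al = 2.5,
                                  grid = energy_grid(max_kev = kvp)) {
  if (!kvp %in% c(80, 100, 120))
    stop("tube voltage must be one of 80, 100 or 120 kVp")
  if (filtration_mm_al < 0) stop("filtration must be >= 0 mm Al")
  if (max(grid) < kvp) stop("energy grid must extend up to the tube voltage")
  e <- as.numeric(grid)
  fl <- pmax(kvp - e, 0)
  if (filtration_mm_al > 0) {
    al <- attenuation_table("aluminum")
    rho_al <- 2.699                      # g/cm^3
    d_cm <- filtration_mm_al / 10
    fl <- fl * exp(-mass_attenuation_at(al, e) * rho_al * d_cm)
  }
  if (sum(fl) <= 0) stop("total fluence must be positive")
  structure(list(grid = grid, fluence = fl, kvp = kvp),
            class = "source_spectrum")
}

#' Load a tabulated source spectrum from a text file
#'
#' Two-column whitespace-delimited text (keV, relative fluence), `#`
#' comments; interpolated linearly onto `grid` and truncated at `kvp`.
#'
#' @param path File path.
#' @param kvp Tube voltage, keV.
#' @param grid An [energy_grid()].
#' @return A `source_spectrum`.
#' @export
read_source_spectrum <- function(path, kvp = 120, grid = energy_grid(max_kev = kvp)) {
  tab <- read_energy_table(path)
  e <- as.numeric(grid)
  fl <- stats::approx(tab$energy, tab$value, xout = e, rule = 2)$y
  fl[e > kvp] <- 0
  fl <- pmax(fl, 0)
  if (sum(fl) <= 0) stop("total fluence must be positive")
  structure(list(grid = grid, fluence = fl, kvp = kvp),
            class = "source_spectrum")
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param spectrum A `source_spectrum`.
#' @return Mean energy, keV.
#' @export
mean_energy <- function(spectrum) {
  e <- as.numeric(spectrum$grid)
  sum(e * spectrum$fluence) / sum(spectrum$fluence)
}

#' Detector energy-bin set
#'
#' The photon-counting detector sorts photons into contiguous half-open
#' energy bins `[t_i, t_{i+1})` defined by ascending thresholds, the last
#' bin closed at the tube voltage. The scanner default is five thresholds at
#' 30, 53, 78, 83 and 98 keV under a 120 kVp beam. Photons below the first
#' threshold are not counted. The bin response is an ideal rectangular
#' indicator.
#'
#' @param thresholds_kev Ascending bin thresholds, keV.
#' @param upper_kev Upper bound of the last bin (= kVp).
#' @return Object of class `energy_bins`.
#' @export
#' @examples
#' b <- energy_bin_set()
#' b$n_bins
energy_bin_set <- function(thresholds_kev = c(30, 53, 78, 83, 98),
                           upper_kev = 120) {
  if (length(thresholds_kev) < 1 || any(diff(thresholds_kev) <= 0))
    stop("thresholds must be strictly ascending")
  if (upper_kev <= max(thresholds_kev))
    stop("upper bound must exceed the last threshold")
  structure(list(thresholds = thresholds_kev, upper = upper_kev,
                 n_bins = length(thresholds_kev)),
            class = "energy_bins")
}

#' Bin response matrix on an energy grid
#'
#' Indicator matrix R with `R[e, b] = 1` when grid energy `e` falls in bin
#' `b`. Rows sum to 1 inside `[t1, upper]` and to 0 below `t1`.
#'
#' @param bins An [energy_bin_set()].
#' @param grid An [energy_grid()].
#' @return Matrix `length(grid) x n_bins`.
#' @export
bin_response_matrix <- function(bins, grid) {
  e <- as.numeric(grid)
  edges <- c(bins$thresholds, bins$upper)
  R <- matrix(0, length(e), bins$n_bins)
  for (b in seq_len(bins$n_bins)) {
    if (b < bins$n_bins) {
      R[, b] <- as.numeric(e >= edges[b] & e < edges[b + 1])
    } else {
      R[, b] <- as.numeric(e >= edges[b] & e <= edges[b + 1])
    }
  }
  R
}
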