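# Voxelized digital phantoms: calibration tube series, labeled-cell pellets,
# and a brain-like axial slice with lesion, skull, cell cluster and scaffold.

#' Voxel phantom container
#'
#' A 2D axial slice of per-material concentration maps on an isotropic voxel
#' grid. Contrast materials (gold, iodine, gadolinium, calcium) are stored in
#' mg/mL; the water-equivalent density map is in g/mL. The default grid is
#' 256 x 256 voxels at 250 um (64 mm field of view), rat-head sized.
#'
#' @param n Grid side length in voxels.
#' @param voxel_size_um Isotropic voxel size, um (default 250).
#' @return Object of class `voxel_phantom` with fields `n`, `voxel_size_um`
#'   and `maps` (named list of `n x n` matrices; `water` always present).
#' @export
voxel_phantom <- function(n = 256, voxel_size_um = 250) {
  if (voxel_size_um <= 0) stop("voxel size must be positive")
  structure(list(n = as.integer(n), voxel_size_um = voxel_size_um,
                 maps = list(water = matrix(0, n, n))),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %dx%d voxels @ %g um; maps: %s\n",
              x$n, x$n, x$voxel_size_um,
              paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

#' Voxel volume of a phantom
#'
#' @param phantom A [voxel_phantom()].
#' @return Volume of one voxel in uL (e.g. 1.5625e-2 uL at 250 um, using the
#'   in-plane voxel as a one-voxel-thick slab).
#' @export
voxel_volume_ul <- function(phantom) {
  (phantom$voxel_size_um * 1e-4)^3 * 1e3   # cm^3 -> mL -> uL
}

#' Concentration map for a material (zeros if absent)
#'
#' @param phantom A [voxel_phantom()].
#' @param material Map name.
#' @return `n x n` matrix.
#' @export
phantom_map <- function(phantom, material) {
  m <- phantom$maps[[material]]
  if (is.null(m)) m <- matrix(0, phantom$n, phantom$n)
  m
}

#' Total elemental mass in a phantom map
#'
#' Sum of concentration times voxel volume over the grid.
#'
#' @param phantom A [voxel_phantom()].
#' @param material Contrast map name (mg/mL maps).
#' @return Mass in ug.
#' @export
material_mass_ug <- function(phantom, material) {
  sum(phantom_map(phantom, material)) * voxel_volume_ul(phantom)
}

# center-of-voxel coordinates (voxel units, origin at grid centre)
.grid_coords <- function(n) {
  idx <- seq_len(n) - (n + 1) / 2
  list(x = matrix(idx, n, n, byrow = TRUE), y = matrix(idx, n, n))
}

# disk mask by center-of-voxel rule
.disk_mask <- function(n, radius_vox, cx = 0, cy = 0) {
  g <- .grid_coords(n)
  (g$x - cx)^2 + (g$y - cy)^2 <= radius_vox^2
}

# mask of exactly n_vox voxels nearest (cx, cy): a rasterized disk whose
# voxel count (hence volume) is exact; ties broken deterministically by index
.nearest_mask <- function(n, n_vox, cx = 0, cy = 0) {
  g <- .grid_coords(n)
  d2 <- (g$x - cx)^2 + (g$y - cy)^2
  ord <- order(d2, seq_along(d2))
  m <- matrix(FALSE, n, n)
  m[ord[seq_len(n_vox)]] <- TRUE
  m
}

.check_phantom <- function(p) {
  for (nm in names(p$maps)) {
    if (any(!is.finite(p$maps[[nm]])) || any(p$maps[[nm]] < 0))
      stop("phantom maps must be finite and nonnegative")
  }
  if (any(p$maps$water > 1.2)) stop("water density must not exceed 1.2 g/mL")
  p
}

#' Build a calibration tube series
#'
#' One phantom per molar concentration: a contrast-doped water-equivalent
#' gel tube (agarose ~ water density 1.0) of the given diameter centred in
#' an air background, mimicking Eppendorf calibration tubes. The scanner
#' series is 0, 10, 15, 20, 30, 40 mM for gold and 0, 10, 15, 20, 30, 40,
#' 60 mM for iodine (0--8 mg/mL for each element).
#'
#' @param concentrations_mM Molar concentrations, mM (>= 0).
#' @param element `"gold"`, `"iodine"` or `"gadolinium"`.
#' @param tube_diameter_mm Tube inner diameter, mm.
#' @param n,voxel_size_um Grid parameters, see [voxel_phantom()].
#' @return List of [voxel_phantom()] objects, one per concentration.
#' @export
#' @examples
#' ph <- build_calibration_series(c(0, 40), "gold", 8)
#' max(ph[[2]]$maps$gold)  # 7.879 mg/mL
build_calibration_series <- function(concentrations_mM, element,
                                     tube_diameter_mm = 8,
                                     n = 256, voxel_size_um = 250) {
  if (any(concentrations_mM < 0)) stop("concentrations must be >= 0")
  r_vox <- (tube_diameter_mm / 2) / (voxel_size_um / 1000)
  if (2 * r_vox > n) stop("tube larger than the voxel grid")
  mass_conc <- molar_to_mass_concentration(concentrations_mM, element)
  lapply(mass_conc, function(cc) {
    p <- voxel_phantom(n, voxel_size_um)
    tube <- .disk_mask(n, r_vox)
    p$maps$water[tube] <- 1.0
    m <- matrix(0, n, n)
    m[tube] <- cc
    p$maps[[element]] <- m
    .check_phantom(p)
  })
}

#' Build a labeled-cell pellet phantom
#'
#' A pellet of gold-labeled cells at the bottom of a water-filled tube. The
#' pellet occupies `cell_count * packing_volume_per_cell` (default 2.8 pL
#' per cell, so 1e6 cells occupy 2.8 uL) rasterized as
#' `ceiling(volume / voxel volume)` voxels; the uniform gold concentration
#' is set so the total gold mass equals exactly
#' `cell_count * per_cell_load` (~45.7 mg/mL at the defaults).
#'
#' @param cell_count Number of cells (>= 0).
#' @param per_cell_load_pg Gold load per cell, pg (default 128).
#' @param packing_volume_per_cell_pl Packed volume per cell, pL (default 2.8).
#' @param tube_diameter_mm Tube inner diameter, mm.
#' @param n,voxel_size_um Grid parameters.
#' @return A [voxel_phantom()] with attribute `"pellet_mask"` (logical
#'   ground-truth pellet mask) and `"true_gold_ug"`.
#' @export
#' @examples
#' p <- build_pellet(1e6)
#' material_mass_ug(p, "gold")  # 128 ug
build_pellet <- function(cell_count, per_cell_load_pg = 128,
                         packing_volume_per_cell_pl = 2.8,
                         tube_diameter_mm = 8,
                         n = 256, voxel_size_um = 250) {
  if (cell_count < 0) stop("cell_count must be >= 0")
  if (per_cell_load_pg <= 0) stop("per-cell load must be positive")
  p <- voxel_phantom(n, voxel_size_um)
  r_vox <- (tube_diameter_mm / 2) / (voxel_size_um / 1000)
  if (2 * r_vox > n) stop("tube larger than the voxel grid")
  tube <- .disk_mask(n, r_vox)
  p$maps$water[tube] <- 1.0
  vvol <- voxel_volume_ul(p)
  pellet_vol_ul <- cell_count * packing_volume_per_cell_pl * 1e-6
  tube_vol_ul <- sum(tube) * vvol
  if (pellet_vol_ul > tube_vol_ul) stop("pellet volume exceeds tube volume")
  mask <- matrix(FALSE, n, n)
  gold <- matrix(0, n, n)
  true_gold_ug <- cell_count * per_cell_load_pg * 1e-6
  if (cell_count > 0) {
    n_vox <- ceiling(pellet_vol_ul / vvol)
    mask <- .nearest_mask(n, n_vox)
    gold[mask] <- true_gold_ug / (n_vox * vvol)   # mg/mL; conserves mass
  }
  p$maps$gold <- gold
  p <- .check_phantom(p)
  attr(p, "pellet_mask") <- mask
  attr(p, "true_gold_ug") <- true_gold_ug
  p
}

#' Build a brain-like axial slice phantom
#'
#' Elliptical head cross-section of water-equivalent tissue, optional
#' calcium skull annulus (150 mg/mL, 2 voxels thick), a lesion cavity, a
#' gold-labeled cell cluster of the requested volume and mass inside the
#' lesion, and an overlapping iodine-labeled scaffold region. Region voxel
#' counts are `ceiling(volume / voxel volume)`; uniform concentrations are
#' set so that the total masses are conserved exactly.
#'
#' @param cell_gold_ug Total gold mass in the cell cluster, ug.
#' @param cell_volume_ul Cell cluster volume, uL.
#' @param scaffold_iodine_ug Total iodine mass in the scaffold, ug.
#' @param scaffold_volume_ul Scaffold volume, uL.
#' @param skull Add the calcium skull annulus?
#' @param skull_ca_mg_ml Calcium concentration in the skull, mg/mL.
#' @param n,voxel_size_um Grid parameters.
#' @return A [voxel_phantom()] with attributes `"cell_mask"`,
#'   `"scaffold_mask"`, `"skull_mask"`, `"lesion_mask"`.
#' @export
build_brain_slice <- function(cell_gold_ug = 64, cell_volume_ul = 1.4,
                              scaffold_iodine_ug = 0, scaffold_volume_ul = 0,
                              skull = TRUE, skull_ca_mg_ml = 150,
                              n = 256, voxel_size_um = 250) {
  if ((cell_gold_ug > 0 && cell_volume_ul <= 0) ||
      (scaffold_iodine_ug > 0 && scaffold_volume_ul <= 0))
    stop("a region with positive mass needs a positive volume")
  p <- voxel_phantom(n, voxel_size_um)
  vvol <- voxel_volume_ul(p)
  mm_vox <- 1 / (voxel_size_um / 1000)            # voxels per mm
  g <- .grid_coords(n)
  # head: ellipse semi-axes 14 x 12 mm
  a <- 14 * mm_vox; b <- 12 * mm_vox
  head <- (g$x / a)^2 + (g$y / b)^2 <= 1
  p$maps$water[head] <- 1.0
  # skull: 2-voxel annulus just inside the head boundary
  skull_mask <- matrix(FALSE, n, n)
  if (skull) {
    dv <- 2 / mm_vox                               # 2 voxels in mm
    inner <- (g$x / (a - 2))^2 + (g$y / (b - 2))^2 <= 1
    skull_mask <- head & !inner
    ca <- matrix(0, n, n)
    ca[skull_mask] <- skull_ca_mg_ml
    p$maps$calcium <- ca
  }
  # lesion cavity: 2.5 mm radius disk in the right hemisphere (water-filled)
  lesion_cx <- 5 * mm_vox
  lesion <- .disk_mask(n, 2.5 * mm_vox, cx = lesion_cx, cy = 0)
  cap <- sum(lesion) * vvol
  if (cell_volume_ul > cap || scaffold_volume_ul > cap)
    stop("requested volume exceeds the lesion cavity capacity")
  cell_mask <- matrix(FALSE, n, n)
  if (cell_volume_ul > 0) {
    n_vox <- ceiling(cell_volume_ul / vvol)
    cell_mask <- .nearest_mask(n, n_vox, cx = lesion_cx, cy = 0)
    gold <- matrix(0, n, n)
    gold[cell_mask] <- cell_gold_ug / (n_vox * vvol)
    p$maps$gold <- gold
  }
  scaffold_mask <- matrix(FALSE, n, n)
  if (scaffold_volume_ul > 0) {
    n_vox <- ceiling(scaffold_volume_ul / vvol)
    # scaffold surrounds/overlaps the cell cluster within the lesion
    scaffold_mask <- .nearest_mask(n, n_vox, cx = lesion_cx, cy = 0)
    iod <- matrix(0, n, n)
    iod[scaffold_mask] <- scaffold_iodine_ug / (n_vox * vvol)
    p$maps$iodine <- iod
  }
  p <- .check_phantom(p)
  attr(p, "cell_mask") <- cell_mask
  attr(p, "scaffold_mask") <- scaffold_mask
  attr(p, "skull_mask") <- skull_mask
  attr(p, "lesion_mask") <- lesion
  p
}

#' Write a phantom to a multi-channel NIfTI file
#'
#' One volume per material map, stacked along the fourth dimension in the
#' order of `names(phantom$maps)`; voxel size recorded in the header.
#'
#' @param phantom A [voxel_phantom()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return Invisibly, the map names written.
#' @export
write_phantom_nifti <- function(phantom, path) {
  arr <- array(0, dim = c(phantom$n, phantom$n, 1, length(phantom$maps)))
  for (i in seq_along(phantom$maps)) arr[, , 1, i] <- phantom$maps[[i]]
  vs <- phantom$voxel_size_um / 1000
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vs, vs, vs, 1)
  RNifti::writeNifti(img, path)
  invisible(names(phantom$maps))
}
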