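# Shared fixtures: desk-scale geometries and phantoms built in code.

# small acquisition for fast pipeline tests: 16 mm field at 250 um
small_config <- function(flux = spcct_default_flux(), n = 64,
                         n_views = 60, n_detectors = 96,
                         voxel_size_um = 250) {
  acquisition_config(flux = flux, n_views = n_views,
                     n_detectors = n_detectors, n = n,
                     voxel_size_um = voxel_size_um)
}

# water disk phantom (diameter in voxels) with optional central contrast disk
disk_phantom <- function(n = 64, water_radius_vox = 24,
                         contrast = NULL, contrast_mg_ml = 4,
                         contrast_radius_vox = 6, voxel_size_um = 250,
                         cx = 0, cy = 0) {
  ph <- voxel_phantom(n, voxel_size_um)
  ph$maps$water[spcct:::.disk_mask(n, water_radius_vox)] <- 1.0
  if (!is.null(contrast)) {
    m <- matrix(0, n, n)
    m[spcct:::.disk_mask(n, contrast_radius_vox, cx = cx, cy = cy)] <- contrast_mg_ml
    ph$maps[[contrast]] <- m
  }
  ph
}

# independent polychromatic expected-count oracle: direct sum over the grid,
# written against the model formula rather than the package internals
oracle_expected_counts <- function(A_list, spectrum, bins, flux) {
  e <- as.numeric(spectrum$grid)
  edges <- c(bins$thresholds, bins$upper)
  mu <- sapply(names(A_list), function(m)
    mass_attenuation_at(attenuation_table(m), e))
  total <- Reduce(`+`, Map(function(a, m) a * mu[, m], A_list, names(A_list)))
  w <- spectrum$fluence
  inside <- e >= edges[1] & e <= bins$upper
  scale <- flux / sum(w[inside])
  vapply(seq_len(bins$n_bins), function(b) {
    sel <- if (b < bins$n_bins) e >= edges[b] & e < edges[b + 1]
           else e >= edges[b] & e <= edges[b + 1]
    sum(w[sel] * exp(-total[sel])) * scale
  }, 0)
}

# brute-force Poisson log-likelihood maximizer over a 2D (water, gold) grid,
# coarse-to-fine; the independent oracle for the ML decomposition. The
# refinement box shrinks slowly (factor 5) because the likelihood valley is
# long, narrow and diagonal: the coarse best lattice point can sit well away
# from the maximum along the valley.
grid_search_ml <- function(y, spectrum, bins, flux, basis = c("water", "gold"),
                           center = c(2.5, 0.005), halfwidth = c(2.5, 0.005),
                           nsteps = 41, levels = 5) {
  e <- as.numeric(spectrum$grid)
  mu <- sapply(basis, function(m) mass_attenuation_at(attenuation_table(m), e))
  W <- spcct:::.bin_weights(spectrum, bins, flux)
  loglik <- function(grid) {
    lam <- exp(-grid %*% t(mu)) %*% W
    rowSums(matrix(y, nrow(lam), length(y), byrow = TRUE) *
              log(pmax(lam, 1e-300))) - rowSums(lam)
  }
  level <- 1
  for (iter in 1:40) {
    g1 <- seq(center[1] - halfwidth[1], center[1] + halfwidth[1], length.out = nsteps)
    g2 <- seq(center[2] - halfwidth[2], center[2] + halfwidth[2], length.out = nsteps)
    grid <- as.matrix(expand.grid(g1, g2))
    center <- grid[which.max(loglik(grid)), ]
    # only shrink once the maximum is interior: the likelihood valley is
    # diagonal and the lattice best can drift to a box edge
    on_edge <- center[1] %in% range(g1) || center[2] %in% range(g2)
    if (!on_edge) {
      if (level == levels) break
      halfwidth <- halfwidth / 4
      level <- level + 1
    }
  }
  spacing <- 2 * halfwidth / (nsteps - 1)       # spacing of the finest grid
  list(A = center, resolution = spacing,
       loglik = loglik(matrix(center, 1)))
}
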