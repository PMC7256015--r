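#!/usr/bin/env Rscript
# Calibrates the default acquisition flux so that the reconstructed gold-map
# background SD in a 40 mm water cylinder (default geometry, physics-mode
# decomposition, ramp FBP) is ~10 mg/mL. The resulting value is frozen into
# spcct_default_flux(). Usage:
#   Rscript scripts/calibrate_flux.R [--target 10] [--seeds 3]

suppressMessages(library(spcct))

args <- commandArgs(trailingOnly = TRUE)
getopt <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else as.numeric(args[i + 1])
}
target <- getopt("--target", 10)   # mg/mL
nseeds <- getopt("--seeds", 3)

measure_sigma <- function(flux, seeds) {
  cfg <- acquisition_config(flux = flux)
  n <- cfg$n
  bg <- voxel_phantom(n, cfg$voxel_size_um)
  bg$maps$water[spcct:::.disk_mask(n, 80)] <- 1.0
  box <- background_box(n)
  sds <- vapply(seeds, function(s) {
    sino <- acquire(bg, cfg, seed = s)
    img <- reconstruct_materials(decompose_sinogram(sino), n)
    background_sd(img$maps$gold, box)
  }, 0)
  mean(sds)
}

# sigma ~ flux^(-1/2): one pilot measurement, one scaling step, one check
pilot_flux <- 30000
s0 <- measure_sigma(pilot_flux, seq_len(nseeds))
cat(sprintf("pilot: flux %d -> sigma %.3f mg/mL\n", pilot_flux, s0))
flux1 <- round(pilot_flux * (s0 / target)^2)
s1 <- measure_sigma(flux1, seq_len(nseeds) + 100)
cat(sprintf("calibrated: flux %d -> sigma %.3f mg/mL (target %.1f)\n",
            flux1, s1, target))
flux2 <- round(flux1 * (s1 / target)^2)
cat(sprintf("refined suggestion: flux %d\n", flux2))
cat("freeze this value in spcct_default_flux()\n")
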