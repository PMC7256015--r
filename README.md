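# spcct

Simulation and quantification for spectral photon-counting CT (SPCCT)
K-edge imaging of nanoparticle-labeled cells.

## The problem

Cell therapies for brain injury need a non-invasive way to verify that the
transplanted cells actually reached the lesion and to follow them over
weeks. Spectral photon-counting CT can do this: energy-resolving detectors
sort photons into bins delimited by programmable thresholds, and the
discontinuity in an element's photoelectric attenuation at its K-shell
binding energy (the K-edge: Au 80.7 keV, I 33.2 keV, Gd 50.2 keV) gives
each heavy element a spectral fingerprint. Decomposing the multi-bin
counts into basis materials turns one scan into element-specific
concentration maps, so gold-labeled therapeutic cells can be separated
from an iodine-labeled carrier scaffold and from skull — something a
conventional Hounsfield-unit image cannot do.

`spcct` implements the full computational chain of such a study as
reusable, tested R code:

* **physics** — embedded mass-attenuation tables with K-edge
  discontinuities, a filtered Kramers source spectrum, rectangular
  detector energy bins (defaults: 120 kVp, thresholds 30/53/78/83/98 keV);
* **phantoms** — calibration tube series (0–40 mM Au, 0–60 mM I, i.e.
  0–8 mg/mL), labeled-cell pellets (128 pg gold/cell, 2.8 pL/cell), and a
  brain-like slice with lesion, calcium skull, cell cluster and scaffold
  on a 250 µm grid;
* **forward model** — 2D parallel-beam line integrals, polychromatic
  Beer–Lambert expected counts per bin, Poisson noise, blank scans;
* **material decomposition** — per-ray maximum-likelihood fit of the
  Poisson bin counts (Newton iterations on the exact polychromatic
  likelihood), plus a calibration-fitted weighted-least-squares mode and a
  conventional total-attenuation sinogram;
* **reconstruction** — ramp/Hann filtered back-projection into mg/mL
  material maps and HU conventional images;
* **quantification** — 2σ ROI segmentation, gold mass = concentration ×
  ROI volume, cell number = mass / per-cell load, and analytic + empirical
  single-voxel detection limits;
* **cohorts & statistics** — longitudinal synthetic subjects with
  delivery variability and simulated ICP-OES ground truth, ordinary
  least-squares calibration regression and Bland–Altman agreement.

The statistic at the core of detectability is the Rose-type analytic limit

    N_min = k · σ_bg · V_voxel / m_cell

with `k = 4`, `σ_bg` the background SD of the gold map (≈10 mg/mL at the
calibrated default flux), `V_voxel = (250 µm)³ = 1.5625e-2 µL` and
`m_cell = 128 pg` of gold per cell — about 4.9 × 10³ cells in a single
voxel.

## Worked example

Simulate a pellet of 0.5 × 10⁶ gold-labeled cells (64 µg gold), scan it at
the default study settings, decompose, reconstruct and quantify:

```r
library(spcct)
cfg    <- acquisition_config()                 # 120 kVp, 5 bins, 250 um voxels
pellet <- build_pellet(cell_count = 5e5)       # 0.5e6 cells x 128 pg = 64 ug gold
sino   <- acquire(pellet, cfg, seed = 1)
msino  <- decompose_sinogram(sino)
img    <- reconstruct_materials(msino, n = cfg$n)
roi    <- segment_roi(img$maps$gold, background_box(cfg$n))
roi_mass(img$maps$gold, roi)
```

```
<count_sinogram> 360 views x 384 detectors x 5 bins (seed 1)
<material_sinogram> basis water/gold/iodine; 360 x 384 rays; mode physics; 100.0% converged
<material_image> water/gold/iodine; 256 x 256 voxels @ 250 um (mg/mL)
<quant_result> 93 voxels (1.453 uL), 41.98 mg/mL, 61.00 ug gold, ~476580 cells
```

The pellet truly contains 64 µg of gold in 1.41 µL at 45.5 mg/mL; the
K-edge image recovers 61.0 µg (−4.7%, within the ~10% quantification bias
expected at this noise level) and an estimated 4.8 × 10⁵ of the 5 × 10⁵
cells. The analytic detection limit at the calibrated noise floor is

```r
analytic_detection_limit(10)   # sigma_bg = 10 mg/mL, k = 4
#> [1] 4882.812
```

Packaged end-to-end experiments (calibration tube series, pellet series,
monocolor and bicolor longitudinal cohorts, detection-limit scan) are
available through `builtin_experiments()` / `run_experiment()`, which
write NIfTI images, CSV tables and a JSON report into a deterministic
artifact directory.

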