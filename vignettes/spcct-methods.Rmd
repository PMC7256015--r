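---
title: "Methods: simulating K-edge cell tracking with spectral photon-counting CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating K-edge cell tracking with spectral photon-counting CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, defaults and numerical choices behind
`spcct`. The package simulates a spectral photon-counting CT (SPCCT) study
of gold-nanoparticle-labeled therapeutic cells injected into a rat brain
lesion, optionally inside an iodine-labeled scaffold, and implements the
downstream analysis: basis-material decomposition, image reconstruction,
gold quantification, detection limits and method-agreement statistics.

## Attenuation physics

Each supported material (water, gold, iodine, gadolinium, calcium, plus
aluminum for source filtration) carries a mass attenuation table
$(\mu/\rho)(E)$ in cm²/g over 15–150 keV, stored as plain text under
`inst/extdata/attenuation/`. Queries interpolate log-log linearly and never
bridge a K-edge: the tables hold doubled sample points at $E_K \mp 0.01$
keV, and a query exactly at $E_K$ resolves to the above-edge value
(right-continuous tie-break, chosen for determinism).

The element tables are generated by `scripts/make_attenuation_tables.R`
from an analytic construction: the exact Klein–Nishina incoherent
cross-section per electron times $N_A Z/A$, plus a per-K-branch power law
$r_0 (E_0/E)^p$ for the photoelectric-plus-coherent part, anchored at
reference values from standard compilations (NIST XCOM). This guarantees
three properties the decomposition is sensitive to: monotone decrease
between edges, a physical Compton floor at high energy (a fitted table
that dips below it measurably distorts the calcium cross-talk discussed
below), and K-edge jump ratios above 2 (Au 4.2, I 5.8, Gd 5.0). The water
and aluminum tables are verbatim compilation rows. Accuracy is at the
few-percent level, which shifts only the package's own flux calibration,
not the structure of any result.

Molar-to-mass conversion uses atomic masses Au 196.97, I 126.90, Gd
157.25 g/mol, so the calibration series 0–40 mM gold and 0–60 mM iodine
both span 0–8 mg/mL.

## Source spectrum and detector bins

The tube spectrum is a Kramers-shaped bremsstrahlung,
$\Phi(E) \propto (\mathrm{kVp} - E)$, hardened by 2.5 mm aluminum; tungsten
characteristic lines are omitted and a measured spectrum can be loaded
from a two-column text file instead. Tube voltage is restricted to 80, 100
or 120 kVp (120 default). The photon-counting detector is ideal: five
rectangular bins on contiguous half-open intervals between the default
thresholds 30, 53, 78, 83, 98 keV, the last bin closed at kVp; photons
below 30 keV are not counted. Real spectral distortions (pile-up, charge
sharing, scatter) are out of scope.

## Phantoms and the voxel grid

Phantoms are 2D axial slices of per-material concentration maps on a
256 × 256 grid of 250 µm voxels (64 mm field — rat-head sized; the
scanner-scale 168 mm field would only add empty rays). A voxel is
$1.5625\times 10^{-2}$ µL. Regions are rasterized by the center-of-voxel
rule; pellet and cell-cluster regions select
$\lceil V / V_\mathrm{voxel} \rceil$ voxels nearest the region centre and
set the uniform concentration to (total mass)/(selected volume), so the
built-in mass bookkeeping is exact and the concentration deviates from
load/packing-volume only by the sub-percent rasterization of the volume.

Defaults tie the geometry to the study quantities: 128 pg gold per cell
and 2.8 pL packed volume per cell (so 10⁶ cells occupy 2.8 µL at
≈45.7 mg/mL); a brain slice with a 14 × 12 mm elliptical head, a 2.5 mm
radius lesion cavity 5 mm lateral of midline, a 2-voxel calcium skull
annulus at 150 mg/mL (bone density is a modeling choice — the value makes
the calcium cross-talk visible), a gold cell cluster of 1.4 µL and an
iodine scaffold region of 4.9 µL by default. Lesion/cluster/scaffold
shapes are disks; the source study does not constrain shapes beyond
injected volumes. Calibration tubes are water-equivalent gel cylinders in
air, matching tube-in-holder calibration scans.

## Forward model

Acquisition is 2D parallel-beam — 360 views over 180°, 384 detector
elements at the voxel pitch — rather than the scanner's helical fan beam;
ramp-filtered back-projection is exact in this geometry and keeps full
acquisitions to seconds. Line integrals are computed by sampling each ray
bilinearly at half-voxel steps (equivalent to rotate-and-sum), giving
$A_m$ in g/cm² per material. Expected counts per bin follow the
polychromatic Beer–Lambert model
$$\lambda_b = \sum_E S(E)\, R_b(E) \exp\!\Big(-\sum_m (\mu/\rho)_m(E)\, A_m\Big),$$
scaled so an unattenuated ray yields the blank counts; measurements are
independent Poisson draws. The blank flux is a single scalar (tube
current and exposure time only enter through it); the default, 12,000
counts per ray summed over bins, was calibrated once with
`scripts/calibrate_flux.R` so that the reconstructed gold map in a 40 mm
water cylinder has a background SD of ≈10 mg/mL — the noise level at
which the analytic detection limit reproduces the reported magnitude
(≈4.9 × 10³ cells/voxel). Flux is uniform across detectors (no bowtie).

## Material decomposition

Step one of the image chain turns each ray's five bin counts into
basis-material line integrals. In physics mode the package maximizes the
exact Poisson log-likelihood
$\ell(A) = \sum_b [y_b \ln \lambda_b(A) - \lambda_b(A)]$
(the $y \ln \lambda$ term is dropped for zero-count bins) by Newton
iterations with the analytic gradient and Hessian, step halving on
$\ell$, and a Fisher-scoring fallback when the Hessian is not usable. The
initializer is the weighted least-squares solution of the linearized
problem: per-bin log-transmission $-\ln(y_b/\mathrm{blank}_b)$ (counts
clamped at 0.5) regressed on spectrum-weighted per-bin effective
coefficients, weights $\max(y_b, 1)$. Convergence requires the gradient
below $10^{-8}(1 + \sum_b y_b)$ or a Newton step below $10^{-12}$
relative — the step criterion matters because near the optimum the
likelihood change falls below floating-point resolution of $\ell$ (scale
$\sim 10^5$) while the prescribed gradient tolerance is still finite. A
ray with zero counts in all bins is flagged non-convergent and reported
as $A = 0$. No nonnegativity constraint is applied: clamping negatives
would bias ROI sums upward in noise, so clamping is deferred to display.

Calibrated mode replaces the per-ray likelihood fit with the same
weighted least squares using coefficients fitted from calibration tube
scans (`fit_calibration()`, which requires at least two distinct
concentrations per material including zero). Both modes are provided
because the prototype's exact algorithm is proprietary; on noiseless
phantoms they agree within a few percent, which the test suite checks.

The default basis is water/gold/iodine. Calcium is deliberately not in
the basis: a skull then leaks into the iodine image — the well-known
iodine/calcium cross-talk of 3-material K-edge imaging, which the tests
reproduce. With the present tables and bins about a third of the
calcium excess (relative to the iodine leakage) also appears in the gold
sinogram; this ratio is hypersensitive to few-percent changes in the
calcium and contrast-element attenuation shapes, so its exact value
should not be over-interpreted. In reconstructed images at default noise
the skull stays below the gold map's noise floor.

## Reconstruction

Material and conventional sinograms are reconstructed by filtered
back-projection: zero-padding to the next power of two, a Ram-Lak $|f|$
frequency response (optional Hann apodization), inverse FFT, pixel-driven
back-projection with linear interpolation, and the $\pi/n_\mathrm{views}$
quadrature weight. Units propagate g/cm² → g/cm³, reported as mg/mL.
Conventional images use $p = -\ln(\sum_b y_b / \sum_b \mathrm{blank}_b)$
and $\mathrm{HU} = 1000\,(\mu - \mu_w)/\mu_w$ with $\mu_w$ the
fluence-weighted water attenuation over the detected spectrum. Because
$p$ is polychromatic, water reads slightly negative (beam hardening,
within ±30 HU at default noise); no hardening correction is applied, as
none is needed downstream.

## Quantification and detection limits

ROIs are segmented algorithmically (the study drew them manually): voxels
above $2\sigma_{bg}$ — with $\sigma_{bg}$ measured in a signal-free
background box — largest 8-connected component (EBImage), holes filled.
Gold mass is ROI concentration × ROI volume, negative voxels included;
cells = mass / (128 pg). At default flux the pellet pipeline recovers
masses within ~10%, an underestimation consistent in scale with the
in-vivo bias the approach shows against elemental analysis.

Two detection limits are reported for a single-voxel inclusion of N
labeled cells in a water cylinder:

* the **analytic** Rose-type limit $N = k\,\sigma_{bg} V/m_\mathrm{cell}$
  ($k = 4$), the N at which the *mean* inclusion signal equals the
  $4\sigma$ threshold — i.e. a 50% single-trial detection probability;
* the **empirical** limit: the smallest N on a grid (step 250) whose
  inclusion voxel exceeds $4\hat\sigma_{bg}$ in ≥95% of 20 seeded
  replicate acquisitions through the full chain.

The empirical limit necessarily exceeds the analytic one: reliability at
95% alone adds a factor $\approx (k + 1.645\,\sigma_c/\sigma_{bg})/k$,
and two discretization effects add more — a one-voxel inclusion projects
onto a matched-pitch detector as a two-pixel triangle aperture, so its
reconstructed peak recovers only ~0.7 of the true concentration, and the
on-axis voxel (the inclusion is placed at the rotation centre, on an
odd-sized grid so a voxel centre coincides with the axis and with a
detector sample at every view) receives no interpolation averaging and so
carries ~1.7× the background noise. Jointly these put the 95%-reliability
limit near 2–2.5× the analytic value; the acceptance script locates it
empirically. The scan reuses computation exactly: per replicate one full
background acquisition is decomposed, and for each N only the rays
crossing the inclusion voxel are redrawn and re-decomposed, with the
inclusion-voxel and background-box values obtained by per-pixel
back-projection of the re-filtered gold sinogram — numerically identical
to full-image FBP at those pixels.

## Synthetic cohorts

The longitudinal generator emulates the study designs: a monocolor arm
(13 animals, 0.5 × 10⁶ cells, imaging windows day 0–3 / 4–7 / 13–14, one
administration-failure animal) and a bicolor arm (9 animals at
0.5/0.25/0.125 × 10⁶ cells in iodine-labeled scaffold, windows day 1–2 /
4–6 / 12–14). Delivery efficiency is log-normal with median 0.75 and
$\sigma_{\log} = 0.3$, clipped to (0, 1] — calibrated so a 0.5 × 10⁶-cell
arm averages ≈48 µg delivered gold with ≥20% between-animal CV; failure
animals get efficiency 0.115 (≈7.4 µg). True gold is exactly constant
across timepoints (no proliferation, no label elimination — the
generator conserves gold, not cells, since imaging cannot distinguish
label release to resident macrophages from cell persistence). The
terminal ICP-OES measurement is truth times $(1 + 0.05\,Z)$, truncated at
zero; 5% CV is typical instrument precision and is configurable. Each
animal draws from its own substream keyed by (seed, index), so records do
not depend on generation order.

What the generator does **not** emulate: cell migration and shape change,
partial-volume mixtures at region boundaries, registration error between
timepoints, scanner drift between sessions, or any systematic
SPCCT-vs-ICP-OES bias beyond what the imaging chain itself produces.
Passing cohort-level tests therefore demonstrates internal consistency of
the pipeline, not agreement with any particular animal data.

## Statistics

`linreg()` is closed-form simple OLS with $R^2 = 1 - SS_{res}/SS_{tot}$
(defined as 0 for a flat response); `bland_altman()` uses differences
estimate − reference, the $n-1$ sample SD and 1.96 limits, the standard
convention. `agreement_report()` flags pairs outside the limits of
agreement and refits the regression without them, always reporting both
fits — mirroring, without endorsing, the post-hoc exclusion practice of
such studies.

## Problem sizes and test design

Unit tests run a 64 × 64 grid with 60 views and 96 detectors (seconds per
pipeline); full-default runs (256 × 256, 360 × 384) appear where the
quantity depends on the calibrated noise floor: segmentation accuracy,
pellet linearity and the detection-limit scan. Every stochastic test
fixes its seed. Independent oracles back the non-trivial operations: a
separately coded spectral sum for expected counts, a coarse-to-fine
brute-force likelihood lattice search for the per-ray ML decomposition
(with a likelihood-dominance check, since along the nearly flat
water–gold ridge lattice and continuum optima can differ by several
lattice spacings), hand-computed Bland–Altman values, and `stats::lm` as
a cross-check for the closed-form OLS.

## Known limitations

Ideal rectangular bin response and a Kramers spectrum stand in for the
unpublished detector response and tube spectrum; parallel-beam replaces
helical fan-beam; 2D slices replace volumetric coverage; no scatter,
pile-up or dose model; attenuation tables are analytic reconstructions
anchored to compilation values rather than full XCOM dumps; and the
calcium→gold leakage fraction is tabulation-sensitive as noted above.
These choices trade scanner fidelity for a fully specified, reproducible
desk-scale model of the method.
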