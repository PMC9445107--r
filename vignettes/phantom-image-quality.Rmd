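---
title: "Simulating and analysing NEMA body phantom PET images across nuclides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing NEMA body phantom PET images across nuclides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`nemaiq` emulates, in image space, what a digital PET/CT delivers when the
NEMA IEC body phantom is filled with ¹⁸F, ⁶⁸Ga or ⁶⁴Cu, and implements the
metric suite used to compare such acquisitions. The chain is deliberately
simple and fully documented:

1. **Ground truth.** `rasterize_phantom()` produces a partial-volume-exact
   voxelization of the phantom: six spheres (10, 13, 17, 22, 28, 37 mm) on
   a 114.4-mm-diameter ring in one transaxial plane, cold 1-mm glass
   walls, a cold 50-mm lung-insert cylinder through the phantom axis, and
   a torso-shaped (stadium cross-section, 300 × 230 mm) background
   compartment at 5.3 kBq/mL. Voxels cut by an interface are resolved by
   supersampled subvoxel classification (default 4³ points), which keeps
   the rasterized sphere volumes within 0.05 % of the analytic value.
2. **Degradation.** `degrade_image()` applies an isotropic Gaussian PSF
   with `σ² = σ_system² + σ_positron²`, optionally an unsharp mask
   (edge-overshoot mimic of resolution-modelling reconstruction), then
   independent Poisson count noise whose expected total equals the target
   number of true coincidences.
3. **Analysis.** Background-corrected 50 % isocontour segmentation,
   recovery coefficients, CRC, CNR, CoV, lung count error
   (`segment_sphere()`, `recovery_coefficients()`, `contrast_recovery()`,
   `contrast_noise_ratio()`, `place_background_vois()`,
   `lung_count_error()`), and a sphere-profile resolution fit
   (`fit_resolution()`).

No sinogram or iterative-reconstruction model is involved: the analysis
consumes reconstructed images, and the resolution estimator explicitly
assumes a Gaussian PSF, so modelling the image-domain consequences is the
consistent level of abstraction.

## The positron-range kernel

The annihilation-point displacement is modelled as an isotropic Gaussian
whose half-width at half maximum equals the nuclide's mean positron range
in water: `σ = range_mean / √(2 ln 2)` (`positron_blur_sigma()`). Two
things are worth being explicit about:

- The real displacement distribution is cusp-like (roughly
  bi-exponential): narrow core, long tails. A Gaussian with HWHM = mean
  range therefore *overstates* the width of the core for a long-range
  emitter. Simulated ⁶⁸Ga images here show a fitted FWHM near 8.3 mm,
  whereas scanner measurements put ⁶⁸Ga around 5.3 mm — the direction and
  ordering across nuclides are reproduced, the absolute ⁶⁸Ga broadening
  is exaggerated. Only directional claims are made for cross-nuclide
  simulation comparisons.
- A Gaussian composes in quadrature with the Gaussian system PSF, which
  is exactly what the resolution estimator fits; the kernel-model
  argument is an enum so a cusp-like kernel can be added without touching
  the composition logic.

The system PSF defaults to 4.4 mm FWHM, chosen a priori so that the
simulated ¹⁸F chain (system ⊕ 0.6-mm positron range ⊕ voxel aperture)
lands in the ~4.6 mm class a digital scanner's PSF-off behaviour shows
for ¹⁸F on this voxel grid.

## Count statistics and noise

Acquisition-time matching across nuclides solves
`yield · A₀ · (1 − e^(−λT))/λ = K` for `T`
(`matched_acquisition_duration()`), with decay treated continuously —
⁶⁴Cu scans run roughly 5× longer than ¹⁸F scans, so a midpoint decay
correction would bias matched counts.

The noise stage draws independent Poisson counts per voxel *after*
blurring, with the rate normalized so the expected total equals
`target_trues · obese_count_factor` (defaults: 7.1 × 10⁷ trues, factor
0.62 for the obese setup, emulating the ~36–38 % count loss caused by a
scatter-medium wrap). Consequences:

- the per-voxel background CoV is exactly `1/√(counts per voxel)`
  (`expected_cov()`), and measured CoV matches it to a few percent;
- real reconstructed PET noise is spatially correlated and its CoV at
  matched trues is lower (~9 % in scanner data vs ~17 % here); CoV and
  CNR values are therefore comparable *within* simulations, not with
  scanner tables;
- the obese emulation is a pure count-reduction: no extra blur, since
  obese-setup resolution loss in scanner data is attributed to
  reconstruction behaviour, which is out of scope.

Negative intensities cannot arise from Poisson noise; the unsharp mask
may ring below zero and those values are retained (reconstructed images
can undershoot), with rates floored at zero for the count draw.

## Segmentation and VOI conventions

- Sphere threshold: `T = B + 0.5 (S_max − B)` — the standard
  background-corrected 50 % isocontour; the maximum is searched within
  nominal radius + 5 mm so neighbouring spheres cannot capture it, and
  the mask is the 26-connected suprathreshold component nearest the
  nominal centre. A plain 50 %-of-max mode exists for sensitivity checks.
- SUV here is synonymous with activity-concentration ratio (no body
  weight in a phantom); RC_peak uses a 12-mm ball around the hottest
  voxel intersected with the isocontour mask.
- Background VOIs: three cylinders (30 mm radius, ≥ 61 mL) at fixed
  angular positions, their top face 15 mm below the deepest sphere
  surface and 15 mm clear of the lung insert and body outline. The
  placement is a deterministic convention — the study's supplementary
  placement figure is not machine-readable — and reproducible by
  construction.
- Lung VOI: 30-mm-diameter cylinder on the insert axis, sphere plane
  ± 30 mm. With pure Gaussian blur and no scatter model the simulated
  lung error is near zero (spill-in across a 10-mm gap of ≥ 2σ);
  scanner values of 4–13 % are dominated by scatter and, for ⁶⁸Ga,
  additional prompt-gamma/single-photon background, neither of which is
  modelled (the count-error machinery itself is exercised by endpoint
  and monotonicity tests).

## Resolution fitting

`sphere_blur_kernel()` implements the exact profile of a blurred
homogeneous sphere with an `sinh`-based branch near `r = 0` to avoid
catastrophic cancellation, verified against independent quadrature and a
brute-force 3D grid convolution to < 10⁻³. The five-parameter model
(S, B, FWHM, R, w) is fitted with radius and wall fixed, by
Levenberg–Marquardt on the raw voxel samples in spherical coordinates.
Fitting raw voxels rather than a binned profile weights every voxel
equally and removes the small bias of evaluating the model at bin
centres; the binned profile (default bin 0.75 mm) is attached to each
fit for plotting. The centre is refined by an intensity-weighted
centroid over the segmentation mask before extraction. FWHM bounds are
[1, 12] mm; hitting a bound, optimizer failure, or S ≤ B flags the fit
as non-converged instead of returning a number.

**Voxel aperture.** A partial-volume-exact truth is the continuous
phantom convolved with the voxel box, so a fitted FWHM contains the
aperture's direction-averaged variance `mean(spacing²)/12` on top of the
applied blur. `effective_image_fwhm()` composes system PSF, positron
kernel and aperture; at the 4.55-mm operating point the composition is
accurate to well under 1 % (the box kernel's non-Gaussian shape
contributes ~1 % only for blurs ≲ 3.5 mm FWHM). Estimator correctness
itself is tested aperture-free on images that sample the analytic model
directly, where recovery is exact to ≪ 1 %.

## Determinism and numerical choices

- One integer seed in `degradation_spec()` drives the single RNG stream
  of the noise stage; the caller's RNG state is saved and restored, and
  identical configurations produce byte-identical JSON reports.
- The Gaussian blur is separable, truncated at 5.5σ and renormalized, so
  activity is conserved to better than 10⁻⁶ away from grid edges; taps
  are point samples of the Gaussian (variance-exact for σ ≥ 0.5·pitch)
  and voxel-integrated below that.
- Comparison statistics round half-away-from-zero at the decimals of the
  printed tables they replicate (`round_half_away()`); headline "up to
  X %" aggregations are computed on the tabulated 2-decimal means, as
  printed, not on full-precision intermediates.
- Degenerate inputs fail loudly: uniform images raise segmentation
  errors, VOI placement errors name the violated constraint, unreachable
  count targets in acquisition matching are errors, and fits at bounds
  are flagged.

## Problem sizes

The default grid is 440 × 440 × 97 voxels (the reconstruction matrix of
the reference acquisitions in-plane; 97 slices cover the sphere plane
± 72 mm, enough for every analysis VOI with blur margin). Full-scale
simulations at this size are used for the end-to-end resolution-recovery
and nuclide-comparison checks (single-digit seconds per stage); metric
property sweeps run on a geometrically identical 2-mm-voxel grid
(170 × 130 × 61), and estimator unit tests on single-sphere subgrids.
Monte-Carlo checks use 20 seeds (resolution bias) and 100 seeds (noise
unbiasedness).

## Known limitations

- No scatter, attenuation-correction artifacts, randoms, dead time or
  ToF; the obese setup is a count factor only. Lung-insert errors are
  therefore near zero (see above).
- The Gaussian positron kernel exaggerates ⁶⁸Ga's absolute resolution
  loss; cross-nuclide simulation results are directional.
- Noise is voxel-independent Poisson, not OSEM-correlated; CoV/CNR are
  internally consistent but not calibrated to scanner values.
- The Jaszczak cold-rod phantom and cold-sphere metrics are out of
  scope.
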