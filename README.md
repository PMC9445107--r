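# nemaiq

Image-quality and spatial-resolution analysis for PET nuclide comparison
studies on the NEMA IEC body phantom.

## The problem

PET radionuclides differ in positron yield, half-life and — most
importantly for image quality — positron range. Positrons from ⁶⁸Ga carry
an endpoint energy three times that of ¹⁸F or ⁶⁴Cu and travel a mean
3.5 mm in water before annihilating (vs 0.6 / 0.7 mm), which blurs ⁶⁸Ga
images beyond the scanner's intrinsic resolution. Phantom studies quantify
this with the NEMA IEC body phantom: six fillable spheres (10–37 mm) in a
warm background with a cold lung insert, scanned at matched count
statistics and analysed for recovery, contrast, noise and resolution.

`nemaiq` provides, for users who want to study these effects without a
scanner (or benchmark an analysis chain against known ground truth):

- **a digital phantom generator** — partial-volume-exact rasterization of
  the body phantom on a 440 × 440 reconstruction grid
  ((1.65 × 1.65 × 1.5) mm³ voxels), degraded by system-plus-positron-range
  Gaussian blur, optional edge enhancement (Gibbs-artifact mimic) and
  Poisson count noise scaled to a target number of true coincidences;
- **the NEMA-style metric suite** — background-corrected 50% isocontour
  sphere segmentation, RC_mean/max/peak, contrast recovery coefficient
  (CRC), contrast-to-noise ratio (CNR), percent background variability
  (CoV_BG) and the lung-insert relative count error;
- **a spatial-resolution estimator** — nonlinear least-squares fit of the
  analytic radial profile of a homogeneous sphere convolved with a 3D
  Gaussian PSF;
- **comparison reporting** — acquisition-time matching across nuclides and
  the cross-nuclide / cross-setup percentage statistics, including exact
  replication of every number derivable from the packaged acquisition
  tables.

## The core model

A sphere of radius `R` and uniform activity `S` in background `B`, imaged
with a Gaussian PSF of width σ, has the exact radial profile

    C(r) = S · g(r; R, σ) + B · (1 − g(r; R + w, σ))

where `w` is the cold glass wall and

    g(r; R, σ) = ½ [erf((R−r)/(√2σ)) + erf((R+r)/(√2σ))]
                 − σ/(r√(2π)) [exp(−(r−R)²/2σ²) − exp(−(r+R)²/2σ²)]

is the 3D Gaussian convolution of the unit sphere (finite and smooth at
r = 0). `fit_resolution()` fixes `R` and `w` to their known values and
fits (S, B, FWHM) to the voxel samples in spherical coordinates around
each sphere; `FWHM = 2√(2 ln 2)·σ`. The positron-range kernel is an
isotropic Gaussian whose half-width at half maximum equals the nuclide's
mean range in water, so range and system PSF compose in quadrature.

## Worked example

Compare ⁶⁸Ga against ¹⁸F at matched counts on the default grid:

```r
library(nemaiq)
rep <- run_experiment("Ga68", ratio = 4, trues = 7.1e7, seed = 1)
print(rep)
#> <iq_report> Ga68, 4:1 contrast, normal setup
#>   CoV_BG 16.8%, lung error 0.04%, FWHM 8.28 +/- 0.10 mm
#>   diameter_mm n_voxels measured_mean ... rc_mean rc_max rc_peak crc_pct   cnr
#> 1          10       65          10.4 ...   0.491  0.641   0.496    32.2  5.75
#> 2          13      145          12.7 ...   0.601  0.781   0.612    46.8  8.36
#> ...
#> 6          37     3800          19.8 ...   0.933  1.303   1.002    91.0 16.26
```

Reading the report: the 3.5 mm mean positron range inflates the fitted
FWHM to 8.3 mm (an ¹⁸F run under the same settings gives 4.7 mm), and the
partial-volume loss hits the smallest sphere hardest — RC_mean drops from
0.93 (37 mm) to 0.49 (10 mm) and CRC from 91% to 32%, while the large
spheres stay close to full recovery. The same run for `"F18"` keeps CRC
above 67% for every sphere. Matched acquisition times can be derived with
`matched_acquisition_duration()`, which equalizes the decay-weighted
expected trues between nuclides (a ⁶⁴Cu scan needs ~5× the ¹⁸F duration
at similar activity because of its 17.4% positron yield).

The table-derived comparison statistics come from
`replicate_tables()`:

```r
rt <- replicate_tables()
rt$fwhm_excess        # Ga68_vs_F18: 18   Ga68_vs_Cu64: 23   (percent)
rt$contrast_gain_pct  # 13
rt$trues_decrease_range  # 36.1 38.3
```

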