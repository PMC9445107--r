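Package: nemaiq
Title: Image Quality and Spatial Resolution Analysis for PET Nuclide
    Phantom Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the image quality of PET radionuclides
    (18F, 68Ga, 64Cu) on the NEMA IEC body phantom. Provides a digital
    phantom generator that rasterizes the six-sphere body phantom on a
    reconstruction grid and degrades it with system plus nuclide-specific
    positron-range blur and Poisson count noise; a NEMA NU 2-2018 style
    metric suite (recovery coefficients, background variability, contrast
    recovery, contrast-to-noise ratio, lung-insert count error); a spatial
    resolution estimator that fits the analytic radial profile of a
    homogeneous sphere convolved with a 3D Gaussian point spread function;
    and reporting helpers for cross-nuclide comparison of count statistics
    and fitted resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
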