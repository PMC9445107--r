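#' Physical constants of a positron-emitting nuclide
#'
#' Constructor with validation for the nuclide property bundle used
#' throughout the package. Yields are stored as fractions (0.967, not
#' 96.7%), half-lives in minutes, positron energies in keV and positron
#' ranges in water in mm.
#'
#' @param name nuclide identifier, e.g. `"F18"`.
#' @param beta_yield positron branching fraction in (0, 1].
#' @param half_life physical half-life in minutes (> 0).
#' @param e_max maximum (endpoint) positron energy in keV.
#' @param e_mean average positron energy in keV (< `e_max`).
#' @param range_max_water maximum positron range in water, mm.
#' @param range_mean_water mean positron range in water, mm
#'   (< `range_max_water`).
#' @return an object of class `nuclide_props`.
#' @export
nuclide_props <- function(name, beta_yield, half_life, e_max, e_mean,
                          range_max_water, range_mean_water) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("`", what, "` must be a single finite number")
    as.numeric(x)
  }
  p <- list(name = name,
            beta_yield = num1(beta_yield, "beta_yield"),
            half_life = num1(half_life, "half_life"),
            e_max = num1(e_max, "e_max"),
            e_mean = num1(e_mean, "e_mean"),
            range_max_water = num1(range_max_water, "range_max_water"),
            range_mean_water = num1(range_mean_water, "range_mean_water"))
  if (p$beta_yield <= 0 || p$beta_yield > 1)
    stop("beta_yield must be in (0, 1]")
  if (p$half_life <= 0) stop("half_life must be > 0")
  if (p$e_mean >= p$e_max) stop("e_mean must be smaller than e_max")
  if (p$range_mean_water < 0 || p$range_max_water <= p$range_mean_water)
    stop("ranges must satisfy 0 <= mean < max")
  structure(p, class = "nuclide_props")
}

#' @export
print.nuclide_props <- function(x, ...) {
  cat(sprintf(paste0(
    "<nuclide %s> beta+ yield %.1f%%, T1/2 %.4g min, ",
    "E(max/mean) %.4g/%.4g keV, range(max/mean) %.2g/%.2g mm\n"),
    x$name, 100 * x$beta_yield, x$half_life, x$e_max, x$e_mean,
    x$range_max_water, x$range_mean_water))
  invisible(x)
}

# registry environment, lazily seeded from the packaged JSON table
.nuclide_env <- new.env(parent = emptyenv())

.nuclide_registry <- function() {
  if (is.null(.nuclide_env$registry)) {
    path <- system.file("extdata", "nuclides.json", package = "nemaiq",
                        mustWork = TRUE)
    tab <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    reg <- list()
    for (i in seq_len(nrow(tab))) {
      p <- do.call(nuclide_props, as.list(tab[i, ]))
      reg[[p$name]] <- p
    }
    .nuclide_env$registry <- reg
  }
  .nuclide_env$registry
}

#' Look up a registered nuclide
#'
#' The registry ships with 18F, 68Ga and 64Cu (beta+ yield, half-life,
#' endpoint and mean positron energies, maximum and mean positron range in
#' water) and can be extended with [register_nuclide()].
#'
#' @param name nuclide identifier (`"F18"`, `"Ga68"`, `"Cu64"`, ...).
#' @return a [nuclide_props()] object.
#' @examples
#' get_nuclide("Ga68")$range_mean_water  # 3.5 mm
#' @export
get_nuclide <- function(name) {
  reg <- .nuclide_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop("unknown nuclide '", name, "'; registered nuclides: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Register (or replace) a nuclide in the registry
#'
#' User-supplied nuclides are merged by name into the session registry.
#' @param props a [nuclide_props()] object.
#' @return `props`, invisibly.
#' @export
register_nuclide <- function(props) {
  if (!inherits(props, "nuclide_props"))
    stop("`props` must be a nuclide_props object")
  reg <- .nuclide_registry()
  reg[[props$name]] <- props
  .nuclide_env$registry <- reg
  invisible(props)
}

#' Standard deviation of the positron-range blurring kernel
#'
#' Maps a nuclide's mean positron range in water onto the width of an
#' isotropic Gaussian annihilation-displacement kernel. Under the
#' `"gaussian_mean_range"` model the kernel's half-width at half maximum
#' equals the mean range, i.e. `sigma = range_mean_water / sqrt(2 * log(2))`.
#' The true annihilation-point distribution is cusp-shaped with long tails;
#' a Gaussian is used because it composes analytically with the Gaussian
#' system PSF that the resolution estimator assumes (see the methods
#' vignette for the consequences of this choice).
#'
#' @param nuclide a [nuclide_props()] object.
#' @param model kernel model; only `"gaussian_mean_range"` is implemented.
#' @return Gaussian sigma in mm.
#' @examples
#' positron_blur_sigma(get_nuclide("F18"))  # 0.6 / sqrt(2 log 2) ~ 0.51 mm
#' @export
positron_blur_sigma <- function(nuclide, model = "gaussian_mean_range") {
  if (!inherits(nuclide, "nuclide_props"))
    stop("`nuclide` must be a nuclide_props object")
  model <- match.arg(model, "gaussian_mean_range")
  nuclide$range_mean_water / sqrt(2 * log(2))
}

# expected true-count integral per unit activity-yield: integral over the
# acquisition of yield * A0 * exp(-lambda t) dt, lambda in 1/s
.integrated_yield <- function(nuclide, activity, duration_s) {
  lambda <- log(2) / (nuclide$half_life * 60)
  nuclide$beta_yield * activity * (1 - exp(-lambda * duration_s)) / lambda
}

#' Acquisition duration matched for equal expected true counts
#'
#' Computes how long a nuclide must be scanned so that its decay-weighted
#' expected true-count integral equals that of a reference acquisition,
#' accounting for positron yield, half-life and the actual activity
#' concentration at scan start. This is the scheme that makes count
#' statistics comparable between nuclides with very different yields
#' (e.g. 64Cu scans run roughly 5x longer than 18F scans).
#'
#' The matched duration solves
#' `yield * A0 * (1 - exp(-lambda T)) / lambda = K` with
#' `lambda = log(2) / half_life`, where `K` is the reference acquisition's
#' integrated-yield constant; the closed form is
#' `T = -log(1 - lambda K / (yield * A0)) / lambda`.
#'
#' @param nuclide target [nuclide_props()].
#' @param activity_conc_at_start target activity concentration at scan
#'   start (kBq/mL, > 0).
#' @param reference_nuclide reference [nuclide_props()].
#' @param reference_conc reference activity concentration at its scan
#'   start (kBq/mL, > 0).
#' @param reference_duration reference acquisition duration in seconds.
#' @return matched duration in seconds.
#' @export
matched_acquisition_duration <- function(nuclide, activity_conc_at_start,
                                         reference_nuclide, reference_conc,
                                         reference_duration) {
  stopifnot(inherits(nuclide, "nuclide_props"),
            inherits(reference_nuclide, "nuclide_props"))
  if (activity_conc_at_start <= 0 || reference_conc <= 0 ||
      reference_duration <= 0)
    stop("activities and durations must be > 0")
  K <- .integrated_yield(reference_nuclide, reference_conc,
                         reference_duration)
  lambda <- log(2) / (nuclide$half_life * 60)
  frac <- lambda * K / (nuclide$beta_yield * activity_conc_at_start)
  if (frac >= 1)
    stop("target count integral unreachable: ", nuclide$name,
         " decays away before accumulating the reference trues")
  -log1p(-frac) / lambda
}
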