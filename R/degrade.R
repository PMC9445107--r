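#' Image degradation settings for a simulated PET acquisition
#'
#' Bundles everything needed to turn a ground-truth phantom image into an
#' emulated reconstructed PET image: the scanner's intrinsic (system)
#' resolution, the nuclide whose positron range adds extra blur, the
#' target number of true coincidences that sets the Poisson noise level,
#' an optional count-reduction factor emulating the extra attenuation and
#' scatter of an obese-patient setup, and an optional unsharp-mask edge
#' enhancement mimicking the edge overshoot (Gibbs artifact) of
#' resolution-modelling reconstruction.
#'
#' @param system_fwhm intrinsic system PSF full width at half maximum, mm.
#' @param nuclide a [nuclide_props()] or `NULL` for a range-free source
#'   (pure system PSF).
#' @param target_trues expected total true counts for a normal-weight
#'   acquisition; `Inf` disables the noise stage.
#' @param counts_per_true scale factor relating image intensity to Poisson
#'   counts (kept for provenance; the count normalizer absorbs it).
#' @param obese_count_factor fraction of trues retained under the obese
#'   setup (1 = normal weight; the study's cooling-pack wrap retained
#'   roughly 0.62).
#' @param edge_enhancement `NULL`, or `list(amount =, scale =)`: the image
#'   becomes `img + amount * (img - gaussian(img, sigma = scale))`.
#' @param seed integer seed making the noise stage reproducible.
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(system_fwhm = 4.4, nuclide = NULL,
                             target_trues = 7.1e7, counts_per_true = 1,
                             obese_count_factor = 1,
                             edge_enhancement = NULL, seed = 1L) {
  if (!is.null(nuclide) && !inherits(nuclide, "nuclide_props"))
    stop("`nuclide` must be NULL or a nuclide_props object")
  if (system_fwhm <= 0) stop("system_fwhm must be > 0")
  if (is.na(target_trues) || target_trues <= 0)
    stop("target_trues must be > 0")
  if (obese_count_factor <= 0 || obese_count_factor > 1)
    stop("obese_count_factor must be in (0, 1]")
  if (counts_per_true <= 0) stop("counts_per_true must be > 0")
  if (!is.null(edge_enhancement)) {
    if (is.null(edge_enhancement$amount) || is.null(edge_enhancement$scale))
      stop("edge_enhancement needs `amount` and `scale`")
    if (edge_enhancement$amount < 0) stop("edge_enhancement amount must be >= 0")
    if (edge_enhancement$scale <= 0) stop("edge_enhancement scale must be > 0")
  }
  structure(list(system_fwhm = system_fwhm, nuclide = nuclide,
                 target_trues = target_trues,
                 counts_per_true = counts_per_true,
                 obese_count_factor = obese_count_factor,
                 edge_enhancement = edge_enhancement,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Convert between FWHM and Gaussian sigma
#' @param fwhm,sigma value to convert (mm).
#' @return the converted value (mm).
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# 1D convolution kernel taps for a Gaussian sampled at voxel pitch h.
# Point-sampling keeps the discrete kernel variance equal to sigma^2 when
# sigma >~ 0.5 h; below that, voxel-integrated (erf-difference) taps are
# used to stay accurate. Taps are normalized to sum 1, so interior columns
# conserve activity exactly.
.gauss_taps <- function(sigma, h) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(5.5 * sigma / h)))
  k <- (-r):r
  if (sigma >= 0.5 * h) {
    t <- stats::dnorm(k * h, sd = sigma)
  } else {
    t <- stats::pnorm((k + 0.5) * h, sd = sigma) -
      stats::pnorm((k - 0.5) * h, sd = sigma)
  }
  t / sum(t)
}

# banded Toeplitz convolution matrix K with K[i, j] = taps[j - i + r + 1]
.conv_matrix <- function(n, taps) {
  r <- (length(taps) - 1L) / 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in (-r):r) {
    ok <- i + k >= 1L & i + k <= n
    K[cbind(i[ok], i[ok] + k)] <- taps[k + r + 1L]
  }
  K
}

#' Separable 3D Gaussian blur of a grid
#'
#' Applies a normalized, truncated (5.5 sigma) Gaussian along each axis.
#' Values beyond the grid are treated as zero; the kernel is normalized so
#' total activity is conserved away from the grid edges.
#' @param grid a [grid3d()].
#' @param sigma_mm isotropic Gaussian standard deviation in mm (0 = no-op).
#' @return a blurred [grid3d()].
#' @export
gaussian_blur <- function(grid, sigma_mm) {
  if (sigma_mm < 0) stop("sigma must be >= 0")
  if (sigma_mm == 0) return(grid)
  a <- grid$values
  d <- dim(a)
  for (axis in 1:3) {
    taps <- .gauss_taps(sigma_mm, grid$spacing[axis])
    if (length(taps) == 1L) next
    K <- .conv_matrix(d[axis], taps)
    if (axis == 1L) {
      dim(a) <- c(d[1], d[2] * d[3])
      a <- K %*% a
      dim(a) <- d
    } else if (axis == 2L) {
      tK <- t(K)
      for (k3 in seq_len(d[3])) a[, , k3] <- a[, , k3] %*% tK
    } else {
      dim(a) <- c(d[1] * d[2], d[3])
      a <- a %*% t(K)
      dim(a) <- d
    }
  }
  grid3d(as.array(a), grid$spacing, grid$origin)
}

#' Degrade a ground-truth image into an emulated reconstructed PET image
#'
#' Applies, in order: (1) isotropic Gaussian blur with
#' `sigma_total = sqrt(sigma_system^2 + sigma_positron^2)` where
#' `sigma_system = system_fwhm / (2 sqrt(2 log 2))` and the positron term
#' comes from [positron_blur_sigma()]; (2) optional unsharp-mask edge
#' enhancement; (3) Poisson count noise, with voxel count rates scaled so
#' the expected total equals `target_trues * obese_count_factor`, then
#' rescaled back to kBq/mL. Deterministic given `deg$seed` (the caller's
#' RNG state is left untouched). Edge enhancement can ring below zero;
#' negative rates are floored at zero for the Poisson draw.
#'
#' The returned grid carries attributes `count_scale` (expected counts per
#' unit of kBq/mL-voxel intensity) and `sigma_total` for provenance.
#'
#' @param truth a [grid3d()] ground-truth image.
#' @param deg a [degradation_spec()].
#' @return a degraded [grid3d()].
#' @export
degrade_image <- function(truth, deg) {
  stopifnot(inherits(truth, "grid3d"), inherits(deg, "degradation_spec"))
  sigma_pos <- if (is.null(deg$nuclide)) 0 else positron_blur_sigma(deg$nuclide)
  sigma_tot <- sqrt(fwhm_to_sigma(deg$system_fwhm)^2 + sigma_pos^2)
  out <- gaussian_blur(truth, sigma_tot)
  if (!is.null(deg$edge_enhancement)) {
    wide <- gaussian_blur(out, deg$edge_enhancement$scale)
    out$values <- out$values +
      deg$edge_enhancement$amount * (out$values - wide$values)
  }
  count_scale <- NA_real_
  if (is.finite(deg$target_trues)) {
    vv <- voxel_volume(truth)
    total <- sum(out$values) * vv
    if (total <= 0) stop("degraded image has no activity to draw counts from")
    normalizer <- deg$target_trues / (total * deg$counts_per_true)
    count_scale <- vv * deg$counts_per_true * deg$obese_count_factor *
      normalizer
    lambda <- pmax(out$values, 0) * count_scale
    counts <- .with_seed(deg$seed, stats::rpois(length(lambda), lambda))
    out$values <- array(counts / count_scale, dim(out$values))
  }
  attr(out, "count_scale") <- count_scale
  attr(out, "sigma_total") <- sigma_tot
  out
}

# run code with a local RNG state; restores the caller's state afterwards
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Predicted background coefficient of variation of a degraded image
#'
#' For independent Poisson counts the per-voxel coefficient of variation in
#' a uniform background is `1 / sqrt(mean counts per voxel)`. Since the
#' noise stage draws independent counts after blurring, the prediction is
#' exact up to the (small) deviation of the local blurred mean from the
#' nominal background level. Spatial correlation of reconstruction noise in
#' real scanners is not modelled.
#'
#' @param deg a [degradation_spec()].
#' @param background_activity background concentration, kBq/mL.
#' @param total_activity image-integrated activity (kBq * mm^3 / mL) that
#'   the count normalizer is computed against; use [activity_integral()] of
#'   the truth or [phantom_activity_integral()] of the phantom description.
#' @param spacing voxel spacing (mm) of the simulated grid.
#' @return predicted CoV (fraction).
#' @export
expected_cov <- function(deg, background_activity, total_activity,
                         spacing = c(1.65, 1.65, 1.5)) {
  stopifnot(inherits(deg, "degradation_spec"))
  if (!is.finite(deg$target_trues))
    stop("noise-free degradation has no count-based CoV")
  lambda_bg <- deg$target_trues * deg$obese_count_factor *
    background_activity * prod(spacing) / total_activity
  if (lambda_bg <= 0) stop("expected zero counts per voxel")
  1 / sqrt(lambda_bg)
}
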