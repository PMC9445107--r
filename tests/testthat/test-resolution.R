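test_that("analytic blurred-sphere kernel matches independent quadrature", {
  for (R in c(5, 18.5)) for (sigma in c(1.5, 2.3)) {
    r <- seq(0, 2 * R, length.out = 41)
    expect_lt(max(abs(sphere_blur_kernel(r, R, sigma) -
                        sphere_profile_quadrature(r, R, sigma))), 1e-6)
  }
})

test_that("kernel limits: step function, smooth centre, asymptotics", {
  # sigma -> 0: indicator of the sphere
  expect_equal(sphere_blur_kernel(c(1, 4.9), 5, 1e-4), c(1, 1))
  expect_equal(sphere_blur_kernel(c(5.1, 10), 5, 1e-4), c(0, 0))
  # continuity through r = 0 (series switch)
  g0 <- sphere_blur_kernel(0, 8, 2)
  expect_equal(g0, .5 * (2 * pnorm(8 / 2) - 1) * 2 - 8 / 2 * sqrt(2 / pi) *
                 exp(-16 / 2), tolerance = 1e-10)
  expect_equal(sphere_blur_kernel(1e-9, 8, 2), g0, tolerance = 1e-8)
  expect_equal(sphere_blur_kernel(0.01, 8, 2), g0, tolerance = 1e-4)
  # profile asymptotics: C(inf) = B, C(0) -> S for R >> sigma
  expect_equal(sphere_profile(60, 20, 3, 4, 10, 0), 3, tolerance = 1e-9)
  expect_equal(sphere_profile(0, 20, 3, 4, 18.5, 0), 20, tolerance = 1e-6)
})

test_that("radial profile extraction is consistent with the forward model", {
  # uniform image: every bin equals the constant
  g <- grid3d(array(2.5, c(31, 31, 31)), c(1.65, 1.65, 1.5))
  p <- extract_profile(g, c(0, 0, 0), 15, 0.8)
  expect_true(all(abs(p$values - 2.5) < 1e-12))
  expect_true(all(diff(p$radii) > 0))
  expect_true(all(p$counts >= 1))
  # bin width larger than r_max: one bin holding every voxel in the ball
  p1 <- extract_profile(g, c(0, 0, 0), 12, 30)
  expect_length(p1$values, 1)
  # synthetic analytic image sampled on the grid reproduces C(r)
  img <- g
  w <- nemaiq:::.index_to_world(img, seq_along(img$values))
  r <- sqrt(rowSums(w^2))
  img$values <- array(sphere_profile(r, 21.2, 5.3, 4.5, 8.5, 1),
                      dim(img$values))
  p2 <- extract_profile(img, c(0, 0, 0), 20, 0.8)
  want <- sphere_profile(p2$r_mean, 21.2, 5.3, 4.5, 8.5, 1)
  expect_lt(max(abs(p2$values - want) / max(want)), 0.02)
  # ball exiting the grid is a geometry error
  expect_error(extract_profile(g, c(20, 0, 0), 15, 0.8), "exits the grid")
})

test_that("noiseless parameter recovery across FWHM and sphere size", {
  # images built by sampling the analytic forward model on the grid, so
  # the fit is checked purely as a parameter-recovery problem
  for (fw in c(3.5, 4.5, 5.5)) for (d in c(10, 37)) {
    shape <- if (d > 20) c(61, 61, 61) else c(41, 41, 41)
    g <- grid3d(array(0, shape), c(1.65, 1.65, 1.5))
    w <- nemaiq:::.index_to_world(g, seq_along(g$values))
    r <- sqrt(rowSums(w^2))
    g$values <- array(sphere_profile(r, 21.2, 5.3, fw, d / 2, 1),
                      dim(g$values))
    ft <- fit_resolution(g, list(center = c(0, 0, 0), diameter = d,
                                 wall = 1), background_mean = 5.3)
    expect_true(ft$converged)
    expect_equal(ft$model$fwhm, fw, tolerance = 0.01)
    expect_equal(ft$model$S, 21.2, tolerance = 0.02)
    expect_equal(ft$model$B, 5.3, tolerance = 0.02)
  }
})

test_that("rasterized spheres carry the voxel-aperture broadening", {
  # a partial-volume-rasterized truth is the continuous phantom convolved
  # with the voxel box, so the fitted FWHM matches the quadrature
  # composition of blur and aperture
  truth <- single_sphere_truth(22, shape = c(41, 41, 41))
  img <- degrade_image(truth, degradation_spec(4.55, target_trues = Inf))
  ft <- fit_resolution(img, list(center = c(0, 0, 0), diameter = 22,
                                 wall = 1), background_mean = 5.3)
  want <- effective_image_fwhm(4.55, spacing = truth$spacing)
  expect_equal(ft$model$fwhm, want, tolerance = 0.01)
})

test_that("two successive blurs compose in quadrature", {
  truth <- single_sphere_truth(28, shape = c(51, 51, 51))
  s1 <- 1.6; s2 <- 1.2
  img <- gaussian_blur(gaussian_blur(truth, s1), s2)
  ft <- fit_resolution(img, list(center = c(0, 0, 0), diameter = 28,
                                 wall = 1), background_mean = 5.3)
  want <- effective_image_fwhm(sigma_to_fwhm(sqrt(s1^2 + s2^2)),
                               spacing = truth$spacing)
  expect_equal(ft$model$fwhm, want, tolerance = 0.02)
})

test_that("degenerate fits are flagged, not returned silently", {
  g <- grid3d(array(5.3, c(31, 31, 31)), c(2, 2, 2))
  ft <- suppressWarnings(
    fit_resolution(g, list(center = c(0, 0, 0), diameter = 22, wall = 1),
                   background_mean = 5.3))
  expect_false(ft$converged)
})

test_that("aggregation uses converged fits with sample SD", {
  mk <- function(fwhm, conv = TRUE)
    structure(list(model = list(fwhm = fwhm), converged = conv),
              class = "resolution_fit")
  agg <- aggregate_resolution(list(mk(4), mk(4), mk(4)))
  expect_equal(agg$mean, 4); expect_equal(agg$sd, 0)
  agg2 <- aggregate_resolution(list(mk(4), mk(5)))
  expect_equal(agg2$mean, 4.5)
  expect_equal(agg2$sd, 0.7071, tolerance = 1e-4)
  expect_error(aggregate_resolution(list(mk(4), mk(5, FALSE))), "at least 2")
})
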