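test_that("isocontour segmentation recovers a blurred sphere's volume", {
  truth <- single_sphere_truth(37, ratio = 8)
  img <- degrade_image(truth, degradation_spec(4.4, target_trues = Inf))
  mask <- segment_sphere(img, c(0, 0, 0), 5.3, 37)
  vol <- length(mask) * voxel_volume(img)
  expect_equal(vol, 4 / 3 * pi * 18.5^3, tolerance = 0.15)
})

test_that("segmentation degenerate cases behave as specified", {
  # uniform image: nothing above background -> segmentation error
  g <- grid3d(array(5.3, c(31, 31, 31)), c(2, 2, 2))
  expect_error(segment_sphere(g, c(0, 0, 0), 5.3, 20), "segmentation failed")
  # zero background, binary sphere: plain 50% of max = the sphere voxels
  b <- single_sphere_truth(22, background = 0, activity = 21.2,
                           supersampling = 1L, shape = c(41, 41, 41))
  mask <- segment_sphere(b, c(0, 0, 0), 0, 22)
  expect_setequal(mask, which(b$values >= 0.5 * max(b$values)))
})

test_that("segmentation does not bleed into a neighbouring sphere", {
  ph <- coarse_phantom(4)
  img <- degrade_image(ph$truth, degradation_spec(4.4, target_trues = Inf))
  masks <- lapply(seq_along(ph$spec$sphere_diameters), function(i)
    segment_sphere(img, ph$spec$sphere_centers[i, ], 5.3,
                   ph$spec$sphere_diameters[i]))
  for (i in seq_along(masks)[-1])
    expect_length(intersect(masks[[i]], masks[[1]]), 0)
})

test_that("background VOIs are deterministic, big enough and disjoint", {
  ph <- coarse_phantom(4)
  bg1 <- place_background_vois(ph$truth, ph$spec)
  bg2 <- place_background_vois(ph$truth, ph$spec)
  expect_identical(bg1$voi_masks, bg2$voi_masks)
  expect_true(all(bg1$voi_volumes >= 61))
  # disjoint from each other
  expect_length(intersect(bg1$voi_masks[[1]], bg1$voi_masks[[2]]), 0)
  expect_length(intersect(bg1$voi_masks[[2]], bg1$voi_masks[[3]]), 0)
  # noiseless uniform background: exact mean, zero CoV
  expect_equal(bg1$mean, 5.3)
  expect_equal(bg1$cov_bg, 0)
  # disjoint from every sphere mask and from the lung insert
  img <- degrade_image(ph$truth, degradation_spec(4.4, target_trues = Inf))
  for (i in seq_along(ph$spec$sphere_diameters)) {
    m <- segment_sphere(img, ph$spec$sphere_centers[i, ], 5.3,
                        ph$spec$sphere_diameters[i])
    expect_length(intersect(m, unlist(bg1$voi_masks)), 0)
  }
  expect_true(all(ph$truth$values[unlist(bg1$voi_masks)] > 0))
  # too short a grid cannot host the VOIs
  short <- grid3d(array(5.3, c(170, 130, 10)), c(2, 2, 2))
  expect_error(place_background_vois(short, ph$spec), "too short")
})

test_that("measured background CoV matches the Poisson prediction", {
  ph <- coarse_phantom(4)
  deg <- degradation_spec(4.4, nuclide = get_nuclide("F18"),
                          target_trues = 7.1e7, seed = 5)
  img <- degrade_image(ph$truth, deg)
  bg <- place_background_vois(img, ph$spec)
  pred <- expected_cov(deg, 5.3, activity_integral(ph$truth),
                       spacing = ph$truth$spacing)
  expect_gt(7.1e7 * 5.3 * voxel_volume(img) /
              activity_integral(ph$truth), 50)  # enough counts per voxel
  expect_equal(bg$cov_bg, pred, tolerance = 0.1)
})

test_that("recovery coefficients satisfy their identities", {
  truth <- single_sphere_truth(22, shape = c(41, 41, 41))
  img <- degrade_image(truth, degradation_spec(
    4.4, target_trues = 2e6, seed = 9))
  mask <- segment_sphere(img, c(0, 0, 0), 5.3, 22)

  # identity: image equal to the true activity on the mask
  flat <- img; flat$values[] <- 0; flat$values[mask] <- 21.2
  rc <- recovery_coefficients(flat, mask, 21.2)
  expect_equal(rc$rc_mean, 1); expect_equal(rc$rc_max, 1)
  expect_equal(rc$rc_peak, 1)

  # homogeneity: doubling the image doubles every RC
  rc1 <- recovery_coefficients(img, mask, 21.2)
  img2 <- img; img2$values <- img$values * 2
  rc2 <- recovery_coefficients(img2, mask, 21.2)
  expect_equal(rc2$rc_mean, 2 * rc1$rc_mean)
  expect_equal(rc2$rc_max, 2 * rc1$rc_max)
  expect_equal(rc2$rc_peak, 2 * rc1$rc_peak)

  # ordering: max >= peak and max >= mean, all positive
  expect_gte(rc1$rc_max, rc1$rc_peak)
  expect_gte(rc1$rc_max, rc1$rc_mean)
  expect_gt(rc1$rc_peak, 0)
})

test_that("noiseless blurred-sphere recovery matches the analytic model", {
  fw <- 4.5
  rcm <- vapply(c(37, 10), function(d) {
    truth <- single_sphere_truth(d, ratio = 4,
                                 shape = if (d > 20) c(61, 61, 61)
                                         else c(41, 41, 41))
    img <- degrade_image(truth, degradation_spec(fw, target_trues = Inf))
    mask <- segment_sphere(img, c(0, 0, 0), 5.3, d)
    got <- recovery_coefficients(img, mask, 21.2)$rc_mean
    # independent check: mean of the analytic profile over the mask radii
    w <- nemaiq:::.index_to_world(img, mask)
    r <- sqrt(rowSums(w^2))
    sig <- sqrt(fwhm_to_sigma(fw)^2 + mean(img$spacing^2) / 12)
    want <- mean(sphere_profile(r, 21.2, 5.3, sigma_to_fwhm(sig), d / 2, 1)) /
      21.2
    expect_equal(got, want, tolerance = 0.02)
    got
  }, numeric(1))
  # brute-force oracle puts the 37 mm sphere's recovery near 0.9 at this
  # blur; pure blur never pushes it above 1
  expect_gt(rcm[1], 0.85); expect_lte(rcm[1], 1.0)
  expect_lt(rcm[2], rcm[1])  # partial volume hits the small sphere harder
})

test_that("contrast recovery and CNR arithmetic", {
  expect_equal(contrast_recovery(8 * 1.1, 1.1, 8, 1), 100)
  expect_equal(contrast_recovery(1.1, 1.1, 8, 1), 0)
  expect_equal(contrast_recovery(8.0, 1.1, 8, 1), 100 * (8 / 1.1 - 1) / 7)
  expect_error(contrast_recovery(5, 1, 1, 1), "ratio")
  expect_error(contrast_recovery(5, 0, 8, 1))

  expect_equal(contrast_noise_ratio(8, 1, 0.1), 70)
  expect_equal(contrast_noise_ratio(5, 5, 0.3), 0)
  expect_equal(contrast_noise_ratio(8, 1, 0.05), 140)  # halving sd doubles
  expect_error(contrast_noise_ratio(8, 1, 0), "noiseless")
})

test_that("lung count error endpoints and blur monotonicity", {
  ph <- coarse_phantom(4)
  bg <- place_background_vois(ph$truth, ph$spec)
  # cold insert, no blur: exactly 0%
  expect_equal(lung_count_error(ph$truth, ph$spec, bg), 0)
  # insert filled at background level: exactly 100%
  full <- ph$truth
  xs <- axis_coords(full, 1); ys <- axis_coords(full, 2)
  lungpix <- which(outer(xs^2, ys^2, "+") <= 25^2)
  ai <- arrayInd(lungpix, dim(full$values)[1:2])
  for (k in seq_len(dim(full$values)[3]))
    full$values[cbind(ai, k)] <- 5.3
  expect_equal(lung_count_error(full, ph$spec, bg), 100)
  # spill-in grows with blur
  errs <- vapply(c(5, 8, 11), function(fw) {
    img <- degrade_image(ph$truth, degradation_spec(fw, target_trues = Inf))
    b <- place_background_vois(img, ph$spec)
    lung_count_error(img, ph$spec, b)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_true(all(errs >= 0 & errs < 15))
})

test_that("metrics are invariant under a global intensity rescaling", {
  ph <- coarse_phantom(4)
  img <- degrade_image(ph$truth, degradation_spec(
    4.4, nuclide = get_nuclide("F18"), target_trues = 7.1e7, seed = 2))
  c0 <- 3.7
  sc <- img; sc$values <- img$values * c0
  bg <- place_background_vois(img, ph$spec)
  bgs <- place_background_vois(sc, ph$spec)
  expect_equal(bgs$cov_bg, bg$cov_bg)
  i <- 6  # 37 mm sphere
  m <- segment_sphere(img, ph$spec$sphere_centers[i, ], bg$mean, 37)
  ms <- segment_sphere(sc, ph$spec$sphere_centers[i, ], bgs$mean, 37)
  expect_identical(m, ms)
  rc <- recovery_coefficients(img, m, 21.2)
  rcs <- recovery_coefficients(sc, ms, 21.2 * c0)
  expect_equal(rcs$rc_mean, rc$rc_mean)
  expect_equal(contrast_recovery(rcs$measured_mean, bgs$mean, 21.2 * c0,
                                 5.3 * c0),
               contrast_recovery(rc$measured_mean, bg$mean, 21.2, 5.3))
  expect_equal(contrast_noise_ratio(rcs$measured_mean, bgs$mean, bgs$sd),
               contrast_noise_ratio(rc$measured_mean, bg$mean, bg$sd))
  expect_equal(lung_count_error(sc, ph$spec, bgs),
               lung_count_error(img, ph$spec, bg))
})
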