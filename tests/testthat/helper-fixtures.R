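# shared fixtures; heavy objects are built once per test run and cached
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

no_lung <- list(center = c(0, 0), diameter = 0, activity = 0)
wide_body <- list(circle_offset = 0, circle_radius = 1e6)

# one centred sphere in a uniform background, partial-volume rasterized
single_sphere_truth <- function(diameter, background = 5.3, ratio = 4,
                                activity = NULL,
                                shape = c(61, 61, 61),
                                spacing = c(1.65, 1.65, 1.5),
                                supersampling = 4L, wall = 1) {
  if (is.null(activity)) activity <- ratio * background
  spec <- phantom_spec(sphere_diameters = diameter,
                       sphere_centers = matrix(0, 1, 3),
                       wall_thickness = wall,
                       background_activity = background,
                       sphere_activity = activity,
                       lung_insert = no_lung, body = wide_body)
  rasterize_phantom(spec, spacing = spacing, shape = shape,
                    supersampling = supersampling)
}

# coarse full NEMA phantom for metric property tests (2 mm voxels)
coarse_phantom <- function(ratio = 4) {
  key <- paste0("coarse_", ratio)
  cached(key, function() {
    spec <- nema_phantom(ratio)
    truth <- rasterize_phantom(spec, spacing = c(2, 2, 2),
                               shape = c(170, 130, 61), supersampling = 4L)
    list(spec = spec, truth = truth)
  })
}

# full-resolution NEMA phantom at the default 440 x 440 grid, ratio 4
default_phantom <- function() {
  cached("default_4", function() {
    spec <- nema_phantom(4)
    list(spec = spec, truth = rasterize_phantom(spec))
  })
}

# independent quadrature oracle for the blurred-sphere radial profile:
# composite Simpson rule on the 1D radial convolution integral
sphere_profile_quadrature <- function(r, R, sigma, n = 4000L) {
  vapply(r, function(ri) {
    if (ri < 1e-9) ri <- 1e-9
    u <- seq(0, R, length.out = n + 1)
    f <- u / (ri * sigma * sqrt(2 * pi)) *
      (exp(-(ri - u)^2 / (2 * sigma^2)) - exp(-(ri + u)^2 / (2 * sigma^2)))
    h <- R / n
    w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    sum(w * f) * h / 3
  }, numeric(1))
}
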