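#' Geometric and activity description of the NEMA IEC body phantom
#'
#' The standard configuration has six fillable spheres (10, 13, 17, 22,
#' 28, 37 mm inner diameter) equally spaced on a 114.4 mm diameter circle
#' in one transaxial plane (the "sphere plane", z = 0), a cold cylindrical
#' lung insert on the phantom axis, and a torso-shaped background
#' compartment. All activities are in kBq/mL.
#'
#' @param sphere_diameters inner diameters (mm) of the spheres.
#' @param sphere_centers n x 3 matrix of sphere centres (mm); default is
#'   the standard ring layout in the z = 0 plane with diameters assigned
#'   counter-clockwise starting at +x.
#' @param wall_thickness glass wall thickness of the sphere shells (mm);
#'   the wall carries no activity.
#' @param background_activity background compartment concentration
#'   (kBq/mL); NEMA NU 2-2018 targets 5.3 kBq/mL.
#' @param sphere_activity concentration in all spheres (one stock fills
#'   every sphere).
#' @param lung_insert list with `center` (x, y in mm), `diameter` (mm) and
#'   `activity` (kBq/mL, 0 = cold) of the axial lung-equivalent cylinder;
#'   it spans the full axial extent of the grid.
#' @param body list describing the torso outline: two half-discs of
#'   `circle_radius` joined over `2 * circle_offset` mm (a stadium shape,
#'   300 mm wide by 230 mm high with the defaults).
#' @return an object of class `phantom_spec`.
#' @seealso [nema_phantom()] for the ratio-based convenience constructor.
#' @export
phantom_spec <- function(sphere_diameters = c(10, 13, 17, 22, 28, 37),
                         sphere_centers = NULL,
                         wall_thickness = 1.0,
                         background_activity = 5.3,
                         sphere_activity = 21.2,
                         lung_insert = list(center = c(0, 0), diameter = 50,
                                            activity = 0),
                         body = list(circle_offset = 35, circle_radius = 115)) {
  n <- length(sphere_diameters)
  if (n > 0 && (any(!is.finite(sphere_diameters)) | any(sphere_diameters <= 0)))
    stop("sphere diameters must be positive")
  if (is.null(sphere_centers)) {
    ang <- (seq_len(n) - 1) * 2 * pi / max(n, 1)
    sphere_centers <- cbind(57.2 * cos(ang), 57.2 * sin(ang), 0)
  }
  sphere_centers <- matrix(as.numeric(sphere_centers), ncol = 3)
  if (nrow(sphere_centers) != n)
    stop("need one centre per sphere diameter")
  if (wall_thickness < 0) stop("wall_thickness must be >= 0")
  if (background_activity < 0 || sphere_activity < 0 ||
      lung_insert$activity < 0)
    stop("activities must be >= 0")
  spec <- structure(list(sphere_diameters = as.numeric(sphere_diameters),
                         sphere_centers = sphere_centers,
                         wall_thickness = wall_thickness,
                         background_activity = background_activity,
                         sphere_activity = sphere_activity,
                         lung_insert = lung_insert,
                         body = body),
                    class = "phantom_spec")
  # spheres must not overlap (walls included) nor intrude into the lung
  if (n > 1) {
    r_out <- sphere_diameters / 2 + wall_thickness
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((sphere_centers[i, ] - sphere_centers[j, ])^2))
      if (d < r_out[i] + r_out[j])
        stop("spheres ", i, " and ", j, " overlap")
    }
  }
  if (n > 0 && lung_insert$diameter > 0) {
    dl <- sqrt((sphere_centers[, 1] - lung_insert$center[1])^2 +
               (sphere_centers[, 2] - lung_insert$center[2])^2)
    if (any(dl < sphere_diameters / 2 + wall_thickness +
            lung_insert$diameter / 2))
      stop("a sphere intrudes into the lung insert")
  }
  spec
}

#' NEMA body phantom at a target sphere-to-background ratio
#'
#' Convenience constructor for the hot-sphere image-quality setups:
#' background at 5.3 kBq/mL and all spheres at `ratio` times that.
#' @param ratio sphere-to-background activity concentration ratio
#'   (typically 4 or 8).
#' @param background_activity background concentration, kBq/mL.
#' @param ... further arguments passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
nema_phantom <- function(ratio = 4, background_activity = 5.3, ...) {
  if (ratio <= 1) stop("hot-sphere setups need ratio > 1")
  phantom_spec(background_activity = background_activity,
               sphere_activity = ratio * background_activity, ...)
}

# signed classification helpers --------------------------------------------

# distance from in-plane points to the stadium body axis; inside iff <= R
.body_axis_dist <- function(spec, x, y) {
  dx <- pmax(abs(x) - spec$body$circle_offset, 0)
  sqrt(dx * dx + y * y)
}

.in_body <- function(spec, x, y) {
  .body_axis_dist(spec, x, y) <= spec$body$circle_radius
}

.in_lung <- function(spec, x, y) {
  sqrt((x - spec$lung_insert$center[1])^2 +
       (y - spec$lung_insert$center[2])^2) <= spec$lung_insert$diameter / 2
}

#' Total activity of a phantom inside a grid's field of view (analytic)
#'
#' Background area times background activity, minus the cold lung and the
#' sphere shells, plus the sphere interiors; used to predict Poisson count
#' rates without rasterizing. The body is assumed to span the full axial
#' extent of the grid.
#' @param spec a [phantom_spec()].
#' @param spacing,shape grid geometry as in [rasterize_phantom()].
#' @return activity integral in kBq * mm^3 / mL.
#' @export
phantom_activity_integral <- function(spec, spacing = c(1.65, 1.65, 1.5),
                                      shape = c(440, 440, 97)) {
  zlen <- shape[3] * spacing[3]
  R <- spec$body$circle_radius; a <- spec$body$circle_offset
  body_area <- pi * R^2 + 2 * a * 2 * R
  lung_area <- pi * (spec$lung_insert$diameter / 2)^2
  r_in <- spec$sphere_diameters / 2
  r_out <- r_in + spec$wall_thickness
  v_in <- sum(4 / 3 * pi * r_in^3)
  v_out <- sum(4 / 3 * pi * r_out^3)
  bg <- spec$background_activity *
    ((body_area - lung_area) * zlen - v_out) +
    spec$lung_insert$activity * lung_area * zlen
  bg + spec$sphere_activity * v_in
}

#' Rasterize a phantom onto a reconstruction grid
#'
#' Produces a partial-volume-exact ground-truth image: each voxel value is
#' the average concentration over the voxel, with sphere interiors at
#' `sphere_activity`, sphere walls at 0, the lung insert at its (usually
#' zero) activity, the body interior at `background_activity` and the
#' exterior at 0. Voxels cut by a region interface are resolved by
#' `supersampling^3` subvoxel classification (`supersampling = 1` reduces
#' to voxel-centre point classification).
#'
#' The default grid emulates a 440 x 440 reconstruction matrix with
#' (1.65, 1.65, 1.5) mm voxels; the default 97 slices cover the sphere
#' plane +/- 72 mm, enough for all analysis VOIs.
#'
#' @param spec a [phantom_spec()].
#' @param spacing voxel spacing (mm).
#' @param shape grid dimensions (nx, ny, nz).
#' @param supersampling subvoxel sampling factor per axis (integer >= 1).
#' @return a [grid3d()] ground-truth image.
#' @export
rasterize_phantom <- function(spec, spacing = c(1.65, 1.65, 1.5),
                              shape = c(440, 440, 97), supersampling = 4L) {
  supersampling <- as.integer(supersampling)
  if (supersampling < 1L) stop("supersampling must be >= 1")
  shape <- as.integer(shape)
  g <- grid3d(array(0, shape), spacing)
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2); zs <- axis_coords(g, 3)

  # subpixel offset grids
  off1 <- function(h, s) ((seq_len(s) - 0.5) / s - 0.5) * h
  ox <- off1(spacing[1], supersampling)
  oy <- off1(spacing[2], supersampling)
  oz <- off1(spacing[3], supersampling)

  # --- in-plane template: background & lung are z-invariant ----------------
  X <- matrix(xs, shape[1], shape[2])
  Y <- matrix(ys, shape[1], shape[2], byrow = TRUE)
  m2 <- sqrt(spacing[1]^2 + spacing[2]^2) / 2
  dbody <- .body_axis_dist(spec, X, Y)
  Rb <- spec$body$circle_radius
  dlung <- sqrt((X - spec$lung_insert$center[1])^2 +
                (Y - spec$lung_insert$center[2])^2)
  rl <- spec$lung_insert$diameter / 2
  frac_body <- (dbody <= Rb) + 0
  frac_lung <- (dlung <= rl) + 0
  if (supersampling > 1L) {
    sub2 <- expand.grid(ox = ox, oy = oy)
    refine <- function(idx, test) {
      f <- numeric(length(idx))
      px <- X[idx]; py <- Y[idx]
      for (k in seq_len(nrow(sub2)))
        f <- f + test(px + sub2$ox[k], py + sub2$oy[k])
      f / nrow(sub2)
    }
    bidx <- which(abs(dbody - Rb) < m2)
    if (length(bidx))
      frac_body[bidx] <- refine(bidx, function(x, y) .in_body(spec, x, y))
    lidx <- which(abs(dlung - rl) < m2)
    if (length(lidx))
      frac_lung[lidx] <- refine(lidx, function(x, y) .in_lung(spec, x, y))
  }
  plane <- spec$background_activity * (frac_body - frac_lung) +
    spec$lung_insert$activity * frac_lung
  vals <- array(plane, shape)  # replicate across z

  # --- spheres: local 3D partial-volume classification ---------------------
  m3 <- sqrt(sum(spacing^2)) / 2
  sub3 <- if (supersampling > 1L) as.matrix(expand.grid(ox, oy, oz)) else NULL
  for (s in seq_along(spec$sphere_diameters)) {
    ctr <- spec$sphere_centers[s, ]
    r_in <- spec$sphere_diameters[s] / 2
    r_out <- r_in + spec$wall_thickness
    lo <- .world_to_index(g, ctr - r_out - m3)
    hi <- .world_to_index(g, ctr + r_out + m3)
    if (any((ctr - r_out) < c(xs[1], ys[1], zs[1]) - spacing / 2) ||
        any((ctr + r_out) > c(xs[shape[1]], ys[shape[2]], zs[shape[3]]) +
            spacing / 2))
      stop("sphere ", s, " extends outside the grid")
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx <- xs[ix] - ctr[1]; dy <- ys[iy] - ctr[2]; dz <- zs[iz] - ctr[3]
    D <- sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
    sub <- vals[ix, iy, iz, drop = FALSE]
    # voxels possibly cut by the inner or outer shell interface
    bndmask <- abs(D - r_in) <= m3 | abs(D - r_out) <= m3
    sub[D <= r_in & !bndmask] <- spec$sphere_activity
    sub[D > r_in & D <= r_out & !bndmask] <- 0
    bnd <- which(bndmask)
    if (length(bnd)) {
      ai <- arrayInd(bnd, dim(D))
      px <- xs[ix][ai[, 1]] - ctr[1]
      py <- ys[iy][ai[, 2]] - ctr[2]
      pz <- zs[iz][ai[, 3]] - ctr[3]
      if (is.null(sub3)) {
        d <- sqrt(px^2 + py^2 + pz^2)
        f_in <- (d <= r_in) + 0
        f_wall <- (d > r_in & d <= r_out) + 0
      } else {
        f_in <- numeric(length(bnd)); f_wall <- numeric(length(bnd))
        for (k in seq_len(nrow(sub3))) {
          d <- sqrt((px + sub3[k, 1])^2 + (py + sub3[k, 2])^2 +
                    (pz + sub3[k, 3])^2)
          f_in <- f_in + (d <= r_in)
          f_wall <- f_wall + (d > r_in & d <= r_out)
        }
        f_in <- f_in / nrow(sub3); f_wall <- f_wall / nrow(sub3)
      }
      sub[bnd] <- f_in * spec$sphere_activity +
        (1 - f_in - f_wall) * sub[bnd]
    }
    vals[ix, iy, iz] <- sub
  }
  grid3d(vals, spacing, g$origin)
}
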