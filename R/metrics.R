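#' Segment a hot sphere with a background-corrected 50% isocontour
#'
#' The threshold is `T = B + 0.5 * (S_max - B)`, where `S_max` is the
#' hottest voxel inside a search ball of radius (nominal sphere radius +
#' `search_margin`) around the nominal centre and `B` the background
#' concentration; the returned mask is the 26-connected component of
#' voxels `>= T` containing the suprathreshold voxel nearest the centre.
#' `method = "plain"` drops the background correction (plain 50% of max)
#' for sensitivity checks.
#'
#' @param image a [grid3d()].
#' @param center nominal sphere centre (mm, world coordinates).
#' @param background_mean background activity concentration (kBq/mL).
#' @param nominal_diameter nominal inner diameter of the sphere (mm),
#'   used to size the search region.
#' @param search_margin extra search radius beyond the nominal radius (mm);
#'   keeps the maximum search from locking onto a neighbouring sphere.
#' @param method `"background_corrected"` (default) or `"plain"`.
#' @return integer vector of 1-based linear voxel indices into `image`.
#' @export
segment_sphere <- function(image, center, background_mean, nominal_diameter,
                           search_margin = 5,
                           method = c("background_corrected", "plain")) {
  stopifnot(inherits(image, "grid3d"))
  method <- match.arg(method)
  r_nom <- nominal_diameter / 2
  ball <- .ball_indices(image, center, r_nom + search_margin)
  if (!length(ball)) stop("search region contains no voxels")
  vals <- image$values[ball]
  s_max <- max(vals)
  if (s_max <= background_mean)
    stop("segmentation failed for sphere at (",
         paste(signif(center, 4), collapse = ", "),
         "): no voxel above the background level")
  thr <- if (method == "background_corrected")
    background_mean + 0.5 * (s_max - background_mean) else 0.5 * s_max

  # crop a box large enough to hold the component, then flood fill
  box_r <- r_nom + search_margin + 8
  d <- dim(image$values)
  lo <- pmax(.world_to_index(image, center - box_r), 1L)
  hi <- pmin(.world_to_index(image, center + box_r), d)
  sub <- image$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  supra <- sub >= thr
  if (!any(supra)) stop("no voxel reaches the segmentation threshold")
  # seed: suprathreshold voxel nearest the nominal centre
  xs <- axis_coords(image, 1)[lo[1]:hi[1]] - center[1]
  ys <- axis_coords(image, 2)[lo[2]:hi[2]] - center[2]
  zs <- axis_coords(image, 3)[lo[3]:hi[3]] - center[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  d2[!supra] <- Inf
  seed <- which.min(d2)
  comp <- .flood_fill26(supra, seed)
  ai <- arrayInd(which(comp), dim(sub))
  lin <- (lo[1] - 1L + ai[, 1]) +
    (lo[2] - 2L + ai[, 2]) * d[1] +
    (lo[3] - 2L + ai[, 3]) * d[1] * d[2]
  sort(lin)
}

# 26-connected component of TRUE voxels containing `seed` (linear index);
# frontier-expansion BFS on a zero-padded copy so offsets cannot wrap
.flood_fill26 <- function(mask, seed) {
  d <- dim(mask)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  ai <- arrayInd(seed, d) + 1L
  seedp <- ai[1] + (ai[2] - 1L) * dp[1] + (ai[3] - 1L) * dp[1] * dp[2]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  loff <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  visited <- array(FALSE, dp)
  visited[seedp] <- TRUE
  frontier <- seedp
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, loff, "+")))
    nb <- nb[pad[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

#' Place and evaluate uniform background VOIs
#'
#' Deterministically places `n` cylindrical volumes of interest in the
#' background compartment, each of at least `min_volume` mL, keeping at
#' least `clearance` mm from every sphere wall, the lung insert and the
#' body outline. The cylinders sit below the sphere plane (their top face
#' `clearance` mm below the deepest sphere surface) at fixed angular
#' positions, so repeated calls give identical masks.
#'
#' @param image a [grid3d()] of the phantom.
#' @param spec the [phantom_spec()] the image was generated from.
#' @param n number of VOIs.
#' @param min_volume minimum VOI volume in mL.
#' @param voi_radius cylinder radius in mm.
#' @param clearance minimum distance to spheres, lung and outline (mm).
#' @return an object of class `background_stats`: list with `voi_masks`
#'   (linear index vectors), `voi_volumes` (mL), `mean`, `sd` (pooled over
#'   the union), `cov_per_voi` and `cov_bg` (mean of the per-VOI CoVs).
#' @export
place_background_vois <- function(image, spec, n = 3L, min_volume = 61,
                                  voi_radius = 30, clearance = 15) {
  stopifnot(inherits(image, "grid3d"), inherits(spec, "phantom_spec"))
  dz <- image$spacing[3]
  h_mm <- dz * ceiling(min_volume * 1000 / (pi * voi_radius^2) / dz)
  r_sph_max <- max(spec$sphere_diameters) / 2 + spec$wall_thickness
  z_top <- -(r_sph_max + clearance)
  z_bot <- z_top - h_mm
  zs <- axis_coords(image, 3)
  if (z_bot < zs[1] - dz / 2)
    stop("grid too short axially to place background VOIs of ",
         min_volume, " mL")
  # radial position: clear of the lung on the inside, the outline outside
  r_center <- spec$lung_insert$diameter / 2 + clearance + voi_radius
  angles <- (pi / 2) + (seq_len(n) - 1) * 2 * pi / n
  cx <- spec$lung_insert$center[1] + r_center * cos(angles)
  cy <- spec$lung_insert$center[2] + r_center * sin(angles)
  # outline clearance check (capsule body): distance to boundary
  d_out <- spec$body$circle_radius -
    (.body_axis_dist(spec, cx, cy) + voi_radius)
  if (any(d_out < clearance))
    stop("background VOIs cannot keep ", clearance,
         " mm clearance from the body outline")
  xs <- axis_coords(image, 1); ys <- axis_coords(image, 2)
  inz <- which(zs >= z_bot & zs <= z_top)
  masks <- vector("list", n)
  d <- dim(image$values)
  for (i in seq_len(n)) {
    inplane <- which(outer((xs - cx[i])^2, (ys - cy[i])^2, "+") <=
                       voi_radius^2)
    ai <- arrayInd(inplane, d[1:2])
    lin <- as.vector(outer(ai[, 1] + (ai[, 2] - 1L) * d[1],
                           (inz - 1L) * d[1] * d[2], "+"))
    masks[[i]] <- sort(lin)
  }
  vv <- voxel_volume(image)
  vols <- vapply(masks, function(m) length(m) * vv / 1000, numeric(1))
  if (any(vols < min_volume))
    stop("voxelized VOI volume fell below ", min_volume, " mL")
  per_mean <- vapply(masks, function(m) mean(image$values[m]), numeric(1))
  per_sd <- vapply(masks, function(m) stats::sd(image$values[m]), numeric(1))
  cov_per_voi <- per_sd / per_mean
  allv <- image$values[unlist(masks)]
  structure(list(voi_masks = masks, voi_volumes = vols,
                 mean = mean(allv), sd = stats::sd(allv),
                 cov_per_voi = cov_per_voi, cov_bg = mean(cov_per_voi)),
            class = "background_stats")
}

#' Mean, maximum and peak recovery coefficients of a segmented sphere
#'
#' `rc_mean` and `rc_max` are the mask mean and maximum divided by the
#' true concentration. `rc_peak` uses the peak value: the mean over a
#' 12-mm-diameter ball centred on the hottest voxel, restricted to the
#' segmentation mask. In the phantom context SUV is synonymous with the
#' activity-concentration ratio, so no body-weight normalization appears.
#'
#' @param image a [grid3d()].
#' @param mask linear voxel indices from [segment_sphere()].
#' @param true_activity true sphere concentration (kBq/mL, > 0).
#' @param peak_diameter diameter of the peak-averaging ball (mm).
#' @return list with `rc_mean`, `rc_max`, `rc_peak` and the underlying
#'   `measured_mean`, `measured_max`, `measured_peak`.
#' @export
recovery_coefficients <- function(image, mask, true_activity,
                                  peak_diameter = 12) {
  stopifnot(inherits(image, "grid3d"), length(mask) > 0)
  if (true_activity <= 0) stop("true_activity must be > 0")
  vals <- image$values[mask]
  m_mean <- mean(vals); m_max <- max(vals)
  argmax <- mask[which.max(vals)]
  ctr <- .index_to_world(image, argmax)[1, ]
  ball <- .ball_indices(image, ctr, peak_diameter / 2, clip = TRUE)
  peak_idx <- intersect(ball, mask)
  m_peak <- mean(image$values[peak_idx])
  list(rc_mean = m_mean / true_activity,
       rc_max = m_max / true_activity,
       rc_peak = m_peak / true_activity,
       measured_mean = m_mean, measured_max = m_max, measured_peak = m_peak)
}

#' Contrast recovery coefficient (NEMA NU 2-2018 hot-sphere definition)
#'
#' `CRC = 100 * (sphere_mean / bg_mean - 1) / (true_sphere / true_bg - 1)`
#' in percent.
#' @param sphere_mean measured sphere mean (kBq/mL).
#' @param bg_mean measured background mean (kBq/mL, > 0).
#' @param true_sphere,true_bg true concentrations (kBq/mL), with
#'   `true_sphere > true_bg > 0`.
#' @return CRC in percent.
#' @export
contrast_recovery <- function(sphere_mean, bg_mean, true_sphere, true_bg) {
  if (true_bg <= 0 || true_sphere <= true_bg)
    stop("need true_sphere > true_bg > 0 (hot-sphere contrast undefined ",
         "at a true ratio of 1)")
  if (bg_mean <= 0) stop("bg_mean must be > 0")
  100 * (sphere_mean / bg_mean - 1) / (true_sphere / true_bg - 1)
}

#' Contrast-to-noise ratio
#'
#' `(sphere_mean - bg_mean) / bg_sd`.
#' @param sphere_mean measured sphere mean (kBq/mL).
#' @param bg_mean measured background mean (kBq/mL).
#' @param bg_sd standard deviation of the background compartment
#'   (kBq/mL, > 0).
#' @return dimensionless CNR.
#' @export
contrast_noise_ratio <- function(sphere_mean, bg_mean, bg_sd) {
  if (bg_sd <= 0)
    stop("bg_sd must be > 0; noiseless images have no defined CNR")
  (sphere_mean - bg_mean) / bg_sd
}

#' Relative count error in the lung insert
#'
#' Mean over a 30-mm-diameter cylindrical VOI on the lung-insert axis,
#' spanning the sphere plane +/- `half_height` mm, relative to the
#' background VOI mean, in percent. A cold insert imaged perfectly gives
#' 0%; blur (spill-in) and scatter push it up.
#'
#' @param image a [grid3d()].
#' @param spec the [phantom_spec()].
#' @param bg a `background_stats` object from [place_background_vois()].
#' @param voi_diameter lung VOI diameter (mm).
#' @param half_height half the axial extent of the VOI (mm).
#' @return percent count error (list-free scalar).
#' @export
lung_count_error <- function(image, spec, bg, voi_diameter = 30,
                             half_height = 30) {
  stopifnot(inherits(image, "grid3d"), inherits(spec, "phantom_spec"),
            inherits(bg, "background_stats"))
  zs <- axis_coords(image, 3)
  if (-half_height < zs[1] - image$spacing[3] / 2 ||
      half_height > zs[length(zs)] + image$spacing[3] / 2)
    stop("lung VOI exits the grid axially")
  xs <- axis_coords(image, 1); ys <- axis_coords(image, 2)
  cx <- spec$lung_insert$center[1]; cy <- spec$lung_insert$center[2]
  inplane <- which(outer((xs - cx)^2, (ys - cy)^2, "+") <=
                     (voi_diameter / 2)^2)
  inz <- which(abs(zs) <= half_height)
  d <- dim(image$values)
  ai <- arrayInd(inplane, d[1:2])
  lin <- as.vector(outer(ai[, 1] + (ai[, 2] - 1L) * d[1],
                         (inz - 1L) * d[1] * d[2], "+"))
  100 * mean(image$values[lin]) / bg$mean
}
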