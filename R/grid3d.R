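#' 3D activity-concentration grid
#'
#' A `grid3d` is the package's image container: a 3D array of activity
#' concentration values (kBq/mL) together with the voxel spacing (mm) and
#' the world coordinate of the centre of voxel `[1, 1, 1]` (mm). World
#' coordinates refer to voxel centres; index `(i, j, k)` maps to
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values 3D numeric array of activity concentrations (kBq/mL).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre. Defaults to placing the grid centre at the world origin.
#' @return An object of class `grid3d` with fields `values`, `spacing`,
#'   `origin`.
#' @export
grid3d <- function(values, spacing, origin = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  if (is.null(origin))
    origin <- -(dim(values) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  values in [%.4g, %.4g] kBq/mL\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of a grid in cubic millimetres
#' @param grid a [grid3d()].
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' World coordinates of the voxel centres along one axis
#' @param grid a [grid3d()].
#' @param axis integer 1, 2 or 3.
#' @return numeric vector of voxel-centre positions (mm).
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(dim(grid$values)[axis]) - 1) * grid$spacing[axis]
}

#' Total activity in a grid
#'
#' Sum of `values * voxel_volume`, i.e. the image-integrated activity in
#' kBq * mm^3 / mL. Used to scale Poisson count rates and to check that
#' blurring conserves activity.
#' @param grid a [grid3d()].
#' @return scalar.
#' @export
activity_integral <- function(grid) sum(grid$values) * voxel_volume(grid)

# nearest voxel index (1-based integer triple) to a world point
.world_to_index <- function(grid, xyz) {
  idx <- round((as.numeric(xyz) - grid$origin) / grid$spacing) + 1
  pmin(pmax(as.integer(idx), 1L), dim(grid$values))
}

# world coordinates (n x 3) of 1-based linear voxel indices
.index_to_world <- function(grid, lin) {
  ai <- arrayInd(lin, dim(grid$values))
  sweep(sweep(ai - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

# linear indices of voxels whose centres lie within `radius` of `center`;
# errors if the bounding box leaves the grid and `clip = FALSE`
.ball_indices <- function(grid, center, radius, clip = FALSE) {
  d <- dim(grid$values)
  lo <- numeric(3); hi <- numeric(3)
  for (a in 1:3) {
    co <- axis_coords(grid, a)
    lo[a] <- (center[a] - radius - grid$origin[a]) / grid$spacing[a] + 1
    hi[a] <- (center[a] + radius - grid$origin[a]) / grid$spacing[a] + 1
  }
  if (!clip && (any(lo < 0.5) || any(hi > d + 0.5)))
    stop("region of radius ", radius, " mm around (",
         paste(signif(center, 4), collapse = ", "), ") exits the grid")
  i1 <- pmax(1L, as.integer(ceiling(lo))); i2 <- pmin(d, as.integer(floor(hi)))
  xs <- axis_coords(grid, 1)[i1[1]:i2[1]] - center[1]
  ys <- axis_coords(grid, 2)[i1[2]:i2[2]] - center[2]
  zs <- axis_coords(grid, 3)[i1[3]:i2[3]] - center[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  keep <- which(d2 <= radius^2)
  ai <- arrayInd(keep, c(nx, ny, nz))
  lin <- (i1[1] - 1L + ai[, 1]) +
    (i1[2] - 2L + ai[, 2]) * d[1] +
    (i1[3] - 2L + ai[, 3]) * d[1] * d[2]
  lin
}

#' Write a grid to a NIfTI-1 file
#'
#' Intensities are written as-is (kBq/mL); spacing goes into `pixdim` and
#' the origin into the sform/qform translation.
#' @param grid a [grid3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_grid_nifti <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  xf <- diag(c(grid$spacing, 1))
  xf[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a grid from a NIfTI-1 file
#' @param path a NIfTI file written by [write_grid_nifti()] or compatible.
#' @return a [grid3d()].
#' @export
read_grid_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  grid3d(vals, spacing = sp, origin = xf[1:3, 4])
}
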