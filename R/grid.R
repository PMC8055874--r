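#' Define a regular 3-D image grid
#'
#' The computational domain matches the imaging domain voxel for voxel:
#' isotropic in-plane spacing with (typically larger) slice spacing, no
#' resampling or refinement. Voxel indices are 0-based in world-coordinate
#' conversions: world = origin + index * spacing.
#'
#' @param shape integer vector of length 3, voxels per axis (>= 1).
#' @param spacing numeric vector of length 3, voxel edge lengths in mm (> 0).
#' @param origin numeric vector of length 3, world coordinate of voxel
#'   (0, 0, 0) in mm.
#' @return An object of class `image_grid` with fields `shape`, `spacing`,
#'   `origin`.
#' @export
#' @examples
#' g <- image_grid(c(64, 64, 8), c(1, 1, 5))
#' voxel_volume(g)  # 5 mm^3
image_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L) || anyNA(shape))
    stop("`shape` must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive lengths (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite lengths (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @rdname image_grid
#' @param grid an `image_grid`.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
format.image_grid <- function(x, ...) {
  sprintf("image_grid(%s; %s mm)", paste(x$shape, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"))
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

## world coordinates (mm) of every voxel centre along one axis
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

## array of distances (mm) from a world-space point, on the grid
distance_field <- function(grid, center) {
  cx <- axis_coords(grid, 1) - center[1]
  cy <- axis_coords(grid, 2) - center[2]
  cz <- axis_coords(grid, 3) - center[3]
  dx2 <- array(cx^2, grid$shape)
  dy2 <- aperm(array(cy^2, grid$shape[c(2, 1, 3)]), c(2, 1, 3))
  dz2 <- aperm(array(cz^2, grid$shape[c(3, 1, 2)]), c(2, 3, 1))
  sqrt(dx2 + dy2 + dz2)
}

## normalized ellipsoidal radius field: 1 on the ellipsoid surface
ellipsoid_radius_field <- function(grid, center, semi_axes) {
  cx <- (axis_coords(grid, 1) - center[1]) / semi_axes[1]
  cy <- (axis_coords(grid, 2) - center[2]) / semi_axes[2]
  cz <- (axis_coords(grid, 3) - center[3]) / semi_axes[3]
  dx2 <- array(cx^2, grid$shape)
  dy2 <- aperm(array(cy^2, grid$shape[c(2, 1, 3)]), c(2, 1, 3))
  dz2 <- aperm(array(cz^2, grid$shape[c(3, 1, 2)]), c(2, 3, 1))
  sqrt(dx2 + dy2 + dz2)
}

check_field <- function(x, grid, what = "field") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("%s must be a 3-D array", what))
  if (!identical(dim(x), as.integer(grid$shape)))
    stop(sprintf("%s has dim %s but grid shape is %s", what,
                 paste(dim(x), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  invisible(x)
}

zeros_like <- function(grid) array(0, grid$shape)
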