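#' Define a voxel grid
#'
#' A voxel grid is the common coordinate frame for all volumes handled by the
#' package: activity maps, attenuation maps and reconstructions.  The world
#' coordinate of the centre of voxel index `(1,1,1)` is `origin` (mm); the
#' world-to-index mapping is affine and invertible.  By default the grid is
#' centred on the world origin with the intrinsic SPECT voxel pitch of
#' 2.46 mm.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param spacing Numeric vector of length 3 (or scalar), mm per voxel.
#' @param origin World coordinate (mm) of the centre of the first voxel;
#'   `NULL` (default) centres the grid on the origin.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(64, 64, 64), spacing = 2.46)
#' grid_extent(g)
voxel_grid <- function(shape, spacing = 2.46, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be positive on all axes")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Physical extent of a grid
#'
#' @param grid A [voxel_grid()].
#' @return Length-3 numeric vector, full extent in mm per axis.
#' @export
grid_extent <- function(grid) grid$shape * grid$spacing

#' Voxel volume of a grid
#'
#' @param grid A [voxel_grid()].
#' @param unit `"mm3"` or `"mL"`.
#' @return Scalar voxel volume.
#' @export
voxel_volume <- function(grid, unit = c("mm3", "mL")) {
  unit <- match.arg(unit)
  v <- prod(grid$spacing)
  if (unit == "mL") v / 1000 else v
}

#' World coordinates of voxel centres along each axis
#'
#' @param grid A [voxel_grid()].
#' @return List of three numeric vectors (mm).
#' @export
grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

#' Convert world coordinates (mm) to fractional voxel indices (1-based)
#'
#' @param grid A [voxel_grid()].
#' @param xyz Numeric vector of length 3 or matrix with 3 columns.
#' @return Same shape as `xyz`, fractional 1-based indices.
#' @export
world_to_index <- function(grid, xyz) {
  if (is.matrix(xyz))
    sweep(sweep(xyz, 2, grid$origin), 2, grid$spacing, "/") + 1
  else (xyz - grid$origin) / grid$spacing + 1
}

#' Convert (fractional) voxel indices to world coordinates (mm)
#'
#' @inheritParams world_to_index
#' @param idx 1-based indices, vector of length 3 or matrix with 3 columns.
#' @export
index_to_world <- function(grid, idx) {
  if (is.matrix(idx))
    sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  else (idx - 1) * grid$spacing + grid$origin
}

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# world-coordinate arrays of all voxel centres, offset by `off` (mm)
grid_coord_arrays <- function(grid, off = c(0, 0, 0)) {
  ax <- grid_axes(grid)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  list(
    x = array(ax[[1]] + off[1], dim = grid$shape),
    y = array(rep(ax[[2]] + off[2], each = nx), dim = grid$shape),
    z = array(rep(ax[[3]] + off[3], each = nx * ny), dim = grid$shape)
  )
}
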