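#' Scalar 3D/4D image with anisotropic physical spacing
#'
#' The universal raster container of the package: a numeric array indexed
#' `(z, y, x)` (single time point) or `(t, z, y, x)` (time series) together
#' with the physical voxel pitch in micrometres and an optional channel
#' name. Voxel indices are 0-based in all public interfaces and the voxel
#' `(0, 0, 0)` centre sits at the physical origin.
#'
#' @param values numeric array, 3D `(z, y, x)` or 4D `(t, z, y, x)`, finite.
#' @param spacing a [voxel_spacing()] (um per voxel along z, y, x).
#' @param channel optional channel name (e.g. `"membrane"`).
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), voxel_spacing(0.8, 0.26, 0.26))
#' dim(g$values)
voxel_grid <- function(values, spacing, channel = NA_character_) {
  if (!is.array(values) || !(length(dim(values)) %in% c(3L, 4L)))
    stop("values must be a 3D (z,y,x) or 4D (t,z,y,x) array")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(values))) stop("voxel values must be finite")
  structure(list(values = values,
                 spacing = as_voxel_spacing(spacing),
                 channel = as.character(channel)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  ax <- if (length(d) == 4L) "(t,z,y,x)" else "(z,y,x)"
  cat(sprintf("<voxel_grid%s> %s %s, spacing (%.3g, %.3g, %.3g) um, range [%.4g, %.4g]\n",
              if (is.na(x$channel)) "" else paste0(" ", x$channel),
              paste(d, collapse = " x "), ax,
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

is_time_series <- function(grid) length(dim(grid$values)) == 4L

#' Extract one time point from a 4D grid
#'
#' @param grid a [voxel_grid()].
#' @param frame 0-based frame index.
#' @return A 3D [voxel_grid()].
#' @export
get_frame <- function(grid, frame) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is_time_series(grid)) {
    if (frame != 0L) stop("grid has a single time point; frame must be 0")
    return(grid)
  }
  nt <- dim(grid$values)[1L]
  if (frame < 0L || frame >= nt) stop("frame out of range [0, ", nt - 1L, "]")
  v <- grid$values[frame + 1L, , , , drop = TRUE]
  dim(v) <- dim(grid$values)[-1L]
  voxel_grid(v, grid$spacing, grid$channel)
}

#' Physical volume of one voxel in um^3
#' @param grid a [voxel_grid()] or [voxel_spacing()].
#' @return numeric scalar, `dz * dy * dx`.
#' @export
voxel_volume <- function(grid) {
  s <- if (inherits(grid, "voxel_grid")) grid$spacing else as_voxel_spacing(grid)
  prod(unclass(s))
}

# internal: coerce mask-like input (voxel_grid or array) to a logical array
as_mask_array <- function(mask) {
  v <- if (inherits(mask, "voxel_grid")) mask$values else mask
  if (!is.array(v) || length(dim(v)) != 3L) stop("mask must be a 3D array")
  array(v >= 0.5, dim(v))
}

grid_spacing <- function(grid, spacing = NULL) {
  if (inherits(grid, "voxel_grid")) grid$spacing
  else if (!is.null(spacing)) as_voxel_spacing(spacing)
  else stop("spacing must be supplied when the input is a bare array")
}

# internal: physical coordinate vectors per axis for a 3D array
axis_coords <- function(d, spacing) {
  list(z = (seq_len(d[1L]) - 1L) * spacing[1L],
       y = (seq_len(d[2L]) - 1L) * spacing[2L],
       x = (seq_len(d[3L]) - 1L) * spacing[3L])
}

# internal: centroid of a logical 3D mask in physical um (z,y,x)
mask_centroid <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  c(mean((idx[, 1L] - 1L) * spacing[1L]),
    mean((idx[, 2L] - 1L) * spacing[2L]),
    mean((idx[, 3L] - 1L) * spacing[3L]))
}
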