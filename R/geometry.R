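#' Construct a 3D point in physical coordinates
#'
#' Points are stored as named numeric vectors in `(z, y, x)` order, in
#' micrometres. All geometry in this package happens in physical space so
#' that angles measured on anisotropic stacks (e.g. 0.8 um z-steps versus
#' 0.26 um xy pixels) are unbiased.
#'
#' @param z,y,x finite physical coordinates in micrometres.
#' @return A named numeric vector of class `point3d`.
#' @export
#' @examples
#' point3d(1, 2, 3)
point3d <- function(z, y, x) {
  p <- c(z = as.numeric(z), y = as.numeric(y), x = as.numeric(x))
  if (!all(is.finite(p))) stop("point3d: all coordinates must be finite")
  class(p) <- "point3d"
  p
}

as_point3d <- function(p) {
  if (inherits(p, "point3d")) return(p)
  p <- as.numeric(p)
  if (length(p) != 3L) stop("a 3D point needs exactly 3 coordinates (z, y, x)")
  point3d(p[1L], p[2L], p[3L])
}

#' Construct a division (or cue) axis from two poles
#'
#' An axis is an ordered pair of physical-space points: apical pole `a` to
#' basal pole `b`. The direction `b - a` is the apical-to-basal division
#' direction.
#'
#' @param a apical pole, a [point3d()] or `(z, y, x)` numeric vector (um).
#' @param b basal pole, same format.
#' @return An object of class `axis3d` with elements `a` and `b`.
#' @export
#' @examples
#' ax <- axis3d(c(0, 0, 0), c(0, 0, 4))
#' axis_length(ax)
axis3d <- function(a, b) {
  a <- as_point3d(a)
  b <- as_point3d(b)
  if (sqrt(sum((unclass(b) - unclass(a))^2)) == 0)
    stop("degenerate axis: poles coincide")
  structure(list(a = a, b = b), class = "axis3d")
}

#' @export
print.axis3d <- function(x, ...) {
  cat(sprintf("<axis3d> apical (%.3f, %.3f, %.3f) -> basal (%.3f, %.3f, %.3f) um, |v| = %.3f um\n",
              x$a[1], x$a[2], x$a[3], x$b[1], x$b[2], x$b[3], axis_length(x)))
  invisible(x)
}

axis_vec <- function(axis) unclass(axis$b) - unclass(axis$a)

#' Length of an axis in micrometres
#' @param axis an [axis3d()].
#' @return numeric scalar, `sqrt(sum((b - a)^2))`.
#' @export
axis_length <- function(axis) sqrt(sum(axis_vec(axis)^2))

#' Unit direction vector of an axis
#'
#' @param axis an [axis3d()].
#' @return A [point3d()] of magnitude 1 (within 1e-12) pointing from the
#'   apical to the basal pole.
#' @export
#' @examples
#' unit_vector(axis3d(c(0, 0, 0), c(0, 0, 2)))
unit_vector <- function(axis) {
  v <- axis_vec(axis)
  m <- sqrt(sum(v^2))
  if (m == 0) stop("degenerate axis: zero magnitude")
  u <- v / m
  point3d(u[1L], u[2L], u[3L])
}

#' 3D angle between two axes
#'
#' The inter-axis angle is `arccos(v1 . v2 / (|v1| |v2|))` with
#' `v = b - a` and the standard componentwise dot product, reported in
#' degrees on the unfolded range \[0, 180\]. The cosine is clamped to
#' \[-1, 1\] before `acos` so floating-point rounding can never produce NaN.
#'
#' @param axis1,axis2 [axis3d()] objects with nonzero magnitude.
#' @return Angle in degrees in \[0, 180\].
#' @export
#' @examples
#' axis_angle(axis3d(c(0, 0, 0), c(0, 0, 1)),
#'            axis3d(c(0, 0, 0), c(0, 1, 1)))  # 45
axis_angle <- function(axis1, axis2) {
  v1 <- axis_vec(axis1)
  v2 <- axis_vec(axis2)
  m1 <- sqrt(sum(v1^2))
  m2 <- sqrt(sum(v2^2))
  if (m1 == 0 || m2 == 0) stop("degenerate axis: zero magnitude")
  ct <- sum(v1 * v2) / (m1 * m2)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' Voxel spacing in micrometres per voxel
#'
#' @param dz,dy,dx strictly positive voxel pitches along z, y, x (um).
#' @return A named numeric vector of class `voxel_spacing`.
#' @export
#' @examples
#' voxel_spacing(0.8, 0.26, 0.26)
voxel_spacing <- function(dz, dy, dx) {
  s <- c(dz = as.numeric(dz), dy = as.numeric(dy), dx = as.numeric(dx))
  if (!all(is.finite(s)) || any(s <= 0))
    stop("voxel_spacing: all pitches must be strictly positive and finite")
  class(s) <- "voxel_spacing"
  s
}

as_voxel_spacing <- function(s) {
  if (inherits(s, "voxel_spacing")) return(s)
  s <- as.numeric(s)
  if (length(s) != 3L) stop("spacing needs exactly 3 values (dz, dy, dx)")
  voxel_spacing(s[1L], s[2L], s[3L])
}

#' Convert 0-based voxel indices to physical coordinates
#'
#' Uses the 0-based voxel-centre convention: voxel `(0, 0, 0)` sits at the
#' physical origin and voxel `(i, j, k)` at `(i dz, j dy, k dx)` um.
#'
#' @param index integer triple `(z, y, x)` (0-based) or an n x 3 matrix of
#'   such triples.
#' @param spacing a [voxel_spacing()] (or `(dz, dy, dx)` numeric).
#' @return A [point3d()] for a single triple, or an n x 3 matrix (um).
#' @export
#' @examples
#' voxel_to_physical(c(10, 20, 30), voxel_spacing(0.8, 0.26, 0.26))
voxel_to_physical <- function(index, spacing) {
  spacing <- as_voxel_spacing(spacing)
  if (is.matrix(index)) {
    if (ncol(index) != 3L) stop("index matrix must have 3 columns (z, y, x)")
    if (any(index < 0)) stop("voxel indices must be nonnegative")
    out <- sweep(index, 2L, unclass(spacing), `*`)
    colnames(out) <- c("z", "y", "x")
    return(out)
  }
  index <- as.numeric(index)
  if (length(index) != 3L) stop("index must be a (z, y, x) triple")
  if (any(index < 0)) stop("voxel indices must be nonnegative")
  p <- index * unclass(spacing)
  point3d(p[1L], p[2L], p[3L])
}
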