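#' Segment one cell from a membrane-marker stack
#'
#' Membrane markers label cell boundaries, so a cell appears as a bright
#' shell around a dark interior. The segmenter blurs the stack, thresholds
#' it (Otsu by default), applies a light morphological closing, fills the
#' shell interior in 3D, and then assigns shell voxels to the interior they
#' are closest to (against the outside background and any other enclosed
#' interior), which places the cell boundary at the membrane midline. The
#' component containing `seed_point` is returned; without a seed the
#' largest interior wins.
#'
#' @param grid 3D membrane-channel [voxel_grid()].
#' @param seed_point optional physical `(z, y, x)` point (um) inside the
#'   target cell.
#' @param threshold optional absolute intensity threshold; default Otsu.
#' @param blur_sigma_voxels Gaussian preblur in voxels.
#' @param closing_radius_um physical radius of the morphological closing.
#' @param min_interior_voxels interiors smaller than this are treated as
#'   noise and ignored.
#' @return A logical-valued [voxel_grid()] mask (channel `"mask"`).
#' @export
segment_cell <- function(grid, seed_point = NULL, threshold = NULL,
                         blur_sigma_voxels = c(0.8, 0.8, 0.8),
                         closing_radius_um = 0.4,
                         min_interior_voxels = 30L) {
  stopifnot(inherits(grid, "voxel_grid"))
  refuse_display_only(grid)
  v <- grid$values
  if (length(dim(v)) != 3L) stop("segment_cell expects a single 3D frame")
  sp <- unclass(grid$spacing)
  dims <- dim(v)
  b <- gaussian_blur_3d(v, blur_sigma_voxels)
  if (is.null(threshold)) {
    lo <- min(b); hi <- max(b)
    if (hi <= lo) stop("blank image: no intensity variation to threshold")
    nrm <- (b - lo) / (hi - lo)
    thr_n <- EBImage::otsu(matrix(nrm, ncol = 1L), range = c(0, 1))
    threshold <- lo + thr_n * (hi - lo)
  }
  B <- array(b >= threshold, dims)
  if (!any(B)) stop("empty mask: threshold removed everything")
  # crop to the thresholded bounding box (+margin) before the morphology
  # stages; everything below runs on the cropped volume
  marg <- pmax(ceiling(closing_radius_um / sp), 1L) + 1L
  bidx <- which(B, arr.ind = TRUE)
  lo_b <- pmax(apply(bidx, 2L, min) - marg, 1L)
  hi_b <- pmin(apply(bidx, 2L, max) + marg, dims)
  full_dims <- dims
  crop <- list(lo_b[1L]:hi_b[1L], lo_b[2L]:hi_b[2L], lo_b[3L]:hi_b[3L])
  B <- B[crop[[1L]], crop[[2L]], crop[[3L]], drop = FALSE]
  dims <- dim(B)
  if (closing_radius_um > 0) {
    dil <- array(.cpp_edt3d(B, dim(B), sp) <= closing_radius_um, dims)
    B <- array(.cpp_edt3d(!dil, dim(dil), sp) > closing_radius_um, dims)
  }
  FF <- array(.cpp_fill_holes3d(B, dims), dims)
  interiors <- FF & !B
  lab <- .cpp_label3d(interiors, dims)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_interior_voxels)
  if (length(keep) == 0L)
    stop("empty mask: no enclosed interior found (is this a membrane channel?)")

  if (!is.null(seed_point)) {
    p <- as.numeric(seed_point)
    vox <- pmin(pmax(round(p / sp) + 1L - (lo_b - 1L), 1L), dims)
    lab0 <- lab[vox[1L], vox[2L], vox[3L]]
    if (!(lab0 %in% keep)) {
      # tolerate a seed that lands on the shell: search a small neighbourhood
      win <- 2L
      zr <- max(1L, vox[1L] - win):min(dims[1L], vox[1L] + win)
      yr <- max(1L, vox[2L] - win):min(dims[2L], vox[2L] + win)
      xr <- max(1L, vox[3L] - win):min(dims[3L], vox[3L] + win)
      near <- lab[zr, yr, xr]
      cand <- unique(near[near %in% keep])
      if (length(cand) == 0L) stop("seed point lies outside any cell interior")
      lab0 <- cand[1L]
    }
  } else {
    lab0 <- keep[which.max(sizes[keep])]
  }
  I0 <- lab == lab0
  others <- lab > 0L & lab != lab0 & array(lab %in% keep, dims)
  d0 <- .cpp_edt3d(I0, dims, sp)
  dout <- .cpp_edt3d(!FF, dims, sp)
  shell <- FF & !interiors
  # strict comparison against other interiors so that independently
  # segmented touching cells partition the shared membrane without overlap
  cell <- I0 | (shell & d0 <= dout &
                  (if (any(others)) d0 < .cpp_edt3d(others, dims, sp) else TRUE))
  cell <- array(cell, dims)
  lab2 <- .cpp_label3d(cell, dims)
  main <- which.max(tabulate(lab2[lab2 > 0L]))
  cell <- array(lab2 == main, dims)
  out <- array(FALSE, full_dims)
  out[crop[[1L]], crop[[2L]], crop[[3L]]] <- cell
  voxel_grid(out, grid$spacing, "mask")
}

#' Detect point-like spots (e.g. centrosomes) in a channel
#'
#' Iterative peak picking: the global maximum is refined to an
#' intensity-weighted centroid over a small window, then suppressed within
#' `min_separation_um` before the next peak is taken.
#'
#' @param grid 3D [voxel_grid()] of the spot channel.
#' @param n number of spots to return.
#' @param min_separation_um minimum distance between spots, um.
#' @param window_um half-size of the centroid refinement window, um.
#' @return An `n x 3` matrix of physical `(z, y, x)` positions (um),
#'   ordered by decreasing peak intensity.
#' @export
detect_spots <- function(grid, n = 2L, min_separation_um = 1.5,
                         window_um = 0.6) {
  stopifnot(inherits(grid, "voxel_grid"))
  refuse_display_only(grid)
  v <- grid$values
  if (length(dim(v)) != 3L) stop("detect_spots expects a single 3D frame")
  sp <- unclass(grid$spacing)
  dims <- dim(v)
  w <- gaussian_blur_3d(v, pmax(0.15 / sp, 0.5))
  bg <- stats::median(w)
  out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("z", "y", "x")))
  cw <- pmax(round(window_um / sp), 1L)
  for (k in seq_len(n)) {
    i <- which.max(w)
    vox <- arrayInd(i, dims)
    zr <- max(1L, vox[1L] - cw[1L]):min(dims[1L], vox[1L] + cw[1L])
    yr <- max(1L, vox[2L] - cw[2L]):min(dims[2L], vox[2L] + cw[2L])
    xr <- max(1L, vox[3L] - cw[3L]):min(dims[3L], vox[3L] + cw[3L])
    blk <- pmax(w[zr, yr, xr] - bg, 0)
    if (sum(blk) <= 0) stop("no spot found (flat channel)")
    gz <- (zr - 1L) * sp[1L]; gy <- (yr - 1L) * sp[2L]; gx <- (xr - 1L) * sp[3L]
    tot <- sum(blk)
    out[k, ] <- c(sum(apply(blk, 1L, sum) * gz),
                  sum(apply(blk, 2L, sum) * gy),
                  sum(apply(blk, 3L, sum) * gx)) / tot
    # suppress this peak
    d2 <- dist2_field(dims, sp, out[k, ])
    w[d2 <= min_separation_um^2] <- -Inf
  }
  out
}
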