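#' One measured mitosis
#'
#' @param nb_id neuroblast identifier.
#' @param cycle 1-based cycle index within the series.
#' @param axis the measured apical-to-basal [axis3d()].
#' @param method `"shape"`, `"centrosome"` or `"landmarks"`.
#' @param telophase_frame,rounding_frame 0-based frame indices (may be NA).
#' @param qc character vector of QC flags (e.g. `"lobe-ambiguity"`).
#' @return An object of class `division_record`.
#' @export
division_record <- function(nb_id, cycle, axis,
                            method = c("shape", "centrosome", "landmarks"),
                            telophase_frame = NA_integer_,
                            rounding_frame = NA_integer_,
                            qc = character()) {
  stopifnot(inherits(axis, "axis3d"))
  method <- match.arg(method)
  structure(list(nb_id = nb_id, cycle = as.integer(cycle), axis = axis,
                 method = method,
                 telophase_frame = telophase_frame,
                 rounding_frame = rounding_frame,
                 qc = qc),
            class = "division_record")
}

#' @export
print.division_record <- function(x, ...) {
  cat(sprintf("<division_record> nb %s cycle %d [%s]%s\n", x$nb_id, x$cycle,
              x$method,
              if (length(x$qc)) paste0(" qc: ", paste(x$qc, collapse = ",")) else ""))
  print(x$axis)
  invisible(x)
}

# deepest interior minimum of a cross-section profile; returns its position
# or NULL when the profile is effectively unimodal (no neck)
profile_neck <- function(a, mids, neck_ratio = 0.85) {
  n <- length(a)
  if (n < 5L) return(NULL)
  best <- NULL; best_depth <- 0
  run_max_l <- cummax(a)
  run_max_r <- rev(cummax(rev(a)))
  for (i in 2:(n - 1L)) {
    flank <- min(run_max_l[i - 1L], run_max_r[i + 1L])
    depth <- flank - a[i]
    if (depth > best_depth) { best_depth <- depth; best <- i }
  }
  if (is.null(best)) return(NULL)
  flank <- min(run_max_l[best - 1L], run_max_r[best + 1L])
  if (flank <= 0 || a[best] > neck_ratio * flank) return(NULL)
  mids[best]
}

# cross-section area profile of a mask along direction v (unit, (z,y,x)),
# by resampling on planes perpendicular to v through `centre`
section_profile <- function(m, sp, centre, v, t_half, r_half,
                            dt = 0.26, da = 0.4) {
  a1 <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(v[2L] * a1[3L] - v[3L] * a1[2L],
          v[3L] * a1[1L] - v[1L] * a1[3L],
          v[1L] * a1[2L] - v[2L] * a1[1L])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2L] * e1[3L] - v[3L] * e1[2L],
          v[3L] * e1[1L] - v[1L] * e1[3L],
          v[1L] * e1[2L] - v[2L] * e1[1L])
  tg <- seq(-t_half, t_half, by = dt)
  ag <- seq(-r_half, r_half, by = da)
  plane <- expand.grid(a = ag, b = ag)
  counts <- numeric(length(tg))
  for (k in seq_along(tg)) {
    p <- matrix(centre, nrow(plane), 3L, byrow = TRUE) +
      tg[k] * matrix(v, nrow(plane), 3L, byrow = TRUE) +
      outer(plane$a, e1) + outer(plane$b, e2)
    counts[k] <- sum(.cpp_interp3(as.numeric(m), as.integer(dim(m)), sp, p) >= 0.5)
  }
  list(t = tg, counts = counts)
}

#' Division axis from the telophase cell shape
#'
#' Automates the three-step pole-finding procedure for membrane-marker
#' stacks: (1) the in-plane long axis of the cell is taken from the first
#' principal axis of the mask's xy maximum-projection (or from a
#' user-supplied bisecting line, replacing a manually drawn axis); (2) the
#' stack is resampled on the plane containing that line and the z axis and
#' the z coordinates of the two pole extremities along the long axis are
#' read off this orthogonal slice; (3) on the z slices so identified, the
#' in-plane extremal points along the long axis give the `(x, y)` of each
#' pole. The apical pole is assigned to the larger-volume lobe (lobes split
#' at the neck, the minimal cross-section perpendicular to the long axis);
#' ties in extremal voxels are resolved by taking their centroid.
#'
#' @param mask binary telophase [voxel_grid()] (two-lobed shape).
#' @param bisect_line optional 2 x 3 matrix of physical `(z, y, x)` points
#'   defining the bisecting line (only its xy direction is used).
#' @param neck_ratio neck depth criterion: the minimal cross-section must
#'   be below this fraction of the smaller flanking maximum, else the
#'   shape is judged single-lobed.
#' @param lobe_tol relative lobe-volume difference below which apical
#'   assignment is flagged `"lobe-ambiguity"`.
#' @return An [axis3d()] (apical to basal, um) with attribute `qc`
#'   (character flags) and attribute `lobe_volumes` (um^3, apical first).
#' @export
find_poles_from_shape <- function(mask, bisect_line = NULL,
                                  neck_ratio = 0.85, lobe_tol = 0.10) {
  stopifnot(inherits(mask, "voxel_grid"))
  m <- as_mask_array(mask$values)
  sp <- unclass(mask$spacing)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  zc <- (idx[, 1L] - 1L) * sp[1L]
  yc <- (idx[, 2L] - 1L) * sp[2L]
  xc <- (idx[, 3L] - 1L) * sp[3L]

  # step 1: in-plane long axis
  if (!is.null(bisect_line)) {
    bl <- as.matrix(bisect_line)
    if (nrow(bl) != 2L || ncol(bl) != 3L)
      stop("bisect_line must be a 2 x 3 matrix of (z, y, x) points")
    u <- c(bl[2L, 2L] - bl[1L, 2L], bl[2L, 3L] - bl[1L, 3L]) # (y, x)
    if (sqrt(sum(u^2)) == 0) stop("degenerate bisecting line")
    method_qc <- character()
  } else {
    proj <- apply(m, c(2L, 3L), max)
    pidx <- which(proj > 0, arr.ind = TRUE)
    pc <- cbind((pidx[, 1L] - 1L) * sp[2L], (pidx[, 2L] - 1L) * sp[3L])
    pr <- stats::prcomp(pc, center = TRUE)
    u <- pr$rotation[, 1L] # (y, x)
    method_qc <- character()
  }
  u <- u / sqrt(sum(u^2))
  cy0 <- mean(yc); cx0 <- mean(xc)
  s <- (yc - cy0) * u[1L] + (xc - cx0) * u[2L]
  ds <- min(sp[2L], sp[3L])

  # step 2: resample on the plane spanned by the bisecting line and z, then
  # find the two pole extremities along the in-slice long direction
  dims <- dim(m)
  nz <- dims[1L]
  sgrid <- seq(min(s) - ds, max(s) + ds, by = ds)
  zgrid <- (seq_len(nz) - 1L) * sp[1L]
  pts <- cbind(rep(zgrid, times = length(sgrid)),
               cy0 + rep(sgrid, each = nz) * u[1L],
               cx0 + rep(sgrid, each = nz) * u[2L])
  S <- matrix(.cpp_interp3(as.numeric(m), as.integer(dims), sp, pts),
              nrow = nz)
  occ <- which(S >= 0.5, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("empty orthogonal slice")
  zs <- cbind(zgrid[occ[, 1L]], sgrid[occ[, 2L]])
  w <- if (nrow(zs) > 1L) stats::prcomp(zs, center = TRUE)$rotation[, 1L] else c(1, 0)
  tproj <- (zs[, 1L] - mean(zs[, 1L])) * w[1L] + (zs[, 2L] - mean(zs[, 2L])) * w[2L]
  band <- 0.5
  pole_zs <- function(side) {
    sel <- if (side > 0) tproj >= max(tproj) - band else tproj <= min(tproj) + band
    wt <- S[occ[sel, , drop = FALSE]]
    c(z = sum(zs[sel, 1L] * wt) / sum(wt), s = sum(zs[sel, 2L] * wt) / sum(wt))
  }
  p_hi_zs <- pole_zs(+1)
  p_lo_zs <- pole_zs(-1)

  # step 3: xy of each pole from the identified z slice
  pole_xyz <- function(zsp) {
    zi <- min(max(round(zsp[["z"]] / sp[1L]) + 1L, 1L), nz)
    sl <- which(idx[, 1L] == zi)
    if (length(sl) == 0L)
      sl <- which(idx[, 1L] == idx[which.min(abs((idx[, 1L] - 1L) * sp[1L] - zsp[["z"]])), 1L])
    base_y <- cy0 + zsp[["s"]] * u[1L]
    base_x <- cx0 + zsp[["s"]] * u[2L]
    d2 <- (yc[sl] - base_y)^2 + (xc[sl] - base_x)^2
    near <- sl[d2 <= max(1.0, min(d2) + ds)^2]
    if (length(near) == 0L) near <- sl[which.min(d2)]
    c(z = zsp[["z"]], y = mean(yc[near]), x = mean(xc[near]))
  }
  p_hi <- pole_xyz(p_hi_zs)
  p_lo <- pole_xyz(p_lo_zs)

  # refine each pole as the centroid of the extremal cap along the current
  # axis estimate: the cap is rotationally symmetric about the axis, which
  # removes the lateral bias a single z-slice has on tilted cells
  zc_all <- (idx[, 1L] - 1L) * sp[1L]
  cap_band <- 1.2
  for (it in 1:2) {
    v0 <- p_hi - p_lo
    vm0 <- sqrt(sum(v0^2))
    if (vm0 == 0) break
    v0 <- v0 / vm0
    tt <- zc_all * v0[1L] + yc * v0[2L] + xc * v0[3L]
    hi_sel <- tt >= max(tt) - cap_band
    lo_sel <- tt <= min(tt) + cap_band
    p_hi <- c(mean(zc_all[hi_sel]), mean(yc[hi_sel]), mean(xc[hi_sel]))
    p_lo <- c(mean(zc_all[lo_sel]), mean(yc[lo_sel]), mean(xc[lo_sel]))
  }

  # neck along the 3D pole-to-pole axis (cross-section areas measured on
  # resampled perpendicular planes); single-lobed shapes are rejected
  v <- p_hi - p_lo
  vm <- sqrt(sum(v^2))
  if (vm == 0) stop("not telophase: degenerate pole geometry")
  v <- v / vm
  mid <- (p_hi + p_lo) / 2
  prof <- section_profile(m, sp, mid, v, t_half = vm / 2 + ds, r_half = vm / 2)
  t_neck <- profile_neck(prof$counts, prof$t, neck_ratio)
  if (is.null(t_neck))
    stop("not telophase: mask has no two-lobed neck along its long axis")
  zc <- (idx[, 1L] - 1L) * sp[1L]
  t3 <- (zc - mid[1L]) * v[1L] + (yc - mid[2L]) * v[2L] + (xc - mid[3L]) * v[3L]
  vol_pos <- sum(t3 >= t_neck) * prod(sp)
  vol_neg <- sum(t3 < t_neck) * prod(sp)
  qc <- character()
  if (abs(vol_pos - vol_neg) <= lobe_tol * max(vol_pos, vol_neg))
    qc <- c(qc, "lobe-ambiguity")

  # apical = extremity of the larger lobe (p_hi sits on the t3 > 0 side)
  if (vol_pos >= vol_neg) { apical <- p_hi; basal <- p_lo; vols <- c(vol_pos, vol_neg) }
  else { apical <- p_lo; basal <- p_hi; vols <- c(vol_neg, vol_pos) }
  ax <- axis3d(apical, basal)
  attr(ax, "qc") <- c(method_qc, qc)
  attr(ax, "lobe_volumes") <- vols
  ax
}

#' Division axis from the two spindle-pole centrosomes
#'
#' @param apical,basal physical `(z, y, x)` positions of the apical and
#'   basal centrosome at metaphase (um); must be distinct.
#' @return An [axis3d()] from apical to basal centrosome.
#' @export
axis_from_centrosomes <- function(apical, basal) {
  axis3d(apical, basal) # axis3d() already rejects coincident points
}

#' Division axis from a centrosome channel
#'
#' Detects the two brightest spots and orients the axis so that it points
#' the same way as `reference_axis` (when the angle between the candidate
#' and the reference exceeds 90 degrees the spot assignment is swapped).
#' Without a reference the brighter spot is called apical and the result
#' carries qc flag `"unoriented"`.
#'
#' @param grid 3D centrosome-channel [voxel_grid()].
#' @param reference_axis optional [axis3d()] fixing the apical direction
#'   (typically the shape-based axis of the same division).
#' @return An [axis3d()] with attribute `qc`.
#' @export
centrosome_axis <- function(grid, reference_axis = NULL) {
  spots <- detect_spots(grid, n = 2L)
  ax <- axis3d(spots[1L, ], spots[2L, ])
  qc <- character()
  if (!is.null(reference_axis)) {
    if (axis_angle(ax, reference_axis) > 90)
      ax <- axis3d(spots[2L, ], spots[1L, ])
  } else {
    qc <- "unoriented"
  }
  ax <- structure(ax, class = "axis3d")
  attr(ax, "qc") <- qc
  ax
}

#' Sphericity of a binary mask
#'
#' `pi^(1/3) (6V)^(2/3) / A` with `V` the voxel-count volume and `A` the
#' isosurface area; equals 1 for a perfect sphere.
#'
#' @param mask binary [voxel_grid()].
#' @return numeric scalar in (0, 1\].
#' @export
sphericity <- function(mask) {
  m <- as_mask_array(if (inherits(mask, "voxel_grid")) mask$values else mask)
  sp <- grid_spacing(mask)
  V <- sum(m) * prod(unclass(sp))
  if (V == 0) stop("empty mask")
  A <- isosurface_area(mask)
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Detect the onset of mitotic rounding in a mask time series
#'
#' Returns the first frame whose 3D sphericity exceeds `threshold` after
#' having been below it. A series that is round from the start returns
#' frame 0; a series that never rounds returns the last frame with qc flag
#' `"never-rounded"`.
#'
#' @param masks a 4D binary [voxel_grid()] or a list of 3D masks.
#' @param threshold sphericity threshold, default 0.92.
#' @return list of class `rounding_onset` with elements `frame` (0-based),
#'   `sphericity` (per frame) and `qc`.
#' @export
detect_rounding_onset <- function(masks, threshold = 0.92) {
  if (inherits(masks, "voxel_grid") && is_time_series(masks)) {
    nt <- dim(masks$values)[1L]
    masks <- lapply(seq_len(nt) - 1L, function(f) get_frame(masks, f))
  }
  if (!is.list(masks) || length(masks) < 3L)
    stop("need a time series of at least 3 mask frames")
  ps <- vapply(masks, sphericity, numeric(1L))
  qc <- character()
  if (ps[1L] >= threshold) {
    frame <- 0L
  } else {
    cross <- which(ps >= threshold)
    if (length(cross) == 0L) {
      frame <- length(ps) - 1L
      qc <- "never-rounded"
    } else frame <- cross[1L] - 1L
  }
  structure(list(frame = frame, sphericity = ps, qc = qc),
            class = "rounding_onset")
}

#' @export
print.rounding_onset <- function(x, ...) {
  cat(sprintf("<rounding_onset> frame %d%s; sphericity %s\n", x$frame,
              if (length(x$qc)) paste0(" (", paste(x$qc, collapse = ","), ")") else "",
              paste(sprintf("%.3f", x$sphericity), collapse = " ")))
  invisible(x)
}

#' Neuroblast-to-daughter (GMC) cue axis
#'
#' The cue axis runs from the neuroblast centroid through the centroid of
#' the neuroblast-side contact patch with the daughter cell (voxels of the
#' neuroblast within one voxel of the daughter mask), extended to unit
#' length. If the masks share no contact patch the axis falls back to the
#' centroid-to-centroid direction with qc flag `"no-contact-patch"`.
#'
#' @param nb_mask,gmc_mask disjoint nonempty binary [voxel_grid()]s on the
#'   same grid.
#' @return Unit-length [axis3d()] with attribute `qc`.
#' @export
gmc_axis <- function(nb_mask, gmc_mask) {
  stopifnot(inherits(nb_mask, "voxel_grid"), inherits(gmc_mask, "voxel_grid"))
  if (!identical(dim(nb_mask$values), dim(gmc_mask$values)))
    stop("masks must share one grid")
  nb <- as_mask_array(nb_mask$values)
  gmc <- as_mask_array(gmc_mask$values)
  if (!any(nb) || !any(gmc)) stop("empty mask")
  if (any(nb & gmc)) stop("masks must be disjoint")
  sp <- unclass(nb_mask$spacing)
  nb_c <- mask_centroid(nb, sp)
  dg <- .cpp_edt3d(gmc, dim(gmc), sp)
  patch <- nb & array(dg <= max(sp) * 1.01, dim(nb))
  qc <- character()
  if (any(patch)) {
    tgt <- mask_centroid(array(patch, dim(nb)), sp)
  } else {
    tgt <- mask_centroid(gmc, sp)
    qc <- "no-contact-patch"
  }
  v <- tgt - nb_c
  mv <- sqrt(sum(v^2))
  if (mv == 0) stop("degenerate geometry: coincident centroids")
  ax <- axis3d(nb_c, nb_c + v / mv)
  attr(ax, "qc") <- qc
  ax
}

#' Alpha and beta angle bookkeeping over division records
#'
#' Alpha is the 3D angle between the division axes of consecutive cycles
#' of the same neuroblast; beta is the angle between a division axis and
#' the daughter-cue axis at the rounding onset of that cycle. Pairs that
#' cannot be measured (missing cycle, missing cue axis) are skipped and
#' listed in the `skipped` attribute.
#'
#' @param records list of [division_record()]s.
#' @param gmc_axes optional list; each element a list with `nb_id`,
#'   `cycle` and `axis` (the cue [axis3d()] for that cycle).
#' @return data.frame with columns `nb_id`, `kind` (`"alpha"`/`"beta"`),
#'   `cycle_ref`, `angle_deg`.
#' @export
measure_alpha_beta <- function(records, gmc_axes = NULL) {
  stopifnot(is.list(records), all(vapply(records, inherits, TRUE, "division_record")))
  ids <- vapply(records, function(r) as.character(r$nb_id), character(1L))
  out <- list()
  skipped <- character()
  for (id in unique(ids)) {
    rs <- records[ids == id]
    cyc <- vapply(rs, function(r) r$cycle, integer(1L))
    rs <- rs[order(cyc)]; cyc <- sort(cyc)
    for (k in seq_along(rs)[-1L]) {
      if (cyc[k] - cyc[k - 1L] == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          nb_id = id, kind = "alpha", cycle_ref = cyc[k],
          angle_deg = axis_angle(rs[[k - 1L]]$axis, rs[[k]]$axis))
      } else {
        skipped <- c(skipped, sprintf("%s: non-consecutive cycles %d,%d",
                                      id, cyc[k - 1L], cyc[k]))
      }
    }
    if (!is.null(gmc_axes)) {
      for (g in gmc_axes) {
        if (as.character(g$nb_id) != id) next
        hit <- which(cyc == g$cycle)
        if (length(hit) == 1L) {
          out[[length(out) + 1L]] <- data.frame(
            nb_id = id, kind = "beta", cycle_ref = g$cycle,
            angle_deg = axis_angle(g$axis, rs[[hit]]$axis))
        } else {
          skipped <- c(skipped, sprintf("%s: no record for cue cycle %d", id, g$cycle))
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(nb_id = character(), kind = character(),
                  cycle_ref = integer(), angle_deg = numeric())
  attr(res, "skipped") <- skipped
  res
}
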