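#' Condition presets from the published angle and contact summaries
#'
#' Each preset names an experimental condition and carries the mean and SD
#' of its division-axis deviation distribution (degrees), or of its
#' neuroblast/glia contact fraction (percent), together with the published
#' sample size. These are the distributions the scene generator emulates.
#'
#' @return A data.frame with columns `name`, `deviation_mean`,
#'   `deviation_sd`, `contact_mean`, `contact_sd`, `n`.
#' @export
#' @examples
#' condition_presets()
condition_presets <- function() {
  data.frame(
    name = c("control", "control_beta", "no_ablation", "control_ablation",
             "gmc_ablation", "older_gmc_ablation", "post_gmc_ablation",
             "post_ablation_recovery", "sas4", "sas4_gmc_ablation",
             "sep1_rnai", "sep1_gmc_ablation",
             "contact_control", "cindr_rnai"),
    deviation_mean = c(24, 14, 18, 23, 36, 27, 59, 25, 33, 49, 32, 37, NA, NA),
    deviation_sd   = c(15,  7, 14, 16, 20, 16, 14, 11, 26, 28, 27, 19, NA, NA),
    contact_mean   = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, 79, 71),
    contact_sd     = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,  5,  9),
    n              = c(37, 52, 35, 27, 35, 26,  9,  9, 50, 22, 29, 21, NA, NA),
    stringsAsFactors = FALSE
  )
}

resolve_preset <- function(preset) {
  if (is.character(preset)) {
    tab <- condition_presets()
    row <- tab[tab$name == preset, ]
    if (nrow(row) != 1L) stop("unknown preset: ", preset)
    if (is.na(row$deviation_mean))
      stop("preset '", preset, "' is a contact preset, not an angle preset")
    return(list(name = row$name, deviation_mean = row$deviation_mean,
                deviation_sd = row$deviation_sd))
  }
  stopifnot(is.list(preset), !is.null(preset$deviation_mean),
            !is.null(preset$deviation_sd))
  if (preset$deviation_mean < 0 || preset$deviation_mean > 180)
    stop("deviation_mean must lie in [0, 180] degrees")
  if (preset$deviation_sd < 0) stop("deviation_sd must be >= 0")
  if (is.null(preset$name)) preset$name <- "custom"
  preset
}

#' Imaging noise model for rendered scenes
#'
#' Shot noise is Poisson at `photon_scale` expected photons per unit
#' intensity; `read_sigma` is additive Gaussian read noise (intensity
#' units); `psf_sigma_um` is the anisotropic Gaussian standing in for the
#' point-spread function; `background` is a constant offset applied before
#' the shot noise. Peak SNR is approximately
#' `1 / sqrt(1/photon_scale + read_sigma^2)`.
#'
#' @param photon_scale expected photons per unit intensity (> 0).
#' @param read_sigma Gaussian read-noise SD, intensity units (>= 0).
#' @param psf_sigma_um `(z, y, x)` Gaussian PSF sigmas in um (>= 0).
#' @param background constant background intensity (>= 0).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 100, read_sigma = 0.02,
                        psf_sigma_um = c(0.6, 0.2, 0.2), background = 0.05) {
  if (photon_scale <= 0) stop("photon_scale must be > 0")
  if (read_sigma < 0 || background < 0 || any(psf_sigma_um < 0))
    stop("noise parameters must be nonnegative")
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 psf_sigma_um = as.numeric(psf_sigma_um),
                 background = background),
            class = "noise_model")
}

#' Geometry and timing configuration for synthetic scenes
#'
#' Defaults emulate the study conditions: a 5 um neuroblast (consistent
#' with the 5 um scale bars of the source imagery), a 4:1 neuroblast:GMC
#' lobe volume ratio at telophase, z sections 0.8 um apart with 0.26 um xy
#' pixels, and a 210 s frame cadence grouped into cycles of
#' `frames_per_cycle` frames (interphase, then rounding, then telophase as
#' the last frame of each cycle block).
#'
#' @param nb_radius neuroblast radius, um.
#' @param lobe_volume_ratio neuroblast:GMC volume ratio at telophase.
#' @param spacing `(dz, dy, dx)` voxel pitch, um.
#' @param membrane_thickness full thickness of the rendered membrane
#'   shell, um.
#' @param telophase_overlap centre separation at telophase as a fraction
#'   of the sum of lobe radii (< 1 keeps a neck).
#' @param neck_radius radius of the cytokinetic-bridge capsule joining the
#'   two telophase lobes, um.
#' @param interphase_aspect long/short axis ratio of the interphase cell
#'   shape (volume-preserving prolate ellipsoid).
#' @param frames_per_cycle frames per division cycle (>= 4).
#' @param fov_um field of view (cube side), um; `NULL` = auto-sized.
#' @param glia_gap gap between neuroblast surface and glia sheath, um.
#' @param glia_thickness thickness of the glia sheath shell, um.
#' @param centrosome_sigma_um Gaussian radius of centrosome spots, um.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(nb_radius = 5, lobe_volume_ratio = 4,
                         spacing = c(0.8, 0.26, 0.26),
                         membrane_thickness = 0.4,
                         telophase_overlap = 0.9,
                         neck_radius = 1.7,
                         interphase_aspect = 3,
                         frames_per_cycle = 6L,
                         fov_um = NULL,
                         glia_gap = 0.1, glia_thickness = 0.5,
                         centrosome_sigma_um = 0.25) {
  if (nb_radius <= 0 || lobe_volume_ratio <= 1)
    stop("need nb_radius > 0 and lobe_volume_ratio > 1 (daughter smaller)")
  if (frames_per_cycle < 4L) stop("frames_per_cycle must be >= 4")
  structure(list(nb_radius = nb_radius,
                 gmc_radius = nb_radius / lobe_volume_ratio^(1 / 3),
                 lobe_volume_ratio = lobe_volume_ratio,
                 spacing = as_voxel_spacing(spacing),
                 membrane_thickness = membrane_thickness,
                 telophase_overlap = telophase_overlap,
                 neck_radius = neck_radius,
                 interphase_aspect = interphase_aspect,
                 frames_per_cycle = as.integer(frames_per_cycle),
                 fov_um = fov_um,
                 glia_gap = glia_gap, glia_thickness = glia_thickness,
                 centrosome_sigma_um = centrosome_sigma_um),
            class = "scene_config")
}

# auto field of view: the scene is centred on the neuroblast; worst-case
# half extent is the interphase semi-long axis or the telophase far pole
scene_fov <- function(config) {
  if (!is.null(config$fov_um)) return(config$fov_um)
  d_t <- config$telophase_overlap * (config$nb_radius + config$gmc_radius)
  half <- max(config$nb_radius * config$interphase_aspect^(2 / 3),
              d_t + config$gmc_radius,
              config$nb_radius + config$gmc_gap %||% 0 +
                config$glia_gap + config$glia_thickness)
  2 * (half + 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform direction on the unit sphere (z, y, x)
runif_sphere <- function() {
  repeat {
    v <- stats::rnorm(3)
    m <- sqrt(sum(v^2))
    if (m > 1e-12) return(v / m)
  }
}

# rotate unit vector `centre` away by `theta_deg` about a uniformly random
# azimuth (or the azimuth given in radians)
rotate_from <- function(centre, theta_deg, azimuth = NULL) {
  a <- if (abs(centre[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(centre[2] * a[3] - centre[3] * a[2],
          centre[3] * a[1] - centre[1] * a[3],
          centre[1] * a[2] - centre[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(centre[2] * e1[3] - centre[3] * e1[2],
          centre[3] * e1[1] - centre[1] * e1[3],
          centre[1] * e1[2] - centre[2] * e1[1])
  if (is.null(azimuth)) azimuth <- stats::runif(1, 0, 2 * pi)
  th <- theta_deg * pi / 180
  cos(th) * centre + sin(th) * (cos(azimuth) * e1 + sin(azimuth) * e2)
}

# normal(mean, sd) truncated to [0, 180] by rejection; sd -> 0 collapses
# to the mean
rtrunc_angle <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, draw[draw >= 0 & draw <= 180])
  }
  out[seq_len(n)]
}

#' Sample a ground-truth division series for one neuroblast
#'
#' The first division axis is uniform on the sphere; each subsequent axis
#' is obtained by rotating the centring direction (the previous axis, or
#' the current daughter-cell direction when `next_axis_mode = "gmc"`) by a
#' deviation angle drawn from a normal truncated to \[0, 180\] degrees,
#' about a uniformly random azimuth. The daughter (GMC) centre is placed
#' at the basal pole, optionally displaced before the next rounding onset
#' to emulate daughter-cell movements.
#'
#' @param preset a preset name from [condition_presets()] or a list with
#'   `deviation_mean` and `deviation_sd` (degrees).
#' @param n_cycles number of division cycles (>= 2).
#' @param seed integer seed; the whole truth is reproducible from it.
#' @param config a [scene_config()].
#' @param noise a [noise_model()].
#' @param glia_coverage_fraction fraction of the neuroblast sphere covered
#'   by the glia sheath, in \[0, 1\].
#' @param next_axis_mode `"previous_axis"` (deviations accumulate from the
#'   last division axis) or `"gmc"` (the next axis is centred on the
#'   current daughter direction, creating beta < alpha scenarios when the
#'   daughter moves).
#' @param gmc_displacement_deg SD (degrees) of the random angular
#'   displacement of the daughter between its birth and the next rounding
#'   onset; 0 disables movement.
#' @return An object of class `scene_truth`; element `cycles` is a list of
#'   per-cycle truths (axis, daughter position, centrosomes, frame
#'   indices, drawn deviation).
#' @export
#' @examples
#' tr <- sample_division_series("control", n_cycles = 3, seed = 1)
#' length(tr$cycles)
sample_division_series <- function(preset, n_cycles, seed,
                                   config = scene_config(),
                                   noise = noise_model(),
                                   glia_coverage_fraction = 0.8,
                                   next_axis_mode = c("previous_axis", "gmc"),
                                   gmc_displacement_deg = 0) {
  preset <- resolve_preset(preset)
  next_axis_mode <- match.arg(next_axis_mode)
  if (n_cycles < 2L) stop("n_cycles must be >= 2")
  if (glia_coverage_fraction < 0 || glia_coverage_fraction > 1)
    stop("glia_coverage_fraction must lie in [0, 1]")
  fov <- scene_fov(config)
  centre <- rep(fov / 2, 3L)
  nb_r <- config$nb_radius
  gmc_r <- config$gmc_radius
  d_t <- config$telophase_overlap * (nb_r + gmc_r)
  fpc <- config$frames_per_cycle

  with_seed(seed, {
    dirs <- vector("list", n_cycles)
    thetas <- rep(NA_real_, n_cycles)
    gmc_dirs <- vector("list", n_cycles)
    dirs[[1L]] <- runif_sphere()
    gmc_dirs[[1L]] <- if (gmc_displacement_deg > 0)
      rotate_from(dirs[[1L]], abs(stats::rnorm(1, 0, gmc_displacement_deg)))
    else dirs[[1L]]
    for (i in seq_len(n_cycles)[-1L]) {
      ctr <- if (next_axis_mode == "gmc") gmc_dirs[[i - 1L]] else dirs[[i - 1L]]
      thetas[i] <- rtrunc_angle(1L, preset$deviation_mean, preset$deviation_sd)
      dirs[[i]] <- rotate_from(ctr, thetas[i])
      gmc_dirs[[i]] <- if (gmc_displacement_deg > 0)
        rotate_from(dirs[[i]], abs(stats::rnorm(1, 0, gmc_displacement_deg)))
      else dirs[[i]]
    }
    scene_truth_from_directions(dirs, gmc_dirs, thetas,
                                preset = preset, config = config,
                                noise = noise,
                                glia_coverage_fraction = glia_coverage_fraction,
                                next_axis_mode = next_axis_mode,
                                gmc_displacement_deg = gmc_displacement_deg,
                                seed = seed)
  })
}

# deterministic scene construction from explicit per-cycle unit directions;
# the sampling front end above draws the directions, tests may supply them
scene_truth_from_directions <- function(dirs, gmc_dirs = dirs,
                                        thetas = rep(NA_real_, length(dirs)),
                                        preset = list(name = "custom",
                                                      deviation_mean = NA_real_,
                                                      deviation_sd = NA_real_),
                                        config = scene_config(),
                                        noise = noise_model(),
                                        glia_coverage_fraction = 0.8,
                                        next_axis_mode = "previous_axis",
                                        gmc_displacement_deg = 0,
                                        seed = 0L) {
  n_cycles <- length(dirs)
  fov <- scene_fov(config)
  centre <- rep(fov / 2, 3L)
  nb_r <- config$nb_radius
  gmc_r <- config$gmc_radius
  d_t <- config$telophase_overlap * (nb_r + gmc_r)
  fpc <- config$frames_per_cycle
  cycles <- vector("list", n_cycles)
  for (i in seq_len(n_cycles)) {
    u <- dirs[[i]]
    apical_pole <- centre - u * nb_r
    basal_pole <- centre + u * (d_t + gmc_r)
    block <- (i - 1L) * fpc
    cycles[[i]] <- structure(list(
      cycle = i,
      direction = u,
      true_axis = axis3d(apical_pole, basal_pole),
      theta_deg = thetas[i],
      gmc_centre = centre + gmc_dirs[[i]] * (nb_r + gmc_r),
      gmc_direction = gmc_dirs[[i]],
      gmc_radius = gmc_r,
      rounding_frame = block + fpc - 3L,
      telophase_frame = block + fpc - 1L,
      apical_centrosome = centre - u * (0.5 * nb_r),
      basal_centrosome = centre + u * (d_t - 0.4 * gmc_r)
    ), class = "cycle_truth")
  }
  structure(list(preset = preset$name,
                 deviation_mean = preset$deviation_mean,
                 deviation_sd = preset$deviation_sd,
                 nb_centre = centre, nb_radius = nb_r,
                 gmc_radius = gmc_r,
                 glia_coverage_fraction = glia_coverage_fraction,
                 glia_cap_axis = -dirs[[1L]],
                 spacing = config$spacing, noise = noise,
                 config = config, fov_um = fov, seed = as.integer(seed),
                 next_axis_mode = next_axis_mode,
                 gmc_displacement_deg = gmc_displacement_deg,
                 n_cycles = n_cycles,
                 cycles = cycles),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> preset '%s' (%g +/- %g deg), %d cycles, seed %d, fov %.1f um\n",
              x$preset, x$deviation_mean, x$deviation_sd, x$n_cycles,
              x$seed, x$fov_um))
  invisible(x)
}

# ---- rendering -------------------------------------------------------------

# squared distance field from `centre` (z,y,x um) on a (nz,ny,nx) grid
dist2_field <- function(dims, spacing, centre) {
  rz <- (seq_len(dims[1L]) - 1L) * spacing[1L] - centre[1L]
  ry <- (seq_len(dims[2L]) - 1L) * spacing[2L] - centre[2L]
  rx <- (seq_len(dims[3L]) - 1L) * spacing[3L] - centre[3L]
  outer(outer(rz^2, ry^2, `+`), rx^2, `+`)
}

# projection field p . u for offsets from `centre`
proj_field <- function(dims, spacing, centre, u) {
  rz <- ((seq_len(dims[1L]) - 1L) * spacing[1L] - centre[1L]) * u[1L]
  ry <- ((seq_len(dims[2L]) - 1L) * spacing[2L] - centre[2L]) * u[2L]
  rx <- ((seq_len(dims[3L]) - 1L) * spacing[3L] - centre[3L]) * u[3L]
  outer(outer(rz, ry, `+`), rx, `+`)
}

sdf_sphere <- function(dims, spacing, centre, r) sqrt(dist2_field(dims, spacing, centre)) - r

# capsule (cylinder with spherical caps) from p1 to p2 with radius r
sdf_capsule <- function(dims, spacing, p1, p2, r) {
  v <- p2 - p1
  L <- sqrt(sum(v^2))
  u <- v / L
  pu <- proj_field(dims, spacing, p1, u)
  d2 <- dist2_field(dims, spacing, p1)
  perp2 <- pmax(d2 - pu^2, 0)
  cl <- pmin(pmax(pu, 0), L)
  sqrt(perp2 + (pu - cl)^2) - r
}

# volume-preserving prolate ellipsoid along u, aspect = long/short ratio
sdf_ellipsoid <- function(dims, spacing, centre, r, u, aspect) {
  la <- r * aspect^(2 / 3)
  lp <- r * aspect^(-1 / 3)
  pu <- proj_field(dims, spacing, centre, u)
  d2 <- dist2_field(dims, spacing, centre)
  perp2 <- pmax(d2 - pu^2, 0)
  (sqrt((pu / la)^2 + perp2 / lp^2) - 1) * lp
}

scene_dims <- function(truth) {
  sp <- unclass(truth$spacing)
  pmax(as.integer(ceiling(truth$fov_um / sp)) + 1L, 2L)
}

# Rasterize a shell |sdf| <= h with sampling-aware thickness: the band
# half-width is locally expanded to at least half the voxel step along the
# surface normal, so the shell stays hole-free at anisotropic spacing.
shell_band <- function(sdf, sp, h) {
  dims <- dim(sdf)
  grad_axis <- function(a, ax, d) {
    n <- dims[ax]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    if (ax == 1L) (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) / (2 * d)
    else if (ax == 2L) (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) / (2 * d)
    else (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) / (2 * d)
  }
  gz <- grad_axis(sdf, 1L, sp[1L])
  gy <- grad_axis(sdf, 2L, sp[2L])
  gx <- grad_axis(sdf, 3L, sp[3L])
  step <- sqrt((gz * sp[1L])^2 + (gy * sp[2L])^2 + (gx * sp[3L])^2)
  # at creases of a union SDF the central-difference gradient cancels;
  # fall back to the worst-case voxel step there so the shell stays closed
  gn <- sqrt(gz^2 + gy^2 + gx^2)
  step <- ifelse(gn > 0.9, step / gn, max(sp))
  h_eff <- pmax(h, 0.55 * step)
  out <- as.numeric(abs(sdf) <= h_eff)
  dim(out) <- dims
  out
}

# NB body signed-distance for a given frame (without the last-born GMC)
nb_shape_sdf <- function(truth, frame, dims) {
  sp <- unclass(truth$spacing)
  fpc <- truth$config$frames_per_cycle
  i <- min(frame %/% fpc + 1L, truth$n_cycles)
  cy <- truth$cycles[[i]]
  centre <- truth$nb_centre
  if (frame >= cy$telophase_frame) {
    d_t <- truth$config$telophase_overlap * (truth$nb_radius + truth$gmc_radius)
    c2 <- centre + cy$direction * d_t
    # two lobes joined by a cytokinetic-bridge capsule so the neck has a
    # well-defined open channel and a deep cross-section minimum
    pmin(sdf_sphere(dims, sp, centre, truth$nb_radius),
         sdf_sphere(dims, sp, c2, truth$gmc_radius),
         sdf_capsule(dims, sp, centre, c2, truth$config$neck_radius))
  } else if (frame >= cy$rounding_frame) {
    sdf_sphere(dims, sp, centre, truth$nb_radius)
  } else {
    elong_u <- if (i > 1L) truth$cycles[[i - 1L]]$direction else cy$direction
    sdf_ellipsoid(dims, sp, centre, truth$nb_radius, elong_u,
                  truth$config$interphase_aspect)
  }
}

#' Render one frame of a synthetic scene
#'
#' The membrane channel is a band of high intensity at each cell boundary
#' (the dividing neuroblast -- rendered as a two-lobed dumbbell at
#' telophase -- plus the last-born daughter cell as a separate adjacent
#' cell); the centrosome channel holds two 3D Gaussian spots; the glia
#' channel is a spherical shell covering `glia_coverage_fraction` of the
#' neuroblast sphere as a spherical-cap complement. With `noise = TRUE`
#' the PSF blur, Poisson shot noise and Gaussian read noise of the scene's
#' [noise_model()] are applied (reproducibly from the scene seed).
#'
#' @param truth a [sample_division_series()] result.
#' @param frame 0-based frame index.
#' @param channels subset of `c("membrane", "centrosomes", "glia")`.
#' @param noise logical; render noiselessly when `FALSE`.
#' @return Named list of 3D [voxel_grid()]s.
#' @export
render_frame <- function(truth, frame,
                         channels = c("membrane", "centrosomes", "glia"),
                         noise = TRUE) {
  stopifnot(inherits(truth, "scene_truth"))
  channels <- match.arg(channels, several.ok = TRUE)
  dims <- scene_dims(truth)
  sp <- unclass(truth$spacing)
  fpc <- truth$config$frames_per_cycle
  i <- min(frame %/% fpc + 1L, truth$n_cycles)
  cy <- truth$cycles[[i]]
  # required half extent for the shapes present in this frame
  req <- truth$nb_radius + truth$config$glia_gap + truth$config$glia_thickness
  if (frame >= cy$telophase_frame)
    req <- max(req, truth$config$telophase_overlap *
                 (truth$nb_radius + truth$gmc_radius) + truth$gmc_radius)
  else if (frame < cy$rounding_frame)
    req <- max(req, truth$nb_radius * truth$config$interphase_aspect^(2 / 3))
  else if (i > 1L)
    req <- max(req, truth$nb_radius + 2 * truth$gmc_radius)
  req <- req + truth$config$membrane_thickness + 0.5
  if (truth$fov_um / 2 < req)
    stop("field of view too small: this frame needs at least ", 2 * req, " um")
  half_t <- truth$config$membrane_thickness / 2
  out <- list()

  if ("membrane" %in% channels) {
    img <- shell_band(nb_shape_sdf(truth, frame, dims), sp, half_t)
    # the last-born GMC is drawn on the rounding frames, where the NB is
    # spherical and the daughter sits tangent at its truth position (the
    # frames on which the daughter-cue axis is defined)
    if (i > 1L && frame >= cy$rounding_frame && frame < cy$telophase_frame) {
      prev <- truth$cycles[[i - 1L]]
      sd2 <- sdf_sphere(dims, sp, prev$gmc_centre, prev$gmc_radius)
      img <- pmax(img, shell_band(sd2, sp, half_t))
      dim(img) <- dims
    }
    out$membrane <- img
  }
  if ("centrosomes" %in% channels) {
    s2 <- 2 * truth$config$centrosome_sigma_um^2
    img <- exp(-dist2_field(dims, sp, cy$apical_centrosome) / s2) +
      exp(-dist2_field(dims, sp, cy$basal_centrosome) / s2)
    out$centrosomes <- img
  }
  if ("glia" %in% channels) {
    f <- truth$glia_coverage_fraction
    r0 <- truth$nb_radius + truth$config$glia_gap
    r1 <- r0 + truth$config$glia_thickness
    d <- sqrt(dist2_field(dims, sp, truth$nb_centre))
    band <- shell_band(d - (r0 + r1) / 2, sp, (r1 - r0) / 2) > 0
    if (f >= 1) {
      img <- as.numeric(band)
    } else if (f <= 0) {
      img <- numeric(length(band))
    } else {
      cos_cap <- 2 * f - 1 # polar half-angle of the uncovered cap
      pu <- proj_field(dims, sp, truth$nb_centre, truth$glia_cap_axis)
      cosang <- ifelse(d > 0, pu / d, 1)
      img <- as.numeric(band & cosang < cos_cap)
    }
    dim(img) <- dims
    out$glia <- img
  }

  for (nm in names(out)) {
    img <- out[[nm]]
    dim(img) <- dims
    if (noise) {
      nm_mod <- truth$noise
      sig_vox <- nm_mod$psf_sigma_um / sp
      if (any(sig_vox > 0)) img <- gaussian_blur_3d(img, sig_vox)
      img <- img + nm_mod$background
      img <- with_seed(derive_seed(truth$seed, frame * 8L + match(nm, c("membrane", "centrosomes", "glia"))), {
        shot <- stats::rpois(length(img), lambda = pmax(img, 0) * nm_mod$photon_scale) /
          nm_mod$photon_scale
        pmax(shot + stats::rnorm(length(img), 0, nm_mod$read_sigma), 0)
      })
      dim(img) <- dims
    }
    out[[nm]] <- voxel_grid(img, truth$spacing, nm)
  }
  out
}

#' Render a full time series of a synthetic scene
#'
#' @param truth a [sample_division_series()] result.
#' @param frames number of frames; default covers all cycles.
#' @param channels channels to render, see [render_frame()].
#' @param noise logical; apply the noise model.
#' @return Named list of 4D [voxel_grid()]s, axes `(t, z, y, x)`.
#' @export
render_stack <- function(truth, frames = NULL,
                         channels = c("membrane", "centrosomes", "glia"),
                         noise = TRUE) {
  channels <- match.arg(channels, several.ok = TRUE)
  if (is.null(frames)) frames <- truth$n_cycles * truth$config$frames_per_cycle
  dims <- scene_dims(truth)
  out <- lapply(channels, function(ch) array(0, c(frames, dims)))
  names(out) <- channels
  for (f in seq_len(frames) - 1L) {
    fr <- render_frame(truth, f, channels, noise)
    for (ch in channels) out[[ch]][f + 1L, , , ] <- fr[[ch]]$values
  }
  lapply(out, function(a) voxel_grid(a, truth$spacing))
}

#' Write a rendered scene and its ground truth to disk
#'
#' One multipage TIFF per channel (via [write_stack()]) plus
#' `truth.json` serialising the full ground truth (axes, daughter
#' positions, frames, noise and seed).
#'
#' @param truth a [sample_division_series()] result.
#' @param dir output directory (created if needed).
#' @param frames,channels,noise passed to [render_stack()].
#' @return `dir`, invisibly.
#' @export
write_scene <- function(truth, dir, frames = NULL,
                        channels = c("membrane", "centrosomes", "glia"),
                        noise = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stacks <- render_stack(truth, frames, channels, noise)
  for (ch in names(stacks))
    write_stack(stacks[[ch]], file.path(dir, paste0(ch, ".tif")))
  tj <- truth
  tj$cycles <- lapply(tj$cycles, function(cy) {
    cy$true_axis <- list(a = as.numeric(cy$true_axis$a), b = as.numeric(cy$true_axis$b))
    lapply(cy, function(e) if (is.numeric(e)) as.numeric(e) else e)
  })
  tj$spacing <- as.numeric(unclass(tj$spacing))
  tj$config <- lapply(unclass(tj$config), function(e)
    if (inherits(e, "voxel_spacing")) as.numeric(unclass(e)) else e)
  tj$noise <- unclass(tj$noise)
  jsonlite::write_json(unclass(tj), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Construct a probability map with a known thresholded volume
#'
#' Stand-in for an external pixel-classification probability map: builds a
#' compact blob whose `>= 0.5` super-level set contains exactly
#' `round(volume_um3 / voxel_volume)` voxels, so threshold-based volume
#' measurements can be validated against a known truth.
#'
#' @param volume_um3 requested foreground volume, um^3 (>= 0).
#' @param fov_um field of view (cube side), um.
#' @param spacing `(dz, dy, dx)` voxel pitch, um.
#' @param seed integer seed (blob placement).
#' @return A [voxel_grid()] with values in \[0, 1\]; attribute
#'   `target_voxels` records the constructed foreground voxel count.
#' @export
render_probability_map <- function(volume_um3, fov_um, spacing, seed) {
  spacing <- as_voxel_spacing(spacing)
  if (volume_um3 < 0) stop("volume must be >= 0")
  dims <- pmax(as.integer(ceiling(fov_um / unclass(spacing))), 1L)
  vv <- voxel_volume(spacing)
  n_target <- round(volume_um3 / vv)
  if (n_target > prod(dims))
    stop("requested volume ", volume_um3, " um^3 exceeds the field of view (",
         prod(dims) * vv, " um^3)")
  with_seed(seed, {
    centre <- unclass(spacing) * (dims - 1L) * stats::runif(3, 0.35, 0.65)
    d <- sqrt(dist2_field(dims, unclass(spacing), centre))
    ord <- order(d)
    p <- numeric(length(d))
    if (n_target > 0)
      p[ord[seq_len(n_target)]] <- 1 - 0.5 * (seq_len(n_target) - 1L) / max(n_target, 1L)
    rest <- length(d) - n_target
    if (rest > 0)
      p[ord[n_target + seq_len(rest)]] <- 0.499 * exp(-(seq_len(rest)) / max(rest / 4, 1))
    dim(p) <- dims
    out <- voxel_grid(p, spacing, "probability")
    attr(out, "target_voxels") <- as.integer(n_target)
    out
  })
}
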