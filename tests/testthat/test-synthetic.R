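test_that("the division-series sampler is deterministic and self-consistent", {
  tr1 <- sample_division_series("control", 4, seed = 123)
  tr2 <- sample_division_series("control", 4, seed = 123)
  expect_identical(tr1, tr2)
  # drawn deviation equals the realised inter-axis angle
  for (i in 2:4) {
    expect_equal(axis_angle(tr1$cycles[[i - 1]]$true_axis, tr1$cycles[[i]]$true_axis),
                 tr1$cycles[[i]]$theta_deg, tolerance = 1e-9)
  }
  # daughter placement: basal direction points at the daughter it creates
  # (arccos conditioning near 0 degrees limits precision to ~sqrt(eps))
  for (i in 1:4) {
    cue <- axis3d(tr1$nb_centre, tr1$cycles[[i]]$gmc_centre)
    expect_lt(axis_angle(cue, tr1$cycles[[i]]$true_axis), 1e-5)
  }
  expect_error(sample_division_series("control", 1, seed = 1), "n_cycles")
  expect_error(sample_division_series("nope", 2, seed = 1), "unknown preset")
})

test_that("zero deviation noise collapses all cycles onto one axis", {
  tr <- sample_division_series(list(deviation_mean = 0, deviation_sd = 0),
                               4, seed = 9)
  for (i in 2:4)
    expect_lt(axis_angle(tr$cycles[[1]]$true_axis, tr$cycles[[i]]$true_axis), 1e-9)
  ta <- truth_angles(tr)
  expect_true(all(ta$alpha_deg < 1e-9))
})

test_that("sampled deviations match the truncated-normal mean", {
  devs <- vapply(1:500, function(s)
    sample_division_series("control", 2, seed = s)$cycles[[2]]$theta_deg,
    numeric(1))
  mom <- truncnorm_moments(24, 15)
  expect_lt(abs(mean(devs) - mom$mean), 1.5) # against the analytic truncated mean
  expect_lt(abs(mean(devs) - 24), 3)         # truncation biases ~ +1.8 degrees
  expect_lt(abs(sd(devs) - mom$sd), 1.5)
})

test_that("rendered stacks are reproducible and converge as shot noise vanishes", {
  tr <- sample_division_series("control", 2, seed = 31)
  f <- tr$cycles[[1]]$telophase_frame
  a <- render_frame(tr, f, channels = "membrane", noise = TRUE)
  b <- render_frame(tr, f, channels = "membrane", noise = TRUE)
  expect_identical(a$membrane$values, b$membrane$values)

  clean <- render_frame(tr, f, channels = "membrane", noise = FALSE)
  blur_ref <- gaussian_blur_3d(clean$membrane$values,
                               tr$noise$psf_sigma_um / unclass(tr$spacing))
  quiet <- sample_division_series("control", 2, seed = 31,
                                  noise = noise_model(photon_scale = 2e5,
                                                      read_sigma = 0,
                                                      background = 0))
  acc <- 0
  for (k in 1:20) {
    quiet$seed <- 31 + k # vary only the noise stream
    acc <- acc + render_frame(quiet, f, channels = "membrane", noise = TRUE)$membrane$values
  }
  rms <- sqrt(mean((acc / 20 - blur_ref)^2))
  expect_lt(rms, 0.02 * max(blur_ref))
})

test_that("noiseless telophase renders have annular sections and recoverable lobes", {
  u <- c(0, 0, 1) # division axis along x
  tr <- scene_with_dirs(list(u))
  fr <- render_frame(tr, tr$cycles[[1]]$telophase_frame,
                     channels = "membrane", noise = FALSE)
  # central z-slice: ring around the NB centre (interior empty, shell high)
  sp <- unclass(tr$spacing)
  zi <- round(tr$nb_centre[1] / sp[1]) + 1
  yi <- round(tr$nb_centre[2] / sp[2]) + 1
  xi <- round(tr$nb_centre[3] / sp[3]) + 1
  sl <- fr$membrane$values[zi, , ]
  expect_identical(sl[yi, xi], 0)                        # hollow centre
  expect_gt(sl[yi, xi - round(tr$nb_radius / sp[3])], 0) # shell at the apical side
  # lobe centroids from the segmented mask, split at the neck
  mask <- segment_cell(fr$membrane, seed_point = tr$nb_centre)
  idx <- which(mask$values, arr.ind = TRUE)
  xs <- (idx[, 3] - 1) * sp[3]
  d_t <- tr$config$telophase_overlap * (tr$nb_radius + tr$gmc_radius)
  gmc_x <- tr$nb_centre[3] + d_t
  cut <- tr$nb_centre[3] + tr$nb_radius # beyond the NB sphere: daughter lobe
  nb_cent <- colMeans(idx[xs < cut, , drop = FALSE] - 1) * sp
  gmc_cent <- colMeans(idx[xs >= cut, , drop = FALSE] - 1) * sp
  expect_lt(abs(gmc_cent[3] - gmc_x), sp[1]) # within one (coarsest) voxel
  expect_lt(abs(nb_cent[1] - tr$nb_centre[1]), sp[1])
})

test_that("glia shell coverage matches the spherical-cap closed form", {
  cfg <- scene_config(spacing = c(0.4, 0.4, 0.4)) # isotropic rasterisation
  full <- sample_division_series("control", 2, seed = 17, config = cfg,
                                 glia_coverage_fraction = 1)
  band <- render_frame(full, full$cycles[[1]]$rounding_frame,
                       channels = "glia", noise = FALSE)
  for (f in c(0.25, 0.5, 0.933)) {
    tr <- sample_division_series("control", 2, seed = 17, config = cfg,
                                 glia_coverage_fraction = f)
    fr <- render_frame(tr, tr$cycles[[1]]$rounding_frame,
                       channels = "glia", noise = FALSE)
    got <- sum(fr$glia$values > 0) / sum(band$glia$values > 0)
    expect_lt(abs(got - f), 0.03)
  }
  # full coverage encloses the neuroblast mask
  full <- sample_division_series("control", 2, seed = 17,
                                 glia_coverage_fraction = 1)
  fr <- render_frame(full, full$cycles[[1]]$rounding_frame,
                     channels = c("membrane", "glia"), noise = FALSE)
  nb <- segment_cell(fr$membrane, seed_point = full$nb_centre)
  cf <- contact_fraction(nb, voxel_grid(array(fr$glia$values >= 0.5,
                                              dim(fr$glia$values)), fr$glia$spacing))
  expect_equal(cf$fraction, 100, tolerance = 0.5)
})

test_that("probability maps hit the requested super-level volume exactly", {
  pm <- render_probability_map(100, fov_um = 10, spacing = c(0.5, 0.5, 0.4), seed = 4)
  expect_identical(sum(pm$values >= 0.5), 1000L)
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  empty <- render_probability_map(0, fov_um = 5, spacing = c(0.5, 0.5, 0.5), seed = 4)
  expect_identical(sum(empty$values >= 0.5), 0L)
  set.seed(11)
  for (v in runif(5, 5, 200)) {
    pm <- render_probability_map(v, fov_um = 12, spacing = c(0.8, 0.26, 0.26), seed = 8)
    vv <- voxel_volume(pm)
    expect_lt(abs(sum(pm$values >= 0.5) * vv - v), vv) # rounding to whole voxels
  }
  expect_error(render_probability_map(1e6, fov_um = 5, spacing = c(1, 1, 1), seed = 1),
               "exceeds the field of view")
})

test_that("a scene too large for its field of view is refused with the needed extent", {
  cfg <- scene_config(nb_radius = 10, fov_um = 15)
  tr <- sample_division_series("control", 2, seed = 1, config = cfg)
  expect_error(render_frame(tr, tr$cycles[[1]]$telophase_frame, channels = "membrane"),
               "needs at least")
})

test_that("written scenes round-trip through TIFF stacks and a truth sidecar", {
  tr <- sample_division_series("control", 2, seed = 21,
                               config = scene_config(frames_per_cycle = 4L))
  dir <- withr::local_tempdir()
  write_scene(tr, dir, frames = 2L, channels = "membrane", noise = FALSE)
  expect_true(file.exists(file.path(dir, "membrane.tif")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  g <- read_stack(file.path(dir, "membrane.tif"))
  expect_equal(dim(g$values)[1], 2)
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(tj$seed, 21)
  expect_equal(tj$spacing, c(0.8, 0.26, 0.26))
})
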