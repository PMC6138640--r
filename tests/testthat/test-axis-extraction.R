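test_that("membrane segmentation recovers cell volume and rejects junk input", {
  tr <- sample_division_series("control", 2, seed = 7)
  fr <- render_frame(tr, tr$cycles[[1]]$rounding_frame,
                     channels = "membrane", noise = FALSE)
  m <- segment_cell(fr$membrane, seed_point = tr$nb_centre)
  vol <- sum(m$values) * voxel_volume(m)
  expect_lt(abs(vol - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.05)
  blank <- voxel_grid(array(0.5, c(8, 10, 10)), voxel_spacing(0.8, 0.26, 0.26))
  expect_error(segment_cell(blank), "blank image")
  far <- tr$nb_centre + c(0, 11, 11)
  expect_error(segment_cell(fr$membrane, seed_point = far), "outside any cell interior")
})

test_that("touching cells are split at the shared membrane", {
  tr <- sample_division_series("control", 2, seed = 11)
  fr <- render_frame(tr, tr$cycles[[2]]$rounding_frame,
                     channels = "membrane", noise = FALSE)
  nb <- segment_cell(fr$membrane, seed_point = tr$nb_centre)
  gmc_c <- tr$cycles[[1]]$gmc_centre
  gm <- segment_cell(fr$membrane, seed_point = gmc_c)
  expect_false(any(nb$values & gm$values))
  # the NB mask must not eat the daughter's interior (and vice versa)
  sp <- unclass(tr$spacing)
  gmc_truth <- ball_at(gmc_c, tr$gmc_radius, dim(nb$values), sp)
  nb_truth <- ball_at(tr$nb_centre, tr$nb_radius, dim(nb$values), sp)
  expect_lt(sum(nb$values & gmc_truth$values) / sum(gmc_truth$values), 0.05)
  expect_lt(sum(gm$values & nb_truth$values) / sum(nb_truth$values), 0.05)
})

test_that("telophase poles are recovered for controlled orientations", {
  # axis along x
  tr <- scene_with_dirs(list(c(0, 0, 1)))
  fr <- render_frame(tr, tr$cycles[[1]]$telophase_frame,
                     channels = "membrane", noise = FALSE)
  ax <- find_poles_from_shape(segment_cell(fr$membrane, seed_point = tr$nb_centre))
  expect_lt(axis_angle(ax, tr$cycles[[1]]$true_axis), 2)
  expect_gt(attr(ax, "lobe_volumes")[1], attr(ax, "lobe_volumes")[2])

  # rotated 30 degrees about z, tilted 20 degrees into z, anisotropic grid
  th <- 30 * pi / 180; ph <- 20 * pi / 180
  u <- c(sin(ph), cos(ph) * sin(th), cos(ph) * cos(th))
  tr2 <- scene_with_dirs(list(u))
  fr2 <- render_frame(tr2, tr2$cycles[[1]]$telophase_frame,
                      channels = "membrane", noise = FALSE)
  ax2 <- find_poles_from_shape(segment_cell(fr2$membrane, seed_point = tr2$nb_centre))
  expect_lt(axis_angle(ax2, tr2$cycles[[1]]$true_axis), 5)

  # a round cell has no neck and is not telophase
  ball <- make_ball(5, c(0.8, 0.26, 0.26))
  expect_error(find_poles_from_shape(ball), "not telophase")
})

test_that("a user bisecting line replaces the automatic long axis", {
  u <- c(0.2, 0.7, 0.6857886) # roughly diagonal unit vector
  u <- u / sqrt(sum(u^2))
  tr <- scene_with_dirs(list(u))
  fr <- render_frame(tr, tr$cycles[[1]]$telophase_frame,
                     channels = "membrane", noise = FALSE)
  m <- segment_cell(fr$membrane, seed_point = tr$nb_centre)
  line <- rbind(tr$nb_centre - 5 * u, tr$nb_centre + 5 * u)
  ax <- find_poles_from_shape(m, bisect_line = line)
  expect_lt(axis_angle(ax, tr$cycles[[1]]$true_axis), 3)
  expect_error(find_poles_from_shape(m, bisect_line = rbind(c(0, 1, 1), c(5, 1, 1))),
               "degenerate bisecting line")
})

test_that("centrosome-based axes agree with truth and the shape method", {
  o <- c(0, 0, 0)
  ax <- axis_from_centrosomes(o, c(4, 0, 0))
  expect_equal(axis_length(ax), 4)
  expect_error(axis_from_centrosomes(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  set.seed(3)
  for (k in 1:3) {
    tr <- sample_division_series("control", 2, seed = 40 + k)
    cy <- tr$cycles[[2]]
    fr <- render_frame(tr, cy$telophase_frame,
                       channels = c("membrane", "centrosomes"), noise = FALSE)
    shape_ax <- find_poles_from_shape(segment_cell(fr$membrane,
                                                   seed_point = tr$nb_centre))
    cax <- centrosome_axis(fr$centrosomes, reference_axis = shape_ax)
    expect_lt(axis_angle(cax, cy$true_axis), 2)
    expect_lt(axis_angle(cax, shape_ax), 3) # method agreement
  }
})

test_that("the same scene measured at different anisotropies agrees", {
  u <- c(0.3, -0.6, 0.7416198); u <- u / sqrt(sum(u^2))
  axes <- list()
  for (sp in list(c(0.8, 0.26, 0.26), c(0.26, 0.26, 0.26))) {
    tr <- scene_with_dirs(list(u), config = scene_config(spacing = sp))
    fr <- render_frame(tr, tr$cycles[[1]]$telophase_frame,
                       channels = "membrane", noise = FALSE)
    axes[[length(axes) + 1]] <-
      find_poles_from_shape(segment_cell(fr$membrane, seed_point = tr$nb_centre))
  }
  expect_lt(axis_angle(axes[[1]], axes[[2]]), 3)
})

test_that("rounding onset is detected from sphericity crossings", {
  sp <- c(0.8, 0.26, 0.26)
  ball <- make_ball(5, sp)
  ro <- detect_rounding_onset(list(ball, ball, ball))
  expect_identical(ro$frame, 0L)
  expect_length(ro$qc, 0)

  dims <- as.integer(ceiling(24 / sp)) + 1L
  lumpy <- ellipsoid_mask(c(3.4, 3.4, 10), dims, sp)   # elongated interphase proxy
  round_m <- ellipsoid_mask(c(5, 5, 5), dims, sp)
  series <- list(lumpy, lumpy, lumpy, round_m, round_m)
  ro2 <- detect_rounding_onset(series)
  expect_identical(ro2$frame, 3L)

  elong <- lapply(c(8, 9, 10, 11), function(a)
    ellipsoid_mask(c(3, 3, a), dims, sp))
  ro3 <- detect_rounding_onset(elong)
  expect_identical(ro3$frame, 3L)
  expect_identical(ro3$qc, "never-rounded")
  expect_error(detect_rounding_onset(list(ball, ball)), "at least 3")
})

test_that("rounding onset matches the generator's rounding frame", {
  tr <- sample_division_series("control", 2, seed = 19)
  fpc <- tr$config$frames_per_cycle
  frames <- 0:(fpc - 1)
  masks <- lapply(frames, function(f) {
    fr <- render_frame(tr, f, channels = "membrane", noise = FALSE)
    segment_cell(fr$membrane, seed_point = tr$nb_centre)
  })
  ro <- detect_rounding_onset(masks)
  expect_lte(abs(ro$frame - tr$cycles[[1]]$rounding_frame), 1)
})

test_that("the daughter-cue axis runs through the contact patch", {
  sp <- c(0.5, 0.25, 0.25)
  dims <- c(41L, 81L, 81L)
  nb_c <- c(10, 10, 10)
  nb <- ball_at(nb_c, 4, dims, sp)
  gmc <- ball_at(nb_c + c(-6.5, 0, 0), 2.4, dims, sp) # tangent below in z
  ga <- gmc_axis(nb, gmc)
  expect_equal(unclass(unit_vector(ga)), c(z = -1, y = 0, x = 0), tolerance = 0.05)
  expect_length(attr(ga, "qc"), 0)
  expect_equal(axis_length(ga), 1, tolerance = 1e-9)

  far <- ball_at(nb_c + c(0, 9.5, 0), 2, dims, sp)    # not touching
  ga2 <- gmc_axis(nb, far)
  expect_identical(attr(ga2, "qc"), "no-contact-patch")
  expect_error(gmc_axis(nb, voxel_grid(array(FALSE, dims), sp)), "empty mask")
  expect_error(gmc_axis(nb, nb), "disjoint")
})

test_that("the cue axis measured from rendered scenes points at the daughter", {
  tr <- sample_division_series("control", 2, seed = 11)
  fr <- render_frame(tr, tr$cycles[[2]]$rounding_frame,
                     channels = "membrane", noise = FALSE)
  nb <- segment_cell(fr$membrane, seed_point = tr$nb_centre)
  gm <- segment_cell(fr$membrane, seed_point = tr$cycles[[1]]$gmc_centre)
  ga <- gmc_axis(nb, gm)
  truth_cue <- axis3d(tr$nb_centre, tr$cycles[[1]]$gmc_centre)
  expect_lt(axis_angle(ga, truth_cue), 3)
})

test_that("alpha/beta bookkeeping pairs cycles correctly", {
  o <- c(0, 0, 0)
  r1 <- division_record("nb1", 1, axis3d(o, c(0, 0, 1)))
  r2 <- division_record("nb1", 2, axis3d(o, c(0, 0, 2)))
  r4 <- division_record("nb1", 4, axis3d(o, c(0, 1, 0)))
  r_other <- division_record("nb2", 2, axis3d(o, c(1, 0, 0)))
  cue <- list(list(nb_id = "nb1", cycle = 2, axis = axis3d(o, c(0, 1, 1))))
  ang <- measure_alpha_beta(list(r1, r2, r4, r_other), gmc_axes = cue)
  expect_equal(ang$angle_deg[ang$kind == "alpha"], 0)
  expect_equal(ang$angle_deg[ang$kind == "beta"], 45, tolerance = 1e-9)
  expect_true(any(grepl("non-consecutive", attr(ang, "skipped"))))
})

test_that("daughter-centred sampling reproduces beta < alpha on average", {
  alphas <- c(); betas <- c()
  for (s in 1:200) {
    tr <- sample_division_series("control_beta", 2, seed = 3000 + s,
                                 next_axis_mode = "gmc",
                                 gmc_displacement_deg = 25)
    ta <- truth_angles(tr)
    alphas <- c(alphas, ta$alpha_deg)
    betas <- c(betas, ta$beta_deg)
  }
  expect_lt(mean(betas), mean(alphas))
})
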