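test_that("isosurface areas match analytic solids", {
  sphere_area <- 4 * pi * 100
  for (sp in list(c(0.26, 0.26, 0.26), c(0.8, 0.26, 0.26))) {
    a <- isosurface_area(make_ball(10, sp))
    expect_lt(abs(a - sphere_area) / sphere_area, 0.05)
  }
  # anisotropic and isotropic renderings of the same sphere agree
  a1 <- isosurface_area(make_ball(10, c(0.8, 0.26, 0.26)))
  a2 <- isosurface_area(make_ball(10, c(0.26, 0.26, 0.26)))
  expect_lt(abs(a1 - a2) / a2, 0.05)

  # axis-aligned cube, side 10 um
  sp <- c(0.26, 0.26, 0.26)
  dims <- rep(47L, 3)
  cube <- array(FALSE, dims)
  cube[4:42, 4:42, 4:42] <- TRUE # 39 voxels * 0.26 um = 10.14 um side
  side <- 39 * 0.26
  expect_lt(abs(isosurface_area(voxel_grid(cube, sp)) - 6 * side^2) / (6 * side^2),
            0.05)
  expect_error(isosurface_area(voxel_grid(array(FALSE, c(4, 4, 4)), sp)), "empty mask")
})

test_that("sphere area follows the r^2 scaling law", {
  rs <- c(3, 5, 10)
  as_ <- vapply(rs, function(r) isosurface_area(make_ball(r, c(0.26, 0.26, 0.26))),
                numeric(1))
  slope <- coef(lm(log(as_) ~ log(rs)))[2]
  expect_lt(abs(slope - 2), 0.05)
})

test_that("contact fractions follow the spherical-cap closed form", {
  cfg <- scene_config(nb_radius = 10, fov_um = 26)
  for (th in c(30, 60, 90, 120)) {
    f <- 1 - (1 - cos(th * pi / 180)) / 2
    tr <- sample_division_series("control", 2, seed = 5, config = cfg,
                                 glia_coverage_fraction = f)
    fr <- render_frame(tr, tr$cycles[[1]]$rounding_frame,
                       channels = c("membrane", "glia"), noise = FALSE)
    nb <- segment_cell(fr$membrane, seed_point = tr$nb_centre)
    glia <- voxel_grid(array(fr$glia$values >= 0.5, dim(fr$glia$values)),
                       fr$glia$spacing)
    cf <- contact_fraction(nb, glia)
    expect_lt(abs(cf$fraction - 100 * f), 3)
    expect_true(cf$contact_area <= cf$nb_area)
  }
})

test_that("contact fraction is monotone in coverage and contact distance", {
  cfg <- scene_config(nb_radius = 5)
  fr_of <- function(f) {
    tr <- sample_division_series("control", 2, seed = 5, config = cfg,
                                 glia_coverage_fraction = f)
    render_frame(tr, tr$cycles[[1]]$rounding_frame,
                 channels = c("membrane", "glia"), noise = FALSE)
  }
  seedp <- sample_division_series("control", 2, seed = 5, config = cfg)$nb_centre
  fracs <- vapply(c(0.3, 0.6, 0.9), function(f) {
    fr <- fr_of(f)
    nb <- segment_cell(fr$membrane, seed_point = seedp)
    contact_fraction(nb, voxel_grid(array(fr$glia$values >= 0.5,
                                          dim(fr$glia$values)),
                                    fr$glia$spacing))$fraction
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  fr <- fr_of(0.6)
  nb <- segment_cell(fr$membrane, seed_point = seedp)
  glia <- voxel_grid(array(fr$glia$values >= 0.5, dim(fr$glia$values)),
                     fr$glia$spacing)
  f1 <- contact_fraction(nb, glia, contact_distance = 0.3)$fraction
  f2 <- contact_fraction(nb, glia, contact_distance = 0.8)$fraction
  expect_lte(f1, f2)
  expect_error(contact_fraction(nb, make_ball(2, c(1, 1, 1))), "mismatched grids")
})

test_that("EdU volumes are exact voxel arithmetic normalised by exposure", {
  pm <- render_probability_map(100, fov_um = 10, spacing = c(0.5, 0.5, 0.4), seed = 2)
  r <- edu_volume(pm, exposure_h = 20)
  expect_equal(r$foreground_volume, 1000 * 0.1)
  expect_equal(r$normalized_volume, 5)
  zero <- voxel_grid(array(0, c(4, 5, 5)), c(0.5, 0.5, 0.4))
  expect_equal(edu_volume(zero, 21)$foreground_volume, 0)
  expect_error(edu_volume(pm, 0), "positive")
  bad <- voxel_grid(array(1.5, c(2, 2, 2)), c(1, 1, 1))
  expect_error(edu_volume(bad, 20), "\\[0, 1\\]")
  # invariant under monotone remapping that fixes the 0.5 level set
  remap <- pm
  p <- pm$values
  remap$values <- p^1.5 / (p^1.5 + (1 - p)^1.5)
  expect_equal(edu_volume(remap, 20)$foreground_volume, r$foreground_volume)
})

test_that("the built-in voxel classifier separates and degrades gracefully", {
  set.seed(14)
  img <- array(rnorm(10 * 40 * 40, 0.2, 0.05), c(10, 40, 40))
  img[, 10:20, 10:20] <- rnorm(10 * 11 * 11, 0.8, 0.05)
  g <- voxel_grid(img, voxel_spacing(0.5, 0.3, 0.3))
  lab <- array(0L, dim(img))
  lab[1:3, 1:5, 1:5] <- 1L
  lab[1:3, 12:18, 12:18] <- 2L
  p <- classify_voxels(g, lab)
  held_fg <- p$values[5:10, 12:18, 12:18]
  held_bg <- p$values[5:10, 25:35, 25:35]
  expect_gte(mean(held_fg > 0.5), 0.99)
  expect_gte(mean(held_bg < 0.5), 0.99)

  # swapping the training labels flips the probabilities
  lab_sw <- lab
  lab_sw[lab == 1L] <- 9L; lab_sw[lab == 2L] <- 1L; lab_sw[lab_sw == 9L] <- 2L
  p_sw <- classify_voxels(g, lab_sw)
  expect_equal(p_sw$values, 1 - p$values, tolerance = 1e-6)

  # identical class distributions: probabilities hover near the class prior
  set.seed(15)
  flat <- voxel_grid(array(rnorm(8000, 0.5, 0.05), c(20, 20, 20)),
                     voxel_spacing(1, 1, 1))
  labf <- array(0L, c(20, 20, 20))
  labf[1:2, 1:10, 1:10] <- 1L  # 200 background labels
  labf[4:5, 1:5, 1:10] <- 2L   # 100 foreground labels -> prior 1/3
  pf <- classify_voxels(flat, labf)
  expect_lt(abs(mean(pf$values) - 1 / 3), 0.1)
  expect_error(classify_voxels(flat, array(0L, c(20, 20, 20))), "both classes")
})
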