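test_that("stacks round-trip through TIFF + sidecar with spacing intact", {
  set.seed(2)
  g3 <- voxel_grid(array(runif(4 * 6 * 5) * 7 - 2, c(4, 6, 5)),
                   voxel_spacing(0.8, 0.26, 0.26), "membrane")
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(g3, f)
  back <- read_stack(f)
  expect_equal(back$values, g3$values, tolerance = 1e-6)
  expect_identical(unclass(back$spacing), unclass(g3$spacing))
  expect_identical(back$channel, "membrane")

  g4 <- voxel_grid(array(runif(2 * 3 * 4 * 4), c(2, 3, 4, 4)),
                   voxel_spacing(1.2, 0.5, 0.5))
  f4 <- withr::local_tempfile(fileext = ".tif")
  write_stack(g4, f4)
  back4 <- read_stack(f4)
  expect_equal(dim(back4$values), c(2, 3, 4, 4))
  expect_equal(back4$values, g4$values, tolerance = 1e-6)
})

test_that("spacing resolution refuses silent defaults and honours overrides", {
  # bare multipage TIFF without sidecar: readable only with explicit spacing
  pages <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 32L, compression = "none")
  expect_error(read_stack(f), "missing voxel spacing")
  g <- read_stack(f, spacing = c(0.8, 0.26, 0.26))
  expect_equal(g$spacing[[1]], 0.8)
  # single page with no z metadata is ambiguous
  f1 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), f1, bits.per.sample = 32L,
                  compression = "none")
  expect_error(read_stack(f1, spacing = c(1, 1, 1)), "ambiguous")
  expect_error(read_stack(withr::local_tempfile(fileext = ".tif")), "no such file")
})

test_that("OME-XML PhysicalSize metadata yields the 0.8 um z-step", {
  f <- file.path(withr::local_tempdir(), "probe.ome.tif")
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = np.arange(3*8*8, dtype='float32').reshape(3,8,8)/192.0\n",
    "tifffile.imwrite(%s, a, ome=True, metadata={'axes':'ZYX',",
    "'PhysicalSizeZ':0.8,'PhysicalSizeY':0.26,'PhysicalSizeX':0.26})\n"),
    shQuote(f))
  status <- system2("python", "-", input = script, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  g <- read_stack(f)
  expect_equal(g$spacing[[1]], 0.8)
  expect_equal(g$spacing[[3]], 0.26)
  expect_equal(dim(g$values)[2], 3)
})

test_that("gaussian blur is separable, mass-conserving and matches dense convolution", {
  a <- array(0, c(11, 11, 11)); a[6, 6, 6] <- 1
  expect_identical(gaussian_blur_3d(a, c(0, 0, 0)), a)
  b <- gaussian_blur_3d(a, c(0.8, 0.8, 0.8))
  expect_equal(sum(b), 1, tolerance = 1e-6)

  # dense-kernel oracle on an 11^3 grid with reflective boundaries
  set.seed(9)
  x <- array(runif(11^3), c(11, 11, 11))
  sig <- c(0.8, 1.1, 0.6)
  kern1 <- function(s) {
    r <- ceiling(4 * s); k <- exp(-0.5 * ((-r):r)^2 / s^2); k / sum(k)
  }
  reflect_idx <- function(i, n) {
    while (any(i < 1 | i > n)) { i[i < 1] <- 1 - i[i < 1]; i[i > n] <- 2 * n + 1 - i[i > n] }
    i
  }
  conv_axis <- function(arr, k, ax) {
    r <- (length(k) - 1) / 2
    out <- array(0, dim(arr))
    n <- dim(arr)[ax]
    for (t in -r:r) {
      idx <- reflect_idx(seq_len(n) + t, n)
      sl <- switch(ax, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      out <- out + k[t + r + 1] * sl
    }
    out
  }
  oracle <- conv_axis(conv_axis(conv_axis(x, kern1(sig[1]), 1), kern1(sig[2]), 2),
                      kern1(sig[3]), 3)
  expect_equal(gaussian_blur_3d(x, sig), oracle, tolerance = 1e-8)

  # isotropic blur commutes with axis transposition
  bi <- gaussian_blur_3d(x, c(0.9, 0.9, 0.9))
  expect_equal(aperm(bi, c(2, 3, 1)),
               gaussian_blur_3d(aperm(x, c(2, 3, 1)), c(0.9, 0.9, 0.9)),
               tolerance = 1e-10)
  expect_error(gaussian_blur_3d(x, c(-1, 0, 0)), "nonnegative")
})

test_that("gamma adjustment rescales, is display-only and guards measurements", {
  g <- voxel_grid(array(seq(0, 4, length.out = 24), c(2, 3, 4)),
                  voxel_spacing(1, 1, 1))
  out <- gamma_adjust(g, gamma = 1)
  expect_equal(range(out$values), c(0, 1))
  out75 <- gamma_adjust(g, gamma = 0.75)
  expect_equal(min(out75$values), 0)
  expect_equal(max(out75$values), 1)
  mid <- gamma_adjust(voxel_grid(array(c(0, 0.5, 1), c(3, 1, 1)), c(1, 1, 1)), 0.75)
  expect_equal(mid$values[2, 1, 1], 0.5^0.75, tolerance = 1e-12)
  expect_true(isTRUE(attr(out75, "display_only")))
  expect_error(segment_cell(out75), "display only")
  expect_error(edu_volume(out75, 20), "display only")
  neg <- voxel_grid(array(-1, c(2, 2, 2)), c(1, 1, 1))
  expect_error(gamma_adjust(neg), "nonnegative")
})
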