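# Phantom generator: determinism, degenerate scenes, speckle statistics,
# PSF anisotropy, and the exactness of the three virtual-translation
# oracles.

test_that("empty scene yields a constant zero volume", {
  spec <- phantom_spec(shape = c(32, 32, 32), fiber_count = 0,
                       speckle = FALSE, noise_snr = NULL, seed = 1)
  v <- generate_phantom(spec)
  expect_true(all(unclass(v) == 0))
})

test_that("identical specs regenerate bit-identical volumes", {
  spec <- phantom_spec(shape = c(48, 48, 48), fiber_count = 50, seed = 42)
  expect_identical(unclass(generate_phantom(spec)),
                   unclass(generate_phantom(spec)))
})

test_that("invalid specs are rejected naming the field", {
  expect_error(phantom_spec(shape = c(16, 64, 64)), "shape")
  expect_error(phantom_spec(spacing = c(0.5, -1, 0.7)), "spacing")
  expect_error(phantom_spec(fiber_count = -3), "fiber_count")
  expect_error(phantom_spec(psf_fwhm = c(2)), "psf_fwhm")
})

test_that("structureless speckle has fully developed statistics", {
  v <- generate_phantom(phantom_spec(shape = c(64, 64, 64), fiber_count = 0,
                                     speckle = TRUE, noise_snr = NULL,
                                     seed = 3))
  x <- as.vector(unclass(v))
  contrast <- sd(x) / mean(x)
  expect_gt(contrast, 0.3)
  expect_lt(contrast, 1.2)
  # unimodal with positive skew (Rayleigh-like)
  expect_gt(mean(((x - mean(x)) / sd(x))^3), 0)
})

test_that("autocorrelation anisotropy follows the axial/transverse PSF", {
  spec <- phantom_spec(shape = c(128, 128, 96), spacing = c(0.53, 0.53, 0.73),
                       fiber_count = 200, speckle = FALSE, noise_snr = NULL,
                       seed = 7)
  v <- unclass(generate_phantom(spec))
  v <- v - mean(v)
  ac <- Re(fft(Mod(fft(v))^2, inverse = TRUE)) / length(v)
  ac <- ac / ac[1, 1, 1]
  # FWHM of the central autocorrelation lobe along one axis, in voxels
  fwhm_axis <- function(prof) {
    below <- which(prof < 0.5)[1]
    # linear interpolation between the straddling samples; lag = index - 1
    lo <- below - 1
    2 * (lo - 1 + (prof[lo] - 0.5) / (prof[lo] - prof[below]))
  }
  fx <- fwhm_axis(ac[1:20, 1, 1]); fz <- fwhm_axis(ac[1, 1, 1:20])
  # physical FWHMs must reproduce the anisotropy of the blur: the
  # autocovariance of a Gaussian-blurred random scene is Gaussian with
  # sqrt(2) times the blur width, so the ratio of physical widths equals
  # the ratio of combined blur sigmas.
  sig <- sqrt(spec$fiber_radius^2 +
                (c(2.0, 2.6) / (2 * sqrt(2 * log(2))))^2)
  expect_gt(fz * 0.73, fx * 0.53)           # axial coarser in um
  expect_equal((fz * 0.73) / (fx * 0.53), sig[2] / sig[1], tolerance = 0.15)
})

test_that("integer shift is an exact circular roll with an inverse", {
  v <- phantom_small()
  expect_identical(unclass(apply_integer_shift(v, c(0, 0, 0))), unclass(v))
  back <- apply_integer_shift(apply_integer_shift(v, c(6, 0, 0)),
                              c(-6, 0, 0))
  expect_identical(unclass(back), unclass(v))
  expect_error(apply_integer_shift(v, c(1.5, 0, 0)), "apply_subvoxel_shift")
  expect_error(apply_integer_shift(v, c(40, 0, 0)), "shape/4")
})

test_that("integer shift moves the full cross-correlation peak to its lag", {
  v <- unclass(phantom_small())[1:32, 1:32, 1:32]
  shifted <- unclass(apply_integer_shift(
    volume_image(v, c(1, 1, 1)), c(4, 4, 0)))
  bf <- brute_force_peak(v, shifted, 6)
  expect_equal(bf$lag, c(4, 4, 0))
})

test_that("subvoxel shift matches the integer roll at whole voxels", {
  v <- phantom_small()
  sp <- voxel_spacing(v)
  same <- apply_subvoxel_shift(v, c(0, 0, 0))
  expect_lt(max(abs(unclass(same) - unclass(v))), 1e-9)
  f <- apply_subvoxel_shift(v, c(3 * sp[1], 0, 0))
  i <- apply_integer_shift(v, c(3, 0, 0))
  interior <- 5:60
  expect_lt(max(abs(unclass(f)[interior, interior, interior] -
                    unclass(i)[interior, interior, interior])) /
              max(abs(unclass(v))), 1e-6)
})

test_that("a blurred point source moves by the exact subvoxel amount", {
  d <- c(48, 48, 64)
  img <- array(0, dim = d)
  img[24, 24, 28] <- 1
  img <- dvc3d:::blur_gaussian(img, c(2, 2, 2))
  vol <- volume_image(img, c(0.73, 0.73, 0.73))
  shifted <- apply_subvoxel_shift(vol, c(0, 0, 4.42))  # 6.054 voxels
  centroid_z <- function(a) {
    w <- pmax(a, 0)
    sum(rep(seq_len(dim(a)[3]), each = prod(dim(a)[1:2])) * w) / sum(w)
  }
  moved <- centroid_z(unclass(shifted)) - centroid_z(unclass(vol))
  expect_equal(moved, 4.42 / 0.73, tolerance = 0.01 / 6.054)
})

test_that("warping by simple fields matches the dedicated shift operators", {
  v <- phantom_small()
  sp <- voxel_spacing(v)
  zero <- uniform_field(dim(v), sp, c(0, 0, 0))
  expect_equal(unclass(apply_field(v, zero)), unclass(v), tolerance = 1e-12,
               ignore_attr = TRUE)
  one <- uniform_field(dim(v), sp, c(sp[1], 0, 0))
  warped <- apply_field(v, one)
  rolled <- apply_integer_shift(v, c(1, 0, 0))
  interior <- 3:62
  expect_lt(max(abs(unclass(warped)[interior, interior, interior] -
                    unclass(rolled)[interior, interior, interior])), 1e-9)
})

test_that("traction fields decay monotonically from the source", {
  tf <- traction_field(c(48, 48, 48), c(0.5, 0.5, 0.7), c(40, 24, 24),
                       peak_um = 5, decay_um = 20)
  mag <- field_magnitude(tf)
  along_x <- mag[48:1, 24, 24]
  r <- abs((48:1) - 40) * 0.5
  expect_true(all(diff(mag[40:1, 24, 24]) < 0))
  expect_equal(max(mag), 5, tolerance = 1e-9)
  expect_equal(as.vector(along_x), 5 * exp(-r / 20), tolerance = 1e-9)
})
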