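# DVC core: config validation, subset correlation against the brute-force
# oracle, subpixel accuracy, and the field-level invariants (shift
# equivariance, antisymmetry, graceful degradation with noise).

test_that("config validation enforces the subset contract", {
  expect_error(dvc_config(subset_size = 48), "power of two")
  expect_error(dvc_config(subset_size = 16), "power of two")
  expect_error(dvc_config(subset_size = 64, grid_spacing = 80), "grid_spacing")
  expect_silent(dvc_config(subset_size = 128))
  expect_equal(dvc_config(subset_size = 128)$grid_spacing, 32L)
})

test_that("identical blocks correlate at zero lag with unit peak", {
  b <- unclass(phantom_small())[1:32, 1:32, 1:32]
  res <- correlate_subset(b, b)
  expect_equal(res$shift, c(0, 0, 0))
  expect_equal(res$peak, 1.0, tolerance = 1e-12)
})

test_that("integer peak equals exhaustive integer-lag search", {
  v <- unclass(phantom_small())
  shifts <- list(c(4, 0, 0), c(0, -3, 2), c(5, 5, 0), c(-2, 4, -4))
  for (s in shifts) {
    a <- v[17:48, 17:48, 17:48]
    rolled <- dvc3d:::roll_array(v, s)[17:48, 17:48, 17:48]
    res <- correlate_subset(a, rolled)
    bf <- brute_force_peak(a, rolled, 6)
    expect_equal(round(res$shift), bf$lag,
                 label = paste("fft peak for shift", paste(s, collapse = ",")))
  }
})

test_that("subvoxel shifts are recovered within a tenth of a voxel", {
  v <- phantom_small()
  sp <- voxel_spacing(v)
  shifted <- apply_subvoxel_shift(v, c(1.5 * sp[1], 0, 0))
  a <- unclass(v)[17:48, 17:48, 17:48]
  b <- unclass(shifted)[17:48, 17:48, 17:48]
  res <- correlate_subset(a, b)
  expect_equal(res$shift[1], 1.5, tolerance = 0.1 / 1.5)
  expect_lt(abs(res$shift[2]), 0.1)
  expect_lt(abs(res$shift[3]), 0.1)
})

test_that("zero-variance blocks flag the node instead of erroring", {
  flat <- array(0.5, dim = c(32, 32, 32))
  tex <- unclass(phantom_small())[1:32, 1:32, 1:32]
  res <- correlate_subset(flat, tex)
  expect_false(res$ok)
  expect_true(is.na(res$peak))
})

test_that("a volume correlated with itself gives a zero field", {
  v <- phantom_small()
  fld <- run_dvc(v, v, cfg32())
  expect_true(all(fld$valid))
  expect_equal(max(abs(fld$u)), 0, tolerance = 1e-9)
  expect_equal(max(abs(fld$v)), 0, tolerance = 1e-9)
  expect_equal(max(abs(fld$w)), 0, tolerance = 1e-9)
  expect_true(all(fld$quality[fld$valid] > 0.99))
})

test_that("shift equivariance: integer and subvoxel shifts are recovered", {
  v <- phantom_mid()
  sp <- voxel_spacing(v)
  ref <- crop_margin(v, 8)
  # integer: every valid node within 0.1 voxel
  fld <- run_dvc(ref, crop_margin(apply_integer_shift(v, c(6, -3, 2)), 8),
                 cfg64(passes = 1))
  expect_true(all(abs(fld$u[fld$valid] / sp[1] - 6) < 0.1))
  expect_true(all(abs(fld$v[fld$valid] / sp[2] + 3) < 0.1))
  expect_true(all(abs(fld$w[fld$valid] / sp[3] - 2) < 0.1))
  # subvoxel: within 0.15 voxel
  s_um <- c(1.2, 0, -0.9)
  flds <- run_dvc(ref, crop_margin(apply_subvoxel_shift(v, s_um), 8),
                  cfg64(passes = 1))
  expect_true(all(abs((flds$u[flds$valid] - s_um[1]) / sp[1]) < 0.15))
  expect_true(all(abs((flds$w[flds$valid] - s_um[3]) / sp[3]) < 0.15))
})

test_that("swapping reference and deformed negates the field", {
  v <- phantom_mid()
  ref <- crop_margin(v, 8)
  def <- crop_margin(apply_integer_shift(v, c(4, 0, -2)), 8)
  fwd <- run_dvc(ref, def, cfg64(passes = 1))
  rev <- run_dvc(def, ref, cfg64(passes = 1))
  ok <- fwd$valid & rev$valid
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(fwd$u[ok] + rev$u[ok])), 0.1 * voxel_spacing(v)[1])
  expect_lt(max(abs(fwd$w[ok] + rev$w[ok])), 0.1 * voxel_spacing(v)[3])
})

test_that("noise-induced recovery error grows as acquisition SNR drops", {
  base <- phantom_spec(shape = c(96, 96, 64), fiber_count = 200,
                       noise_snr = NULL, seed = 77)
  clean <- generate_phantom(base)
  sp <- voxel_spacing(clean)
  moved <- apply_integer_shift(clean, c(3, 0, 0))
  # noise-free analysis: the estimator's intrinsic result for this scene
  fld0 <- run_dvc(crop_margin(clean, 5), crop_margin(moved, 5), cfg32())
  errs <- vapply(c(35, 25, 15), function(snr) {
    ref <- add_noise(clean, snr, seed = 900 + snr)
    def <- add_noise(moved, snr, seed = 1900 + snr)
    fld <- run_dvc(crop_margin(ref, 5), crop_margin(def, 5), cfg32())
    ok <- fld$valid & fld0$valid
    median(sqrt((fld$u[ok] - fld0$u[ok])^2 + (fld$v[ok] - fld0$v[ok])^2 +
                  (fld$w[ok] - fld0$w[ok])^2) / sp[1])
  }, 0)
  expect_true(all(diff(errs) > 0))
})

test_that("volumes of unequal shape or spacing are rejected", {
  v <- phantom_small()
  small <- volume_image(unclass(v)[1:48, , ], voxel_spacing(v))
  expect_error(run_dvc(v, small, cfg32()), "equal shape")
  resp <- volume_image(unclass(v), c(1, 1, 1))
  expect_error(run_dvc(v, resp, cfg32()), "spacing")
})

test_that("excluded-mask nodes are invalidated", {
  v <- phantom_small()
  mask <- array(FALSE, dim = dim(v))
  mask[1:32, , ] <- TRUE
  fld <- run_dvc(v, v, cfg32(), exclude_mask = mask)
  centers_x <- fld$origin[1] + (seq_len(dim(fld$u)[1]) - 1) * fld$step[1]
  inside <- array(rep(centers_x <= 32, times = prod(dim(fld$u)[2:3])),
                  dim(fld$u))
  expect_true(all(!fld$valid[inside]))
  expect_true(all(fld$valid[!inside]))
})
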