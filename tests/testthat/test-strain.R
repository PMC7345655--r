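# Strain mapper: smoothing behavior, analytic exactness of the stencil,
# and frame invariance.

dense_field <- function(fun, d = c(9, 9, 9), spacing = c(0.5, 0.5, 0.7),
                        step = 4) {
  gx <- (1 + (seq_len(d[1]) - 1) * step - 1) * spacing[1]
  gy <- (1 + (seq_len(d[2]) - 1) * step - 1) * spacing[2]
  gz <- (1 + (seq_len(d[3]) - 1) * step - 1) * spacing[3]
  g <- expand.grid(x = gx, y = gy, z = gz)
  out <- fun(g$x, g$y, g$z)
  deformation_field(array(out$u, d), array(out$v, d), array(out$w, d),
                    origin = c(1, 1, 1), step = rep(step, 3),
                    spacing = spacing)
}

test_that("box filtering preserves constant and affine fields", {
  f <- dense_field(function(x, y, z) list(u = x * 0 + 1, v = x * 0, w = x * 0))
  expect_equal(smooth_field(f)$u, f$u, tolerance = 1e-12)
  g <- dense_field(function(x, y, z) list(u = 0.01 * x, v = 0.02 * y,
                                          w = -0.01 * z))
  sg <- smooth_field(g)
  interior <- 2:8
  expect_equal(sg$u[interior, interior, interior],
               g$u[interior, interior, interior], tolerance = 1e-12)
  expect_error(smooth_field(g, kernel = c(2, 3, 3)), "odd")
})

test_that("box filtering shrinks white noise by sqrt(kernel volume)", {
  d <- c(20, 20, 20)
  sigma <- 0.1
  set.seed(99)
  reps <- vapply(1:5, function(i) {
    noise <- array(rnorm(prod(d), sd = sigma), d)
    f <- deformation_field(noise, array(0, d), array(0, d),
                           origin = c(1, 1, 1), step = c(4, 4, 4),
                           spacing = c(0.5, 0.5, 0.7))
    sm <- smooth_field(f)
    interior <- 3:18
    sd(sm$u[interior, interior, interior])
  }, 0)
  expect_equal(mean(reps), sigma / sqrt(27), tolerance = 0.15)
})

test_that("rigid translation has exactly zero strain", {
  f <- dense_field(function(x, y, z) list(u = x * 0 + 2, v = x * 0 - 1,
                                          w = x * 0 + 0.5))
  st <- compute_strain(f)
  for (nm in c("exx", "eyy", "ezz", "exy", "eyz", "exz"))
    expect_equal(max(abs(st[[nm]][st$valid])), 0, tolerance = 1e-12)
})

test_that("uniaxial stretch and simple shear give the textbook tensors", {
  st <- compute_strain(dense_field(function(x, y, z)
    list(u = 0.01 * x, v = x * 0, w = x * 0)))
  expect_equal(mean(st$exx[st$valid]), 0.01, tolerance = 1e-12)
  expect_equal(max(abs(st$eyy[st$valid])), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$exy[st$valid])), 0, tolerance = 1e-12)
  sh <- compute_strain(dense_field(function(x, y, z)
    list(u = 0.02 * y, v = x * 0, w = x * 0)))
  expect_equal(mean(sh$exy[sh$valid]), 0.01, tolerance = 1e-12)
  expect_equal(max(abs(sh$exx[sh$valid])), 0, tolerance = 1e-12)
  expect_equal(max(abs(sh$eyy[sh$valid])), 0, tolerance = 1e-12)
})

test_that("affine fields recover the symmetrized gradient exactly", {
  A <- matrix(c(0.012, 0.004, -0.002,
                0.006, -0.008, 0.003,
                -0.001, 0.005, 0.009), 3, 3, byrow = TRUE)
  f <- dense_field(function(x, y, z) list(
    u = A[1, 1] * x + A[1, 2] * y + A[1, 3] * z,
    v = A[2, 1] * x + A[2, 2] * y + A[2, 3] * z,
    w = A[3, 1] * x + A[3, 2] * y + A[3, 3] * z))
  sym <- (A + t(A)) / 2
  for (method in c("plane", "axial")) {
    st <- compute_strain(f, method = method)
    expect_equal(mean(st$exx[st$valid]), sym[1, 1], tolerance = 1e-10)
    expect_equal(mean(st$eyy[st$valid]), sym[2, 2], tolerance = 1e-10)
    expect_equal(mean(st$ezz[st$valid]), sym[3, 3], tolerance = 1e-10)
    expect_equal(mean(st$exy[st$valid]), sym[1, 2], tolerance = 1e-10)
    expect_equal(mean(st$eyz[st$valid]), sym[2, 3], tolerance = 1e-10)
    expect_equal(mean(st$exz[st$valid]), sym[1, 3], tolerance = 1e-10)
    expect_lt(max(abs(st$exx[st$valid] - sym[1, 1])), 1e-10)
  }
})

test_that("adding a constant to the field leaves strain unchanged", {
  f <- dense_field(function(x, y, z) list(u = 0.01 * x + 0.002 * y,
                                          v = -0.005 * y, w = 0.003 * z))
  g <- f
  g$u <- g$u + 5; g$v <- g$v - 2; g$w <- g$w + 1
  sf <- compute_strain(f); sg <- compute_strain(g)
  for (nm in c("exx", "eyy", "ezz", "exy", "eyz", "exz"))
    expect_equal(sf[[nm]], sg[[nm]], tolerance = 1e-10)
})

test_that("strain needs at least three nodes per axis and flags borders", {
  d <- c(2, 5, 5)
  f <- deformation_field(array(0, d), array(0, d), array(0, d),
                         origin = c(1, 1, 1), step = c(4, 4, 4),
                         spacing = c(0.5, 0.5, 0.7))
  expect_error(compute_strain(f), ">= 3 nodes")
  g <- dense_field(function(x, y, z) list(u = 0.01 * x, v = 0 * x, w = 0 * x))
  st <- compute_strain(g)
  expect_false(any(st$valid[1, , ]))
  expect_false(any(st$valid[, , dim(g$u)[3]]))
  expect_true(all(st$valid[2:8, 2:8, 2:8]))
})

test_that("invalid nodes poison their stencil neighborhood only", {
  g <- dense_field(function(x, y, z) list(u = 0.01 * x, v = 0 * x, w = 0 * x))
  g$valid[5, 5, 5] <- FALSE
  st <- compute_strain(g)
  expect_false(st$valid[4, 5, 5])
  expect_false(st$valid[5, 4, 4])
  expect_true(st$valid[2, 2, 2])
  expect_equal(st$exx[2, 2, 2], 0.01, tolerance = 1e-10)
})
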