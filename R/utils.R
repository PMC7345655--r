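# Internal numeric helpers: seeded evaluation, FFT-domain filters, circular
# rolls, trilinear interpolation. All arrays are (x, y, z) with z = depth.

# Evaluate `code` under a private RNG stream, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Signed DFT frequencies in cycles per sample for length n.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Anisotropic Gaussian low-pass via the 3-D FFT; sigma in voxels per axis.
# A Gaussian of std sigma has transfer exp(-2 pi^2 sigma^2 f^2).
blur_gaussian <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3L, length(sigma) == 3L)
  if (all(sigma <= 0)) return(arr)
  d <- dim(arr)
  g <- lapply(1:3, function(a) exp(-2 * pi^2 * sigma[a]^2 * fft_freq(d[a])^2))
  h <- outer(outer(g[[1]], g[[2]]), g[[3]])
  Re(fft(fft(arr) * h, inverse = TRUE)) / prod(d)
}

# Circular roll: out[i] = in[i - shift] per axis (content moves by +shift).
roll_array <- function(arr, shift) {
  d <- dim(arr)
  idx <- lapply(1:3, function(a) {
    s <- shift[a] %% d[a]
    ((seq_len(d[a]) - 1 - s) %% d[a]) + 1
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Trilinear interpolation of a 3-D array at fractional 1-based coordinates.
# Coordinates outside the domain return `fill` (default NA) unless
# `extrapolate` is set, in which case the edge cell's linear model is
# extended outward (degenerate single-node axes extend as constants).
trilinear <- function(arr, xi, yi, zi, fill = NA_real_, extrapolate = FALSE) {
  d <- dim(arr)
  if (extrapolate && any(d == 1L)) {
    # pad degenerate axes by replication so every axis has a cell
    reps <- ifelse(d == 1L, 2L, 1L)
    arr <- arr[rep(seq_len(d[1]), length.out = d[1] * reps[1]),
               rep(seq_len(d[2]), length.out = d[2] * reps[2]),
               rep(seq_len(d[3]), length.out = d[3] * reps[3]), drop = FALSE]
    d <- dim(arr)
  }
  out <- rep(fill, length(xi))
  ok <- if (extrapolate) {
    is.finite(xi) & is.finite(yi) & is.finite(zi)
  } else {
    xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3] &
      is.finite(xi) & is.finite(yi) & is.finite(zi)
  }
  if (!any(ok)) return(out)
  x <- xi[ok]; y <- yi[ok]; z <- zi[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  x0 <- pmax(x0, 1L); y0 <- pmax(y0, 1L); z0 <- pmax(z0, 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

# Zero-filled translation (no wrap-around), shift along one axis only.
shift_zero <- function(arr, axis, s) {
  d <- dim(arr)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s >= 0) 1:(n - s) else (1 - s):n
  dst <- if (s >= 0) (1 + s):n else 1:(n + s)
  ix <- function(a, i) if (a == axis) list(i)[[1]] else seq_len(d[a])
  out[ix(1, dst), ix(2, dst), ix(3, dst)] <-
    arr[ix(1, src), ix(2, src), ix(3, src)]
  out
}

# Running-maximum box dilation of a logical 3-D array by `margin` voxels
# per axis (box structuring element applied separably, no wrap-around).
dilate_box <- function(mask, margin) {
  margin <- rep_len(as.integer(margin), 3L)
  m <- mask * 1
  for (a in 1:3) {
    if (margin[a] <= 0) next
    acc <- m
    for (s in seq_len(margin[a])) {
      acc <- pmax(acc, shift_zero(m, a, s), shift_zero(m, a, -s))
    }
    m <- acc
  }
  array(m > 0, dim = dim(mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
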