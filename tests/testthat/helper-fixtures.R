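# Shared fixtures, generated once per test run and memoized: phantom
# generation is the expensive step, and several files exercise the same
# scenes.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# 64^3 speckle phantom, default sampling, noise-free: fast unit-test scene.
phantom_small <- function() fixture("small", {
  generate_phantom(phantom_spec(shape = c(64, 64, 64), fiber_count = 120,
                                noise_snr = NULL, seed = 7))
})

# 128 x 128 x 96 phantom at 25 dB: the mid-size pipeline scene.
phantom_mid <- function() fixture("mid", {
  generate_phantom(phantom_spec(shape = c(128, 128, 96), seed = 21))
})

# Small single-pass and iterative configs used across files.
cfg32 <- function(passes = 1) {
  dvc_config(subset_size = 32, grid_spacing = 16, max_passes = passes)
}
cfg64 <- function(passes = 3, grid = 16) {
  dvc_config(subset_size = 64, grid_spacing = grid, max_passes = passes,
             min_subset = 32)
}

# Brute-force zero-mean normalized correlation over integer lags: the
# independent oracle for correlate_subset's integer peak (plain triple
# loop over circularly rolled copies; no FFT, no windowing).
brute_force_peak <- function(a, b, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  best <- -Inf; best_lag <- c(0, 0, 0)
  for (sx in -max_lag:max_lag) for (sy in -max_lag:max_lag)
    for (sz in -max_lag:max_lag) {
      rolled <- b
      d <- dim(b)
      idx <- function(n, s) ((seq_len(n) - 1 + s) %% n) + 1
      rolled <- b[idx(d[1], sx), idx(d[2], sy), idx(d[3], sz)]
      v <- sum(a * rolled) / (na * nb)
      if (v > best) { best <- v; best_lag <- c(sx, sy, sz) }
    }
  list(lag = best_lag, value = best)
}

# Ground-truth field values of a traction scene at DVC node positions.
traction_truth_at_nodes <- function(fld, crop, center_vox, peak_um,
                                    decay_um, direction, spacing) {
  d <- dim(fld$u)
  nx <- fld$origin[1] + (seq_len(d[1]) - 1) * fld$step[1] + crop
  ny <- fld$origin[2] + (seq_len(d[2]) - 1) * fld$step[2] + crop
  nz <- fld$origin[3] + (seq_len(d[3]) - 1) * fld$step[3] + crop
  g <- expand.grid(x = nx, y = ny, z = nz)
  r <- sqrt(((g$x - center_vox[1]) * spacing[1])^2 +
            ((g$y - center_vox[2]) * spacing[2])^2 +
            ((g$z - center_vox[3]) * spacing[3])^2)
  mag <- peak_um * exp(-r / decay_um)
  dirn <- direction / sqrt(sum(direction^2))
  list(u = array(mag * dirn[1], d), v = array(mag * dirn[2], d),
       w = array(mag * dirn[3], d), r = array(r, d))
}
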