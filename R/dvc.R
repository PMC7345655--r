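# Subset-based digital volume correlation: zero-mean normalized
# cross-correlation computed spectrally per subset, integer peak search
# restricted to plausible lags, separable three-point subpixel refinement,
# and an iterative coarse-to-fine pass loop that warps the deformed volume
# by the running field estimate.

#' DVC correlation parameters
#'
#' @param subset_size edge length of the cubic correlation subset in
#'   voxels; a power of two >= 32. Default 128, the size used throughout
#'   the validation protocols.
#' @param grid_spacing voxels between subset centers (<= subset_size).
#'   Default `subset_size / 4` (75% overlap), a standard DVC density.
#' @param max_passes number of refinement passes; the subset is halved
#'   after each pass down to `min_subset`. `max_passes = 1` reproduces a
#'   fixed-subset single-pass analysis.
#' @param min_subset smallest subset edge allowed during halving.
#' @param update_tol convergence tolerance on the median displacement
#'   update, um; the pass loop stops early once an update falls below it.
#' @param correlation_threshold nodes whose normalized correlation peak
#'   falls below this are flagged invalid.
#' @param window_alpha taper fraction of the separable raised-cosine
#'   (Tukey) window applied to each subset before spectral correlation, to
#'   suppress periodic wrap-around bias.
#' @return An object of class `dvc_config`.
#' @export
dvc_config <- function(subset_size = 128, grid_spacing = subset_size / 4,
                       max_passes = 3, min_subset = 32, update_tol = 0.02,
                       correlation_threshold = 0.2, window_alpha = 0.5) {
  subset_size <- as.integer(subset_size)
  if (subset_size < 32 || bitwAnd(subset_size, subset_size - 1L) != 0L)
    stop("`subset_size` must be a power of two >= 32", call. = FALSE)
  grid_spacing <- as.integer(grid_spacing)
  if (grid_spacing < 1 || grid_spacing > subset_size)
    stop("`grid_spacing` must be in [1, subset_size]", call. = FALSE)
  if (min_subset < 32) stop("`min_subset` must be >= 32", call. = FALSE)
  structure(list(subset_size = subset_size, grid_spacing = grid_spacing,
                 max_passes = as.integer(max_passes),
                 min_subset = as.integer(min_subset),
                 update_tol = update_tol,
                 correlation_threshold = correlation_threshold,
                 window_alpha = window_alpha),
            class = "dvc_config")
}

# Cache for windows and their autocorrelation envelopes, keyed by
# dimensions and taper fraction (subset shapes recur thousands of times).
.win_cache <- new.env(parent = emptyenv())

# Tukey window together with its circular autocorrelation envelope
# E(s) = sum_x w(x) w(x+s), normalized to E(0) = 1. Dividing the raw
# correlation by E removes the taper-induced decay with |lag| that would
# otherwise bias the three-point subpixel fit toward zero lag.
window_and_envelope <- function(d, alpha) {
  key <- paste(c(d, alpha), collapse = "_")
  got <- .win_cache[[key]]
  if (!is.null(got)) return(got)
  w <- tukey_window(d, alpha)
  fw <- fft(w)
  env <- Re(fft(Conj(fw) * fw, inverse = TRUE)) / prod(d)
  env <- env / env[1, 1, 1]
  out <- list(w = w, env = env)
  .win_cache[[key]] <- out
  out
}

# Separable 3-D Tukey (tapered-cosine) window for a subset of dims d.
tukey_window <- function(d, alpha) {
  w1 <- function(n) {
    if (alpha <= 0) return(rep(1, n))
    t <- seq(0, 1, length.out = n)
    w <- rep(1, n)
    lo <- t < alpha / 2
    hi <- t > 1 - alpha / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
    w
  }
  outer(outer(w1(d[1]), w1(d[2])), w1(d[3]))
}

# Map circular correlation array indices to signed lags.
signed_lags <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Correlate one subset pair
#'
#' Zero-mean normalized cross-correlation of two equally shaped intensity
#' blocks, computed with FFTs after windowing; the integer peak (searched
#' over lags up to a quarter of the block size, ties broken toward the
#' smallest lag) is refined per axis by a three-point fit: log-parabolic
#' when all three correlation samples are positive (exact for a
#' Gaussian-shaped peak, as speckle autocorrelation approximately is),
#' plain parabolic otherwise.
#'
#' @param ref_block,def_block 3-D numeric arrays of identical dimensions.
#' @param max_lag largest absolute integer lag searched per axis; default
#'   a quarter of the block size.
#' @param window_alpha Tukey taper fraction (see [dvc_config()]).
#' @return A list: `shift` (length-3 displacement of `def_block` relative
#'   to `ref_block`, voxels), `peak` (normalized correlation in \[-1, 1\]),
#'   `ok` (`FALSE` when a block has zero variance).
#' @export
correlate_subset <- function(ref_block, def_block, max_lag = NULL,
                             window_alpha = 0.5) {
  d <- dim(ref_block)
  if (!identical(d, dim(def_block)))
    stop("subset blocks must have identical dimensions", call. = FALSE)
  if (is.null(max_lag)) max_lag <- floor(min(d) / 4)
  we <- window_and_envelope(d, window_alpha)
  a <- (ref_block - mean(ref_block)) * we$w
  b <- (def_block - mean(def_block)) * we$w
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0)
    return(list(shift = c(NA_real_, NA_real_, NA_real_), peak = NA_real_,
                ok = FALSE))
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / prod(d) /
    sqrt(na2 * nb2) / pmax(we$env, 0.05)
  lags <- lapply(d, signed_lags)
  allow <- lapply(seq_along(d), function(i) abs(lags[[i]]) <= max_lag)
  sub <- cc[allow[[1]], allow[[2]], allow[[3]], drop = FALSE]
  sub_lags <- lapply(seq_along(d), function(i) lags[[i]][allow[[i]]])
  mx <- max(sub)
  cand <- which(sub == mx, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    norms <- sub_lags[[1]][cand[, 1]]^2 + sub_lags[[2]][cand[, 2]]^2 +
      sub_lags[[3]][cand[, 3]]^2
    cand <- cand[which.min(norms), , drop = FALSE]
  }
  peak_lag <- c(sub_lags[[1]][cand[1, 1]], sub_lags[[2]][cand[1, 2]],
                sub_lags[[3]][cand[1, 3]])
  # three-point refinement along each axis around the integer peak
  delta <- numeric(3)
  for (ax in 1:3) {
    idx0 <- ((peak_lag[ax] %% d[ax])) + 1
    im <- ((peak_lag[ax] - 1) %% d[ax]) + 1
    ip <- ((peak_lag[ax] + 1) %% d[ax]) + 1
    pick <- function(i) {
      ii <- (peak_lag %% d) + 1
      ii[ax] <- i
      cc[ii[1], ii[2], ii[3]]
    }
    c0 <- pick(idx0); cm <- pick(im); cp <- pick(ip)
    if (all(c(cm, c0, cp) > 0)) {
      num <- log(cm) - log(cp)
      den <- log(cm) - 2 * log(c0) + log(cp)
    } else {
      num <- cm - cp
      den <- cm - 2 * c0 + cp
    }
    # a genuine maximum has negative curvature; otherwise leave integer
    delta[ax] <- if (is.finite(den) && den < 0) 0.5 * num / den else 0
    delta[ax] <- max(min(delta[ax], 0.5), -0.5)
  }
  list(shift = peak_lag + delta, peak = max(min(mx, 1), -1), ok = TRUE)
}

# Subset start positions along one axis: 1-based, step gs, subsets of edge
# `sub` fully inside [1, n].
subset_starts <- function(n, sub, gs) {
  if (n < sub) return(integer(0))
  seq(1L, n - sub + 1L, by = gs)
}

#' Run digital volume correlation between two volumes
#'
#' Lays a regular grid of cubic subsets over the reference volume and, for
#' each pass, warps the reference volume by the running displacement field
#' (identity on the first pass), correlates every warped-reference subset
#' against the same location of the deformed volume, and adds the measured
#' residual to the running field; the subset is halved between passes for
#' coarse-to-fine refinement. The fixed point of this iteration is the
#' displacement field sampled at the grid nodes, free of the gradient bias
#' a single translation-only pass leaves on strained subsets.
#' Displacements are returned in um (voxel shifts scaled by the voxel
#' spacing).
#'
#' @param ref,deformed [volume_image()] objects of equal shape and spacing.
#' @param config a [dvc_config()].
#' @param exclude_mask optional logical array (volume shape); nodes whose
#'   center falls inside it are flagged invalid (e.g. a segmented cell
#'   body, where the matrix displacement is undefined).
#' @return A [deformation_field()] on the subset-center grid with per-node
#'   peak correlation (`quality`) and validity mask; attribute `passes`
#'   records subset size and median update per pass.
#' @export
run_dvc <- function(ref, deformed, config = dvc_config(),
                    exclude_mask = NULL) {
  d <- dim(ref)
  if (!identical(d, dim(deformed)))
    stop("volumes must have equal shape", call. = FALSE)
  sp <- voxel_spacing(ref)
  if (max(abs(sp - voxel_spacing(deformed))) > 1e-9)
    stop("volumes must have equal voxel spacing", call. = FALSE)
  sub0 <- config$subset_size
  starts <- lapply(1:3, function(a) subset_starts(d[a], sub0, config$grid_spacing))
  ng <- lengths(starts)
  if (any(ng == 0))
    stop(sprintf(paste0("no %d-voxel subset fits inside a %s volume; ",
                        "use a smaller subset_size"),
                 sub0, paste(d, collapse = "x")), call. = FALSE)
  centers <- lapply(1:3, function(a) starts[[a]] + sub0 / 2)
  zero <- array(0, dim = ng)
  u <- zero; v <- zero; w <- zero
  quality <- array(NA_real_, dim = ng)
  okmask <- array(TRUE, dim = ng)
  ref_arr <- unclass(ref)
  def_arr <- unclass(deformed)
  pass_log <- list()
  sub <- sub0
  for (pass in seq_len(config$max_passes)) {
    warped_ref <- if (pass == 1) ref_arr else {
      fld <- deformation_field(u, v, w,
                               origin = vapply(centers, `[`, 0, 1),
                               step = rep(config$grid_spacing, 3),
                               spacing = sp)
      warp_by_field(ref_arr, fld, sp)
    }
    half <- sub / 2
    upd <- c()
    for (k in seq_len(ng[3])) for (j in seq_len(ng[2])) for (i in seq_len(ng[1])) {
      if (!okmask[i, j, k]) next
      cx <- centers[[1]][i]; cy <- centers[[2]][j]; cz <- centers[[3]][k]
      rx <- (cx - half):(cx + half - 1); ry <- (cy - half):(cy + half - 1)
      rz <- (cz - half):(cz + half - 1)
      res <- correlate_subset(warped_ref[rx, ry, rz], def_arr[rx, ry, rz],
                              window_alpha = config$window_alpha)
      if (!res$ok) { okmask[i, j, k] <- FALSE; next }
      du <- res$shift * sp
      u[i, j, k] <- u[i, j, k] + du[1]
      v[i, j, k] <- v[i, j, k] + du[2]
      w[i, j, k] <- w[i, j, k] + du[3]
      quality[i, j, k] <- res$peak
      upd <- c(upd, sqrt(sum(du^2)))
    }
    pass_log[[pass]] <- list(subset = sub, median_update = stats::median(upd))
    converged <- length(upd) > 0 && stats::median(upd) < config$update_tol
    if (pass < config$max_passes && sub / 2 >= config$min_subset) sub <- sub / 2
    if (converged) break
  }
  valid <- okmask & !is.na(quality) & quality >= config$correlation_threshold
  if (!is.null(exclude_mask)) {
    for (k in seq_len(ng[3])) for (j in seq_len(ng[2])) for (i in seq_len(ng[1])) {
      if (exclude_mask[centers[[1]][i], centers[[2]][j], centers[[3]][k]])
        valid[i, j, k] <- FALSE
    }
  }
  if (!any(valid))
    stop("no valid DVC node: volumes may be uncorrelated or subsets too small",
         call. = FALSE)
  fld <- deformation_field(u, v, w,
                           origin = vapply(centers, `[`, 0, 1),
                           step = rep(config$grid_spacing, 3),
                           spacing = sp, quality = quality, valid = valid)
  attr(fld, "passes") <- pass_log
  fld
}

# Dense backward warp of the reference volume by the running field
# estimate: w(x) = ref(x - u(x)), so that w matches the deformed volume
# where u is correct and the residual correlation vanishes at the fixed
# point u = u_true.
warp_by_field <- function(ref_arr, field, sp) {
  d <- dim(ref_arr)
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  uv <- interp_field_at(field, ix, iy, iz)
  vals <- trilinear(ref_arr, ix - uv$u / sp[1], iy - uv$v / sp[2],
                    iz - uv$w / sp[3])
  vals[is.na(vals)] <- 0
  array(vals, dim = d)
}
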