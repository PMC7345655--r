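#' 3-D intensity volume with voxel spacing
#'
#' The unit of all imaging I/O in dvc3d: a 3-D numeric array of grayscale
#' intensities together with the physical voxel spacing in micrometres per
#' voxel along each axis. Axis order is (x, y, z) with z the axial (depth)
#' direction; indices are voxel positions, physical position =
#' (index - 1) * spacing micrometres.
#'
#' @param data 3-D numeric array, dimensions (nx, ny, nz).
#' @param spacing numeric length-3, voxel spacing (sx, sy, sz) in um/voxel;
#'   all entries must be positive.
#' @return An object of class `volume_image`: the array with a `spacing`
#'   attribute.
#' @examples
#' v <- volume_image(array(runif(8^3), dim = c(8, 8, 8)), c(0.53, 0.53, 0.73))
#' dim(v)
#' voxel_spacing(v)
#' @export
volume_image <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (um/voxel)",
         call. = FALSE)
  structure(data, spacing = spacing, class = c("volume_image", "array"))
}

#' @rdname volume_image
#' @param x a `volume_image`.
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("object carries no voxel spacing", call. = FALSE)
  sp
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x)
  sp <- voxel_spacing(x)
  cat(sprintf("<volume_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um/px\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  extent %.1f x %.1f x %.1f um, intensity range [%.4g, %.4g]\n",
              d[1] * sp[1], d[2] * sp[2], d[3] * sp[3],
              min(x), max(x)))
  invisible(x)
}

#' Crop a symmetric margin from a volume
#'
#' Virtual translations in dvc3d are circular rolls (or spectral-domain
#' shifts, which are also periodic), so a border at least as wide as the
#' largest applied shift must be discarded before correlation to keep
#' wrap-around content out of the analysis.
#'
#' @param vol a [volume_image()].
#' @param margin voxels to remove from both ends of each axis; scalar or
#'   length-3.
#' @return The cropped `volume_image` (spacing preserved).
#' @export
crop_margin <- function(vol, margin) {
  margin <- rep_len(as.integer(margin), 3L)
  d <- dim(vol)
  if (any(d - 2 * margin < 1))
    stop("margin leaves no voxels on some axis", call. = FALSE)
  idx <- lapply(1:3, function(a) (margin[a] + 1):(d[a] - margin[a]))
  volume_image(unclass(vol)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               voxel_spacing(vol))
}

#' Add acquisition noise to a volume at a given SNR
#'
#' Additive white Gaussian noise whose standard deviation is set from the
#' root-mean-square signal intensity: SNR(dB) = 20 log10(rms / sigma).
#' Used by the error-floor protocol to simulate replicate scans of one
#' scene with independent detector noise draws.
#'
#' @param vol a [volume_image()].
#' @param snr_db signal-to-noise ratio in decibels.
#' @param seed integer seed for the noise draw.
#' @return A `volume_image` of the same shape.
#' @export
add_noise <- function(vol, snr_db, seed) {
  rms <- sqrt(mean(unclass(vol)^2))
  sigma <- rms * 10^(-snr_db / 20)
  noisy <- with_seed(seed, unclass(vol) + array(stats::rnorm(length(vol), sd = sigma),
                                                dim = dim(vol)))
  volume_image(noisy, voxel_spacing(vol))
}
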