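# Synthetic coherent-imaging phantoms: random fiber networks blurred by an
# anisotropic PSF, modulated by fully developed speckle, with additive
# detector noise -- plus exactly known virtual deformations that serve as
# ground truth for the DVC, accumulation and strain stages.

#' Specification of a synthetic speckle phantom
#'
#' Describes a volumetric scene that emulates coherent microscopy of a
#' fibrous gel: randomly oriented straight fibers with Gaussian
#' cross-section, rasterized and convolved with an anisotropic Gaussian
#' point-spread function, optionally modulated by fully developed speckle
#' (the modulus of a PSF-scale-correlated complex Gaussian field) and
#' degraded by additive Gaussian noise.
#'
#' @param shape integer length-3, voxels per axis (x, y, z); each >= 32.
#' @param spacing numeric length-3, um per voxel; defaults to the
#'   transverse/axial sampling of a typical coherence-microscopy volume
#'   (0.533, 0.533, 0.73).
#' @param fiber_count number of fiber segments to draw; 0 gives an empty
#'   scene (plus uniform background if speckle is on).
#' @param fiber_radius Gaussian cross-section standard deviation of a
#'   fiber, um.
#' @param psf_fwhm length-2: transverse and axial PSF full width at half
#'   maximum, um. Default c(2.0, 2.6).
#' @param background uniform backscatter level relative to peak fiber
#'   intensity, so speckle carries texture even between fibers.
#' @param speckle logical; multiply by a fully developed speckle magnitude
#'   field correlated at the PSF scale.
#' @param noise_snr additive-noise SNR in dB (see [add_noise()]), or `NULL`
#'   for a noise-free volume.
#' @param seed integer; identical specs (same seed) regenerate bit-identical
#'   volumes.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(128, 128, 96),
                         spacing = c(0.533, 0.533, 0.73),
                         fiber_count = 300,
                         fiber_radius = 0.3,
                         psf_fwhm = c(2.0, 2.6),
                         background = 0.12,
                         speckle = TRUE,
                         noise_snr = 25,
                         seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 32))
    stop("`shape` must be 3 integers, each >= 32", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (um/voxel)", call. = FALSE)
  if (fiber_count < 0 || fiber_count != round(fiber_count))
    stop("`fiber_count` must be a non-negative integer", call. = FALSE)
  if (length(psf_fwhm) != 2L || any(psf_fwhm <= 0))
    stop("`psf_fwhm` must be positive (transverse, axial) um", call. = FALSE)
  if (!is.null(noise_snr) && (!is.finite(noise_snr)))
    stop("`noise_snr` must be finite dB or NULL", call. = FALSE)
  structure(list(shape = shape, spacing = spacing,
                 fiber_count = as.integer(fiber_count),
                 fiber_radius = as.numeric(fiber_radius),
                 psf_fwhm = as.numeric(psf_fwhm),
                 background = as.numeric(background),
                 speckle = isTRUE(speckle),
                 noise_snr = noise_snr,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic speckle phantom volume
#'
#' Deterministic under the spec's seed: the same `phantom_spec` always
#' regenerates a bit-identical volume. Intensities are scaled to \[0, 1\]
#' (a completely empty scene returns all zeros).
#'
#' @param spec a [phantom_spec()].
#' @return A [volume_image()] of dimension `spec$shape`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  with_seed(spec$seed, {
    structure_im <- rasterize_fibers(d, spec$spacing, spec$fiber_count)
    sigma_psf <- fwhm_to_sigma(c(spec$psf_fwhm[1], spec$psf_fwhm[1],
                                 spec$psf_fwhm[2]))
    sigma_vox <- sqrt(spec$fiber_radius^2 + sigma_psf^2) / spec$spacing
    if (spec$fiber_count > 0) {
      structure_im <- blur_gaussian(structure_im, sigma_vox)
      structure_im[structure_im < 0] <- 0
      mx <- max(structure_im)
      if (mx > 0) structure_im <- structure_im / mx
      structure_im <- structure_im + spec$background
    } else if (spec$speckle) {
      structure_im <- structure_im + spec$background
    }
    img <- structure_im
    if (spec$speckle) {
      img <- img * speckle_field(d, sigma_psf / spec$spacing)
    }
    if (!is.null(spec$noise_snr) && any(img != 0)) {
      sigma_n <- sqrt(mean(img^2)) * 10^(-spec$noise_snr / 20)
      img <- img + array(stats::rnorm(length(img), sd = sigma_n), dim = d)
    }
    rng <- range(img)
    if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
    else img <- array(0, dim = d)
    volume_image(img, spec$spacing)
  })
}

# Rasterize `n` random straight fiber segments as accumulated point mass on
# the voxel lattice. Points are sampled every half voxel along each segment;
# the Gaussian cross-section is applied later, folded into the PSF blur.
rasterize_fibers <- function(d, spacing, n) {
  if (n == 0) return(array(0, dim = d))
  lmax <- sqrt(sum(d^2))
  lin_all <- vector("list", n)
  for (i in seq_len(n)) {
    p0 <- stats::runif(3) * d + 0.5
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    len <- stats::runif(1, 0.25, 1) * lmax
    t <- seq(0, len, by = 0.5)
    px <- round(p0[1] + t * u[1]); py <- round(p0[2] + t * u[2])
    pz <- round(p0[3] + t * u[3])
    ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
    if (!any(ok)) next
    lin_all[[i]] <- (pz[ok] - 1) * d[1] * d[2] + (py[ok] - 1) * d[1] + px[ok]
  }
  array(tabulate(unlist(lin_all), nbins = prod(d)), dim = d)
}

# Fully developed speckle magnitude: modulus of a complex circular Gaussian
# field low-pass filtered to the PSF scale, normalized to unit mean. The
# pointwise amplitude stays Rayleigh (contrast ~ 0.52) because a filtered
# Gaussian field remains Gaussian; filtering sets the grain size.
speckle_field <- function(d, sigma_vox) {
  re <- array(stats::rnorm(prod(d)), dim = d)
  im <- array(stats::rnorm(prod(d)), dim = d)
  mag <- sqrt(blur_gaussian(re, sigma_vox)^2 + blur_gaussian(im, sigma_vox)^2)
  mag / mean(mag)
}

#' Add a bright ellipsoidal inclusion (a synthetic "cell") to a volume
#'
#' @param vol a [volume_image()].
#' @param center_vox ellipsoid center, 1-based voxel coordinates.
#' @param radii_um semi-axes in um.
#' @param intensity added intensity at the center (tapers smoothly to the
#'   boundary).
#' @return A list with elements `volume` (the modified volume, rescaled to
#'   \[0, 1\]) and `inside` (logical array of ground-truth membership).
#' @export
add_ellipsoid <- function(vol, center_vox, radii_um, intensity = 2) {
  d <- dim(vol); sp <- voxel_spacing(vol)
  ax <- (seq_len(d[1]) - center_vox[1]) * sp[1]
  ay <- (seq_len(d[2]) - center_vox[2]) * sp[2]
  az <- (seq_len(d[3]) - center_vox[3]) * sp[3]
  r2 <- outer(outer((ax / radii_um[1])^2, (ay / radii_um[2])^2, `+`),
              (az / radii_um[3])^2, `+`)
  inside <- r2 <= 1
  img <- unclass(vol) + intensity * pmax(1 - r2, 0)
  img <- img / max(img)
  list(volume = volume_image(img, sp), inside = inside)
}

#' Translate a volume by a whole number of voxels (circular roll)
#'
#' The translation is exact and preserves speckle statistics everywhere,
#' including the borders, because content wraps around; callers must
#' afterwards [crop_margin()] by at least the largest shift so wrapped
#' content never enters a correlation.
#'
#' @param vol a [volume_image()].
#' @param shift_voxels integer length-3; each entry must be smaller in
#'   magnitude than a quarter of the corresponding axis length.
#' @return The rolled `volume_image`.
#' @export
apply_integer_shift <- function(vol, shift_voxels) {
  if (any(shift_voxels != round(shift_voxels)))
    stop("non-integer shift: use apply_subvoxel_shift() for subvoxel translations",
         call. = FALSE)
  shift_voxels <- as.integer(round(shift_voxels))
  if (any(abs(shift_voxels) >= dim(vol) / 4))
    stop("|shift| must be < shape/4 per axis", call. = FALSE)
  volume_image(roll_array(unclass(vol), shift_voxels), voxel_spacing(vol))
}

#' Translate a volume by a physical (subvoxel) amount via the Fourier shift
#' theorem
#'
#' A linear phase ramp in the spectral domain implements an exact
#' translation for band-limited content; the shift in voxels is
#' `shift_um / spacing` per axis. Like the integer roll, the operation is
#' periodic, so margins of at least the shift magnitude must be cropped
#' before analysis.
#'
#' @param vol a [volume_image()].
#' @param shift_um numeric length-3 physical translation in um.
#' @return The translated `volume_image`.
#' @export
apply_subvoxel_shift <- function(vol, shift_um) {
  stopifnot(length(shift_um) == 3L, all(is.finite(shift_um)))
  sp <- voxel_spacing(vol)
  s_vox <- shift_um / sp
  d <- dim(vol)
  ramp <- lapply(1:3, function(a) {
    f <- fft_freq(d[a])
    r <- exp(-2i * pi * f * s_vox[a])
    # real output for even n: the Nyquist bin must carry a real factor
    if (d[a] %% 2 == 0) r[d[a] / 2 + 1] <- cos(2 * pi * f[d[a] / 2 + 1] * s_vox[a])
    r
  })
  h <- outer(outer(ramp[[1]], ramp[[2]]), ramp[[3]])
  out <- Re(fft(fft(unclass(vol)) * h, inverse = TRUE)) / prod(d)
  volume_image(out, sp)
}
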