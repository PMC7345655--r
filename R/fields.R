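# Deformation fields: vector-valued (U, V, W) displacement maps in um on a
# regular measurement grid embedded in a volume's voxel lattice.

#' Displacement field on a regular measurement grid
#'
#' Holds the three displacement components U, V, W (um, along x, y, z) on a
#' regular grid of nodes. Node `(i, j, k)` sits at voxel coordinate
#' `origin + (c(i, j, k) - 1) * step` (1-based) of the underlying volume.
#' The sign convention is that of backward warping: a deformed volume
#' relates to its reference by `deformed(x) = reference(x - u(x))`, i.e.
#' material moves by `+u`.
#'
#' @param u,v,w 3-D numeric arrays (same dimensions): displacement in um.
#' @param origin voxel coordinate (1-based) of the first grid node.
#' @param step voxels between adjacent nodes per axis.
#' @param spacing um per voxel of the underlying volume.
#' @param quality optional array of peak correlation values per node.
#' @param valid optional logical array; defaults to all finite nodes.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(u, v, w, origin = c(1, 1, 1), step = c(1, 1, 1),
                              spacing, quality = NULL, valid = NULL) {
  stopifnot(is.array(u), length(dim(u)) == 3L,
            identical(dim(u), dim(v)), identical(dim(u), dim(w)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (um/voxel)", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(u) & is.finite(v) & is.finite(w)
  stopifnot(identical(dim(valid), dim(u)))
  structure(list(u = u, v = v, w = w,
                 origin = as.numeric(rep_len(origin, 3L)),
                 step = as.numeric(rep_len(step, 3L)),
                 spacing = spacing,
                 quality = quality,
                 valid = valid),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("<deformation_field> %d x %d x %d nodes (step %s vox), %d/%d valid\n",
              d[1], d[2], d[3], paste(x$step, collapse = "x"),
              sum(x$valid), length(x$valid)))
  if (any(x$valid)) {
    m <- field_magnitude(x)
    cat(sprintf("  |u| median %.3f um, max %.3f um\n",
                stats::median(m[x$valid]), max(m[x$valid])))
  }
  invisible(x)
}

#' @rdname deformation_field
#' @param field a `deformation_field`.
#' @return `field_magnitude()`: array of displacement magnitudes |u| in um.
#' @export
field_magnitude <- function(field) {
  sqrt(field$u^2 + field$v^2 + field$w^2)
}

# 1-based voxel coordinates of every grid node, as three arrays.
node_coords <- function(field) {
  d <- dim(field$u)
  gx <- field$origin[1] + (seq_len(d[1]) - 1) * field$step[1]
  gy <- field$origin[2] + (seq_len(d[2]) - 1) * field$step[2]
  gz <- field$origin[3] + (seq_len(d[3]) - 1) * field$step[3]
  list(x = array(rep(gx, times = d[2] * d[3]), dim = d),
       y = array(rep(rep(gy, each = d[1]), times = d[3]), dim = d),
       z = array(rep(gz, each = d[1] * d[2]), dim = d))
}

#' Synthetic displacement fields with known analytic form
#'
#' Constructors for dense (one node per voxel) ground-truth fields used to
#' deform phantoms: a uniform translation, an affine field
#' `u(p) = A p + b` (p the physical position in um), and a localized
#' traction-like field whose magnitude decays monotonically with distance
#' from a point source, emulating a pull applied at one spot of a gel.
#'
#' @param shape volume dimensions in voxels.
#' @param spacing um per voxel.
#' @param shift_um uniform displacement, um.
#' @return A dense [deformation_field()].
#' @export
uniform_field <- function(shape, spacing, shift_um) {
  d <- as.integer(shape)
  mk <- function(val) array(val, dim = d)
  deformation_field(mk(shift_um[1]), mk(shift_um[2]), mk(shift_um[3]),
                    spacing = spacing)
}

#' @rdname uniform_field
#' @param A 3x3 displacement-gradient matrix (um displacement per um
#'   position, i.e. dimensionless).
#' @param b length-3 offset, um.
#' @export
affine_field <- function(shape, spacing, A, b = c(0, 0, 0)) {
  d <- as.integer(shape)
  stopifnot(is.matrix(A), all(dim(A) == c(3, 3)))
  pos <- node_coords(deformation_field(array(0, d), array(0, d), array(0, d),
                                       spacing = spacing))
  px <- (pos$x - 1) * spacing[1]; py <- (pos$y - 1) * spacing[2]
  pz <- (pos$z - 1) * spacing[3]
  deformation_field(
    A[1, 1] * px + A[1, 2] * py + A[1, 3] * pz + b[1],
    A[2, 1] * px + A[2, 2] * py + A[2, 3] * pz + b[2],
    A[3, 1] * px + A[3, 2] * py + A[3, 3] * pz + b[3],
    spacing = spacing)
}

#' @rdname uniform_field
#' @param center_vox source position, 1-based voxel coordinates.
#' @param peak_um displacement magnitude at the source, um.
#' @param decay_um e-folding length of the exponential decay, um.
#' @param direction length-3 pull direction (normalized internally).
#' @export
traction_field <- function(shape, spacing, center_vox, peak_um, decay_um,
                           direction = c(-1, 0, 0)) {
  d <- as.integer(shape)
  dirn <- direction / sqrt(sum(direction^2))
  pos <- node_coords(deformation_field(array(0, d), array(0, d), array(0, d),
                                       spacing = spacing))
  dx <- (pos$x - center_vox[1]) * spacing[1]
  dy <- (pos$y - center_vox[2]) * spacing[2]
  dz <- (pos$z - center_vox[3]) * spacing[3]
  mag <- peak_um * exp(-sqrt(dx^2 + dy^2 + dz^2) / decay_um)
  deformation_field(mag * dirn[1], mag * dirn[2], mag * dirn[3],
                    spacing = spacing)
}

# Interpolate the field components at arbitrary voxel coordinates
# (vectors), returning um. With `extend = TRUE` (used by dense warps) the
# edge cells' linear model is extrapolated beyond the node hull, so
# smoothly varying fields stay consistent out to the volume borders; with
# `extend = FALSE` positions outside the grid return NA.
interp_field_at <- function(field, xi, yi, zi, extend = TRUE) {
  gx <- (xi - field$origin[1]) / field$step[1] + 1
  gy <- (yi - field$origin[2]) / field$step[2] + 1
  gz <- (zi - field$origin[3]) / field$step[3] + 1
  list(u = trilinear(field$u, gx, gy, gz, extrapolate = extend),
       v = trilinear(field$v, gx, gy, gz, extrapolate = extend),
       w = trilinear(field$w, gx, gy, gz, extrapolate = extend))
}

#' Deform a volume by a displacement field (backward warping)
#'
#' Produces `out(x) = vol(x - u(x)/spacing)` by trilinear interpolation:
#' the forward model that turns a reference scene into its deformed image
#' under the field. Voxels whose source position falls outside the volume
#' are filled with `fill` and reported in the `"invalid"` attribute.
#'
#' @param vol a [volume_image()].
#' @param field a [deformation_field()] defined over the volume (dense or
#'   on a coarser grid; interpolated, linearly extrapolated at borders, as needed).
#' @param fill value for voxels sampling outside the domain.
#' @return A `volume_image` with attribute `invalid` (logical array).
#' @export
apply_field <- function(vol, field, fill = 0) {
  sp <- voxel_spacing(vol)
  if (max(abs(sp - field$spacing)) > 1e-9)
    stop("volume and field voxel spacings differ", call. = FALSE)
  d <- dim(vol)
  dense <- identical(dim(field$u), d) && all(field$step == 1) &&
    all(field$origin == 1)
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  if (dense) {
    uv <- list(u = field$u, v = field$v, w = field$w)
  } else {
    uv <- interp_field_at(field, as.vector(ix), as.vector(iy), as.vector(iz))
  }
  sx <- ix - array(uv$u / sp[1], dim = d)
  sy <- iy - array(uv$v / sp[2], dim = d)
  sz <- iz - array(uv$w / sp[3], dim = d)
  vals <- trilinear(unclass(vol), as.vector(sx), as.vector(sy), as.vector(sz))
  invalid <- array(is.na(vals), dim = d)
  vals[is.na(vals)] <- fill
  out <- volume_image(array(vals, dim = d), sp)
  attr(out, "invalid") <- invalid
  out
}
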