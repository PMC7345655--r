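# Time-lapse field pipeline: per-depth-stack drift removal, incremental to
# cumulative displacement accumulation, and foreground (cell) segmentation
# for masking.

#' Assign grid z-planes to acquisition depth stacks
#'
#' Volumetric coherence microscopes that fuse images acquired at stepped
#' focal depths produce the volume as a pile of depth sub-stacks, each of
#' which can drift rigidly between timepoints. This helper maps every
#' z-plane of a measurement grid to a stack index given the stack
#' thickness; the default (infinite thickness) treats the whole volume as
#' one stack.
#'
#' @param field a [deformation_field()].
#' @param thickness_um stack thickness in um, or `Inf` for a single stack.
#' @return Integer vector, one stack id per grid z-plane.
#' @export
stack_map <- function(field, thickness_um = Inf) {
  nz <- dim(field$u)[3]
  if (!is.finite(thickness_um)) return(rep(1L, nz))
  z_um <- (field$origin[3] + (seq_len(nz) - 1) * field$step[3] - 1) *
    field$spacing[3]
  as.integer(floor(z_um / thickness_um)) + 1L
}

#' Remove per-depth-stack rigid drift from a displacement field
#'
#' Thermal expansion, gel settling and stage backlash superimpose a rigid
#' offset on each acquisition depth stack. The mean of each displacement
#' component over the valid nodes of each stack is taken as that stack's
#' global drift and subtracted, leaving every stack exactly zero-mean; the
#' removed drift vectors are reported in the `"drift"` attribute.
#'
#' @param field a [deformation_field()].
#' @param stacks integer vector mapping each grid z-plane to a stack id
#'   (see [stack_map()]); default: one stack for the whole volume.
#' @return The drift-corrected `deformation_field` with attribute `drift`,
#'   a data.frame (stack, du, dv, dw, n_nodes). Stacks with no valid node
#'   are left unchanged with a warning.
#' @export
correct_drift <- function(field, stacks = NULL) {
  nz <- dim(field$u)[3]
  if (is.null(stacks)) stacks <- rep(1L, nz)
  if (length(stacks) != nz)
    stop("`stacks` must give one stack id per grid z-plane", call. = FALSE)
  out <- field
  ids <- sort(unique(stacks))
  drift <- data.frame(stack = ids, du = 0, dv = 0, dw = 0, n_nodes = 0L)
  for (r in seq_along(ids)) {
    zsel <- which(stacks == ids[r])
    vsel <- field$valid[, , zsel, drop = FALSE]
    n <- sum(vsel)
    drift$n_nodes[r] <- n
    if (n == 0) {
      warning(sprintf("depth stack %d has no valid node; left unchanged",
                      ids[r]))
      next
    }
    for (comp in c("u", "v", "w")) {
      slab <- field[[comp]][, , zsel, drop = FALSE]
      m <- mean(slab[vsel])
      drift[[paste0("d", comp)]][r] <- m
      out[[comp]][, , zsel] <- slab - m
    }
  }
  attr(out, "drift") <- drift
  out
}

#' Ordered sequence of incremental displacement fields
#'
#' @param fields list of [deformation_field()] objects sharing one grid,
#'   the per-timestep (incremental) DVC outputs in time order.
#' @param times optional strictly increasing timestamps.
#' @return An object of class `field_sequence`.
#' @export
field_sequence <- function(fields, times = seq_along(fields)) {
  if (length(fields) == 0) stop("empty field sequence", call. = FALSE)
  stopifnot(all(vapply(fields, inherits, TRUE, "deformation_field")))
  g0 <- fields[[1]]
  same <- vapply(fields, function(f) {
    identical(dim(f$u), dim(g0$u)) && all(f$origin == g0$origin) &&
      all(f$step == g0$step)
  }, TRUE)
  if (!all(same)) stop("all fields must share one grid", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  structure(list(fields = fields, times = times), class = "field_sequence")
}

#' Accumulate incremental displacements into cumulative maps
#'
#' The cumulative displacement at the first timestep equals the first
#' increment; afterwards each increment is evaluated at the node's current
#' deformed position (trilinear interpolation of the incremental field at
#' `x + cumulative(x)`) and added:
#' `cum_n(x) = cum_{n-1}(x) + inc_n(x + cum_{n-1}(x))`.
#' Nodes whose deformed position leaves the grid become invalid from that
#' timestep on.
#'
#' @param seq a [field_sequence()] of drift-corrected incremental fields.
#' @return A list of cumulative [deformation_field()] objects, one per
#'   timestep.
#' @export
accumulate_fields <- function(seq) {
  stopifnot(inherits(seq, "field_sequence"))
  fields <- seq$fields
  cum <- vector("list", length(fields))
  cum[[1]] <- fields[[1]]
  if (length(fields) == 1) return(cum)
  pos <- node_coords(fields[[1]])
  sp <- fields[[1]]$spacing
  for (n in 2:length(fields)) {
    prev <- cum[[n - 1]]
    inc <- fields[[n]]
    xi <- as.vector(pos$x + prev$u / sp[1])
    yi <- as.vector(pos$y + prev$v / sp[2])
    zi <- as.vector(pos$z + prev$w / sp[3])
    uv <- interp_field_at(inc, xi, yi, zi, extend = FALSE)
    d <- dim(prev$u)
    still <- !is.na(uv$u) & !is.na(uv$v) & !is.na(uv$w)
    cu <- prev$u + array(uv$u, d)
    cv <- prev$v + array(uv$v, d)
    cw <- prev$w + array(uv$w, d)
    valid <- prev$valid & inc$valid & array(still, d)
    cu[!valid] <- NA; cv[!valid] <- NA; cw[!valid] <- NA
    cum[[n]] <- deformation_field(cu, cv, cw, origin = prev$origin,
                                  step = prev$step, spacing = sp,
                                  quality = inc$quality, valid = valid)
  }
  cum
}

#' Segment bright foreground objects (cells) in a volume
#'
#' Thresholds the mean intensity projection along each axis (Otsu's
#' method), back-projects the three binary images, and takes
#' their intersection, optionally dilated by a safety margin. A projection
#' whose above-threshold fraction exceeds `max_fg_fraction` is treated as
#' homogeneous texture with no segmentable object and contributes an empty
#' mask: a cell body is a bright, localized minority of the projection,
#' while Otsu on pure matrix texture merely splits the speckle
#' distribution near its middle. The
#' resulting mask marks voxels to exclude from DVC subsets and to blank in
#' strain maps, since displacement of the matrix is undefined inside a
#' cell body.
#'
#' @param vol a [volume_image()].
#' @param margin dilation margin in voxels; the default (4) is about one
#'   PSF support at the default transverse sampling, recovering the blurred
#'   object rim the projection threshold misses.
#' @param threshold fixed threshold on the normalized (\[0, 1\]) mean
#'   projections, or `NULL` (default) for Otsu with the texture guard.
#' @param max_fg_fraction largest above-threshold projection fraction
#'   accepted as a genuine object.
#' @return Logical array of the volume's shape (`TRUE` = foreground).
#' @export
segment_foreground <- function(vol, margin = 4, threshold = NULL,
                               max_fg_fraction = 0.25) {
  arr <- unclass(vol)
  d <- dim(arr)
  if (max(arr) == min(arr)) {
    warning("constant volume: empty foreground mask")
    return(array(FALSE, dim = d))
  }
  proj <- list(apply(arr, c(2, 3), mean),   # along x -> (y, z)
               apply(arr, c(1, 3), mean),   # along y -> (x, z)
               apply(arr, c(1, 2), mean))   # along z -> (x, y)
  bin <- lapply(proj, function(p) {
    rng <- range(p)
    if (rng[2] == rng[1]) return(array(FALSE, dim = dim(p)))
    pn <- (p - rng[1]) / (rng[2] - rng[1])
    th <- if (!is.null(threshold)) threshold else {
      tryCatch(EBImage::otsu(EBImage::Image(pn), range = c(0, 1)),
               error = function(e) Inf)
    }
    fg <- pn > th
    if (is.null(threshold) && mean(fg) > max_fg_fraction)
      fg[] <- FALSE   # homogeneous texture, no localized object
    fg
  })
  mx <- array(rep(as.vector(bin[[1]]), each = d[1]), dim = d)
  my <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) my[, , k] <- matrix(bin[[2]][, k], d[1], d[2])
  mz <- array(rep(as.vector(bin[[3]]), times = d[3]), dim = d)
  mask <- mx & my & mz
  if (margin > 0 && any(mask)) mask <- dilate_box(mask, margin)
  mask
}
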