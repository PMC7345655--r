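# Infinitesimal strain mapping: noise suppression by box-mean filtering of
# the displacement grid, then the symmetrized displacement gradient
# eps_ij = (d u_i / d x_j + d u_j / d x_i) / 2 estimated with
# plane-averaged central differences on a 3x3x3 node stencil.

#' Box-mean filter a displacement field
#'
#' Each component is replaced by the mean over the valid nodes of an odd
#' box neighborhood; validity is unchanged. Direct differentiation of a
#' DVC field amplifies node-to-node noise, so a small mean filter is
#' applied before strain computation.
#'
#' @param field a [deformation_field()].
#' @param kernel odd box edge lengths (scalar or length-3), in grid nodes.
#' @return The smoothed `deformation_field`.
#' @export
smooth_field <- function(field, kernel = c(3, 3, 3)) {
  kernel <- rep_len(as.integer(kernel), 3L)
  if (any(kernel %% 2 == 0)) stop("`kernel` must be odd per axis", call. = FALSE)
  h <- (kernel - 1) %/% 2
  d <- dim(field$u)
  out <- field
  vnum <- field$valid * 1
  for (comp in c("u", "v", "w")) {
    x <- field[[comp]]
    x[!field$valid] <- 0
    acc <- array(0, dim = d); cnt <- array(0, dim = d)
    for (dz in -h[3]:h[3]) for (dy in -h[2]:h[2]) for (dx in -h[1]:h[1]) {
      sh <- c(dx, dy, dz)
      xs <- x
      cs <- vnum
      for (a in 1:3) if (sh[a] != 0) {
        xs <- shift_zero(xs, a, sh[a]); cs <- shift_zero(cs, a, sh[a])
      }
      acc <- acc + xs; cnt <- cnt + cs
    }
    sm <- acc / pmax(cnt, 1)
    sm[cnt == 0] <- NA
    sm[!field$valid] <- field[[comp]][!field$valid]
    out[[comp]] <- sm
  }
  out
}

#' Symmetric strain tensor field from a displacement field
#'
#' Estimates each gradient d u_i / d x_j by central differences along axis
#' j averaged over the 3x3 plane of neighbors orthogonal to j (the full
#' 3x3x3 stencil), using the physical node pitch (grid step times voxel
#' spacing, um) so the strains are dimensionless. A plain 1-D central
#' difference is available with `method = "axial"`. Boundary nodes, and
#' nodes with any invalid stencil neighbor, are invalid.
#'
#' @param field a [deformation_field()].
#' @param method `"plane"` (3x3-averaged central difference, default) or
#'   `"axial"` (plain central difference).
#' @return An object of class `strain_field` with arrays `exx, eyy, ezz,
#'   exy, eyz, exz`, a `valid` mask, and the grid geometry of the input.
#' @export
compute_strain <- function(field, method = c("plane", "axial")) {
  method <- match.arg(method)
  d <- dim(field$u)
  if (any(d < 3)) stop("grid must span >= 3 nodes per axis", call. = FALSE)
  pitch <- field$step * field$spacing  # um between adjacent nodes
  grad <- function(x, axis) {
    num <- shift_zero(x, axis, -1) - shift_zero(x, axis, 1)
    g <- num / (2 * pitch[axis])
    if (method == "plane") {
      others <- setdiff(1:3, axis)
      acc <- array(0, dim = d)
      for (da in -1:1) for (db in -1:1) {
        gs <- g
        if (da != 0) gs <- shift_zero(gs, others[1], da)
        if (db != 0) gs <- shift_zero(gs, others[2], db)
        acc <- acc + gs
      }
      g <- acc / 9
    }
    g
  }
  comp <- list(u = field$u, v = field$v, w = field$w)
  for (nm in names(comp)) comp[[nm]][!field$valid] <- NA
  g <- list()
  for (i in 1:3) for (j in 1:3)
    g[[paste0(i, j)]] <- grad(comp[[c("u", "v", "w")[i]]], j)
  eps <- list(exx = g[["11"]], eyy = g[["22"]], ezz = g[["33"]],
              exy = (g[["12"]] + g[["21"]]) / 2,
              eyz = (g[["23"]] + g[["32"]]) / 2,
              exz = (g[["13"]] + g[["31"]]) / 2)
  valid <- Reduce(`&`, lapply(eps, is.finite))
  # boundary nodes never have a full stencil
  valid[c(1, d[1]), , ] <- FALSE
  valid[, c(1, d[2]), ] <- FALSE
  valid[, , c(1, d[3])] <- FALSE
  for (nm in names(eps)) eps[[nm]][!valid] <- NA
  structure(c(eps, list(valid = valid, origin = field$origin,
                        step = field$step, spacing = field$spacing)),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  d <- dim(x$exx)
  cat(sprintf("<strain_field> %d x %d x %d nodes, %d valid\n",
              d[1], d[2], d[3], sum(x$valid)))
  if (any(x$valid)) {
    for (nm in c("exx", "eyy", "ezz", "exy", "eyz", "exz"))
      cat(sprintf("  %s: median %.2e, range [%.2e, %.2e]\n", nm,
                  stats::median(x[[nm]][x$valid]), min(x[[nm]][x$valid]),
                  max(x[[nm]][x$valid])))
  }
  invisible(x)
}
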