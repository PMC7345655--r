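# File formats. Volumes travel as multi-page grayscale TIFF (page = z
# slice; within a page, row = y and column = x) with voxel spacing in a
# sidecar JSON (and in the TIFF resolution tags for the transverse axes).
# Displacement and strain fields are written as per-component TIFF stacks,
# min-max normalized (TIFF floats are stored on [0, 1]) with scale/offset
# recorded in a JSON manifest; fields also export to legacy-ASCII VTK
# structured grids for 3-D rendering.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a volume as a multi-page TIFF with spacing metadata
#'
#' 32-bit float storage; intensities must lie in \[0, 1\] (the range of
#' every generated phantom). The voxel spacing (um/voxel) is written to a
#' sidecar JSON `<path>.json`; on reading, a sidecar wins over TIFF
#' resolution tags (a conflict is messaged), and a missing spacing is an
#' error unless supplied explicitly.
#'
#' @param vol a [volume_image()].
#' @param path TIFF file path.
#' @return `write_volume()`: the path, invisibly. `read_volume()`: a
#'   [volume_image()].
#' @export
write_volume <- function(vol, path) {
  arr <- unclass(vol)
  if (min(arr) < 0 || max(arr) > 1)
    stop("volume intensities must lie in [0, 1] for TIFF storage",
         call. = FALSE)
  sp <- voxel_spacing(vol)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32,
                  reduce = FALSE)
  jsonlite::write_json(list(spacing_um = sp, axis_order = "xyz",
                            page_axis = "z"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @param spacing optional explicit spacing (um/voxel), used if no sidecar
#'   exists.
#' @export
read_volume <- function(path, spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("expected >= 2 pages: a volume, not a single image", call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, TRUE)))
    stop("unsupported format: multi-channel (RGB) TIFF", call. = FALSE)
  sc <- sidecar_path(path)
  side <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
          else NULL
  if (!is.null(side$spacing_um)) {
    if (!is.null(spacing) &&
        max(abs(as.numeric(side$spacing_um) - spacing)) > 1e-9)
      message("sidecar spacing overrides the supplied spacing")
    spacing <- as.numeric(side$spacing_um)
  }
  if (is.null(spacing))
    stop(paste("no voxel spacing found: provide `spacing` or a sidecar",
               sidecar_path(path)), call. = FALSE)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  arr <- array(0, dim = d)
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  volume_image(arr, spacing)
}

#' Write / read a deformation field as per-component TIFF stacks
#'
#' Each component (u, v, w, quality) is stored as a multi-page TIFF after
#' min-max normalization; scale and offset, grid origin/step, voxel
#' spacing and the validity mask are recorded in `manifest.json` so the
#' round trip is lossless to float precision.
#'
#' @param field a [deformation_field()].
#' @param dir output directory (created if needed).
#' @return `write_field()`: the directory, invisibly; `read_field()`: a
#'   [deformation_field()].
#' @export
write_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comps <- list(u = field$u, v = field$v, w = field$w)
  if (!is.null(field$quality)) comps$quality <- field$quality
  norm <- list()
  for (nm in names(comps)) {
    x <- comps[[nm]]
    x[!is.finite(x)] <- 0
    lo <- min(x); hi <- max(x)
    scl <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(x)[3]), function(k) t((x[, , k] - lo) / scl))
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32)
    norm[[nm]] <- list(offset = lo, scale = scl)
  }
  jsonlite::write_json(
    list(components = names(comps), normalization = norm,
         origin = field$origin, step = field$step,
         spacing_um = field$spacing, units = "um",
         valid = as.integer(field$valid), dim = dim(field$u)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_field
#' @export
read_field <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  d <- as.integer(man$dim)
  get <- function(nm) {
    pages <- tiff::readTIFF(file.path(dir, paste0(nm, ".tif")), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = d)
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    arr * man$normalization[[nm]]$scale + man$normalization[[nm]]$offset
  }
  valid <- array(as.logical(man$valid), dim = d)
  q <- if ("quality" %in% man$components) get("quality") else NULL
  deformation_field(get("u"), get("v"), get("w"), origin = man$origin,
                    step = man$step, spacing = man$spacing_um,
                    quality = q, valid = valid)
}

#' Export a displacement or strain field to legacy-ASCII VTK
#'
#' Writes a `STRUCTURED_GRID` dataset with point coordinates in um and,
#' for a displacement field, a `VECTORS` array (um) plus the peak
#' correlation as scalars; for a strain field, a symmetric `TENSORS`
#' array. Invalid nodes are exported as zero with a companion `validity`
#' scalar. Readable by ParaView and other VTK-based viewers for the
#' color-coded map / cone-arrow renderings used to inspect matrix
#' deformation.
#'
#' @param x a [deformation_field()] or `strain_field`.
#' @param path output `.vtk` file.
#' @return The path, invisibly.
#' @export
export_vtk <- function(x, path) {
  is_strain <- inherits(x, "strain_field")
  if (!is_strain && !inherits(x, "deformation_field"))
    stop("`x` must be a deformation_field or strain_field", call. = FALSE)
  valid <- x$valid
  if (!any(valid)) stop("field has no valid node to export", call. = FALSE)
  d <- dim(valid)
  n <- prod(d)
  gx <- (x$origin[1] + (seq_len(d[1]) - 1) * x$step[1] - 1) * x$spacing[1]
  gy <- (x$origin[2] + (seq_len(d[2]) - 1) * x$step[2] - 1) * x$spacing[2]
  gz <- (x$origin[3] + (seq_len(d[3]) - 1) * x$step[3] - 1) * x$spacing[3]
  px <- rep(gx, times = d[2] * d[3])
  py <- rep(rep(gy, each = d[1]), times = d[3])
  pz <- rep(gz, each = d[1] * d[2])
  z <- function(a) { a <- as.vector(a); a[!is.finite(a)] <- 0; a }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               if (is_strain) "dvc3d strain field (dimensionless)"
               else "dvc3d displacement field (um)",
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("POINTS %d float", n)), con)
  write(t(cbind(px, py, pz)), con, ncolumns = 3)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS validity int 1", "LOOKUP_TABLE default"), con)
  write(as.integer(valid), con, ncolumns = 9)
  if (is_strain) {
    writeLines("TENSORS strain float", con)
    m <- cbind(z(x$exx), z(x$exy), z(x$exz),
               z(x$exy), z(x$eyy), z(x$eyz),
               z(x$exz), z(x$eyz), z(x$ezz))
    write(t(m), con, ncolumns = 9)
  } else {
    writeLines("VECTORS displacement float", con)
    write(t(cbind(z(x$u), z(x$v), z(x$w))), con, ncolumns = 3)
    if (!is.null(x$quality)) {
      writeLines(c("SCALARS peak_correlation float 1",
                   "LOOKUP_TABLE default"), con)
      write(z(x$quality), con, ncolumns = 9)
    }
  }
  invisible(path)
}
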