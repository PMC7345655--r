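# Validation protocols: sampling-rate arithmetic, the error floor between
# replicate volumes, virtual-translation accuracy across transverse
# sampling rates (the layout of the published summary table), and quartile
# summaries for box plots.

#' Transverse sampling rates from a fixed field of view
#'
#' A scanned field of view of fixed physical width imaged with different
#' pixel counts yields one sampling rate (um/px) per count.
#'
#' @param fov_um transverse field of view, um (default 320).
#' @param pixels pixel counts (default 400, 600, 800).
#' @return data.frame with `pixels`, exact `rate_um_px`, and the rate
#'   rounded to two decimals (`rate_rounded`).
#' @export
sampling_rates <- function(fov_um = 320, pixels = c(400, 600, 800)) {
  rate <- fov_um / pixels
  data.frame(pixels = pixels, rate_um_px = rate,
             rate_rounded = round(rate, 2))
}

#' Error floor between two replicate volumes
#'
#' Runs DVC between two volumes of the same nominal scene (replicate scans,
#' or one phantom with independent noise draws) and summarizes the
#' apparent per-component displacements: their standard deviation and
#' interquartile range are the sensitivity limit (error floor) of the
#' measurement. No drift correction is applied; the floor is reported raw.
#'
#' @param volA,volB [volume_image()] objects of one scene.
#' @param config a [dvc_config()]; single-pass by default here since no
#'   real deformation is present.
#' @return An `error_floor_stats` data.frame with rows U, V, W and
#'   Average (the arithmetic mean of the three components) and columns
#'   `std`, `iqr`, `mean`, `median` (um), plus attribute `field`.
#' @export
error_floor <- function(volA, volB,
                        config = dvc_config(max_passes = 1)) {
  fld <- run_dvc(volA, volB, config)
  stats_from_field(fld)
}

# Per-component displacement statistics over valid nodes, Average row =
# arithmetic mean of the three component rows.
stats_from_field <- function(fld) {
  if (sum(fld$valid) < 8)
    stop("fewer than 8 valid nodes; enlarge the volume or subsets",
         call. = FALSE)
  comp <- list(U = fld$u[fld$valid], V = fld$v[fld$valid],
               W = fld$w[fld$valid])
  tab <- data.frame(
    component = c("U", "V", "W"),
    std = vapply(comp, stats::sd, 0),
    iqr = vapply(comp, stats::IQR, 0),
    mean = vapply(comp, mean, 0),
    median = vapply(comp, stats::median, 0),
    n = vapply(comp, length, 0L))
  avg <- data.frame(component = "Average", std = mean(tab$std),
                    iqr = mean(tab$iqr), mean = mean(tab$mean),
                    median = mean(tab$median), n = tab$n[1])
  out <- rbind(tab, avg)
  rownames(out) <- out$component
  attr(out, "field") <- fld
  class(out) <- c("error_floor_stats", "data.frame")
  out
}

#' Simulate a replicate-scan pair of one scene
#'
#' One speckle phantom (single speckle realization) plus two independent
#' additive-noise draws at the given SNR: the synthetic stand-in for two
#' consecutively scanned volumes of an undisturbed sample.
#'
#' @param spec a [phantom_spec()] (its `noise_snr` is ignored; noise is
#'   drawn here).
#' @param snr_db acquisition SNR in dB for both draws.
#' @return List of two [volume_image()] objects.
#' @export
replicate_pair <- function(spec, snr_db = 25) {
  spec$noise_snr <- NULL
  clean <- generate_phantom(spec)
  list(add_noise(clean, snr_db, seed = spec$seed * 2L + 101L),
       add_noise(clean, snr_db, seed = spec$seed * 2L + 103L))
}

#' Virtual-translation accuracy experiment across sampling rates
#'
#' For each transverse sampling rate, generates a speckle phantom at that
#' spacing, applies (i) the prescribed integer transverse voxel shift to
#' both x and y (the same physical length at every rate) by circular roll
#' and (ii) the prescribed axial physical shift via the Fourier-shift
#' oracle, crops the wrap-around margins, runs DVC, and tabulates the
#' recovered mean/median displacements against ground truth together with
#' error-floor columns from a replicate-noise pair — the layout of the
#' published validation table. Ground-truth columns come from the shift
#' specification alone, never from DVC output.
#'
#' @param scene_seed integer seed; each rate derives its own sub-seed.
#' @param rates transverse sampling rates in um/px (default
#'   `sampling_rates()$rate_um_px`).
#' @param shifts_vox integer transverse shift per rate (default 4, 6, 8
#'   voxels, i.e. the same 3.20 um at each default rate).
#' @param axial_shift_um physical axial shift, um (default 4.42, applied
#'   with the subvoxel oracle since it is not an integer multiple of the
#'   axial spacing).
#' @param axial_spacing axial sampling rate, um/px (default 0.73).
#' @param shape phantom voxel dimensions before margin cropping.
#' @param snr_db acquisition SNR for the error-floor replicate pair.
#' @param config a [dvc_config()]; default single-pass, subset 128.
#' @param fibers fiber count of the phantom scene.
#' @return An object of class `vt_experiment`: list with `table` (rows U,
#'   V, W, Average; per-rate error-floor and displacement columns plus
#'   ground truth), `per_rate` details, and the call parameters.
#' @export
virtual_translation_experiment <- function(scene_seed = 11L,
                                           rates = sampling_rates()$rate_um_px,
                                           shifts_vox = c(4L, 6L, 8L),
                                           axial_shift_um = 4.42,
                                           axial_spacing = 0.73,
                                           shape = c(256, 256, 160),
                                           snr_db = 25,
                                           config = dvc_config(max_passes = 1),
                                           fibers = 300L) {
  stopifnot(length(rates) == length(shifts_vox))
  margin <- as.integer(ceiling(max(shifts_vox,
                                   axial_shift_um / axial_spacing)) + 2L)
  per_rate <- vector("list", length(rates))
  for (i in seq_along(rates)) {
    r <- rates[i]; nshift <- as.integer(shifts_vox[i])
    spec <- phantom_spec(shape = shape, spacing = c(r, r, axial_spacing),
                         fiber_count = fibers, noise_snr = snr_db,
                         seed = scene_seed + 1000L * i)
    vol <- generate_phantom(spec)
    ref <- crop_margin(vol, margin)
    # transverse: integer roll in x and y, same physical length per rate
    trans <- crop_margin(apply_integer_shift(vol, c(nshift, nshift, 0L)),
                         margin)
    fld_t <- run_dvc(ref, trans, config)
    # axial: physical shift via the Fourier subvoxel oracle
    axial <- crop_margin(apply_subvoxel_shift(vol, c(0, 0, axial_shift_um)),
                         margin)
    fld_a <- run_dvc(ref, axial, config)
    # error floor: replicate-noise pair of the same scene
    pair <- replicate_pair(spec, snr_db)
    ef <- error_floor(crop_margin(pair[[1]], margin),
                      crop_margin(pair[[2]], margin), config)
    per_rate[[i]] <- list(
      rate = r, shift_vox = nshift,
      gt = c(U = nshift * r, V = nshift * r, W = axial_shift_um),
      transverse = stats_from_field(fld_t),
      axial = stats_from_field(fld_a),
      error_floor = ef,
      subvoxel_transverse = FALSE)
  }
  structure(list(table = vt_table(per_rate, rates),
                 per_rate = per_rate,
                 rates = rates, shifts_vox = shifts_vox,
                 axial_shift_um = axial_shift_um, scene_seed = scene_seed),
            class = "vt_experiment")
}

# Assemble the published table's layout: rows U, V, W, Average; per rate a
# pair of columns (error floor STD (IQR), displacement mean (median)); a
# final ground-truth column.
vt_table <- function(per_rate, rates) {
  rows <- c("U", "V", "W", "Average")
  tab <- data.frame(component = rows)
  disp_stat <- function(pr, row, what) {
    # U, V from the transverse experiment; W from the axial one;
    # Average mixes them as the component mean
    if (row == "Average") {
      mean(c(pr$transverse[c("U", "V"), what], pr$axial["W", what]))
    } else if (row == "W") pr$axial["W", what]
    else pr$transverse[row, what]
  }
  for (i in seq_along(per_rate)) {
    pr <- per_rate[[i]]
    lab <- sprintf("%.2f", round(pr$rate, 2))
    tab[[paste0("ef_std_", lab)]] <-
      vapply(rows, function(rw) unlist(pr$error_floor[rw, "std"]), 0)
    tab[[paste0("ef_iqr_", lab)]] <-
      vapply(rows, function(rw) unlist(pr$error_floor[rw, "iqr"]), 0)
    tab[[paste0("disp_mean_", lab)]] <-
      vapply(rows, function(rw) unlist(disp_stat(pr, rw, "mean")), 0)
    tab[[paste0("disp_median_", lab)]] <-
      vapply(rows, function(rw) unlist(disp_stat(pr, rw, "median")), 0)
  }
  gt <- vapply(rows, function(rw) {
    if (rw == "Average") mean(c(per_rate[[1]]$gt))
    else per_rate[[1]]$gt[rw]
  }, 0)
  tab$ground_truth <- gt
  rownames(tab) <- rows
  tab
}

#' @export
print.vt_experiment <- function(x, ...) {
  cat("<vt_experiment> virtual-translation accuracy\n")
  cat(sprintf("  rates: %s um/px; transverse shifts: %s vox; axial %.2f um\n",
              paste(sprintf("%.2f", x$rates), collapse = ", "),
              paste(x$shifts_vox, collapse = ", "), x$axial_shift_um))
  print(format(x$table, digits = 4))
  invisible(x)
}

#' Write the virtual-translation summary table to a delimited file
#'
#' @param x a `vt_experiment`.
#' @param path output path (tab-separated text).
#' @export
write_vt_table <- function(x, path) {
  stopifnot(inherits(x, "vt_experiment"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Five-number box-plot summary
#'
#' Median, quartiles (type-7), whiskers at the most extreme data inside
#' 1.5 IQR of the box, and the outliers beyond them.
#'
#' @param x numeric sample.
#' @return List: `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
summarize_boxplot <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  inside <- x >= lo & x <= hi
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = sort(x[!inside]))
}
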