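# Six semi-quantitative kinetic maps computed pixel-by-pixel from the
# 9-frame series SI_0..SI_8:
#   MSI       = max_i (SI_{i+1} - SI_i),        i = 0..7, intensity units
#   SI_slope  = 100 (SI_8 - SI_mean) / SI_mean, SI_mean = (SI_1 + SI_2)/2
#   E_initial = 100 (SI_1 - SI_0) / SI_0
#   ESER      = 100 (SI_1 - SI_0) / (SI_2 - SI_0)
#   E_peak    = 100 (SI_peak - SI_0) / SI_0
#   SEP       = 100 (SI_2 - SI_0) / SI_0
# SI_peak is the value at the peak timepoint of the region-mean
# time-intensity curve (one timepoint per region) by default; a per-pixel
# peak mode is available. Degenerate denominators give 0 and are flagged.

# dim-preserving frame slice (1 x n studies would otherwise drop dims)
#' @noRd
frame_slice <- function(f, i) array(f[, , i], dim(f)[1:2])

#' @noRd
flagged_ratio <- function(num, den, scale = 100) {
  bad <- !is.finite(den) | den == 0
  out <- ifelse(bad, 0, scale * num / ifelse(bad, 1, den))
  structure(out, flagged = bad)
}

#' Maximum slope of increase (MSI)
#'
#' Per pixel, the largest consecutive-frame increase
#' \eqn{\max_i (SI_{i+1} - SI_i)} over all eight steps (pre-contrast to
#' first post-contrast included). Units: intensity.
#'
#' @param study a `dce_study`.
#' @param region `roi_mask` used for region bookkeeping (MSI itself is
#'   purely per-pixel).
#' @return numeric matrix.
#' @export
compute_msi <- function(study, region = NULL) {
  f <- study$frames
  out <- frame_slice(f, 2) - frame_slice(f, 1)
  for (i in 2:8) out <- pmax(out, frame_slice(f, i + 1) - frame_slice(f, i))
  structure(out, flagged = matrix(FALSE, nrow(out), ncol(out)))
}

#' Slope of signal intensity (SI_slope)
#'
#' `100 * (SI_8 - SI_mean) / SI_mean` with `SI_mean = (SI_1 + SI_2) / 2`;
#' percent. Pixels with `SI_mean = 0` are set to 0 and flagged.
#' @inheritParams compute_msi
#' @export
compute_si_slope <- function(study, region = NULL) {
  f <- study$frames
  si_mean <- (frame_slice(f, 2) + frame_slice(f, 3)) / 2
  flagged_ratio(frame_slice(f, 9) - si_mean, si_mean)
}

#' Initial enhancement percentage (E_initial)
#'
#' `100 * (SI_1 - SI_0) / SI_0`; percent. `SI_0 = 0` pixels → 0, flagged.
#' @inheritParams compute_msi
#' @export
compute_e_initial <- function(study, region = NULL) {
  f <- study$frames
  flagged_ratio(frame_slice(f, 2) - frame_slice(f, 1), frame_slice(f, 1))
}

#' Early signal enhancement ratio (ESER)
#'
#' `100 * (SI_1 - SI_0) / (SI_2 - SI_0)`; percent. `SI_2 = SI_0` pixels →
#' 0, flagged.
#' @inheritParams compute_msi
#' @export
compute_eser <- function(study, region = NULL) {
  f <- study$frames
  flagged_ratio(frame_slice(f, 2) - frame_slice(f, 1), frame_slice(f, 3) - frame_slice(f, 1))
}

#' Region-level peak enhancement timepoint
#'
#' Argmax over post-contrast frames t = 1..8 of the region-mean
#' time-intensity curve.
#' @inheritParams compute_msi
#' @return integer in 1..8.
#' @export
peak_timepoint <- function(study, region) {
  stopifnot(!is.null(region), any(region))
  m <- vapply(1:8, function(t) mean(frame_slice(study$frames, t + 1)[region > 0]), 0)
  which.max(m)
}

#' Peak enhancement percentage (E_peak)
#'
#' `100 * (SI_peak - SI_0) / SI_0`; percent. By default `SI_peak` is taken
#' at the single peak timepoint of the region-mean curve; with
#' `per_pixel_peak = TRUE` each pixel uses its own post-contrast maximum.
#' @inheritParams compute_msi
#' @param per_pixel_peak logical, see above.
#' @export
compute_e_peak <- function(study, region, per_pixel_peak = FALSE) {
  f <- study$frames
  if (per_pixel_peak) {
    pk <- frame_slice(f, 2)
    for (t in 2:8) pk <- pmax(pk, frame_slice(f, t + 1))
  } else {
    pk <- frame_slice(f, peak_timepoint(study, region) + 1)
  }
  flagged_ratio(pk - frame_slice(f, 1), frame_slice(f, 1))
}

#' Second enhancement percentage (SEP)
#'
#' `100 * (SI_2 - SI_0) / SI_0`; percent. `SI_0 = 0` pixels → 0, flagged.
#' @inheritParams compute_msi
#' @export
compute_sep <- function(study, region = NULL) {
  f <- study$frames
  flagged_ratio(frame_slice(f, 3) - frame_slice(f, 1), frame_slice(f, 1))
}

#' Compute the six-map set for one region
#'
#' Bundles MSI, SI_slope, E_initial, ESER, E_peak and SEP. Maps are
#' computed over the full raster (filter-bank features need context beyond
#' the ROI); the region determines the shared peak timepoint and the
#' flagged-pixel accounting.
#'
#' @inheritParams compute_e_peak
#' @return a `parametric_map_set`: named list of six matrices with
#'   attributes `peak_timepoint` and `n_flagged` (flagged pixels within the
#'   region across maps).
#' @export
compute_map_set <- function(study, region, per_pixel_peak = FALSE) {
  stopifnot(!is.null(region), any(region))
  maps <- list(msi = compute_msi(study, region),
               si_slope = compute_si_slope(study, region),
               e_initial = compute_e_initial(study, region),
               eser = compute_eser(study, region),
               e_peak = compute_e_peak(study, region, per_pixel_peak),
               sep = compute_sep(study, region))
  nf <- sum(vapply(maps, function(m) sum(attr(m, "flagged")[region > 0]), 0))
  structure(maps,
            peak_timepoint = if (per_pixel_peak) NA_integer_ else peak_timepoint(study, region),
            n_flagged = nf, class = "parametric_map_set")
}

#' Write a map set to NIfTI files
#' @param maps a `parametric_map_set`.
#' @param dir output directory.
#' @param prefix file-name prefix, e.g. `"P0001_intra"`.
#' @return invisibly, the written paths.
#' @export
write_map_set <- function(maps, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(unclass(maps[[nm]]), p)
    p
  }, "")
  invisible(paths)
}
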