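#' Subtraction image
#'
#' Subtracts the pre-contrast frame from one post-contrast frame; negative
#' values are retained.
#'
#' @param study a `dce_study`.
#' @param timepoint post-contrast index in 1..8.
#' @return matrix of class `subtraction_image` with attribute
#'   `source_timepoint`.
#' @export
subtract_frames <- function(study, timepoint) {
  stopifnot(length(timepoint) == 1, timepoint >= 1, timepoint <= 8)
  out <- study$frames[, , timepoint + 1] - study$frames[, , 1]
  structure(out, source_timepoint = as.integer(timepoint),
            class = c("subtraction_image", "matrix", "array"))
}

#' Otsu threshold (maximum between-class variance)
#'
#' Histogram-based threshold: values are binned into `n_bins` equal-width
#' bins over their range; the returned threshold is the internal bin edge
#' maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}, ties broken toward the lower
#' edge. Pixels strictly above the threshold form the upper (foreground)
#' class.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold (a bin edge), numeric scalar.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (r[1] == r[2]) stop("constant input: no separating threshold")
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- tabulate(pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
                     n_bins), n_bins)
  p <- h / sum(h)
  w0 <- cumsum(p)[-n_bins]
  m0 <- cumsum(p * mids)[-n_bins]
  mt <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  edges[which.max(bcv) + 1L]
}

#' Segment the intratumoral region
#'
#' Semi-automatic lesion segmentation: an Otsu threshold is computed from
#' the subtraction-image values inside a user-supplied seed box; the mask
#' is the largest 8-connected component of supra-threshold pixels within
#' the box, with holes filled.
#'
#' @param sub a [subtract_frames()] image (or plain matrix).
#' @param seed_box named vector `c(rmin, rmax, cmin, cmax)` (inclusive,
#'   1-based) inside the image.
#' @param n_bins histogram bins for the threshold.
#' @return logical matrix of class `roi_mask` with attributes `region_tag =
#'   "intratumoral"` and `threshold`.
#' @export
segment_intratumoral <- function(sub, seed_box, n_bins = 256) {
  sb <- as.integer(round(seed_box[c("rmin", "rmax", "cmin", "cmax")]))
  stopifnot(sb[1] >= 1, sb[3] >= 1, sb[2] <= nrow(sub), sb[4] <= ncol(sub),
            sb[1] < sb[2], sb[3] < sb[4])
  box_vals <- sub[sb[1]:sb[2], sb[3]:sb[4]]
  thr <- otsu_threshold(as.numeric(box_vals), n_bins)
  supra <- matrix(FALSE, nrow(sub), ncol(sub))
  supra[sb[1]:sb[2], sb[3]:sb[4]] <- box_vals > thr
  if (!any(supra)) stop("no supra-threshold pixels in seed box")
  lab <- EBImage::bwlabel(EBImage::Image(supra + 0, dim(supra)))
  tab <- tabulate(as.integer(lab))
  mask <- as.matrix(lab) == which.max(tab)
  mask <- matrix(as.matrix(EBImage::fillHull(EBImage::Image(mask + 0, dim(mask)))) > 0,
                 nrow(sub), ncol(sub))
  structure(mask, region_tag = "intratumoral", threshold = thr,
            class = c("roi_mask", "matrix", "array"))
}

#' Peritumoral ring by radial dilation
#'
#' Dilates the intratumoral mask by a Euclidean radial distance (mm
#' converted to pixels, rounded to nearest integer), removes the core, and
#' clips the ring to the breast mask.
#'
#' @param core intratumoral `roi_mask` (non-empty, contained in `breast`).
#' @param breast breast-parenchyma mask, same dimensions.
#' @param radius_mm radial dilation distance in mm (default 4).
#' @param pixel_spacing_mm pixel spacing in mm.
#' @return logical `roi_mask` with `region_tag = "peritumoral"` and
#'   attribute `radius_px`.
#' @export
dilate_peritumoral <- function(core, breast, radius_mm = 4, pixel_spacing_mm) {
  stopifnot(any(core), radius_mm > 0, pixel_spacing_mm > 0,
            all(dim(core) == dim(breast)))
  if (any(core & !breast)) stop("core must be contained in the breast mask")
  r_px <- round(radius_mm / pixel_spacing_mm)
  d <- as.matrix(EBImage::distmap(EBImage::Image(1 - (core > 0), dim(core))))
  ring <- matrix(d > 0 & d <= r_px & (breast > 0), nrow(core), ncol(core))
  if (!any(ring)) stop("peritumoral ring is empty (core fills the breast mask)")
  structure(ring, region_tag = "peritumoral", radius_px = r_px,
            class = c("roi_mask", "matrix", "array"))
}

#' Choose the subtraction timepoint used for segmentation
#'
#' Default rule: the post-contrast timepoint whose subtraction image has
#' maximum mean enhancement inside the seed box.
#'
#' @param study a `dce_study`.
#' @param seed_box seed box as in [segment_intratumoral()].
#' @return integer in 1..8.
#' @export
segmentation_timepoint <- function(study, seed_box) {
  sb <- as.integer(round(seed_box[c("rmin", "rmax", "cmin", "cmax")]))
  m <- vapply(1:8, function(t) {
    s <- study$frames[, , t + 1] - study$frames[, , 1]
    mean(s[sb[1]:sb[2], sb[3]:sb[4]])
  }, 0)
  which.max(m)
}

#' Build the full ROI set for one study
#'
#' Convenience wrapper: picks the segmentation timepoint, segments the
#' lesion in the seed box, and derives the peritumoral ring constrained to
#' the breast mask.
#'
#' @param study a `dce_study`.
#' @param seed_box seed box; defaults to the study's `seed_box` attribute.
#' @param breast breast mask; defaults to the study's `breast_mask`
#'   attribute.
#' @param radius_mm peritumoral dilation radius, mm.
#' @param timepoint subtraction timepoint; `NULL` = automatic rule.
#' @return list with elements `intra`, `peri`, `breast`, `timepoint`.
#' @export
build_roi_set <- function(study, seed_box = attr(study, "seed_box"),
                          breast = attr(study, "breast_mask"),
                          radius_mm = 4, timepoint = NULL) {
  stopifnot(!is.null(seed_box), !is.null(breast))
  if (is.null(timepoint)) timepoint <- segmentation_timepoint(study, seed_box)
  sub <- subtract_frames(study, timepoint)
  intra <- segment_intratumoral(sub, seed_box)
  # clip a lesion that spills past the breast edge before ring construction
  if (any(intra & !breast)) {
    intra_m <- intra & (breast > 0)
    intra <- structure(intra_m, region_tag = "intratumoral",
                       threshold = attr(intra, "threshold"),
                       class = c("roi_mask", "matrix", "array"))
  }
  peri <- dilate_peritumoral(intra, breast, radius_mm, study$pixel_spacing_mm)
  list(intra = intra, peri = peri, breast = breast > 0,
       timepoint = as.integer(timepoint))
}

#' Dice overlap of two binary masks
#' @param a,b logical matrices of equal dimensions.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0; b <- b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Read/write ROI masks as PNG (0/255)
#' @param mask logical matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(t(mask * 1), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  t(png::readPNG(path)) > 0.5
}
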