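# Feature bank: per (region, map) pair
#   first-order  15   on mu+/-3sigma quantized 8-bit levels
#   GLCM         60   15 Haralick descriptors x 4 directions, distance 1
#   Laws        100   25 5x5 masks x {mean, sd, skewness, kurtosis}
#   Gabor       240   40 filters x {mean, sd, skewness, kurtosis, energy, entropy}
# = 415; 2 regions x 6 maps x 415 = 4980 features per case.
# First-order and GLCM operate on the quantized levels; Laws and Gabor on
# the continuous z-normalized map (filter banks on quantized data alias).

FEATURE_FAMILIES <- c("firstorder", "glcm", "laws", "gabor")
MAP_NAMES <- c("msi", "si_slope", "e_initial", "eser", "e_peak", "sep")
REGION_NAMES <- c("intra", "peri")

#' Normalize and quantize a map within an ROI
#'
#' Clips ROI intensities to \eqn{[\mu - 3\sigma, \mu + 3\sigma]} (mu, sigma
#' = ROI mean and SD) and maps them linearly onto 8-bit gray levels 0..255,
#' rounding half up. A constant ROI (sigma = 0) yields all levels 128 and
#' is flagged.
#'
#' @param map numeric matrix.
#' @param region logical ROI mask, same dimensions, >= 2 pixels.
#' @return a `quantized_roi`: list with `levels` (integer vector over ROI
#'   pixels, column-major order), `index` (ROI pixel indices), `dim`,
#'   `mu`, `sigma`, `n_levels = 256`, `flagged`.
#' @export
normalize_quantize <- function(map, region) {
  idx <- which(region > 0)
  if (length(idx) < 2) stop("ROI must contain at least 2 pixels")
  x <- as.numeric(map)[idx]
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sigma == 0) {
    lv <- rep(128L, length(x))
    flagged <- TRUE
  } else {
    lo <- mu - 3 * sigma
    xc <- pmin(pmax(x, lo), mu + 3 * sigma)
    lv <- as.integer(floor(255 * (xc - lo) / (6 * sigma) + 0.5))
    flagged <- FALSE
  }
  structure(list(levels = lv, index = idx, dim = dim(map),
                 mu = mu, sigma = sigma, n_levels = 256L, flagged = flagged),
            class = "quantized_roi")
}

#' First-order statistics of a quantized ROI
#'
#' Fifteen descriptors of the in-ROI gray levels: mean, median, min, max,
#' range, SD (n-1), variance (n-1), skewness, kurtosis (non-excess),
#' energy (sum of squares), entropy (bits, 256-bin histogram), uniformity,
#' RMS, mean absolute deviation, IQR.
#'
#' @param q a [normalize_quantize()] result.
#' @return named numeric vector of length 15.
#' @export
firstorder_features <- function(q) {
  x <- as.numeric(q$levels)
  ms <- moment_stats(x)
  p <- tabulate(q$levels + 1L, q$n_levels) / length(x)
  c(mean = ms[["mean"]],
    median = stats::median(x),
    min = min(x), max = max(x), range = max(x) - min(x),
    sd = ms[["sd"]], variance = ms[["sd"]]^2,
    skewness = ms[["skewness"]], kurtosis = ms[["kurtosis"]],
    energy = sum(x^2),
    entropy = entropy_bits(p),
    uniformity = sum(p^2),
    rms = sqrt(mean(x^2)),
    mad = mean(abs(x - mean(x))),
    iqr = stats::IQR(x))
}

# ---- GLCM -------------------------------------------------------------

# Direction offsets (drow, dcol) in matrix coordinates for 0, 45, 90, 135
# degrees (0 = along a row, i.e. increasing column; image y axis points
# down so 45 pairs a pixel with its upper-right neighbour).
GLCM_OFFSETS <- list(d0 = c(0L, 1L), d45 = c(-1L, 1L),
                     d90 = c(-1L, 0L), d135 = c(-1L, -1L))

#' @noRd
glcm_pairs <- function(q, off) {
  nr <- q$dim[1]; nc <- q$dim[2]
  lvl <- matrix(NA_integer_, nr, nc)
  lvl[q$index] <- q$levels
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- lvl[r1, c1, drop = FALSE]
  b <- lvl[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  cbind(i = a[ok], j = b[ok])
}

# Sparse symmetric normalized GLCM: data.frame(i, j, p) over nonzero cells.
#' @noRd
glcm_sparse <- function(q, off) {
  pr <- glcm_pairs(q, off)
  if (nrow(pr) == 0) return(NULL)
  keys <- c(pr[, 1] * 256 + pr[, 2], pr[, 2] * 256 + pr[, 1])  # symmetrize
  tab <- table(keys)
  k <- as.numeric(names(tab))
  data.frame(i = k %/% 256, j = k %% 256, p = as.numeric(tab) / sum(tab))
}

#' @noRd
haralick_from_sparse <- function(g) {
  nms <- c("contrast", "dissimilarity", "homogeneity", "asm", "energy",
           "correlation", "entropy", "variance", "sum_average",
           "sum_variance", "sum_entropy", "difference_variance",
           "difference_entropy", "imc1", "imc2")
  if (is.null(g)) return(stats::setNames(rep(0, 15), nms))
  i <- g$i; j <- g$j; p <- g$p
  dif <- abs(i - j); s <- i + j
  px <- tapply(p, i, sum)                       # marginal (symmetric: px = py)
  lev <- as.numeric(names(px)); px <- as.numeric(px)
  mu_x <- sum(lev * px)
  var_x <- sum((lev - mu_x)^2 * px)
  contrast <- sum(p * dif^2)
  dissim <- sum(p * dif)
  homog <- sum(p / (1 + dif^2))
  asm <- sum(p^2)
  correlation <- if (var_x > 0) sum(p * (i - mu_x) * (j - mu_x)) / var_x else 0
  entropy <- -sum(p * log2(p))
  variance <- sum(p * (i - mu_x)^2)
  p_s <- tapply(p, s, sum); s_lev <- as.numeric(names(p_s)); p_s <- as.numeric(p_s)
  sum_avg <- sum(s_lev * p_s)
  sum_var <- sum((s_lev - sum_avg)^2 * p_s)
  sum_ent <- entropy_bits(p_s)
  p_d <- tapply(p, dif, sum); d_lev <- as.numeric(names(p_d)); p_d <- as.numeric(p_d)
  d_avg <- sum(d_lev * p_d)
  diff_var <- sum((d_lev - d_avg)^2 * p_d)
  diff_ent <- entropy_bits(p_d)
  # IMC1/2: HX = HY by symmetry; HXY2 = HX + HY for the product measure
  hx <- entropy_bits(px)
  lpx <- log2(px)[match(i, lev)]; lpy <- log2(px)[match(j, lev)]
  hxy1 <- -sum(p * (lpx + lpy))
  hxy2 <- 2 * hx
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  arg <- 1 - exp(-2 * log(2) * (hxy2 - entropy))  # entropies in bits -> nats
  imc2 <- sqrt(max(0, arg))
  stats::setNames(c(contrast, dissim, homog, asm, sqrt(asm), correlation,
                    entropy, variance, sum_avg, sum_var, sum_ent, diff_var,
                    diff_ent, imc1, imc2), nms)
}

#' Haralick GLCM features of a quantized ROI
#'
#' Symmetric normalized distance-1 co-occurrence matrices in four
#' directions (0, 45, 90, 135 degrees), restricted to pixel pairs lying
#' entirely inside the ROI; 15 Haralick descriptors per direction.
#' Directions with no valid pair return zeros (flagged via attribute).
#'
#' @param q a [normalize_quantize()] result.
#' @return named numeric vector of length 60 (`d0_contrast`, ...).
#' @export
glcm_features <- function(q) {
  out <- numeric(0)
  flagged <- character(0)
  for (d in names(GLCM_OFFSETS)) {
    g <- glcm_sparse(q, GLCM_OFFSETS[[d]])
    if (is.null(g)) flagged <- c(flagged, d)
    h <- haralick_from_sparse(g)
    names(h) <- paste(d, names(h), sep = "_")
    out <- c(out, h)
  }
  structure(out, flagged_directions = flagged)
}

# ---- Laws -------------------------------------------------------------

LAWS_VECTORS <- list(L5 = c(1, 4, 6, 4, 1),
                     E5 = c(-1, -2, 0, 2, 1),
                     S5 = c(-1, 0, 2, 0, -1),
                     W5 = c(-1, 2, 0, -2, 1),
                     R5 = c(1, -4, 6, -4, 1))

#' Laws texture-energy features
#'
#' Applies all 25 5x5 Laws masks (outer products of the L5/E5/S5/W5/R5
#' vectors; first letter = vertical/row direction) to the z-normalized map,
#' forms texture-energy images as the absolute response smoothed by a 15x15
#' mean filter, and summarizes each within the ROI by mean, SD, skewness
#' and kurtosis.
#'
#' @param map numeric matrix (raw map; z-normalized internally using ROI
#'   mean/SD).
#' @param region logical ROI mask.
#' @return named numeric vector of length 100 (`L5E5_mean`, ...).
#' @export
laws_features <- function(map, region) {
  idx <- which(region > 0)
  x <- as.numeric(map)[idx]
  sigma <- stats::sd(x)
  z <- if (sigma > 0) (map - mean(x)) / sigma else map * 0
  box <- rep(1 / 15, 15)
  out <- numeric(0)
  for (u in names(LAWS_VECTORS)) {
    for (v in names(LAWS_VECTORS)) {
      resp <- conv_sep(z, LAWS_VECTORS[[u]], LAWS_VECTORS[[v]])
      energy <- conv_sep(abs(resp), box, box)
      ms <- moment_stats(energy[idx])
      names(ms) <- paste0(u, v, "_", names(ms))
      out <- c(out, ms)
    }
  }
  out
}

# ---- Gabor ------------------------------------------------------------

GABOR_WAVELENGTHS <- c(2, 4, 6, 8, 10)
GABOR_ORIENTATIONS <- seq(0, 157.5, by = 22.5)

#' @noRd
gabor_kernel <- function(wavelength, theta_deg, sigma = 0.5 * wavelength,
                         gamma = 1) {
  th <- theta_deg * pi / 180
  h <- max(3L, ceiling(3 * sigma))
  g <- expand.grid(x = -h:h, y = -h:h)
  xr <- g$x * cos(th) + g$y * sin(th)
  yr <- -g$x * sin(th) + g$y * cos(th)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  k <- env * exp(2i * pi * xr / wavelength)
  # exact DC correction of the real (even) part; odd part sums to ~0 already
  re <- Re(k); re <- re - env * sum(re) / sum(env)
  im <- Im(k); im <- im - mean(im)
  matrix(complex(real = re, imaginary = im), 2 * h + 1, 2 * h + 1)
}

#' @noRd
gabor_bank <- function() {
  kernels <- list()
  for (w in GABOR_WAVELENGTHS) {
    for (o in GABOR_ORIENTATIONS) {
      kernels[[sprintf("w%g_o%g", w, o)]] <- gabor_kernel(w, o)
    }
  }
  kernels
}

#' Gabor filter-bank features
#'
#' DC-free complex Gabor filters at wavelengths 2, 4, 6, 8, 10 px and 8
#' orientations (0 to 157.5 degrees in 22.5-degree steps; theta is the
#' direction of sinusoidal modulation). The magnitude response on the
#' z-normalized map is summarized within the ROI by mean, SD, skewness,
#' kurtosis, energy (mean squared magnitude) and entropy (bits, 32-bin
#' histogram).
#'
#' @inheritParams laws_features
#' @return named numeric vector of length 240 (`w2_o0_mean`, ...).
#' @export
gabor_features <- function(map, region) {
  idx <- which(region > 0)
  x <- as.numeric(map)[idx]
  sigma <- stats::sd(x)
  z <- if (sigma > 0) (map - mean(x)) / sigma else map * 0
  bank <- gabor_bank()
  resp <- conv_bank_fft(z, bank, cache_key = "gabor")
  out <- numeric(0)
  for (nm in names(bank)) {
    m <- Mod(resp[[nm]])[idx]
    ms <- moment_stats(m)
    rng <- range(m)
    if (rng[2] > rng[1]) {
      h <- tabulate(pmin(1L + floor(32 * (m - rng[1]) / (rng[2] - rng[1])), 32L), 32L)
      ent <- entropy_bits(h / sum(h))
    } else ent <- 0
    v <- c(ms, energy = mean(m^2), entropy = ent)
    names(v) <- paste(nm, names(v), sep = "_")
    out <- c(out, v)
  }
  out
}

# ---- assembly ---------------------------------------------------------

#' Extract the full feature vector for one study
#'
#' For each region (intratumoral, peritumoral) and each of the six
#' parametric maps, extracts the configured feature families. With all four
#' families this yields exactly 4980 named features
#' (2 regions x 6 maps x 415).
#'
#' @param study a `dce_study`.
#' @param rois a [build_roi_set()] result (or list with `intra`, `peri`).
#' @param families subset of `c("firstorder", "glcm", "laws", "gabor")`.
#' @return named numeric vector; names `{region}_{map}_{family}_{feature}`.
#' @export
extract_all_features <- function(study, rois, families = FEATURE_FAMILIES) {
  stopifnot(all(families %in% FEATURE_FAMILIES))
  out <- numeric(0)
  for (rg in REGION_NAMES) {
    region <- rois[[if (rg == "intra") "intra" else "peri"]]
    maps <- compute_map_set(study, region)
    for (mp in MAP_NAMES) {
      m <- unclass(maps[[mp]])
      attr(m, "flagged") <- NULL
      q <- if (any(c("firstorder", "glcm") %in% families)) normalize_quantize(m, region)
      blocks <- list()
      if ("firstorder" %in% families) blocks$firstorder <- firstorder_features(q)
      if ("glcm" %in% families) blocks$glcm <- as.numeric_keep(glcm_features(q))
      if ("laws" %in% families) blocks$laws <- laws_features(m, region)
      if ("gabor" %in% families) blocks$gabor <- gabor_features(m, region)
      for (fam in names(blocks)) {
        b <- blocks[[fam]]
        names(b) <- paste(rg, mp, fam, names(b), sep = "_")
        out <- c(out, b)
      }
    }
  }
  out
}

#' @noRd
as.numeric_keep <- function(x) {
  a <- as.numeric(x); names(a) <- names(x); a
}

#' Build a feature table for a cohort
#'
#' Runs segmentation, parametric maps and feature extraction per patient
#' and stacks the resulting vectors.
#'
#' @param cohort list of `dce_study`.
#' @param families feature families to extract.
#' @param radius_mm peritumoral dilation radius (mm).
#' @param rois_list optional precomputed list of ROI sets (one per study).
#' @return a `feature_table`: numeric matrix patients x features with
#'   rownames = patient ids and attribute `standardized = FALSE`.
#' @export
build_feature_table <- function(cohort, families = FEATURE_FAMILIES,
                                radius_mm = 4, rois_list = NULL) {
  rows <- lapply(seq_along(cohort), function(i) {
    rois <- if (is.null(rois_list)) build_roi_set(cohort[[i]], radius_mm = radius_mm)
            else rois_list[[i]]
    extract_all_features(cohort[[i]], rois, families)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- vapply(cohort, function(s) s$patient_id, "")
  structure(tab, standardized = FALSE, class = c("feature_table", "matrix", "array"))
}

#' Z-standardize a feature table using training rows only
#'
#' Column mean/SD are computed on the training rows and applied to every
#' row; zero-SD columns are set to 0 and flagged.
#'
#' @param table a `feature_table` (patients x features matrix).
#' @param training_rows integer indices of training rows (>= 2).
#' @return standardized `feature_table` with attributes `center`, `scale`,
#'   `zero_sd_features`.
#' @export
standardize_features <- function(table, training_rows) {
  stopifnot(length(training_rows) >= 2)
  tr <- table[training_rows, , drop = FALSE]
  ctr <- colMeans(tr)
  n <- nrow(tr)
  scl <- sqrt(colSums(sweep(tr, 2, ctr)^2) / (n - 1))
  zero <- scl == 0 | !is.finite(scl)
  scl[zero] <- 1
  out <- sweep(sweep(table, 2, ctr), 2, scl, "/")
  out[, zero] <- 0
  structure(out, standardized = TRUE, center = ctr, scale = scl,
            zero_sd_features = colnames(table)[zero],
            class = c("feature_table", "matrix", "array"))
}

#' Write a feature table to CSV (+ JSON sidecar)
#' @param table a `feature_table`.
#' @param path CSV path; sidecar written to `paste0(path, ".json")`.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(unclass(table)), path, row.names = TRUE)
  side <- list(standardized = isTRUE(attr(table, "standardized")),
               center = attr(table, "center"), scale = attr(table, "scale"),
               zero_sd_features = attr(table, "zero_sd_features"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
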