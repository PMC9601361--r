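#' Configuration for the synthetic DCE-MRI cohort generator
#'
#' Builds the parameter set that drives [generate_cohort()]. The generator
#' emulates the data regime the signature pipeline expects: one
#' representative 2D slice per patient, a pre-contrast frame plus eight
#' post-contrast frames, an ellipse-like enhancing lesion whose
#' time--intensity curve follows the empirical wash-in/wash-out form
#' \deqn{SI(t) = SI_0 [1 + A (1 - e^{-\alpha t}) e^{-\beta t}]}
#' with class-dependent kinetics, an independently informative peritumoral
#' rim, weakly enhancing breast parenchyma, multiplicative spatial texture
#' and additive Gaussian acquisition noise.
#'
#' Estrogen-receptor (ER) status drives the kinetic and rim contrasts;
#' progesterone-receptor (PR) status is sampled jointly with ER at a
#' configurable odds ratio, so both endpoints are learnable from one cohort
#' (PR more weakly, through the association).
#'
#' @param n_patients number of patients to simulate.
#' @param image_size side length of the square frames, pixels.
#' @param pixel_spacing_mm in-plane pixel spacing (default 340 mm field of
#'   view over a 1024 matrix).
#' @param positive_fraction marginal probability of ER positivity.
#' @param pr_positive_fraction marginal probability of PR positivity.
#' @param er_pr_odds_ratio odds ratio of the joint ER/PR label distribution.
#' @param kinetic_params_by_class list with elements `positive` and
#'   `negative`, each a list with wash-in amplitude `A`, wash-in rate
#'   `alpha` (1/frame), wash-out rate `beta` (1/frame), heterogeneity skew
#'   `h` (scales a skewed within-lesion enhancement field), and
#'   between-patient SDs `A_sd`, `alpha_sd`, `beta_sd`, `h_sd`.
#' @param peritumoral_effect relative increase of the rim's enhancing-patch
#'   fraction in ER-positive cases (0 = uninformative rim).
#' @param rim_enhancing_fraction baseline fraction of rim pixels that
#'   enhance (patchy rim).
#' @param rim_width_mm width of the enhancing rim, mm.
#' @param texture_params list with `corr_length` (px) and `amplitude` of the
#'   multiplicative spatial random field.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param baseline_intensity pre-contrast lesion intensity, arbitrary units.
#' @param seed integer master seed; identical config + seed reproduces the
#'   cohort exactly.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 100,
                             image_size = 128,
                             pixel_spacing_mm = 340 / 1024,
                             positive_fraction = 0.66,
                             pr_positive_fraction = 0.63,
                             er_pr_odds_ratio = 6,
                             kinetic_params_by_class = list(
                               positive = list(A = 2.6, alpha = 1.4, beta = 0.08,
                                               A_sd = 0.4, alpha_sd = 0.25, beta_sd = 0.02,
                                               h = 0.60, h_sd = 0.12),
                               negative = list(A = 2.0, alpha = 0.9, beta = 0.04,
                                               A_sd = 0.4, alpha_sd = 0.25, beta_sd = 0.02,
                                               h = 0.10, h_sd = 0.05)
                             ),
                             peritumoral_effect = 0.35,
                             rim_enhancing_fraction = 0.45,
                             rim_width_mm = 4,
                             texture_params = list(corr_length = 4, amplitude = 0.15),
                             noise_sd = 5,
                             baseline_intensity = 100,
                             seed = 1L) {
  stopifnot(n_patients >= 1, image_size >= 32, pixel_spacing_mm > 0,
            positive_fraction > 0, positive_fraction < 1,
            pr_positive_fraction > 0, pr_positive_fraction < 1,
            er_pr_odds_ratio > 0, noise_sd >= 0, baseline_intensity > 0,
            texture_params$corr_length >= 0, texture_params$amplitude >= 0,
            rim_width_mm > 0)
  for (cls in c("positive", "negative")) {
    kp <- kinetic_params_by_class[[cls]]
    stopifnot(!is.null(kp), kp$alpha >= 0, kp$beta >= 0, kp$h >= 0,
              kp$A_sd >= 0, kp$alpha_sd >= 0, kp$beta_sd >= 0, kp$h_sd >= 0)
  }
  structure(list(n_patients = as.integer(n_patients),
                 image_size = as.integer(image_size),
                 pixel_spacing_mm = pixel_spacing_mm,
                 positive_fraction = positive_fraction,
                 pr_positive_fraction = pr_positive_fraction,
                 er_pr_odds_ratio = er_pr_odds_ratio,
                 kinetic_params_by_class = kinetic_params_by_class,
                 peritumoral_effect = peritumoral_effect,
                 rim_enhancing_fraction = rim_enhancing_fraction,
                 rim_width_mm = rim_width_mm,
                 texture_params = texture_params,
                 noise_sd = noise_sd,
                 baseline_intensity = baseline_intensity,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic per-patient substream seed (kept < 2^31).
#' @noRd
patient_seed <- function(master_seed, patient_index) {
  (as.double(master_seed) * 48271 + as.double(patient_index) * 1009 + 7) %% 2147483647
}

# Joint (ER, PR) cell probabilities with given marginals and odds ratio.
#' @noRd
joint_label_probs <- function(p_er, p_pr, or) {
  if (abs(or - 1) < 1e-12) {
    p11 <- p_er * p_pr
  } else {
    a <- or - 1
    b <- -((or - 1) * (p_er + p_pr) + 1)
    cc <- or * p_er * p_pr
    disc <- sqrt(b^2 - 4 * a * cc)
    roots <- c((-b - disc) / (2 * a), (-b + disc) / (2 * a))
    ok <- roots >= max(0, p_er + p_pr - 1) & roots <= min(p_er, p_pr)
    p11 <- roots[ok][1]
  }
  c(p11 = p11, p10 = p_er - p11, p01 = p_pr - p11,
    p00 = 1 - p_er - p_pr + p11)
}

# Smooth multiplicative texture field: white noise blurred by a Gaussian of
# SD = corr_length, re-standardised, scaled by amplitude.
#' @noRd
texture_field <- function(n, corr_length, amplitude) {
  z <- matrix(stats::rnorm(n * n), n, n)
  if (corr_length > 0) {
    h <- ceiling(3 * corr_length)
    g <- stats::dnorm(seq(-h, h), sd = corr_length)
    g <- g / sum(g)
    z <- conv_sep(z, g, g)
    z <- (z - mean(z)) / stats::sd(z)
  }
  1 + amplitude * z
}

#' Generate one synthetic DCE-MRI study
#'
#' Simulates a single patient: a 9-frame time series (frame 1 = pre-contrast)
#' holding an elliptical lesion, an enhancing peritumoral rim and weakly
#' enhancing parenchyma. Ground truth (lesion mask, breast mask, seed box,
#' kinetic parameters) is attached for testing.
#'
#' @param config a [synthetic_config()].
#' @param patient_index 0-based patient index, `< n_patients`.
#' @param er_label,pr_label optional fixed binary labels; when `NULL` they
#'   are drawn from the config's joint label distribution.
#' @return a `dce_study`: list with `patient_id`, `frames` (array
#'   `image_size` x `image_size` x 9), `pixel_spacing_mm`, `er_label`,
#'   `pr_label`, `acquisition_index`, and attributes `lesion_mask`,
#'   `breast_mask`, `seed_box`, `kinetics`.
#' @export
generate_study <- function(config, patient_index, er_label = NULL, pr_label = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            patient_index >= 0, patient_index < config$n_patients)
  n <- config$image_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(patient_seed(config$seed, patient_index))

  if (is.null(er_label) || is.null(pr_label)) {
    pj <- joint_label_probs(config$positive_fraction, config$pr_positive_fraction,
                            config$er_pr_odds_ratio)
    cell <- sample.int(4, 1, prob = pj)
    lab <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))[cell, ]
    if (is.null(er_label)) er_label <- lab[1]
    if (is.null(pr_label)) pr_label <- lab[2]
  }

  # geometry: ellipse lesion near centre, large elliptical breast region
  a_px <- stats::runif(1, 8, 16)
  b_px <- stats::runif(1, 8, 16)
  theta <- stats::runif(1, 0, pi)
  cx <- n / 2 + stats::runif(1, -n / 8, n / 8)
  cy <- n / 2 + stats::runif(1, -n / 8, n / 8)
  if (max(a_px, b_px) * 2 + 4 > n) stop("lesion larger than image; reduce axes or enlarge image")
  xi <- matrix(seq_len(n), n, n)
  yi <- matrix(seq_len(n), n, n, byrow = TRUE)
  xr <- (xi - cx) * cos(theta) + (yi - cy) * sin(theta)
  yr <- -(xi - cx) * sin(theta) + (yi - cy) * cos(theta)
  lesion <- (xr / a_px)^2 + (yr / b_px)^2 <= 1
  breast <- ((xi - n * 0.45) / (0.48 * n))^2 + ((yi - n / 2) / (0.52 * n))^2 <= 1

  rim_px <- config$rim_width_mm / config$pixel_spacing_mm
  d_out <- as.matrix(EBImage::distmap(EBImage::Image(1 - lesion, dim(lesion))))
  rim <- d_out > 0 & d_out <= rim_px & breast

  kp <- config$kinetic_params_by_class[[if (er_label == 1) "positive" else "negative"]]
  A <- max(0, stats::rnorm(1, kp$A, kp$A_sd))
  alpha <- max(0, stats::rnorm(1, kp$alpha, kp$alpha_sd))
  beta <- max(0, stats::rnorm(1, kp$beta, kp$beta_sd))
  h <- min(0.9, max(0, stats::rnorm(1, kp$h, kp$h_sd)))

  # Rim kinetics are class-neutral (drawn around the between-class mean,
  # independently of the lesion draw). The only class information in the
  # rim is the fraction of enhancing patches, modulated by
  # peritumoral_effect, so peritumoral_effect = 0 makes the rim carry no
  # label signal. The per-ROI mu +/- 3 sigma quantization downstream
  # removes purely multiplicative contrasts, so both the intratumoral
  # heterogeneity signal and the rim signal are planted in distribution
  # shape (skewed enhancement field; enhancing-patch mixing fraction).
  kpos <- config$kinetic_params_by_class$positive
  kneg <- config$kinetic_params_by_class$negative
  A_rim0 <- max(0, stats::rnorm(1, (kpos$A + kneg$A) / 2, kpos$A_sd))
  alpha_rim <- max(0, stats::rnorm(1, (kpos$alpha + kneg$alpha) / 2, kpos$alpha_sd))
  beta_rim <- max(0, stats::rnorm(1, (kpos$beta + kneg$beta) / 2, kpos$beta_sd))
  A_rim <- 0.35 * A_rim0
  rim_frac <- min(0.95, max(0.05, config$rim_enhancing_fraction *
                              (1 + config$peritumoral_effect * (er_label == 1))))
  A_bg <- 0.25

  # lesion heterogeneity: smooth exponential-marginal field scaling the
  # per-pixel wash-out rate by the class-dependent h. Early frames (which
  # drive segmentation) are barely affected; late frames acquire a skewed
  # within-lesion distribution, so the signal survives quantization without
  # biasing the lesion boundary.
  g_les <- texture_field(n, corr_length = 2, amplitude = 1) - 1
  e_les <- pmin(stats::qexp(stats::pnorm(g_les / stats::sd(g_les))), 2.5)
  beta_px <- pmax(beta * (1 + h * (e_les - 1)), 0)
  # rim patchiness: smooth field thresholded at the enhancing fraction
  g_rim <- texture_field(n, corr_length = 3, amplitude = 1) - 1
  rim_on <- g_rim > stats::quantile(g_rim[rim], 1 - rim_frac)

  tex <- texture_field(n, config$texture_params$corr_length,
                       config$texture_params$amplitude)
  si0 <- config$baseline_intensity * ifelse(breast, 1, 0.15) * tex
  amp <- matrix(A_bg, n, n)
  amp[!breast] <- 0
  amp[rim & rim_on] <- A_rim
  amp[lesion] <- A
  al_m <- matrix(alpha_rim, n, n); al_m[lesion] <- alpha
  be_m <- matrix(beta_rim, n, n); be_m[lesion] <- beta_px[lesion]
  frames <- array(0, dim = c(n, n, 9))
  for (t in 0:8) {
    enh <- (1 - exp(-al_m * t)) * exp(-be_m * t)
    f <- si0 * (1 + amp * enh)
    if (config$noise_sd > 0) f <- f + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
    frames[, , t + 1] <- pmax(f, 0)
  }

  pad <- 6L
  rng_r <- range(which(rowSums(lesion) > 0))
  rng_c <- range(which(colSums(lesion) > 0))
  seed_box <- c(rmin = max(1L, rng_r[1] - pad), rmax = min(n, rng_r[2] + pad),
                cmin = max(1L, rng_c[1] - pad), cmax = min(n, rng_c[2] + pad))

  structure(list(patient_id = sprintf("P%04d", patient_index),
                 frames = frames,
                 pixel_spacing_mm = config$pixel_spacing_mm,
                 er_label = as.integer(er_label),
                 pr_label = as.integer(pr_label),
                 acquisition_index = as.integer(patient_index)),
            lesion_mask = lesion, breast_mask = breast, seed_box = seed_box,
            kinetics = list(A = A, alpha = alpha, beta = beta, A_rim = A_rim,
                            alpha_rim = alpha_rim, beta_rim = beta_rim),
            class = "dce_study")
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
#' @noRd
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic DCE-MRI cohort
#'
#' Labels are sampled jointly (ER and PR positively associated at the
#' configured odds ratio), then each study is generated from its own
#' deterministic substream, so the cohort is a pure function of
#' (config, seed) and individual studies can be regenerated independently.
#'
#' @param config a [synthetic_config()] with `n_patients >= 2`.
#' @return list of `dce_study`, ordered by `acquisition_index`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"), config$n_patients >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  pj <- joint_label_probs(config$positive_fraction, config$pr_positive_fraction,
                          config$er_pr_odds_ratio)
  cells <- sample.int(4, config$n_patients, replace = TRUE, prob = pj)
  lab <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))[cells, , drop = FALSE]
  lapply(seq_len(config$n_patients), function(i) {
    generate_study(config, i - 1L, er_label = lab[i, 1], pr_label = lab[i, 2])
  })
}

#' Simulate a second reader's segmentation
#'
#' Perturbs a binary mask by adding a smooth, seeded random field to its
#' signed Euclidean distance transform and re-thresholding, i.e. random
#' boundary erosion/dilation bounded by `jitter_px`; the result is reduced
#' to its largest connected component with holes filled.
#'
#' @param mask logical matrix (non-empty).
#' @param jitter_px maximum boundary displacement in pixels; 0 returns the
#'   input unchanged.
#' @param seed integer seed.
#' @return perturbed logical mask.
#' @export
simulate_second_reader <- function(mask, jitter_px = 2, seed = 1L) {
  stopifnot(is.matrix(mask), any(mask), jitter_px >= 0)
  mask <- mask > 0
  if (jitter_px == 0) return(mask)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d_in <- as.matrix(EBImage::distmap(EBImage::Image(mask + 0, dim(mask))))
  d_out <- as.matrix(EBImage::distmap(EBImage::Image(1 - mask, dim(mask))))
  signed <- d_in - d_out            # > 0 inside, < 0 outside
  f <- texture_field(nrow(mask), corr_length = 3, amplitude = 1) - 1
  f <- f / max(abs(f)) * jitter_px
  out <- signed > f
  if (!any(out)) stop("perturbation emptied the mask")
  lab <- EBImage::bwlabel(EBImage::Image(out + 0, dim(out)))
  tab <- tabulate(as.integer(lab))
  out <- as.matrix(lab) == which.max(tab)
  out <- matrix(as.matrix(EBImage::fillHull(EBImage::Image(out + 0, dim(out)))) > 0,
                nrow(mask), ncol(mask))
  if (!any(out)) stop("perturbation emptied the mask")
  out
}

#' Write a cohort to disk
#'
#' Writes each study as a 3D NIfTI (third axis = time) and a cohort
#' manifest CSV with patient id, acquisition index, labels, seed box and
#' file path; the config is stored alongside as YAML.
#'
#' @param cohort list of `dce_study`.
#' @param dir output directory (created if needed).
#' @param config optional [synthetic_config()] to record.
#' @return invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    path <- file.path(dir, paste0(s$patient_id, ".nii.gz"))
    RNifti::writeNifti(s$frames, path)
    sb <- attr(s, "seed_box")
    data.frame(patient_id = s$patient_id,
               acquisition_index = s$acquisition_index,
               er_label = s$er_label, pr_label = s$pr_label,
               seed_rmin = sb["rmin"], seed_rmax = sb["rmax"],
               seed_cmin = sb["cmin"], seed_cmax = sb["cmax"],
               path = path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(config)) {
    cfg <- config
    cfg$kinetic_params_by_class <- lapply(cfg$kinetic_params_by_class, as.list)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(manifest)
}
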