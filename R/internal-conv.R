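# Internal 2D filtering helpers. All filters are applied as correlations
# (no kernel flip) with symmetric boundary reflection, so that filter
# banks behave identically at the image border and in the interior.

#' @noRd
pad_symmetric <- function(img, pr, pc) {
  nr <- nrow(img); nc <- ncol(img)
  stopifnot(pr < nr, pc < nc)
  ri <- c(rev(seq_len(pr)), seq_len(nr), nr:(nr - pr + 1L))
  ci <- c(rev(seq_len(pc)), seq_len(nc), nc:(nc - pc + 1L))
  if (pr == 0L) ri <- seq_len(nr)
  if (pc == 0L) ci <- seq_len(nc)
  img[ri, ci, drop = FALSE]
}

# Separable correlation: kernel = u %o% v, u along rows (dim 1), v along
# columns (dim 2). u, v must have odd length.
#' @noRd
conv_sep <- function(img, u, v) {
  hu <- (length(u) - 1L) %/% 2L
  hv <- (length(v) - 1L) %/% 2L
  p <- pad_symmetric(img, hu, hv)
  nr <- nrow(img); nc <- ncol(img)
  # rows (dim 1) with u
  acc <- 0
  for (k in seq_along(u)) {
    if (u[k] != 0) acc <- acc + u[k] * p[(k - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- 0
  for (k in seq_along(v)) {
    if (v[k] != 0) out <- out + v[k] * acc[, (k - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

# Correlation of img with each kernel in `kernels` (odd-sized matrices,
# possibly complex), via a shared padded FFT. Returns a list of rasters.
# `cache_key`, if non-NULL, memoises the kernel FFTs for repeated calls
# with identical image dimensions (the kernels are assumed fixed per key).
.conv_cache <- new.env(parent = emptyenv())

#' @noRd
conv_bank_fft <- function(img, kernels, cache_key = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  hmax_r <- max(vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, 1L))
  hmax_c <- max(vapply(kernels, function(k) (ncol(k) - 1L) %/% 2L, 1L))
  p <- pad_symmetric(img, hmax_r, hmax_c)
  pr <- nrow(p); pc <- ncol(p)
  key <- if (is.null(cache_key)) NULL else paste(cache_key, pr, pc, sep = "_")
  F_img <- stats::fft(p)
  kf <- if (!is.null(key) && !is.null(.conv_cache[[key]])) {
    .conv_cache[[key]]
  } else {
    out <- lapply(kernels, function(k) {
      kr <- nrow(k); kc <- ncol(k)
      hk_r <- (kr - 1L) %/% 2L; hk_c <- (kc - 1L) %/% 2L
      kp <- matrix(0 + 0i, pr, pc)
      kp[seq_len(kr), seq_len(kc)] <- k
      # centre the kernel at (1,1) so correlation needs no phase shift;
      # conj gives correlation rather than convolution
      kp <- kp[c((hk_r + 1L):pr, seq_len(hk_r)), c((hk_c + 1L):pc, seq_len(hk_c)), drop = FALSE]
      Conj(stats::fft(kp))
    })
    if (!is.null(key)) .conv_cache[[key]] <- out
    out
  }
  lapply(kf, function(Fk) {
    full <- stats::fft(F_img * Fk, inverse = TRUE) / (pr * pc)
    full[hmax_r + seq_len(nr), hmax_c + seq_len(nc), drop = FALSE]
  })
}

# Moment summaries used by the texture families: mean, sd (n-1), skewness
# m3/m2^1.5 and kurtosis m4/m2^2 (population central moments, kurtosis of a
# Gaussian -> 3). Degenerate (m2 = 0) skew/kurt are 0.
#' @noRd
moment_stats <- function(x) {
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = mu, sd = if (n > 1) stats::sd(x) else 0, skewness = skew, kurtosis = kurt)
}

# Shannon entropy (bits) of a discrete probability vector.
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
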