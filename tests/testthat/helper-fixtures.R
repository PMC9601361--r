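# Shared fixtures: tiny deterministic studies and brute-force oracles.

# A dce_study whose every lesion pixel follows the given 9-point curve
# exactly (no noise, no texture); background stays at `bg`.
curve_study <- function(si, n = 16, bg = 10) {
  stopifnot(length(si) == 9)
  frames <- array(bg, dim = c(n, n, 9))
  lesion <- matrix(FALSE, n, n)
  lesion[5:12, 5:12] <- TRUE
  for (t in 1:9) {
    f <- frames[, , t]
    f[lesion] <- si[t]
    frames[, , t] <- f
  }
  structure(list(patient_id = "TEST", frames = frames, pixel_spacing_mm = 0.332,
                 er_label = 1L, pr_label = 1L, acquisition_index = 0L),
            lesion_mask = lesion,
            breast_mask = matrix(TRUE, n, n),
            seed_box = c(rmin = 3, rmax = 14, cmin = 3, cmax = 14),
            class = "dce_study")
}

# A study with arbitrary per-pixel frames (matrix list), for map oracles.
frames_study <- function(frames) {
  structure(list(patient_id = "TEST", frames = frames, pixel_spacing_mm = 0.332,
                 er_label = 1L, pr_label = 1L, acquisition_index = 0L),
            class = "dce_study")
}

small_config <- function(...) {
  synthetic_config(n_patients = 6, seed = 42, ...)
}

# Brute-force between-class variance scan over histogram cut points
# (independent of the package's cumulative-sum implementation).
otsu_bruteforce <- function(values, n_bins = 256) {
  r <- range(values)
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- tabulate(pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
                     n_bins), n_bins)
  best <- -Inf; best_edge <- NA
  for (cut in 1:(n_bins - 1)) {
    n0 <- sum(h[1:cut]); n1 <- sum(h) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:cut] * mids[1:cut]) / n0
    mu1 <- sum(h[(cut + 1):n_bins] * mids[(cut + 1):n_bins]) / n1
    w0 <- n0 / sum(h); w1 <- n1 / sum(h)
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; best_edge <- edges[cut + 1] }
  }
  best_edge
}

# Exhaustive symmetric GLCM by explicit pair enumeration.
glcm_bruteforce <- function(levels_matrix, offset) {
  nr <- nrow(levels_matrix); nc <- ncol(levels_matrix)
  counts <- list()
  add <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    counts[[key]] <<- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  for (r in 1:nr) for (cl in 1:nc) {
    r2 <- r + offset[1]; c2 <- cl + offset[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        !is.na(levels_matrix[r, cl]) && !is.na(levels_matrix[r2, c2])) {
      add(levels_matrix[r, cl], levels_matrix[r2, c2])
    }
  }
  counts
}

# Exhaustive pairwise-concordance AUC (ties count 1/2).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Direct (small, readable) correlation of image with kernel, symmetric
# reflection padding; oracle for the separable/FFT paths.
conv_bruteforce <- function(img, kernel) {
  hr <- (nrow(kernel) - 1) %/% 2; hc <- (ncol(kernel) - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (cl in 1:nc) {
    acc <- 0
    for (dr in -hr:hr) for (dc in -hc:hc) {
      acc <- acc + kernel[dr + hr + 1, dc + hc + 1] *
        img[reflect(r + dr, nr), reflect(cl + dc, nc)]
    }
    out[r, cl] <- acc
  }
  out
}
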