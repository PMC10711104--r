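# Shared helpers: independent brute-force oracles and tiny fixtures.
# Oracles deliberately use naive enumeration, never the package's own
# computational path.

# central finite differences of a scalar function over an array
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# signed distance by all-pairs nearest-opposite-pixel search
brute_signed_distance <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    opp <- which(mask != mask[i, j], arr.ind = TRUE)
    d <- sqrt(min((opp[, 1] - i)^2 + (opp[, 2] - j)^2))
    out[i, j] <- if (mask[i, j] != 0) -d else d
  }
  out
}

# median filter by direct window collection with reflect padding
brute_median_filter <- function(x, offsets) {
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- apply(offsets, 1, function(o)
      x[reflect(i + o[1], h), reflect(j + o[2], w)])
    out[i, j] <- stats::median(vals)
  }
  out
}

# Otsu by direct split-and-variance sweep on the raw pixel vector
brute_otsu <- function(gray) {
  x <- as.integer(round(as.vector(gray)))
  n <- length(x)
  best <- -Inf; bestT <- NA_integer_
  for (T in 0:255) {
    d1 <- x[x <= T]; d2 <- x[x > T]
    if (!length(d1) || !length(d2)) next
    v <- (length(d1) / n) * (length(d2) / n) * (mean(d1) - mean(d2))^2
    if (v > best + 1e-12) { best <- v; bestT <- T }
  }
  bestT
}

# per-pixel recount of all metric ratios from raw masks
brute_metrics <- function(pred, truth, C) {
  pa <- iou <- prec <- numeric(C)
  for (c in 0:(C - 1)) {
    tp <- sum(pred == c & truth == c)
    fp <- sum(pred == c & truth != c)
    fn <- sum(pred != c & truth == c)
    pa[c + 1] <- tp / (tp + fn)
    iou[c + 1] <- tp / (tp + fp + fn)
    prec[c + 1] <- tp / (tp + fp)
  }
  list(pa = pa, iou = iou, precision = prec)
}

# small scene set shared across training-related tests
tiny_scenes <- function(n, size = 32, seed0 = 400, noise = 0) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_params(size = size, seed = seed0 + i,
                                noise_density = noise)))
}

tiny_config <- function(size = 32, ...) {
  network_config(num_classes = 3, input_size = size, width_scale = 16,
                 encoder_blocks = 3, cca_reduction = 4, aspp_width = 16,
                 ...)
}
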