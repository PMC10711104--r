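# Post-segmentation trait extraction: HSV colour-range selection, Otsu
# binarisation, crown-area estimation, class proportions and the
# predicted-vs-actual regression.

#' RGB to HSV conversion on the OpenCV integer scale
#'
#' Hue in `[0, 180]` (degrees / 2), saturation and value in `[0, 255]`.
#'
#' @param image `H x W x 3` array with values in 0..255 (or 0..1).
#' @return `H x W x 3` array of H, S, V planes.
#' @export
rgb_to_hsv_cv <- function(image) {
  x <- as_fmap(image)
  if (max(x) <= 1) x <- x * 255
  d <- dim(x)
  m <- t(matrix(x, d[1] * d[2], 3L))          # 3 x n, 0..255
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- array(0, d)
  # quantised to the integer scale so the palette's contiguous integer
  # intervals (e.g. orange 11-25, yellow 26-34) partition hue exactly
  out[, , 1] <- round(hsv[1, ] * 180)         # degrees / 2
  out[, , 2] <- round(hsv[2, ] * 255)
  out[, , 3] <- round(hsv[3, ] * 255)
  out
}

# vectorised HSV (OpenCV scale) -> RGB 0..255
hsv_cv_to_rgb <- function(h, s, v) {
  hh <- (h * 2) / 60                           # sector in [0, 6)
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  sv <- s / 255
  p <- v * (1 - sv)
  q <- v * (1 - sv * f)
  t <- v * (1 - sv * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' The HSV colour-range palette
#'
#' Reads the shipped colour table: per named colour, hue interval(s) on the
#' 0-180 scale and saturation/value intervals on the 0-255 scale.  Red owns
#' two hue intervals (0-10 and 156-180); black, gray and white are
#' distinguished by S/V bands.  The table ships as an editable JSON file.
#'
#' @param path Optional path to an alternative palette JSON.
#' @return Named list of `hsv_range` lists.
#' @export
hsv_palette <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hsv_palette.json", package = "acunet")
  pal <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(pal, function(p) {
    structure(list(
      name = p$name,
      hue = lapply(p$hue, function(h) as.numeric(unlist(h))),
      s = as.numeric(unlist(p$s)), v = as.numeric(unlist(p$v))),
      class = "hsv_range")
  })
  stats::setNames(out, vapply(pal, function(p) p$name, character(1)))
}

#' Select pixels matching an HSV colour range
#'
#' A pixel is selected when its hue lies in any of the range's hue
#' intervals and its saturation and value lie in their intervals.
#'
#' @param image `H x W x 3` RGB array.
#' @param range An `hsv_range` (an entry of [hsv_palette()]) or a colour
#'   name looked up in the default palette.
#' @return Logical matrix mask.
#' @export
hsv_mask <- function(image, range) {
  if (is.character(range)) {
    pal <- hsv_palette()
    if (!range %in% names(pal))
      stop("unknown colour name: ", range, call. = FALSE)
    range <- pal[[range]]
  }
  hsv <- rgb_to_hsv_cv(image)
  d <- dim(hsv)
  h <- matrix(hsv[, , 1], d[1], d[2])
  s <- matrix(hsv[, , 2], d[1], d[2])
  v <- matrix(hsv[, , 3], d[1], d[2])
  hue_ok <- Reduce(`|`, lapply(range$hue, function(iv)
    h >= iv[1] & h <= iv[2]))
  hue_ok & s >= range$s[1] & s <= range$s[2] &
    v >= range$v[1] & v <= range$v[2]
}

#' Otsu threshold of an 8-bit grayscale image
#'
#' Exhaustive sweep over thresholds `T` in 0..255, maximising the
#' between-class variance of the split into `{x <= T}` and `{x > T}`;
#' ties are broken by the smallest `T`.
#'
#' @param gray Numeric matrix/array with values in 0..255.
#' @return Integer threshold.
#' @export
otsu_threshold <- function(gray) {
  x <- as.integer(round(as.vector(gray)))
  if (any(x < 0L | x > 255L)) stop("values outside 0..255", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("degenerate histogram: need >= 2 distinct gray levels",
         call. = FALSE)
  counts <- tabulate(x + 1L, 256L)
  n <- length(x)
  levels <- 0:255
  w1 <- cumsum(counts)                       # pixels with value <= T
  sum1 <- cumsum(counts * levels)
  total <- sum1[256]
  between <- numeric(256)
  for (ti in 1:256) {
    n1 <- w1[ti]; n2 <- n - n1
    if (n1 == 0 || n2 == 0) { between[ti] <- -Inf; next }
    mu1 <- sum1[ti] / n1
    mu2 <- (total - sum1[ti]) / n2
    between[ti] <- (n1 / n) * (n2 / n) * (mu1 - mu2)^2
  }
  as.integer(which.max(between) - 1L)        # smallest T on ties
}

#' Crown area and extent from a class mask
#'
#' Plant height is the vertical extent of stem-or-leaf pixels, crown width
#' the horizontal extent of leaf pixels, and the crown area is approximated
#' as half the product of plant height and crown width (both converted to
#' cm by `scale`).
#'
#' @param mask Integer matrix with classes 0 (background), 1 (stem),
#'   2 (leaf).
#' @param scale Pixel size in cm per pixel.
#' @param id Plant identifier carried into the record.
#' @return List of class `phenotype_record`.
#' @export
crown_area <- function(mask, scale, id = NA_character_) {
  stopifnot(is.matrix(mask), scale > 0)
  fg <- mask == 1L | mask == 2L
  if (!any(fg)) stop("no foreground pixels", call. = FALSE)
  rows <- range(which(rowSums(fg) > 0))
  height_px <- rows[2] - rows[1] + 1L
  leaf <- mask == 2L
  crown_width_px <- if (any(leaf)) {
    cols <- range(which(colSums(leaf) > 0))
    cols[2] - cols[1] + 1L
  } else 0L
  area <- 0.5 * (height_px * scale) * (crown_width_px * scale)
  pr <- class_proportions(mask)
  structure(list(id = id, height_px = height_px,
                 crown_width_px = crown_width_px, scale = scale,
                 crown_area = area,
                 stem_fraction = pr$fractions[["stem"]],
                 leaf_fraction = pr$fractions[["leaf"]]),
            class = "phenotype_record")
}

#' @export
print.phenotype_record <- function(x, ...) {
  cat(sprintf(
    "phenotype record%s: height %d px, crown width %d px, scale %.4g cm/px\n",
    if (is.na(x$id)) "" else paste0(" [", x$id, "]"), x$height_px,
    x$crown_width_px, x$scale))
  cat(sprintf("  crown area %.4g cm^2; stem %.3f, leaf %.3f of pixels\n",
              x$crown_area, x$stem_fraction, x$leaf_fraction))
  invisible(x)
}

#' Class pixel proportions of a mask
#'
#' @param mask Integer matrix with classes 0/1/2.
#' @return List with `fractions` (background, stem, leaf; sums to 1) and
#'   `ten_unit` (the same rescaled to a 10-unit whole, the stacked-bar
#'   convention).
#' @export
class_proportions <- function(mask) {
  stopifnot(is.matrix(mask))
  if (any(!mask %in% 0:2)) stop("mask classes must be 0/1/2", call. = FALSE)
  n <- length(mask)
  fr <- c(background = sum(mask == 0L), stem = sum(mask == 1L),
          leaf = sum(mask == 2L)) / n
  list(fractions = fr, ten_unit = 10 * fr)
}

#' Ordinary least squares of actual vs predicted trait values
#'
#' Fits `actual = intercept + slope * pred` and reports the coefficient of
#' determination.
#'
#' @param pred,actual Numeric vectors of equal length (>= 3).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
fit_predicted_vs_actual <- function(pred, actual) {
  if (length(pred) != length(actual) || length(pred) < 3L)
    stop("need equal-length vectors with >= 3 points", call. = FALSE)
  if (stats::var(pred) == 0)
    stop("zero variance in predictions", call. = FALSE)
  fit <- stats::lm(actual ~ pred)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Crown phenotype from a prediction overlay
#'
#' Implements the trait-extraction chain on a predicted mask rendered as a
#' colour overlay: HSV range selection of the target colour, grayscale
#' conversion, Otsu binarisation, then extent/area measurement on the
#' binary leaf image combined with the stem-or-leaf height.
#'
#' @param mask Predicted integer class mask (0/1/2).
#' @param scale cm per pixel.
#' @param id Plant identifier.
#' @return A `phenotype_record`.
#' @export
phenotype_from_mask <- function(mask, scale, id = NA_character_) {
  overlay <- render_mask_overlay(mask)
  leaf_sel <- hsv_mask(overlay, "red")       # leaves painted red
  gray <- matrix(255 * leaf_sel, nrow(mask), ncol(mask))
  leaf_bin <- if (length(unique(as.vector(gray))) >= 2L) {
    gray > otsu_threshold(gray)
  } else leaf_sel
  recovered <- mask
  recovered[recovered == 2L] <- 0L
  recovered[leaf_bin] <- 2L
  crown_area(recovered, scale, id = id)
}

# paint a class mask as an RGB overlay: background black, stem green,
# leaf red (the convention used when extracting the leaf part)
render_mask_overlay <- function(mask) {
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], 3L))
  out[, , 1][mask == 2L] <- 255
  out[, , 2][mask == 1L] <- 200
  out
}
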