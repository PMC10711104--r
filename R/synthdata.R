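# Seeded generator of synthetic seedling scenes (image + ground-truth
# mask): dark background, thin stems rooted at the bottom border, filled
# rotated ellipse leaves in the green hue band, optional impulse noise.
# Deliberately minimal realism - geometry plus colour bands - but enough
# to exercise segmentation, losses, metrics and phenotyping end to end.

#' Parameters of a synthetic seedling scene
#'
#' All geometric ranges are fractions of the image size, so scenes look
#' alike at any resolution.  Colour ranges are HSV on the 0-180 / 0-255
#' scale; the defaults keep leaves strictly inside the palette's "green"
#' range, stems inside "orange" (a brown bark tone) and the background
#' inside "black" (the dark-cloth imaging background).
#'
#' @param size Image side in pixels (square scenes).
#' @param stem_count Number of stems, each rooted at the bottom border.
#' @param stem_width Stem thickness range, fraction of `size`.
#' @param leaf_count Range of leaf counts.
#' @param leaf_axes Semi-axis ranges (major, minor), fraction of `size`.
#' @param leaf_hsv,stem_hsv,background_hsv 2x3 matrices (rows = min/max) of
#'   HSV bounds for per-pixel colour jitter.
#' @param noise_density Salt-and-pepper impulse noise density in `[0, 1]`,
#'   applied to the image only.
#' @param seed Integer seed; scenes are bit-identical given the seed.
#' @return List of class `scene_params`.
#' @export
scene_params <- function(size = 512L, stem_count = 2L,
                         stem_width = c(0.012, 0.025),
                         leaf_count = c(8L, 14L),
                         leaf_axes = list(major = c(0.06, 0.12),
                                          minor = c(0.035, 0.07)),
                         leaf_hsv = rbind(c(40, 80, 80), c(70, 230, 230)),
                         stem_hsv = rbind(c(12, 80, 70), c(22, 200, 180)),
                         background_hsv = rbind(c(0, 0, 2), c(180, 120, 40)),
                         noise_density = 0, seed = 1L) {
  stopifnot(size >= 32, noise_density >= 0, noise_density <= 1,
            all(stem_width > 0), all(unlist(leaf_axes) < 0.5))
  structure(list(size = as.integer(size), stem_count = as.integer(stem_count),
                 stem_width = stem_width, leaf_count = as.integer(leaf_count),
                 leaf_axes = leaf_axes, leaf_hsv = leaf_hsv,
                 stem_hsv = stem_hsv, background_hsv = background_hsv,
                 noise_density = noise_density, seed = as.integer(seed)),
            class = "scene_params")
}

#' Generate one synthetic scene
#'
#' The mask is drawn first (stems as thickened polylines rooted at the
#' bottom border, class 1; leaves as filled rotated ellipses attached to
#' stem points, class 2; background 0), then the image is coloured per
#' class with independent per-pixel HSV jitter inside the configured
#' ranges, and impulse noise is optionally added to the image only.
#'
#' @param params A `scene_params` list.
#' @return List with `image` (`size x size x 3`, 0..255) and `mask`
#'   (integer matrix, values 0/1/2).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(params$seed)
  n <- params$size
  mask <- matrix(0L, n, n)
  stem_pts <- NULL
  for (s in seq_len(params$stem_count)) {
    w_px <- max(1, stats::runif(1, params$stem_width[1],
                                params$stem_width[2]) * n)
    pts <- stem_polyline(n)
    mask <- draw_disks(mask, pts, w_px / 2, 1L)
    keep <- pts[, 1] < 0.75 * n & pts[, 1] > 0.1 * n
    stem_pts <- rbind(stem_pts, pts[keep, , drop = FALSE])
  }
  n_leaves <- sample(params$leaf_count[1]:params$leaf_count[2], 1L)
  for (l in seq_len(n_leaves)) {
    at <- stem_pts[sample(nrow(stem_pts), 1L), ]
    a <- stats::runif(1, params$leaf_axes$major[1],
                      params$leaf_axes$major[2]) * n
    b <- stats::runif(1, params$leaf_axes$minor[1],
                      params$leaf_axes$minor[2]) * n
    theta <- stats::runif(1, 0, pi)
    centre <- at + c(stats::runif(1, -0.6, -0.1) * a * sign(stats::runif(1) - 0.5),
                     stats::runif(1, -1, 1) * a)
    centre[1] <- min(max(centre[1], a + 1), 0.7 * n)
    centre[2] <- min(max(centre[2], a + 1), n - a - 1)
    mask <- draw_ellipse(mask, centre, a, b, theta, 2L)
  }
  image <- colour_scene(mask, params)
  if (params$noise_density > 0) {
    npix <- n * n
    hit <- sample(npix, round(params$noise_density * npix))
    vals <- sample(c(0, 255), length(hit), replace = TRUE)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[hit] <- vals
      image[, , ch] <- plane
    }
  }
  list(image = image, mask = mask)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# polyline of (row, col) points from the bottom border upwards
stem_polyline <- function(n) {
  x <- stats::runif(1, 0.3, 0.7) * n
  top <- stats::runif(1, 0.05, 0.15) * n
  rows <- seq(n, top, by = -1)
  drift <- cumsum(stats::rnorm(length(rows), 0, 0.15))
  cols <- x + drift * n / 256
  cols <- pmin(pmax(cols, 2), n - 1)
  cbind(row = rows, col = cols)
}

draw_disks <- function(mask, pts, radius, value) {
  n <- nrow(mask)
  r <- max(0, radius)
  ri <- ceiling(r)
  offs <- expand.grid(di = -ri:ri, dj = -ri:ri)
  offs <- offs[offs$di^2 + offs$dj^2 <= max(r, 0.5)^2, , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    rows <- pmin(pmax(round(pts[, 1] + offs$di[k]), 1), n)
    cols <- pmin(pmax(round(pts[, 2] + offs$dj[k]), 1), n)
    mask[cbind(rows, cols)] <- value
  }
  mask
}

draw_ellipse <- function(mask, centre, a, b, theta, value) {
  n <- nrow(mask)
  ext <- ceiling(max(a, b))
  rows <- max(1, floor(centre[1] - ext)):min(n, ceiling(centre[1] + ext))
  cols <- max(1, floor(centre[2] - ext)):min(n, ceiling(centre[2] + ext))
  dr <- outer(rows - centre[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - centre[2])
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- mask[rows, cols]
  sub[inside] <- value
  mask[rows, cols] <- sub
  mask
}

colour_scene <- function(mask, params) {
  n <- nrow(mask)
  image <- array(0, c(n, n, 3L))
  paint <- function(image, sel, bounds) {
    k <- sum(sel)
    if (k == 0) return(image)
    h <- stats::runif(k, bounds[1, 1], bounds[2, 1])
    s <- stats::runif(k, bounds[1, 2], bounds[2, 2])
    v <- stats::runif(k, bounds[1, 3], bounds[2, 3])
    rgb <- hsv_cv_to_rgb(h, s, v)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[sel] <- rgb[, ch]
      image[, , ch] <- plane
    }
    image
  }
  image <- paint(image, mask == 0L, params$background_hsv)
  image <- paint(image, mask == 1L, params$stem_hsv)
  image <- paint(image, mask == 2L, params$leaf_hsv)
  round(image)
}

#' Generate a dataset directory of synthetic scenes
#'
#' Writes `images/` and `masks/` (grayscale PNG class codes 0/1/2),
#' `train.txt` / `val.txt` split lists at the configured ratio (validation
#' size `floor((1 - ratio) * n)`), and a `manifest.json` echoing the
#' parameters.  Scene i uses seed `params$seed + i`, the split uses
#' `params$seed`.
#'
#' @param n Number of scenes (>= 2).
#' @param params A `scene_params` list.
#' @param out_dir Output directory (created if missing).
#' @param ratio Training fraction in (0, 1), default 0.9.
#' @return Invisibly, a list with the train/val file name vectors.
#' @export
generate_dataset <- function(n, params = scene_params(), out_dir,
                             ratio = 0.9) {
  stopifnot(n >= 2, ratio > 0, ratio < 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  names_all <- sprintf("scene_%04d", seq_len(n))
  for (i in seq_len(n)) {
    p <- params
    p$seed <- params$seed + i
    sc <- generate_scene(p)
    write_image(sc$image, file.path(out_dir, "images",
                                    paste0(names_all[i], ".png")))
    write_mask(sc$mask, file.path(out_dir, "masks",
                                  paste0(names_all[i], ".png")))
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(params$seed)
  val_idx <- sort(sample(n, val_count(n, ratio)))
  writeLines(names_all[-val_idx], file.path(out_dir, "train.txt"))
  writeLines(names_all[val_idx], file.path(out_dir, "val.txt"))
  jsonlite::write_json(
    list(n = n, ratio = ratio, params = unclass(params)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(train = names_all[-val_idx], val = names_all[val_idx]))
}

# validation-set size under the floor convention (at least one held out);
# the epsilon guards against floating-point droop in (1 - ratio) * n
val_count <- function(n, ratio) {
  max(1L, as.integer(floor((1 - ratio) * n + 1e-9)))
}

#' Load a dataset directory into memory
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @param split `"train"`, `"val"` or `"all"`.
#' @return List of `list(image=, mask=)` samples.
#' @export
load_dataset <- function(dir, split = c("all", "train", "val")) {
  split <- match.arg(split)
  nm <- if (split == "all") {
    sub("\\.png$", "", sort(list.files(file.path(dir, "images"),
                                       pattern = "\\.png$")))
  } else {
    readLines(file.path(dir, paste0(split, ".txt")))
  }
  lapply(nm, function(s) list(
    name = s,
    image = read_image(file.path(dir, "images", paste0(s, ".png"))),
    mask = read_mask(file.path(dir, "masks", paste0(s, ".png")))))
}
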