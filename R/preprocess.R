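# Image cleanup before training/inference: cropping and median filtering.

#' Filter window description
#'
#' @param size Odd window size `p >= 3`; the half width is `m = (p - 1)/2`.
#' @param shape `"square"` (p x p), `"cross"` (horizontal and vertical arms
#'   of length p) or `"line"` (horizontal 1 x p).
#' @return List of class `acu_window` with the window offset matrix.
#' @export
filter_window <- function(size = 3L, shape = c("square", "cross", "line")) {
  shape <- match.arg(shape)
  if (size %% 2L == 0L || size < 3L)
    stop("window size must be odd and >= 3", call. = FALSE)
  m <- (size - 1L) %/% 2L
  offs <- switch(shape,
    square = as.matrix(expand.grid(di = -m:m, dj = -m:m)),
    cross = unique(rbind(cbind(di = -m:m, dj = 0L),
                         cbind(di = 0L, dj = -m:m))),
    line = cbind(di = 0L, dj = -m:m))
  structure(list(size = as.integer(size), shape = shape, m = m,
                 offsets = matrix(as.integer(offs), ncol = 2L)),
            class = "acu_window")
}

#' Crop a rectangular region from an image
#'
#' Coordinates are 0-based and half-open: the crop covers columns
#' `left .. left + width - 1` and rows `top .. top + height - 1`.
#'
#' @param image Matrix or `H x W x C` array.
#' @param box Numeric vector `c(left, top, width, height)` in pixels.
#' @return The cropped sub-raster with the input's dimensionality.
#' @export
crop <- function(image, box) {
  stopifnot(length(box) == 4)
  box <- as.integer(box)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  left <- box[1]; top <- box[2]; width <- box[3]; height <- box[4]
  if (width < 1L || height < 1L || left < 0L || top < 0L ||
      left + width > W || top + height > H)
    stop("crop box out of bounds", call. = FALSE)
  rows <- top + seq_len(height)
  cols <- left + seq_len(width)
  if (length(d) == 2L) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

#' Median filter an image
#'
#' Each pixel is replaced by the median of the values in its window;
#' borders are handled by reflect padding.  Multi-channel images are
#' filtered per channel.
#'
#' @param image Matrix or `H x W x C` array.
#' @param window An `acu_window` (see [filter_window()]) or an odd integer
#'   size, interpreted as a square window.
#' @return Filtered image, same shape as the input.
#' @export
median_filter <- function(image, window = 3L) {
  if (is.numeric(window) && length(window) == 1L)
    window <- filter_window(window)
  stopifnot(inherits(window, "acu_window"))
  if (is.matrix(image))
    return(median_filter_cpp(image, window$offsets))
  stopifnot(length(dim(image)) == 3L)
  out <- image
  for (c in seq_len(dim(image)[3]))
    out[, , c] <- median_filter_cpp(image[, , c], window$offsets)
  out
}
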