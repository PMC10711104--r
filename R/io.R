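# PNG image / mask I/O.  Images are H x W x 3 arrays in 0..255; class
# masks are integer matrices written as 8-bit grayscale PNG holding the
# raw class codes 0/1/2.

#' Read / write RGB images and class masks
#'
#' @param path PNG file path.
#' @return `read_image`: `H x W x 3` numeric array in 0..255.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' @rdname read_image
#' @param image `H x W x 3` array in 0..255.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' @rdname read_image
#' @details `read_mask` returns the integer matrix of class codes stored
#'   in a grayscale mask PNG; `write_mask` writes one.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' @rdname read_image
#' @param mask Integer matrix of class codes (0..255).
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}
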