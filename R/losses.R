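# Dice loss, boundary (signed-distance) loss and their composite.
#
# Conventions fixed here and used by every exported loss:
#  * probabilities `probs` are H x W x C arrays normalised over channels;
#  * labels are either integer masks (values 0..C-1) or one-hot H x W x C;
#  * Dice pools intersections and masses over all pixels AND all classes
#    (no per-class averaging) and adds eps = 1e-6 to the denominator;
#  * the boundary loss reduces by the spatial MEAN per foreground class and
#    then averages over foreground classes, so its scale is resolution
#    independent; background (class 0) is excluded;
#  * foreground classes empty in the ground truth have no zero-crossing in
#    their distance map and are skipped (degenerate case).

DICE_EPS <- 1e-6

#' One-hot encode an integer class mask
#'
#' @param mask Integer matrix with values in `0..C-1`.
#' @param num_classes Number of classes C.
#' @return `H x W x C` binary array.
#' @export
one_hot <- function(mask, num_classes) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0 | mask >= num_classes))
    stop("mask values out of range 0..C-1", call. = FALSE)
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], num_classes))
  for (c in seq_len(num_classes))
    out[, , c] <- (mask == c - 1L) + 0
  out
}

as_one_hot <- function(labels, probs) {
  if (is.matrix(labels)) labels <- one_hot(labels, dim(probs)[3])
  if (!identical(dim(labels), dim(probs)))
    stop("probs and labels shapes disagree", call. = FALSE)
  labels
}

#' Dice loss
#'
#' `1 - 2 * sum(g * s) / (sum(g) + sum(s))` with the sums pooled over all
#' pixels and all classes.  0 for a perfect one-hot match, 1 for complete
#' disagreement; always in `[0, 1]`.
#'
#' @param probs `H x W x C` probability array.
#' @param labels Integer mask or one-hot array.
#' @return Scalar loss.
#' @export
dice_loss <- function(probs, labels) {
  probs <- as_fmap(probs)
  if (length(probs) == 0) stop("empty input", call. = FALSE)
  g <- as_one_hot(labels, probs)
  inter <- sum(g * probs)
  denom <- sum(g) + sum(probs) + DICE_EPS
  1 - 2 * inter / denom
}

# gradient of dice_loss w.r.t. probs
dice_loss_grad <- function(probs, g) {
  inter <- sum(g * probs)
  denom <- sum(g) + sum(probs) + DICE_EPS
  -2 * g / denom + 2 * inter / denom^2
}

#' Signed Euclidean distance map of a binary region
#'
#' Negative strictly inside the region, positive strictly outside; the
#' magnitude is the distance to the nearest pixel of the opposite value
#' (unit pixel spacing).  When the mask is all-zero or all-one there is no
#' opposite pixel: the defined side keeps value `Inf`/`-Inf` and the result
#' carries attribute `degenerate = TRUE`.
#'
#' @param mask Binary (logical or 0/1 numeric) matrix.
#' @return Numeric matrix of signed distances with attribute `degenerate`.
#' @export
signed_distance_map <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  degenerate <- all(m) || !any(m)
  dist_to_fg <- sqrt(edt_sq_cpp(m))
  dist_to_bg <- sqrt(edt_sq_cpp(!m))
  phi <- dist_to_fg - dist_to_bg
  attr(phi, "degenerate") <- degenerate
  phi
}

#' Boundary loss
#'
#' For each foreground class c, the spatial mean of
#' `phi_c(q) * s_c(q)` where `phi_c` is the signed distance map of the
#' ground-truth region of class c; the per-class means are averaged over
#' foreground classes.  Negative values reward probability mass placed
#' inside the true region.  Foreground classes with an empty (or full)
#' ground-truth region are skipped.
#'
#' @inheritParams dice_loss
#' @param sdm Optional precomputed list of signed distance maps, one per
#'   foreground class (as produced by [boundary_distance_maps()]).
#' @return Scalar loss (may be negative).
#' @export
boundary_loss <- function(probs, labels, sdm = NULL) {
  probs <- as_fmap(probs)
  g <- as_one_hot(labels, probs)
  if (is.null(sdm)) sdm <- boundary_distance_maps_onehot(g)
  total <- 0
  used <- 0L
  for (c in seq_along(sdm)) {
    phi <- sdm[[c]]
    if (isTRUE(attr(phi, "degenerate"))) next
    total <- total + mean(phi * probs[, , c + 1L])
    used <- used + 1L
  }
  if (used == 0L) return(0)
  total / used
}

#' Precompute signed distance maps for the foreground classes of a mask
#'
#' Distance maps depend only on the ground truth, so during training they
#' are computed once per mask and cached.
#'
#' @param mask Integer class mask (values `0..C-1`).
#' @param num_classes Number of classes C.
#' @return List of `C - 1` signed distance maps (foreground classes only).
#' @export
boundary_distance_maps <- function(mask, num_classes) {
  lapply(seq_len(num_classes - 1L), function(c)
    signed_distance_map(mask == c))
}

boundary_distance_maps_onehot <- function(g) {
  C <- dim(g)[3]
  lapply(seq_len(C - 1L), function(c) {
    m <- matrix(g[, , c + 1L] != 0, dim(g)[1], dim(g)[2])
    signed_distance_map(m)
  })
}

# gradient of boundary_loss w.r.t. probs (linear, so probs-independent)
boundary_loss_grad <- function(dimprobs, sdm) {
  gr <- array(0, dimprobs)
  live <- Filter(function(p) !isTRUE(attr(p, "degenerate")), sdm)
  if (length(live) == 0L) return(gr)
  n <- dimprobs[1] * dimprobs[2]
  for (c in seq_along(sdm)) {
    phi <- sdm[[c]]
    if (isTRUE(attr(phi, "degenerate"))) next
    gr[, , c + 1L] <- phi / (n * length(live))
  }
  gr
}

#' Composite Dice + boundary loss
#'
#' `dice_loss + weight * boundary_loss`; the default weight of 1 gives the
#' plain sum of the two terms.
#'
#' @inheritParams boundary_loss
#' @param weight Non-negative boundary weight (default 1).
#' @return Scalar loss.
#' @export
dice_boundary_loss <- function(probs, labels, weight = 1, sdm = NULL) {
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0)
    stop("weight must be a non-negative scalar", call. = FALSE)
  dice_loss(probs, labels) + weight * boundary_loss(probs, labels, sdm)
}

# combined loss value + gradient wrt probs, for the training loop
loss_and_grad <- function(probs, mask, loss = "dice_boundary",
                          boundary_weight = 1, sdm = NULL) {
  g <- one_hot(mask, dim(probs)[3])
  if (loss %in% c("boundary", "dice_boundary") && is.null(sdm))
    sdm <- boundary_distance_maps(mask, dim(probs)[3])
  value <- 0
  grad <- array(0, dim(probs))
  if (loss %in% c("dice", "dice_boundary")) {
    value <- value + dice_loss(probs, g)
    grad <- grad + dice_loss_grad(probs, g)
  }
  if (loss %in% c("boundary", "dice_boundary")) {
    w <- if (loss == "boundary") 1 else boundary_weight
    value <- value + w * boundary_loss(probs, g, sdm)
    grad <- grad + w * boundary_loss_grad(dim(probs), sdm)
  }
  list(value = value, grad = grad)
}
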