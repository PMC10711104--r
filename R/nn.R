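# Minimal CNN layer framework with explicit forward/backward passes.
# Feature maps are numeric arrays of dim c(H, W, C); layers are mutable
# environments carrying parameters, gradients and forward caches.
# Convolutions run as im2col (C++) + BLAS matrix products.

new_layer <- function(class, ...) {
  l <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  class(l) <- c(class, "acu_layer")
  l
}

as_fmap <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

# ---- conv2d ---------------------------------------------------------------

nn_conv2d <- function(in_ch, out_ch, k = 3L, dilation = 1L, bias = TRUE,
                      init_sd = NULL) {
  fan_in <- in_ch * k * k
  if (is.null(init_sd)) init_sd <- sqrt(2 / fan_in)   # He initialisation
  W <- matrix(stats::rnorm(out_ch * fan_in, sd = init_sd), out_ch, fan_in)
  l <- new_layer("nn_conv2d",
    in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
    dil = as.integer(dilation), pad = as.integer(dilation * (k - 1L) / 2L),
    W = W, b = if (bias) numeric(out_ch) else NULL,
    param_names = if (bias) c("W", "b") else "W")
  l
}

#' @keywords internal
fwd.nn_conv2d <- function(l, x, train) {
  x <- as_fmap(x)
  d <- dim(x)
  if (l$k == 1L) {
    cols <- t(matrix(x, d[1] * d[2], d[3]))
  } else {
    cols <- im2col_cpp(x, l$k, l$pad, l$dil)
  }
  y <- l$W %*% cols
  if (!is.null(l$b)) y <- y + l$b
  if (train) {
    l$cols <- cols
    l$in_dim <- d
  }
  array(t(y), c(d[1], d[2], l$out_ch))
}

bwd.nn_conv2d <- function(l, dy) {
  d <- l$in_dim
  dym <- t(matrix(dy, d[1] * d[2], l$out_ch))
  l$dW <- l$dW + dym %*% t(l$cols)
  if (!is.null(l$b)) l$db <- l$db + rowSums(dym)
  dcols <- crossprod(l$W, dym)
  if (l$k == 1L) {
    array(t(dcols), d)
  } else {
    col2im_cpp(dcols, d[1], d[2], d[3], l$k, l$pad, l$dil)
  }
}

# ---- relu -----------------------------------------------------------------

nn_relu <- function() new_layer("nn_relu", param_names = character())

fwd.nn_relu <- function(l, x, train) {
  y <- pmax(x, 0)
  if (train) l$mask <- x > 0
  y
}

bwd.nn_relu <- function(l, dy) dy * l$mask

# ---- 2x2 max pooling ------------------------------------------------------

nn_maxpool2 <- function() new_layer("nn_maxpool2", param_names = character())

fwd.nn_maxpool2 <- function(l, x, train) {
  x <- as_fmap(x)
  r <- maxpool2_fwd_cpp(x)
  if (train) {
    l$idx <- r$idx
    l$in_dim <- dim(x)
  }
  r$y
}

bwd.nn_maxpool2 <- function(l, dy) {
  maxpool2_bwd_cpp(dy, l$idx, l$in_dim[1], l$in_dim[2])
}

# ---- bilinear x2 upsampling ----------------------------------------------

nn_upsample2 <- function() new_layer("nn_upsample2", param_names = character())

fwd.nn_upsample2 <- function(l, x, train) {
  x <- as_fmap(x)
  if (train) l$in_dim <- dim(x)
  bilinear_fwd_cpp(x, 2L * dim(x)[1], 2L * dim(x)[2])
}

bwd.nn_upsample2 <- function(l, dy) {
  bilinear_bwd_cpp(dy, l$in_dim[1], l$in_dim[2])
}

# ---- batch normalisation (statistics over the spatial plane) --------------

nn_batchnorm <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_layer("nn_batchnorm",
    ch = ch, eps = eps, momentum = momentum,
    gamma = rep(1, ch), beta = numeric(ch),
    run_mean = numeric(ch), run_var = rep(1, ch),
    param_names = c("gamma", "beta"))
}

fwd.nn_batchnorm <- function(l, x, train) {
  x <- as_fmap(x)
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  # statistics are always per-image (instance normalisation): training runs
  # with batch accumulation of gradients but batch-of-1 forward passes, so
  # using running statistics at inference would evaluate a different
  # network than the one trained.  Running stats are still tracked.
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  if (train) {
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * va
  }
  invstd <- 1 / sqrt(va + l$eps)
  xhat <- sweep(xm, 2L, mu, `-`)
  xhat <- sweep(xhat, 2L, invstd, `*`)
  y <- sweep(sweep(xhat, 2L, l$gamma, `*`), 2L, l$beta, `+`)
  if (train) {
    l$xhat <- xhat
    l$invstd <- invstd
    l$in_dim <- d
  }
  array(y, d)
}

bwd.nn_batchnorm <- function(l, dy) {
  d <- l$in_dim
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  l$dgamma <- l$dgamma + colSums(dym * l$xhat)
  l$dbeta <- l$dbeta + colSums(dym)
  dxhat <- sweep(dym, 2L, l$gamma, `*`)
  # standard batchnorm backward through the batch statistics
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), `-`)
  t2 <- sweep(l$xhat, 2L, colMeans(dxhat * l$xhat), `*`)
  dx <- sweep(t1 - t2, 2L, l$invstd, `*`)
  array(dx, d)
}

# ---- generic dispatch -----------------------------------------------------

layer_forward <- function(l, x, train = FALSE) {
  switch(class(l)[1],
    nn_conv2d    = fwd.nn_conv2d(l, x, train),
    nn_relu      = fwd.nn_relu(l, x, train),
    nn_maxpool2  = fwd.nn_maxpool2(l, x, train),
    nn_upsample2 = fwd.nn_upsample2(l, x, train),
    nn_batchnorm = fwd.nn_batchnorm(l, x, train),
    stop("unknown layer class: ", class(l)[1]))
}

layer_backward <- function(l, dy) {
  switch(class(l)[1],
    nn_conv2d    = bwd.nn_conv2d(l, dy),
    nn_relu      = bwd.nn_relu(l, dy),
    nn_maxpool2  = bwd.nn_maxpool2(l, dy),
    nn_upsample2 = bwd.nn_upsample2(l, dy),
    nn_batchnorm = bwd.nn_batchnorm(l, dy),
    stop("unknown layer class: ", class(l)[1]))
}

# ---- parameter plumbing ---------------------------------------------------

layer_param_count <- function(l) {
  sum(vapply(l$param_names, function(nm) length(l[[nm]]), numeric(1)))
}

zero_grad_layer <- function(l) {
  for (nm in l$param_names) {
    g <- l[[nm]]
    g[] <- 0
    assign(paste0("d", nm), g, envir = l)
  }
}

drop_cache_layer <- function(l) {
  for (nm in c("cols", "mask", "idx", "xhat", "invstd"))
    if (!is.null(l[[nm]])) assign(nm, NULL, envir = l)
}

adam_init_layer <- function(l) {
  for (nm in l$param_names) {
    z <- l[[nm]]
    z[] <- 0
    assign(paste0("m_", nm), z, envir = l)
    assign(paste0("v_", nm), z, envir = l)
  }
}

adam_step_layer <- function(l, lr, t, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  for (nm in l$param_names) {
    g <- l[[paste0("d", nm)]]
    m <- beta1 * l[[paste0("m_", nm)]] + (1 - beta1) * g
    v <- beta2 * l[[paste0("v_", nm)]] + (1 - beta2) * g * g
    assign(paste0("m_", nm), m, envir = l)
    assign(paste0("v_", nm), v, envir = l)
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    assign(nm, l[[nm]] - lr * mhat / (sqrt(vhat) + eps), envir = l)
  }
}

# softmax over the channel dimension of an (H, W, C) array
softmax_channels <- function(z) {
  d <- dim(z)
  zm <- matrix(z, d[1] * d[2], d[3])
  zm <- zm - apply(zm, 1L, max)
  ez <- exp(zm)
  array(ez / rowSums(ez), d)
}
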