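# AC-UNet assembly: VGG16 convolutional encoder, re-tuned ASPP bridge,
# decoder with up-concatenation, criss-cross attention on decoder features.

VGG16_BLOCK_WIDTHS <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                           c(512L, 512L, 512L), c(512L, 512L, 512L))
DECODER_WIDTHS <- c(512L, 256L, 128L, 64L)

#' Network configuration for AC-UNet
#'
#' The default configuration reproduces the full-size network: a VGG16
#' convolutional encoder (13 conv layers, fully connected layers removed),
#' an ASPP bridge with dilation rates (1, 2, 7, 15) projected to 256
#' channels, a four-stage decoder (512, 256, 128, 64 channels) with
#' bilinear up-concatenation, recurrent criss-cross attention after every
#' decoder stage, and a 1x1 convolution to `num_classes` followed by
#' softmax.  `width_scale` divides every channel width by the same factor,
#' giving a faithful miniature for CPU-scale experiments; `encoder_blocks`
#' truncates the encoder for toy settings.
#'
#' @param num_classes Number of output classes (default 3:
#'   background/stem/leaf).
#' @param input_size Expected square input size in pixels; must be divisible
#'   by `2^(encoder_blocks - 1)` so the bridge resolution is integral.
#' @param width_scale Integer divisor applied to all channel widths.
#' @param encoder_blocks Number of VGG16 blocks kept (2..5).
#' @param use_aspp,use_cca Enable the ASPP bridge / criss-cross attention.
#'   Both `FALSE` gives the plain VGG16-UNet baseline.
#' @param aspp_rates Dilation schedule for the ASPP branches; the rate-1
#'   entry is realised as the 1x1 branch.  Must pass [validate_rates()].
#' @param aspp_width ASPP branch/projection width before scaling.
#' @param cca_recurrence Number of attention recurrences (2 gives full-image
#'   context).
#' @param cca_reduction Channel reduction for the query/key projections;
#'   must divide every decoder width after scaling.
#' @param use_pretrained_encoder Optional path to a VGG16 convolutional
#'   checkpoint loaded into the encoder (`FALSE` to skip).
#' @return A list of class `acunet_config`.
#' @export
network_config <- function(num_classes = 3L, input_size = 512L,
                           width_scale = 1L, encoder_blocks = 5L,
                           use_aspp = TRUE, use_cca = TRUE,
                           aspp_rates = c(1L, 2L, 7L, 15L),
                           aspp_width = 256L, cca_recurrence = 2L,
                           cca_reduction = 8L,
                           use_pretrained_encoder = FALSE) {
  stopifnot(num_classes >= 2, encoder_blocks >= 2, encoder_blocks <= 5,
            width_scale >= 1, width_scale == round(width_scale))
  n_pools <- encoder_blocks - 1L
  if (encoder_blocks == 5L && input_size %% 16L != 0L)
    stop("input_size must be divisible by 16", call. = FALSE)
  if (input_size %% (2L^n_pools) != 0L)
    stop("input_size must be divisible by 2^(encoder_blocks - 1)",
         call. = FALSE)
  if (use_aspp) {
    if (length(aspp_rates) < 2L || aspp_rates[1] != 1L)
      stop("aspp_rates must start with the rate-1 (1x1) branch",
           call. = FALSE)
    verdict <- validate_rates(3L, aspp_rates)
    if (verdict != "valid")
      stop("aspp_rates fail the gridding check: ", verdict, call. = FALSE)
  }
  enc_widths <- lapply(VGG16_BLOCK_WIDTHS[seq_len(encoder_blocks)],
                       function(w) scale_width(w, width_scale))
  dec_widths <- scale_width(utils::tail(DECODER_WIDTHS, n_pools),
                            width_scale)
  aspp_w <- scale_width(aspp_width, width_scale)
  if (use_cca && any(dec_widths %% cca_reduction != 0L))
    stop("cca_reduction must divide every decoder width", call. = FALSE)
  structure(list(
    num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    width_scale = as.integer(width_scale),
    encoder_blocks = as.integer(encoder_blocks),
    encoder_widths = enc_widths, decoder_widths = dec_widths,
    use_aspp = use_aspp, use_cca = use_cca,
    aspp_rates = as.integer(aspp_rates), aspp_width = aspp_w,
    cca_recurrence = as.integer(cca_recurrence),
    cca_reduction = as.integer(cca_reduction),
    use_pretrained_encoder = use_pretrained_encoder),
    class = "acunet_config")
}

scale_width <- function(w, s) {
  out <- as.integer(w / s)
  if (any(out < 1L) || any(w %% s != 0L))
    stop("width_scale must divide all channel widths", call. = FALSE)
  out
}

# ---- ASPP bridge ----------------------------------------------------------

#' Build an atrous spatial pyramid pooling block
#'
#' Five parallel branches over the input map: a 1x1 convolution (the rate-1
#' branch), three 3x3 dilated convolutions at the remaining rates (padding
#' equal to the dilation, so the spatial size is preserved), and an
#' image-level branch (global average pooling, 1x1 convolution, broadcast
#' upsampling).  Branch outputs are concatenated and projected by a 1x1
#' convolution to `width` channels followed by batch normalisation.
#'
#' @param in_channels Input channel count.
#' @param rates Dilation schedule including the leading 1; validated via
#'   [validate_rates()].
#' @param width Channel width of every branch and of the output.
#' @return An `acu_aspp` block usable inside [build_acunet()].
#' @export
build_aspp <- function(in_channels, rates = c(1L, 2L, 7L, 15L),
                       width = 256L) {
  stopifnot(in_channels >= 1)
  if (length(rates) < 2L || rates[1] != 1L)
    stop("rates must start with 1 (the 1x1 branch)", call. = FALSE)
  verdict <- validate_rates(3L, rates)
  if (verdict != "valid")
    stop("invalid ASPP rates: ", verdict, call. = FALSE)
  dil_rates <- rates[-1]
  branches <- c(
    list(nn_conv2d(in_channels, width, k = 1L)),
    lapply(dil_rates, function(r)
      nn_conv2d(in_channels, width, k = 3L, dilation = r)))
  blk <- new_layer("acu_aspp",
    rates = as.integer(rates), width = as.integer(width),
    in_channels = as.integer(in_channels),
    branches = branches,
    branch_relus = replicate(length(branches), nn_relu()),
    pool_conv = nn_conv2d(in_channels, width, k = 1L),
    pool_relu = nn_relu(),
    proj = nn_conv2d((length(branches) + 1L) * width, width, k = 1L),
    proj_bn = nn_batchnorm(width),
    proj_relu = nn_relu(),
    param_names = character())
  blk
}

aspp_forward <- function(blk, x, train = FALSE) {
  x <- as_fmap(x)
  d <- dim(x)
  outs <- vector("list", length(blk$branches) + 1L)
  for (i in seq_along(blk$branches)) {
    y <- layer_forward(blk$branches[[i]], x, train)
    outs[[i]] <- layer_forward(blk$branch_relus[[i]], y, train)
  }
  # image-level branch: GAP -> 1x1 conv -> ReLU -> broadcast
  g <- array(colMeans(matrix(x, d[1] * d[2], d[3])), c(1L, 1L, d[3]))
  g <- layer_forward(blk$pool_conv, g, train)
  g <- layer_forward(blk$pool_relu, g, train)
  gv <- as.vector(g)
  outs[[length(outs)]] <- array(rep(gv, each = d[1] * d[2]),
                                c(d[1], d[2], blk$width))
  cc <- cat_channels(outs)
  y <- layer_forward(blk$proj, cc, train)
  y <- layer_forward(blk$proj_bn, y, train)
  y <- layer_forward(blk$proj_relu, y, train)
  if (train) blk$in_dim <- d
  y
}

aspp_backward <- function(blk, dy) {
  d <- blk$in_dim
  g <- layer_backward(blk$proj_relu, dy)
  g <- layer_backward(blk$proj_bn, g)
  g <- layer_backward(blk$proj, g)
  parts <- split_channels(g, rep(blk$width, length(blk$branches) + 1L))
  dx <- array(0, d)
  for (i in seq_along(blk$branches)) {
    gb <- layer_backward(blk$branch_relus[[i]], parts[[i]])
    dx <- dx + layer_backward(blk$branches[[i]], gb)
  }
  # image-level branch backward: spatial sum -> conv -> spread of the mean
  gp <- parts[[length(parts)]]
  gsum <- array(colSums(matrix(gp, d[1] * d[2], blk$width)),
                c(1L, 1L, blk$width))
  gsum <- layer_backward(blk$pool_relu, gsum)
  gg <- layer_backward(blk$pool_conv, gsum)
  dx + array(rep(as.vector(gg) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

# ---- criss-cross attention ------------------------------------------------

#' Build a recurrent criss-cross attention block
#'
#' Every position of an `H x W x C` map attends over the `H + W - 1`
#' positions of its row and column: query and key 1x1 projections to
#' `channels / reduction` channels, a value projection to `channels`,
#' a joint softmax over the cross, value aggregation and a scaled residual
#' addition.  The pass is repeated `recurrence` times with shared
#' parameters, which propagates information across the full image.
#'
#' @param channels Feature channels; must be divisible by `reduction`.
#' @param recurrence Number of repeats (default 2).
#' @param reduction Query/key channel reduction (default 8).
#' @return An `acu_cca` block.
#' @export
build_cca <- function(channels, recurrence = 2L, reduction = 8L) {
  if (channels %% reduction != 0L)
    stop("channels must be divisible by reduction", call. = FALSE)
  dqk <- as.integer(channels / reduction)
  new_layer("acu_cca",
    channels = as.integer(channels), recurrence = as.integer(recurrence),
    dqk = dqk,
    convq = nn_conv2d(channels, dqk, k = 1L),
    convk = nn_conv2d(channels, dqk, k = 1L),
    convv = nn_conv2d(channels, channels, k = 1L),
    gamma = 0.1,
    param_names = "gamma")
}

cca_forward <- function(blk, x, train = FALSE) {
  cur <- as_fmap(x)
  steps <- if (train) vector("list", blk$recurrence) else NULL
  for (t in seq_len(blk$recurrence)) {
    q <- conv_apply(blk$convq, cur)
    k <- conv_apply(blk$convk, cur)
    v <- conv_apply(blk$convv, cur)
    at <- cca_attention_fwd_cpp(q$y, k$y, v$y)
    out <- cur + blk$gamma * at$agg
    if (train) {
      steps[[t]] <- list(q = q, k = k, v = v,
                         Arow = at$Arow, Acol = at$Acol, agg = at$agg)
    }
    cur <- out
  }
  if (train) blk$steps <- steps
  cur
}

cca_backward <- function(blk, dy) {
  for (t in rev(seq_len(blk$recurrence))) {
    st <- blk$steps[[t]]
    blk$dgamma <- blk$dgamma + sum(dy * st$agg)
    dagg <- blk$gamma * dy
    g <- cca_attention_bwd_cpp(st$q$y, st$k$y, st$v$y,
                               st$Arow, st$Acol, dagg)
    dy <- dy +
      conv_grad(blk$convq, g$dQ, st$q) +
      conv_grad(blk$convk, g$dK, st$k) +
      conv_grad(blk$convv, g$dV, st$v)
  }
  blk$steps <- NULL
  dy
}

# conv helpers with explicit caches (needed when one conv runs several
# times per pass, as in the recurrent CCA)
conv_apply <- function(l, x) {
  x <- as_fmap(x)
  d <- dim(x)
  cols <- if (l$k == 1L) t(matrix(x, d[1] * d[2], d[3])) else
    im2col_cpp(x, l$k, l$pad, l$dil)
  y <- l$W %*% cols
  if (!is.null(l$b)) y <- y + l$b
  list(y = array(t(y), c(d[1], d[2], l$out_ch)), cols = cols, in_dim = d)
}

conv_grad <- function(l, dy, cache) {
  d <- cache$in_dim
  dym <- t(matrix(dy, d[1] * d[2], l$out_ch))
  l$dW <- l$dW + dym %*% t(cache$cols)
  if (!is.null(l$b)) l$db <- l$db + rowSums(dym)
  dcols <- crossprod(l$W, dym)
  if (l$k == 1L) array(t(dcols), d) else
    col2im_cpp(dcols, d[1], d[2], d[3], l$k, l$pad, l$dil)
}

# ---- model assembly -------------------------------------------------------

#' Build the AC-UNet segmentation model
#'
#' Assembles the encoder/bridge/decoder/head described by the
#' configuration.  With `use_aspp = FALSE, use_cca = FALSE` this is the
#' VGG16-UNet baseline (24,891,267 trainable parameters at full width for
#' 3 classes).  The ASPP output is projected back to the bridge width by an
#' extra 1x1 convolution so the decoder is identical between the baseline
#' and AC-UNet.
#'
#' @param config An `acunet_config`, see [network_config()].
#' @return An `acunet_model` environment with a forward contract
#'   image -> per-pixel class probabilities ([predict_probs()]).
#' @export
build_acunet <- function(config = network_config()) {
  stopifnot(inherits(config, "acunet_config"))
  B <- config$encoder_blocks
  m <- new_layer("acunet_model", config = config)
  # encoder
  enc <- vector("list", B)
  in_ch <- 3L
  for (b in seq_len(B)) {
    widths <- config$encoder_widths[[b]]
    block <- list()
    for (w in widths) {
      block <- c(block, list(nn_conv2d(in_ch, w, k = 3L), nn_relu()))
      in_ch <- w
    }
    enc[[b]] <- block
  }
  m$enc <- enc
  m$pools <- replicate(B - 1L, nn_maxpool2())
  bridge_ch <- utils::tail(config$encoder_widths[[B]], 1L)
  # bridge
  if (config$use_aspp) {
    m$aspp <- build_aspp(bridge_ch, config$aspp_rates, config$aspp_width)
    m$aspp_proj <- nn_conv2d(config$aspp_width, bridge_ch, k = 1L)
    m$aspp_proj_relu <- nn_relu()
  }
  # decoder: four up-concatenation stages
  dec <- vector("list", B - 1L)
  cur_ch <- bridge_ch
  for (i in seq_len(B - 1L)) {
    skip_ch <- utils::tail(config$encoder_widths[[B - i]], 1L)
    out_ch <- config$decoder_widths[i]
    stage <- list(
      up = nn_upsample2(),
      conv1 = nn_conv2d(cur_ch + skip_ch, out_ch, k = 3L),
      relu1 = nn_relu(),
      conv2 = nn_conv2d(out_ch, out_ch, k = 3L),
      relu2 = nn_relu(),
      cca = if (config$use_cca)
        build_cca(out_ch, config$cca_recurrence, config$cca_reduction)
      else NULL,
      skip_index = B - i)
    dec[[i]] <- stage
    cur_ch <- out_ch
  }
  m$dec <- dec
  m$head <- nn_conv2d(cur_ch, config$num_classes, k = 1L)
  m$all_layers <- collect_layers(m)
  if (!isFALSE(config$use_pretrained_encoder))
    load_vgg16_weights(m, config$use_pretrained_encoder)
  m
}

collect_layers <- function(m) {
  ls <- list()
  for (b in m$enc) ls <- c(ls, b)
  ls <- c(ls, m$pools)
  if (!is.null(m$aspp)) {
    a <- m$aspp
    ls <- c(ls, a$branches, a$branch_relus,
            list(a$pool_conv, a$pool_relu, a$proj, a$proj_bn, a$proj_relu),
            list(m$aspp_proj, m$aspp_proj_relu))
  }
  for (st in m$dec) {
    ls <- c(ls, list(st$up, st$conv1, st$relu1, st$conv2, st$relu2))
    if (!is.null(st$cca))
      ls <- c(ls, list(st$cca, st$cca$convq, st$cca$convk, st$cca$convv))
  }
  c(ls, list(m$head))
}

#' Count trainable parameters of a model
#'
#' @param model An `acunet_model`.
#' @return Integer-valued count of trainable scalars (weights, biases,
#'   batch-norm affine terms, attention residual scales).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$all_layers, layer_param_count, numeric(1)))
}

#' Forward pass returning per-pixel class probabilities
#'
#' @param model An `acunet_model`.
#' @param image `H x W x 3` numeric array; raw 0..255 images are rescaled
#'   to `[0, 1]` internally.
#' @param train Keep caches for a subsequent backward pass.
#' @return `H x W x C` array; each pixel's probabilities sum to 1.
#' @export
predict_probs <- function(model, image, train = FALSE) {
  x <- normalize_image(image)
  logits <- forward_logits(model, x, train)
  probs <- softmax_channels(logits)
  if (train) model$probs <- probs
  probs
}

normalize_image <- function(image) {
  x <- as_fmap(image)
  if (max(x) > 1.5) x <- x / 255
  x
}

forward_logits <- function(m, x, train = FALSE) {
  B <- m$config$encoder_blocks
  feats <- vector("list", B)
  cur <- x
  for (b in seq_len(B)) {
    for (l in m$enc[[b]]) cur <- layer_forward(l, cur, train)
    feats[[b]] <- cur
    if (b < B) cur <- layer_forward(m$pools[[b]], cur, train)
  }
  if (!is.null(m$aspp)) {
    cur <- aspp_forward(m$aspp, cur, train)
    cur <- layer_forward(m$aspp_proj, cur, train)
    cur <- layer_forward(m$aspp_proj_relu, cur, train)
  }
  for (st in m$dec) {
    cur <- layer_forward(st$up, cur, train)
    cur <- cat_channels(list(cur, feats[[st$skip_index]]))
    cur <- layer_forward(st$conv1, cur, train)
    cur <- layer_forward(st$relu1, cur, train)
    cur <- layer_forward(st$conv2, cur, train)
    cur <- layer_forward(st$relu2, cur, train)
    if (!is.null(st$cca)) cur <- cca_forward(st$cca, cur, train)
  }
  layer_forward(m$head, cur, train)
}

# backward pass from d(loss)/d(logits); requires a train-mode forward
backward_logits <- function(m, dlogits) {
  B <- m$config$encoder_blocks
  g <- layer_backward(m$head, dlogits)
  dskip <- vector("list", B)
  for (i in rev(seq_along(m$dec))) {
    st <- m$dec[[i]]
    if (!is.null(st$cca)) g <- cca_backward(st$cca, g)
    g <- layer_backward(st$relu2, g)
    g <- layer_backward(st$conv2, g)
    g <- layer_backward(st$relu1, g)
    g <- layer_backward(st$conv1, g)
    up_ch <- dim(g)[3] - utils::tail(
      dim_skip_width(m, st$skip_index), 1L)
    parts <- split_channels(g, c(up_ch, dim(g)[3] - up_ch))
    si <- st$skip_index
    dskip[[si]] <- if (is.null(dskip[[si]])) parts[[2]] else
      dskip[[si]] + parts[[2]]
    g <- layer_backward(st$up, parts[[1]])
  }
  if (!is.null(m$aspp)) {
    g <- layer_backward(m$aspp_proj_relu, g)
    g <- layer_backward(m$aspp_proj, g)
    g <- aspp_backward(m$aspp, g)
  }
  dfeat <- g
  for (b in rev(seq_len(B))) {
    if (b < B) {
      dfeat <- layer_backward(m$pools[[b]], dfeat)
    }
    if (!is.null(dskip[[b]])) dfeat <- dfeat + dskip[[b]]
    for (l in rev(m$enc[[b]])) dfeat <- layer_backward(l, dfeat)
  }
  invisible(dfeat)
}

dim_skip_width <- function(m, b) {
  utils::tail(m$config$encoder_widths[[b]], 1L)
}

# Data-dependent initialisation (LSUV-style): walk the network in forward
# order and rescale every convolution so its pre-activation standard
# deviation is ~1 on a calibration image.  Plain VGG-style stacks (no
# normalisation layers, as in the parameter-count-matched baseline) are
# otherwise highly init-seed sensitive when trained from scratch.
lsuv_scale <- function(l, x, target = 1) {
  y <- conv_apply(l, x)$y
  s <- stats::sd(y)
  if (is.finite(s) && s > 1e-8) {
    l$W <- l$W * (target / s)
    y <- y * (target / s)
  }
  y
}

#' Variance-scaling initialisation on calibration data
#'
#' Rescales every convolution weight so that its output standard deviation
#' is approximately `target` when the model is run on the supplied image.
#' Deterministic given the model and image.  Called by [train()] before
#' the first step (disable with `lsuv = FALSE`).
#'
#' @param model An `acunet_model`.
#' @param image A representative `H x W x 3` input image.
#' @param target Target pre-activation standard deviation.
#' @return The model, invisibly, with rescaled weights.
#' @export
lsuv_init <- function(model, image, target = 1) {
  m <- model
  B <- m$config$encoder_blocks
  x <- normalize_image(image)
  feats <- vector("list", B)
  cur <- x
  for (b in seq_len(B)) {
    blk <- m$enc[[b]]
    for (l in blk) {
      cur <- if (inherits(l, "nn_conv2d")) lsuv_scale(l, cur, target)
      else layer_forward(l, cur, FALSE)
    }
    feats[[b]] <- cur
    if (b < B) cur <- layer_forward(m$pools[[b]], cur, FALSE)
  }
  if (!is.null(m$aspp)) {
    a <- m$aspp
    d <- dim(cur)
    outs <- vector("list", length(a$branches) + 1L)
    for (i in seq_along(a$branches))
      outs[[i]] <- pmax(lsuv_scale(a$branches[[i]], cur, target), 0)
    g <- array(colMeans(matrix(cur, d[1] * d[2], d[3])), c(1L, 1L, d[3]))
    gv <- pmax(as.vector(lsuv_scale(a$pool_conv, g, target)), 0)
    outs[[length(outs)]] <- array(rep(gv, each = d[1] * d[2]),
                                  c(d[1], d[2], a$width))
    cc <- cat_channels(outs)
    y <- lsuv_scale(a$proj, cc, target)
    y <- layer_forward(a$proj_bn, y, FALSE)
    y <- pmax(y, 0)
    cur <- pmax(lsuv_scale(m$aspp_proj, y, target), 0)
  }
  for (st in m$dec) {
    cur <- layer_forward(st$up, cur, FALSE)
    cur <- cat_channels(list(cur, feats[[st$skip_index]]))
    cur <- pmax(lsuv_scale(st$conv1, cur, target), 0)
    cur <- pmax(lsuv_scale(st$conv2, cur, target), 0)
    if (!is.null(st$cca)) cur <- cca_forward(st$cca, cur, FALSE)
  }
  lsuv_scale(m$head, cur, target)
  invisible(m)
}

# backward through the softmax head given d(loss)/d(probs)
dlogits_from_dprobs <- function(probs, dprobs) {
  d <- dim(probs)
  pm <- matrix(probs, d[1] * d[2], d[3])
  gm <- matrix(dprobs, d[1] * d[2], d[3])
  array(pm * (gm - rowSums(gm * pm)), d)
}

# ---- channel concat / split ----------------------------------------------

cat_channels <- function(xs) {
  d <- dim(xs[[1]])
  total <- sum(vapply(xs, function(x) dim(x)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], total))
  at <- 0L
  for (x in xs) {
    cx <- dim(x)[3]
    out[, , at + seq_len(cx)] <- x
    at <- at + cx
  }
  out
}

split_channels <- function(x, widths) {
  at <- 0L
  lapply(widths, function(w) {
    idx <- at + seq_len(w)
    at <<- at + w
    x[, , idx, drop = FALSE]
  })
}

# ---- optimizer / parameter plumbing over a whole model --------------------

model_zero_grads <- function(m) {
  for (l in m$all_layers) zero_grad_layer(l)
  invisible(m)
}

model_adam_init <- function(m) {
  for (l in m$all_layers) adam_init_layer(l)
  m$adam_t <- 0L
  invisible(m)
}

model_adam_step <- function(m, lr, beta2 = 0.999) {
  m$adam_t <- m$adam_t + 1L
  for (l in m$all_layers) adam_step_layer(l, lr, m$adam_t, beta2 = beta2)
  invisible(m)
}

model_drop_caches <- function(m) {
  for (l in m$all_layers) drop_cache_layer(l)
  invisible(m)
}

model_get_params <- function(m) {
  lapply(m$all_layers, function(l)
    stats::setNames(lapply(l$param_names, function(nm) l[[nm]]),
                    l$param_names))
}

model_set_params <- function(m, params) {
  stopifnot(length(params) == length(m$all_layers))
  for (i in seq_along(params)) {
    l <- m$all_layers[[i]]
    for (nm in names(params[[i]])) assign(nm, params[[i]][[nm]], envir = l)
  }
  invisible(m)
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint itself is an opaque binary file; a sidecar JSON manifest
#' (`<path>.json`) records the configuration and any metadata supplied.
#'
#' @param model An `acunet_model`.
#' @param path Destination file.
#' @param meta Named list merged into the manifest (seed, epoch, metrics).
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  saveRDS(list(config = model$config, params = model_get_params(model),
               bn_state = lapply(model$all_layers, function(l)
                 if (inherits(l, "nn_batchnorm"))
                   list(run_mean = l$run_mean, run_var = l$run_var)
                 else NULL)),
          path)
  manifest <- c(list(config = unclass(model$config),
                     params_total = count_parameters(model),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                meta)
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- build_acunet(ck$config)
  model_set_params(m, ck$params)
  for (i in seq_along(ck$bn_state)) {
    if (!is.null(ck$bn_state[[i]])) {
      l <- m$all_layers[[i]]
      l$run_mean <- ck$bn_state[[i]]$run_mean
      l$run_var <- ck$bn_state[[i]]$run_var
    }
  }
  m
}

# ---- VGG16 encoder checkpoint loading -------------------------------------

# torch-style feature indices of the 13 VGG16 conv layers
VGG16_FEATURE_INDICES <- c(0L, 2L, 5L, 7L, 10L, 12L, 14L, 17L, 19L, 21L,
                           24L, 26L, 28L)

#' Load standard VGG16 convolutional weights into the encoder
#'
#' Accepts an RDS file (or an already-read list) holding entries named
#' `features.<i>.weight` (arrays of dim `out x in x k x k`) and
#' `features.<i>.bias` for the 13 convolutional layers of VGG16, the layout
#' used by common VGG16 checkpoints.  Requires a full-width
#' (`width_scale = 1`) encoder.
#'
#' @param model An `acunet_model`.
#' @param weights File path or named list.
#' @return The model, invisibly, with encoder weights replaced.
#' @export
load_vgg16_weights <- function(model, weights) {
  if (is.character(weights)) weights <- readRDS(weights)
  if (model$config$width_scale != 1L)
    stop("pretrained VGG16 weights require width_scale = 1", call. = FALSE)
  convs <- Filter(function(l) inherits(l, "nn_conv2d"),
                  unlist(model$enc, recursive = FALSE))
  idx <- VGG16_FEATURE_INDICES[seq_along(convs)]
  for (i in seq_along(convs)) {
    wname <- sprintf("features.%d.weight", idx[i])
    bname <- sprintf("features.%d.bias", idx[i])
    wt <- weights[[wname]]
    if (is.null(wt)) stop("checkpoint entry missing: ", wname,
                          call. = FALSE)
    l <- convs[[i]]
    expect_dim <- c(l$out_ch, l$in_ch, l$k, l$k)
    if (!identical(as.integer(dim(wt)), as.integer(expect_dim)))
      stop(sprintf("shape mismatch for %s: got [%s], want [%s]", wname,
                   paste(dim(wt), collapse = ","),
                   paste(expect_dim, collapse = ",")), call. = FALSE)
    # (out, in, ki, kj) -> rows out, columns (ki fastest, kj, in)
    l$W <- matrix(aperm(wt, c(3, 4, 2, 1)), ncol = l$out_ch)
    l$W <- t(l$W)
    if (!is.null(weights[[bname]])) l$b <- as.numeric(weights[[bname]])
  }
  invisible(model)
}

#' Predict a class mask for one image
#'
#' @param model An `acunet_model`.
#' @param image `H x W x 3` array.
#' @return Integer matrix of class labels (0-based) of the input size.
#' @export
predict_mask <- function(model, image) {
  probs <- predict_probs(model, image)
  d <- dim(probs)
  pm <- matrix(probs, d[1] * d[2], d[3])
  matrix(max.col(pm, ties.method = "first") - 1L, d[1], d[2])
}
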