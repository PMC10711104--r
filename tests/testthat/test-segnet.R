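# Architecture assembly: configuration, ASPP, parameter counts, forward
# contract, checkpoints, VGG16 weight loading.

test_that("network configuration enforces its invariants", {
  expect_error(network_config(input_size = 500), "divisible")
  expect_error(network_config(aspp_rates = c(1, 2, 9)), "gridding")
  expect_error(network_config(aspp_rates = c(2, 7, 15)), "rate-1")
  expect_error(network_config(width_scale = 8, cca_reduction = 16),
               "reduction")
  cfg <- network_config()
  expect_identical(cfg$decoder_widths, c(512L, 256L, 128L, 64L))
  expect_identical(cfg$aspp_rates, c(1L, 2L, 7L, 15L))
  expect_identical(vapply(cfg$encoder_widths, length, integer(1)),
                   c(2L, 2L, 3L, 3L, 3L))
})

test_that("ASPP block has len(rates)+1 branches and preserves shape", {
  blk <- build_aspp(512, c(1, 2, 7, 15), 256)
  expect_length(blk$branches, 4L)              # 1x1 + three dilated 3x3
  expect_identical(blk$branches[[1]]$k, 1L)
  expect_identical(vapply(blk$branches[-1], function(b) b$dil, integer(1)),
                   c(2L, 7L, 15L))
  # projection input = (branches + pooling branch) * width
  expect_identical(nrow(blk$proj$W), 256L)
  expect_identical(ncol(blk$proj$W), 5L * 256L)
  expect_error(build_aspp(512, c(1, 2, 9), 256), "invalid")
  small <- build_aspp(4, c(1, 2, 7, 15), 8)
  for (hw in list(c(8L, 8L), c(5L, 9L))) {
    x <- array(rnorm(hw[1] * hw[2] * 4), c(hw, 4L))
    y <- acunet:::aspp_forward(small, x, FALSE)
    expect_identical(dim(y), c(hw, 8L))
  }
})

test_that("parameter counts match closed-form layer arithmetic", {
  head195 <- acunet:::nn_conv2d(64, 3, k = 1)
  expect_equal(acunet:::layer_param_count(head195), 195)  # 64*3 + 3
  cfg <- network_config(use_aspp = FALSE, use_cca = FALSE)
  m <- build_acunet(cfg)
  enc_convs <- Filter(function(l) inherits(l, "nn_conv2d"),
                      unlist(m$enc, recursive = FALSE))
  enc_total <- sum(vapply(enc_convs, acunet:::layer_param_count,
                          numeric(1)))
  expect_equal(enc_total, 14714688)            # VGG16 conv stack
  expect_equal(count_parameters(m), 24891267)  # + decoder + 3-class head
  # independent closed-form oracle: conv params = out*(in*k*k + 1)
  conv_p <- function(i, o, k) o * (i * k * k + 1)
  dec_oracle <- conv_p(1024, 512, 3) + conv_p(512, 512, 3) +
    conv_p(768, 256, 3) + conv_p(256, 256, 3) +
    conv_p(384, 128, 3) + conv_p(128, 128, 3) +
    conv_p(192, 64, 3) + conv_p(64, 64, 3)
  expect_equal(count_parameters(m), enc_total + dec_oracle + 195)
})

test_that("enabling ASPP and CCA adds parameters", {
  base <- count_parameters(build_acunet(tiny_config(use_aspp = FALSE,
                                                    use_cca = FALSE)))
  with_aspp <- count_parameters(build_acunet(tiny_config(use_cca = FALSE)))
  with_both <- count_parameters(build_acunet(tiny_config()))
  expect_gt(with_aspp, base)
  expect_gt(with_both, with_aspp)
})

test_that("forward returns a normalised probability map of the input size", {
  set.seed(301)
  cfg <- tiny_config()
  m <- build_acunet(cfg)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  probs <- predict_probs(m, img)
  expect_identical(dim(probs), c(32L, 32L, 3L))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(apply(probs, c(1, 2), sum), matrix(1, 32, 32),
               tolerance = 1e-5)
  mask <- predict_mask(m, img)
  expect_true(all(mask %in% 0:2))
  expect_identical(dim(mask), c(32L, 32L))
})

test_that("checkpoints round-trip through save and load", {
  set.seed(302)
  m <- build_acunet(tiny_config())
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  p1 <- predict_probs(m, img)
  ck <- file.path(tempdir(), "model.ckpt")
  save_checkpoint(m, ck, meta = list(seed = 302, epoch = 0))
  expect_true(file.exists(paste0(ck, ".json")))
  manifest <- jsonlite::read_json(paste0(ck, ".json"))
  expect_equal(manifest$seed, 302)
  m2 <- load_checkpoint(ck)
  expect_equal(predict_probs(m2, img), p1, tolerance = 1e-12)
  expect_equal(count_parameters(m2), count_parameters(m))
})

test_that("standard VGG16 convolutional checkpoints load by name map", {
  set.seed(303)
  cfg <- network_config(use_aspp = FALSE, use_cca = FALSE)
  m <- build_acunet(cfg)
  widths <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
  ins <- c(3, widths[-13])
  idx <- acunet:::VGG16_FEATURE_INDICES
  ckpt <- list()
  for (i in seq_along(idx)) {
    ckpt[[sprintf("features.%d.weight", idx[i])]] <-
      array(rnorm(widths[i] * ins[i] * 9, sd = 0.05),
            c(widths[i], ins[i], 3, 3))
    ckpt[[sprintf("features.%d.bias", idx[i])]] <- rnorm(widths[i], sd = 0.01)
  }
  load_vgg16_weights(m, ckpt)
  # weight layout check: our column index is 1 + ki + 3*kj + 9*c
  # (0-based ki, kj, c), matching the checkpoint's [o, c+1, ki+1, kj+1]
  w1 <- ckpt[["features.0.weight"]]
  l1 <- m$enc[[1]][[1]]
  expect_equal(l1$W[5, 1 + 0 + 3 * 2 + 9 * 1], w1[5, 2, 1, 3])
  expect_equal(l1$b, ckpt[["features.0.bias"]])
  probs <- predict_probs(m, array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_equal(apply(probs, c(1, 2), sum), matrix(1, 32, 32),
               tolerance = 1e-5)
  bad <- ckpt
  bad[["features.0.weight"]] <- array(0, c(64, 3, 5, 5))
  m3 <- build_acunet(cfg)
  expect_error(load_vgg16_weights(m3, bad), "shape mismatch")
  expect_error(
    load_vgg16_weights(build_acunet(tiny_config(use_aspp = FALSE,
                                                use_cca = FALSE)), ckpt),
    "width_scale")
})
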