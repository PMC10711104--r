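# Layer-level numerics: every backward pass is checked against central
# finite differences of its own forward pass.

test_that("dilated convolution forward/backward match finite differences", {
  set.seed(101)
  l <- acunet:::nn_conv2d(2, 3, k = 3, dilation = 2)
  acunet:::zero_grad_layer(l)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  y <- acunet:::layer_forward(l, x, train = TRUE)
  expect_identical(dim(y), c(8L, 8L, 3L))      # padding preserves size
  dy <- array(rnorm(length(y)), dim(y))
  dx <- acunet:::layer_backward(l, dy)
  gnum <- num_grad(function(xx)
    sum(acunet:::layer_forward(l, xx, FALSE) * dy), x)
  expect_equal(dx, gnum, tolerance = 1e-6)
  fW <- function(w) {
    old <- l$W; l$W <- w
    r <- sum(acunet:::layer_forward(l, x, FALSE) * dy)
    l$W <- old; r
  }
  expect_equal(l$dW, num_grad(fW, l$W), tolerance = 1e-6)
})

test_that("pooling, upsampling and batchnorm backward passes are exact", {
  set.seed(102)
  mp <- acunet:::nn_maxpool2()
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  y <- acunet:::layer_forward(mp, x, TRUE)
  expect_identical(dim(y), c(3L, 3L, 2L))
  dy <- array(rnorm(length(y)), dim(y))
  expect_equal(acunet:::layer_backward(mp, dy),
               num_grad(function(xx)
                 sum(acunet:::layer_forward(mp, xx, TRUE) * dy), x),
               tolerance = 1e-6)
  up <- acunet:::nn_upsample2()
  yu <- acunet:::layer_forward(up, y, TRUE)
  expect_identical(dim(yu), c(6L, 6L, 2L))
  dyu <- array(rnorm(length(yu)), dim(yu))
  expect_equal(acunet:::layer_backward(up, dyu),
               num_grad(function(xx)
                 sum(acunet:::layer_forward(up, xx, TRUE) * dyu), y),
               tolerance = 1e-6)
  bn <- acunet:::nn_batchnorm(3)
  bn$gamma <- runif(3, 0.5, 1.5); bn$beta <- rnorm(3)
  acunet:::zero_grad_layer(bn)
  xb <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  yb <- acunet:::layer_forward(bn, xb, TRUE)
  dyb <- array(rnorm(length(yb)), dim(yb))
  dxb <- acunet:::layer_backward(bn, dyb)
  expect_equal(dxb,
               num_grad(function(xx)
                 sum(acunet:::layer_forward(bn, xx, TRUE) * dyb), xb),
               tolerance = 1e-5)
})

test_that("criss-cross attention gradients match finite differences", {
  set.seed(103)
  cca <- build_cca(8, recurrence = 2, reduction = 4)
  for (l in list(cca, cca$convq, cca$convk, cca$convv))
    acunet:::zero_grad_layer(l)
  x <- array(rnorm(5 * 6 * 8, sd = 0.5), c(5, 6, 8))
  y <- acunet:::cca_forward(cca, x, train = TRUE)
  expect_identical(dim(y), dim(x))
  dy <- array(rnorm(length(y)), dim(y))
  dx <- acunet:::cca_backward(cca, dy)
  expect_equal(dx, num_grad(function(xx)
    sum(acunet:::cca_forward(cca, xx, FALSE) * dy), x),
    tolerance = 1e-5)
  fq <- function(w) {
    old <- cca$convq$W; cca$convq$W <- w
    r <- sum(acunet:::cca_forward(cca, x, FALSE) * dy)
    cca$convq$W <- old; r
  }
  expect_equal(cca$convq$dW, num_grad(fq, cca$convq$W), tolerance = 1e-5)
})

test_that("attention weights per position sum to one over the cross", {
  set.seed(104)
  Q <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  K <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  V <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  at <- acunet:::cca_attention_fwd_cpp(Q, K, V)
  for (i in 1:4) for (j in 1:5) {
    expect_equal(sum(at$Arow[, j, i]) + sum(at$Acol[, i, j]), 1)
    expect_equal(at$Acol[i, i, j], 0)        # duplicate self masked
  }
  # constant V: aggregation returns that constant (weights sum to 1)
  Vc <- array(rep(c(2, -1, 0.5), each = 20), c(4, 5, 3))
  atc <- acunet:::cca_attention_fwd_cpp(Q, K, Vc)
  expect_equal(atc$agg, Vc, tolerance = 1e-12)
})

test_that("two recurrences propagate a single-pixel perturbation everywhere", {
  set.seed(105)
  cca <- build_cca(8, recurrence = 2, reduction = 8)
  x <- array(rnorm(8 * 8 * 8, sd = 0.5), c(8, 8, 8))
  y0 <- acunet:::cca_forward(cca, x, FALSE)
  x2 <- x
  x2[3, 5, ] <- x2[3, 5, ] + 1
  y1 <- acunet:::cca_forward(cca, x2, FALSE)
  changed <- apply(abs(y1 - y0), c(1, 2), max) > 1e-12
  expect_true(all(changed))
  # a single pass only reaches the perturbed row and column
  cca1 <- build_cca(8, recurrence = 1, reduction = 8)
  z0 <- acunet:::cca_forward(cca1, x, FALSE)
  z1 <- acunet:::cca_forward(cca1, x2, FALSE)
  changed1 <- apply(abs(z1 - z0), c(1, 2), max) > 1e-12
  expect_false(all(changed1))
  expect_true(all(changed1[3, ]) && all(changed1[, 5]))
})

test_that("adam with zero learning rate leaves parameters unchanged", {
  set.seed(106)
  l <- acunet:::nn_conv2d(2, 2, k = 3)
  W0 <- l$W
  acunet:::zero_grad_layer(l)
  acunet:::adam_init_layer(l)
  l$dW <- matrix(rnorm(length(l$W)), nrow(l$W))
  acunet:::adam_step_layer(l, lr = 0, t = 1)
  expect_identical(l$W, W0)
  acunet:::adam_step_layer(l, lr = 0.1, t = 2)
  expect_false(identical(l$W, W0))
})
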