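# Dice, boundary and composite losses against hand-derived values and
# brute-force oracles.

test_that("dice loss reproduces the hand examples", {
  g <- array(c(1, 0, 0, 1), c(1, 2, 2))          # 2 pixels, 2 classes
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-5)
  s_disjoint <- array(c(0, 1, 1, 0), c(1, 2, 2))
  expect_equal(dice_loss(s_disjoint, g), 1, tolerance = 1e-5)
  s_half <- array(0.5, c(1, 2, 2))               # 1 - 2*1/(2+2)
  expect_equal(dice_loss(s_half, g), 0.5, tolerance = 1e-5)
  expect_error(dice_loss(array(0, c(0, 0, 2)), g), "empty|shape")
  expect_error(dice_loss(array(0.5, c(2, 2, 2)), array(1, c(3, 3, 2))),
               "shape")
})

test_that("dice loss stays in [0,1] and is class-permutation symmetric", {
  set.seed(21)
  for (i in 1:25) {
    h <- sample(2:6, 1); w <- sample(2:6, 1); C <- sample(2:4, 1)
    mask <- matrix(sample(0:(C - 1), h * w, TRUE), h, w)
    z <- array(rnorm(h * w * C), c(h, w, C))
    probs <- aperm(apply(z, c(1, 2), function(v) exp(v) / sum(exp(v))),
                   c(2, 3, 1))
    l <- dice_loss(probs, one_hot(mask, C))
    expect_gte(l, 0); expect_lte(l, 1)
    perm <- sample(C)
    expect_equal(dice_loss(probs[, , perm, drop = FALSE],
                           one_hot(mask, C)[, , perm, drop = FALSE]),
                 l, tolerance = 1e-12)
  }
})

test_that("signed distance maps match hand values and handle degeneracy", {
  phi <- signed_distance_map(matrix(c(0, 1, 0), 1, 3))
  expect_equal(as.vector(phi), c(1, -1, 1))
  expect_false(attr(phi, "degenerate"))
  all_bg <- signed_distance_map(matrix(0, 3, 3))
  expect_true(all(all_bg > 0))
  expect_true(attr(all_bg, "degenerate"))
  all_fg <- signed_distance_map(matrix(1, 3, 3))
  expect_true(all(all_fg < 0))
  expect_true(attr(all_fg, "degenerate"))
  # mirrored mask gives mirrored map
  set.seed(5)
  m <- matrix(sample(0:1, 30, TRUE), 5, 6)
  expect_equal(signed_distance_map(m[, 6:1]),
               signed_distance_map(m)[, 6:1], ignore_attr = TRUE)
})

test_that("signed distance maps equal brute-force nearest-opposite search", {
  set.seed(31)
  for (i in 1:40) {
    h <- sample(2:12, 1); w <- sample(2:12, 1)
    m <- matrix(sample(0:1, h * w, TRUE, prob = c(0.6, 0.4)), h, w)
    if (all(m == 0) || all(m == 1)) next
    expect_equal(unclass(signed_distance_map(m)), brute_signed_distance(m),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("boundary loss matches the 1x3 example and basic identities", {
  mask <- matrix(c(0, 1, 0), 1, 3)
  s <- array(c(1, 0, 1, 0, 1, 0), c(1, 3, 2))
  # phi = (1,-1,1); mean(phi * s_fg) = -1/3
  expect_equal(boundary_loss(s, one_hot(mask, 2)), -1 / 3)
  s0 <- array(c(1, 1, 1, 0, 0, 0), c(1, 3, 2))
  expect_equal(boundary_loss(s0, one_hot(mask, 2)), 0)
})

test_that("boundary loss is linear in the probabilities", {
  set.seed(8)
  mask <- matrix(sample(0:2, 36, TRUE), 6, 6)
  g <- one_hot(mask, 3)
  s1 <- array(runif(108), c(6, 6, 3))
  s2 <- array(runif(108), c(6, 6, 3))
  for (a in c(0, 0.25, 0.7, 1)) {
    expect_equal(boundary_loss(a * s1 + (1 - a) * s2, g),
                 a * boundary_loss(s1, g) + (1 - a) * boundary_loss(s2, g),
                 tolerance = 1e-12)
  }
})

test_that("moving probability mass into the true region decreases the loss", {
  # single foreground blob on a 4x4 grid; shifting mass from the farthest
  # outside pixel to an inside pixel must strictly decrease the loss
  mask <- matrix(0L, 4, 4); mask[2:3, 2:3] <- 1L
  g <- one_hot(mask, 2)
  s <- array(0, c(4, 4, 2)); s[, , 2] <- 0.25; s[, , 1] <- 0.75
  phi <- signed_distance_map(mask == 1L)
  far <- which(phi == max(phi), arr.ind = TRUE)[1, ]
  inside <- which(phi == min(phi), arr.ind = TRUE)[1, ]
  l0 <- boundary_loss(s, g)
  s2 <- s
  s2[far[1], far[2], 2] <- s2[far[1], far[2], 2] - 0.2
  s2[inside[1], inside[2], 2] <- s2[inside[1], inside[2], 2] + 0.2
  expect_lt(boundary_loss(s2, g), l0)
})

test_that("composite loss is the exact weighted sum", {
  set.seed(13)
  mask <- matrix(sample(0:2, 25, TRUE), 5, 5)
  g <- one_hot(mask, 3)
  z <- array(rnorm(75), c(5, 5, 3))
  probs <- aperm(apply(z, c(1, 2), function(v) exp(v) / sum(exp(v))),
                 c(2, 3, 1))
  expect_equal(dice_boundary_loss(probs, g, weight = 0),
               dice_loss(probs, g))
  expect_equal(dice_boundary_loss(probs, g, weight = 1),
               dice_loss(probs, g) + boundary_loss(probs, g))
  expect_equal(dice_boundary_loss(probs, g, weight = 2.5),
               dice_loss(probs, g) + 2.5 * boundary_loss(probs, g))
  expect_error(dice_boundary_loss(probs, g, weight = -1), "non-negative")
  # perfect prediction: dice term ~0, composite equals the (non-positive)
  # boundary term at s = g
  expect_equal(dice_boundary_loss(g, g), boundary_loss(g, g),
               tolerance = 1e-5)
  expect_lte(dice_boundary_loss(g, g), 0)
})

test_that("loss gradients agree with finite differences on a 4x4 instance", {
  set.seed(17)
  mask <- matrix(sample(0:2, 16, TRUE), 4, 4)
  z <- array(rnorm(48), c(4, 4, 3))
  probs <- aperm(apply(z, c(1, 2), function(v) exp(v) / sum(exp(v))),
                 c(2, 3, 1))
  lg <- acunet:::loss_and_grad(probs, mask, "dice_boundary", 1)
  gnum <- num_grad(function(p)
    dice_boundary_loss(p, one_hot(mask, 3)), probs)
  expect_equal(lg$grad, gnum, tolerance = 1e-4)
})
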