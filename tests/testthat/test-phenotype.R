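# HSV selection, Otsu thresholding, crown phenotyping, OLS.

test_that("pure-colour probes hit the expected palette entries", {
  img <- array(0, c(1, 4, 3))
  img[1, 1, ] <- c(0, 255, 0)      # pure green -> H 60, S 255, V 255
  img[1, 2, ] <- c(255, 0, 0)      # pure red -> H 0
  img[1, 3, ] <- c(0, 0, 0)        # black -> V 0
  img[1, 4, ] <- c(0, 0, 255)      # pure blue -> H 120
  hsv <- rgb_to_hsv_cv(img)
  expect_equal(hsv[1, 1, ], c(60, 255, 255))
  expect_true(hsv_mask(img, "green")[1, 1])
  expect_true(hsv_mask(img, "red")[1, 2])
  expect_true(hsv_mask(img, "black")[1, 3])
  expect_true(hsv_mask(img, "blue")[1, 4])
  expect_false(hsv_mask(img, "green")[1, 3])   # black rejected by green
  expect_false(hsv_mask(img, "green")[1, 2])
  expect_error(hsv_mask(img, "mauve"), "unknown")
})

test_that("chromatic palette ranges partition hue space in the colour band", {
  pal <- hsv_palette()
  chroma <- c("red", "orange", "yellow", "green", "cyan", "blue", "purple")
  for (H in 0:180) {
    rgb <- acunet:::hsv_cv_to_rgb(H, 200, 180)
    probe <- array(rgb, c(1, 1, 3))
    hits <- vapply(chroma, function(nm) hsv_mask(probe, pal[[nm]])[1, 1],
                   logical(1))
    expect_equal(sum(hits), 1L, info = paste("H =", H))
  }
})

test_that("otsu threshold reproduces the worked examples", {
  expect_identical(otsu_threshold(matrix(c(rep(0, 50), rep(255, 50)),
                                         10, 10)), 0L)
  expect_identical(otsu_threshold(matrix(c(rep(10, 90), rep(200, 10)),
                                         10, 10)), 10L)
  expect_error(otsu_threshold(matrix(128, 4, 4)), "degenerate")
})

test_that("otsu equals the exhaustive sweep oracle on random images", {
  set.seed(53)
  for (i in 1:50) {
    g <- matrix(sample(0:255, 256, TRUE,
                       prob = stats::runif(256)^2), 16, 16)
    if (length(unique(as.vector(g))) < 2) next
    expect_identical(otsu_threshold(g), brute_otsu(g))
  }
})

test_that("crown area follows half height times width, scaled", {
  mk <- matrix(0L, 300, 300)
  mk[101:300, 150] <- 1L            # stem rows 101..300: height 200 px
  mk[101:140, 101:200] <- 2L        # leaves cols 101..200: width 100 px
  r <- crown_area(mk, 0.1)
  expect_equal(r$height_px, 200L)
  expect_equal(r$crown_width_px, 100L)
  expect_equal(r$crown_area, 100)   # 0.5 * 20 cm * 10 cm
  expect_equal(crown_area(mk, 0.2)$crown_area, 400)  # quadratic in scale
  expect_error(crown_area(matrix(0L, 5, 5), 0.1), "foreground")
})

test_that("crown area ignores background and is translation invariant", {
  mk <- matrix(0L, 64, 64)
  mk[20:50, 30] <- 1L; mk[18:28, 24:40] <- 2L
  r1 <- crown_area(mk, 0.05)
  shifted <- matrix(0L, 64, 64)
  shifted[7:64, 1:45] <- mk[1:58, 16:60]   # shift up-left inside frame
  r2 <- crown_area(shifted, 0.05)
  expect_equal(r1$crown_area, r2$crown_area)
  expect_equal(r1$height_px, r2$height_px)
})

test_that("class proportions count pixels and rescale to ten units", {
  m <- matrix(c(rep(0L, 70), rep(1L, 10), rep(2L, 20)), 10, 10)
  p <- class_proportions(m)
  expect_equal(unname(p$fractions), c(0.7, 0.1, 0.2))
  expect_equal(unname(p$ten_unit), c(7, 1, 2))
  expect_equal(unname(class_proportions(matrix(0L, 4, 4))$fractions),
               c(1, 0, 0))
  set.seed(3)
  rnd <- matrix(sample(0:2, 100, TRUE), 10, 10)
  expect_equal(sum(class_proportions(rnd)$fractions), 1)
})

test_that("predicted-vs-actual OLS matches closed form", {
  f <- fit_predicted_vs_actual(c(1, 2, 3), c(1, 2, 3))
  expect_equal(f$slope, 1); expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  f2 <- fit_predicted_vs_actual(c(1, 2, 3), c(3, 5, 7))
  expect_equal(f2$slope, 2); expect_equal(f2$r_squared, 1)
  pred <- c(1, 2, 3); act <- c(1.1, 1.9, 3.2)
  f3 <- fit_predicted_vs_actual(pred, act)
  b <- cov(pred, act) / var(pred)
  a <- mean(act) - b * mean(pred)
  ss_res <- sum((act - a - b * pred)^2)
  ss_tot <- sum((act - mean(act))^2)
  expect_equal(f3$slope, b)
  expect_equal(f3$r_squared, 1 - ss_res / ss_tot)
  expect_error(fit_predicted_vs_actual(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(fit_predicted_vs_actual(1:2, 1:2), "3 points")
})

test_that("the prediction-overlay phenotype chain recovers the direct record", {
  mk <- matrix(0L, 80, 80)
  mk[21:80, 40:41] <- 1L
  mk[21:40, 26:55] <- 2L
  direct <- crown_area(mk, 0.1)
  chained <- phenotype_from_mask(mk, 0.1)
  expect_equal(chained$crown_area, direct$crown_area)
  expect_equal(chained$height_px, direct$height_px)
  expect_equal(chained$crown_width_px, direct$crown_width_px)
})
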