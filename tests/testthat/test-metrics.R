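test_that("median_subtract centres at the median", {
  expect_equal(median_subtract(matrix(3, 5, 5)), matrix(0, 5, 5))
  img <- matrix(c(0, 0, 0, -4), 2, 2)
  expect_equal(median_subtract(img), img)   # median of {0,0,0,-4} is 0
  set.seed(1)
  r <- matrix(rnorm(64), 8, 8)
  expect_equal(median(median_subtract(r)), 0)
})

test_that("eval_mask thresholds strictly at half the extremum", {
  img <- matrix(0, 8, 8); img[3, 5] <- -1
  cen <- median_subtract(img)
  m <- eval_mask(cen, "below")
  expect_equal(which(m), which(img == -1))
  # sign symmetry
  m2 <- eval_mask(median_subtract(-img), "above")
  expect_equal(which(m2), which(m))
  # a pixel exactly at half the minimum is excluded (strict inequality)
  img3 <- matrix(0, 8, 8); img3[2, 2] <- -1; img3[5, 5] <- -0.5
  m3 <- eval_mask(median_subtract(img3), "below")
  expect_false(m3[5, 5])
  expect_true(m3[2, 2])
  expect_warning(eval_mask(matrix(0, 4, 4), "below"), "empty")
})

test_that("amplitude response sums the in-mask amplitude", {
  img <- matrix(0, 8, 8); img[3, 5] <- -1
  cen <- median_subtract(img)
  m <- eval_mask(cen, "below")
  expect_equal(amplitude_response(cen, m), -1)
  # linear in the image for a fixed mask
  expect_equal(amplitude_response(3 * cen, m), -3)
  expect_true(is.na(amplitude_response(cen, matrix(FALSE, 8, 8))))
})

test_that("position error is the centroid distance in pixels", {
  # mask centroid at (0, 0), truth (3, 4) -> 5
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE
  expect_equal(position_error(m, c(3, 4)), 5)
  # centroid at the truth -> 0
  m2 <- matrix(FALSE, 9, 9); m2[4:6, 4:6] <- TRUE
  expect_equal(position_error(m2, c(4, 4)), 0)
  # adding a point-symmetric pixel pair about the centroid changes nothing
  m3 <- m2; m3[2, 3] <- TRUE; m3[8, 7] <- TRUE
  expect_equal(position_error(m3, c(4, 4)), 0)
  expect_true(is.na(position_error(matrix(FALSE, 4, 4), c(0, 0))))
})

test_that("ringing is the population std outside the mask", {
  img <- matrix(0, 4, 4)
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE
  expect_equal(ringing(img, m), 0)
  img2 <- matrix(c(-1, 1), 4, 4)      # outside values split evenly
  m2 <- matrix(FALSE, 4, 4)
  expect_equal(ringing(img2, m2), 1)  # mean 0, population variance 1
  # shift invariance of the std
  expect_equal(ringing(img2 + 5, m2), 1)
  expect_true(is.na(ringing(img2, matrix(TRUE, 4, 4))))
})

test_that("figures_of_merit absorbs global offsets via the median", {
  ps <- single_target_phantom(t_xy = c(8, -6), size = 5)
  img <- rasterize_target(ps, 28)
  tp <- position_to_pixels(c(8, -6), 28)
  f1 <- figures_of_merit(img, tp, "below")
  f2 <- figures_of_merit(img + 123.4, tp, "below")
  expect_equal(f1$AR, f2$AR)
  expect_equal(f1$PE, f2$PE)
  expect_equal(f1$RNG, f2$RNG)
  # the rasterized truth evaluates against itself nearly perfectly
  expect_lt(f1$PE, 1)
  expect_equal(f1$RNG, 0)
})

test_that("summarize_series reports mean and sample sd in table order", {
  mk <- function(ar, pe, rng)
    structure(list(AR = ar, PE = pe, RNG = rng), class = "figures_of_merit")
  s <- summarize_series(list(mk(0, 1, 2), mk(2, 1, 2)))
  expect_equal(s$metric, c("AR", "PE", "RNG"))
  expect_equal(s$mean, c(1, 1, 2))
  expect_equal(s$sd[1], sd(c(0, 2)))
  # identical entries -> zero sd
  s2 <- summarize_series(list(mk(1, 2, 3), mk(1, 2, 3)))
  expect_equal(s2$sd, rep(0, 3))
  # flagged missing values excluded with count
  s3 <- summarize_series(list(mk(1, NA, 3), mk(3, NA, 3), mk(2, NA, 3)))
  expect_equal(s3$n_missing[s3$metric == "PE"], 3L)
  expect_equal(s3$n_used[s3$metric == "AR"], 3L)
})
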