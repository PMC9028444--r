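sample_pair <- function(seed = 1) {
  set.seed(seed)
  mk <- function(s) {
    v <- eim_valid_mask()
    m <- matrix(0, 16, 16)
    m[v] <- runif(208, 0.5, 2)    # positive voltages: harmonic blend benign
    eit_sample(structure(m, class = c("eim", "matrix", "array")),
               matrix(runif(4096, 0, 1), 64, 64))
  }
  list(a = mk(), b = mk())
}

test_that("measurement-noise augmentations preserve the zero pattern", {
  e <- random_eim(4)
  v <- eim_valid_mask()
  expect_identical(apply_thermal_jitter(e, 0), e)
  expect_identical(apply_quantization(e, 0), e)
  expect_identical(apply_channel_gain(e, 0), e)
  set.seed(1)
  for (f in list(function(x) apply_thermal_jitter(x, 1e-2),
                 function(x) apply_quantization(x, 1e-2),
                 function(x) apply_channel_gain(x, 1e-2))) {
    out <- f(e)
    expect_true(all(out[!v] == 0))
    expect_false(identical(out, e))
  }
})

test_that("quantization noise has the half-normal mean absolute change", {
  e <- random_eim(5)
  v <- eim_valid_mask()
  set.seed(2)
  deltas <- replicate(60, {
    out <- apply_quantization(e, 1e-3)
    mean(abs(out[v] - e[v]))
  })
  expect_lt(abs(mean(deltas) - 1e-3 * sqrt(2 / pi)) / (1e-3 * sqrt(2 / pi)),
            0.05)
})

test_that("channel gain applies one multiplier per injection row", {
  e <- random_eim(6)
  v <- eim_valid_mask()
  set.seed(3)
  out <- apply_channel_gain(e, 0.3)
  for (k in 1:16) {
    ratios <- out[k, v[k, ]] / e[k, v[k, ]]
    expect_lt(diff(range(ratios)), 1e-12)
  }
  set.seed(9); a <- apply_channel_gain(e, 0.3)
  set.seed(9); b <- apply_channel_gain(e, 0.3)
  expect_identical(a, b)
})

test_that("alpha_blend is linear in targets and harmonic in voltages", {
  p <- sample_pair(7)
  expect_identical(alpha_blend(p$a, p$b, 1), p$a)
  expect_identical(alpha_blend(p$a, p$b, 0), p$b)

  # worked harmonic value: U1 = 1, U2 = 1/3, alpha = 0.5 -> 0.5
  expect_equal(blend_voltages(1, 1 / 3, 0.5), 0.5)

  out <- alpha_blend(p$a, p$b, 0.3)
  expect_equal(out$target, 0.3 * p$a$target + 0.7 * p$b$target)
  v <- eim_valid_mask()
  expect_true(all(unclass(out$eim)[!v] == 0))

  # blending a sample with itself is the identity at any alpha
  self <- alpha_blend(p$a, p$a, 0.42)
  expect_equal(self$target, p$a$target)
  expect_equal(unclass(self$eim), unclass(p$a$eim), tolerance = 1e-12)

  # opposite-sign voltages fall back to the linear blend, finite always
  g <- blend_voltages(1, -1, 0.5)
  expect_true(is.finite(g))
  expect_equal(g, 0)
})

test_that("expand_rotations emits 16 consistently rotated samples", {
  p <- sample_pair(8)$a
  out <- expand_rotations(p)
  expect_length(out, 16L)
  expect_identical(out[[1]], p)
  # n = 8 target is the exact 180-degree pixel permutation
  r180 <- p$target[64:1, 64:1]
  expect_identical(out[[9]]$target, r180)
  # EIM side: n = 4 then n = 12 returns the original exactly
  e4 <- out[[5]]$eim
  expect_identical(unclass(shift_eim(e4, 12)), unclass(p$eim))
  # all zero patterns intact
  v <- eim_valid_mask()
  for (s in out) expect_true(all(unclass(s$eim)[!v] == 0))
})

test_that("rotation expansion commutes with channel gain up to row relabeling", {
  p <- sample_pair(9)$a
  n <- 5
  set.seed(4)
  gained <- apply_channel_gain(p$eim, 0.2)
  shifted_then <- shift_eim(gained, n)
  set.seed(4)
  gains <- rnorm(16, 1, 0.2)
  shifted_first <- shift_eim(p$eim, n)
  manual <- unclass(shifted_first) * gains[(((0:15) - n) %% 16) + 1]
  expect_equal(unclass(shifted_then), manual, tolerance = 1e-12)
})
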