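test_that("receptive field follows the stride-1 kernel arithmetic", {
  expect_identical(receptive_field(net_config()), 21L)
  expect_identical(receptive_field(net_config_small()), 21L)
  expect_identical(receptive_field(
    net_config(conv_channels = 4L, kernel = 3L)), 3L)
  expect_identical(receptive_field(
    net_config(conv_channels = c(4L, 4L), kernel = 5L)), 9L)
})

test_that("initialization is seeded and the census matches the design", {
  cfg <- tiny_config()
  a <- init_network(cfg, seed = 5)
  b <- init_network(cfg, seed = 5)
  expect_identical(a[c("conv", "W1", "b1", "W2", "b2")],
                   b[c("conv", "W1", "b1", "W2", "b2")])
  cen <- param_census(a)
  expect_identical(cen$n_dense, 2L)
  expect_identical(cen$n_pooling, 0L)
  expect_identical(cen$shared_rows, 16L)
  # default config head input: 16 rows x 2048 features
  d <- net_config()
  expect_identical(d$row_feature_width, 2048L)
  expect_identical(nrow(init_network(tiny_config(), 1)$W1),
                   tiny_config()$row_feature_width)
  expect_error(net_config(head_widths = c(128L, 1024L)), "grid_size")
})

test_that("forward_pass emits a finite 64 x 64 image", {
  p <- init_network(tiny_config(), seed = 2)
  e <- random_eim(1)
  img <- forward_pass(p, e)
  expect_equal(dim(img), c(64L, 64L))
  expect_true(all(is.finite(img)))
  expect_true(all(img > -1))          # expm1 head: MSLE domain safe
  bad <- unclass(e); bad[2, 5] <- NA
  expect_error(forward_pass(p, structure(bad, class = class(e))),
               "non-finite")
})

test_that("the conv front end is exactly shift equivariant", {
  p <- init_network(tiny_config(), seed = 3)
  e <- random_eim(2)
  F0 <- conv_features(p, e)
  for (n in c(1, 4, 6, 11)) {
    Fn <- conv_features(p, shift_eim(e, n))
    idx <- ((0:15 - n) %% 16) + 1
    # exact up to floating-point associativity in the layer-norm sums
    expect_lt(max(abs(Fn - F0[idx, idx, , drop = FALSE])), 1e-12)
  }
})

test_that("the full network is exactly equivariant at 90-degree shifts", {
  p <- init_network(tiny_config(), seed = 4)
  e <- random_eim(3)
  img <- forward_pass(p, e)
  for (n in c(4, 8, 12)) {
    a <- forward_pass(p, shift_eim(e, n))
    b <- rot_image(img, n)
    expect_lt(max(abs(a - b)), 1e-12)
  }
})

test_that("permuting head rows permutes per-row outputs (shared weights)", {
  # with canonicalized rows and plain mean aggregation, a diagonal shift
  # only permutes which row produces which canonical map; the row-shared
  # head therefore leaves the mean unchanged for every shift
  p <- init_network(tiny_config(aggregation = "mean"), seed = 6)
  e <- random_eim(4)
  for (n in c(1, 5, 10))
    expect_equal(forward_pass(p, shift_eim(e, n)), forward_pass(p, e),
                 tolerance = 1e-12)
})

test_that("loss_w2 sums squared weights (literal mode available)", {
  expect_equal(loss_w2(c(3, 4)), 25)
  expect_equal(loss_w2(c(3, 4), squared = FALSE), 7)
  p <- init_network(tiny_config(), seed = 7)
  for (l in seq_along(p$conv)) p$conv[[l]]$W[] <- 0
  p$W1[] <- 0; p$W2[] <- 0
  expect_equal(loss_w2(p), 0)
})

test_that("loss_tv is the anisotropic neighbour sum without wraparound", {
  expect_equal(loss_tv(matrix(5, 8, 8)), 0)
  expect_equal(loss_tv(matrix(c(0, 0, 1, 1), 2, 2)), 2)
  set.seed(8)
  img <- matrix(rnorm(64), 8, 8)
  expect_equal(loss_tv(-3.5 * img), 3.5 * loss_tv(img))
})

test_that("loss_msle matches its closed forms", {
  t1 <- matrix(0.3, 4, 4)
  expect_equal(loss_msle(t1, t1), 0)
  expect_equal(loss_msle(matrix(0, 64, 64), matrix(exp(1) - 1, 64, 64)), 1)
  a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
  expect_equal(loss_msle(a, b), loss_msle(b, a))
  expect_gte(loss_msle(a, b), 0)
  expect_error(loss_msle(matrix(-2, 2, 2), matrix(0, 2, 2)), "-1")
})

test_that("loss_total composes the components with the printed weights", {
  w <- loss_weights("printed")
  expect_equal(w$tv_weight, 0.1)
  expect_equal(w$msle_weight, 1e-6)
  expect_equal(loss_total(weights = w,
                          components = c(w2 = 1, tv = 10, msle = 1e6)), 3)
  # zero components give zero
  expect_equal(loss_total(weights = w,
                          components = c(w2 = 0, tv = 0, msle = 0)), 0)
  # monotone in each component
  base <- loss_total(weights = w, components = c(w2 = 1, tv = 1, msle = 1))
  for (nm in c("w2", "tv", "msle")) {
    cmp <- c(w2 = 1, tv = 1, msle = 1); cmp[nm] <- cmp[nm] + 1
    expect_gt(loss_total(weights = w, components = cmp), base)
  }
})
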