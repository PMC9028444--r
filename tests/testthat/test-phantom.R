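test_that("inverse_transform applies translation, rotation, then scaling", {
  id <- shape_spec("sphere")
  pts <- rbind(c(1, 2, 3), c(0, 0, 0))
  expect_equal(inverse_transform(pts, id), pts)

  tr <- shape_spec("sphere", t = c(1, 0, 0))
  expect_equal(inverse_transform(rbind(c(1, 0, 0)), tr),
               rbind(c(0, 0, 0)))

  sc <- shape_spec("sphere", s = c(2, 2, 2))
  expect_equal(inverse_transform(rbind(c(2, 0, 0)), sc),
               rbind(c(1, 0, 0)))

  # rotation acts after translation: shape frame sees rotated offsets
  rot <- shape_spec("sphere", t = c(1, 0, 0), euler = c(0, 0, pi / 2))
  got <- inverse_transform(rbind(c(1, 1, 0)), rot)
  expect_equal(as.numeric(got), c(-1, 0, 0), tolerance = 1e-12)

  expect_error(shape_spec("sphere", s = c(0, 1, 1)), "zero scaling")
})

test_that("shape masks implement the three unit-shape inequalities", {
  origin <- rbind(c(0, 0, 0))
  for (k in c("sphere", "cube", "octahedron"))
    expect_true(shape_mask(k, origin))

  corner <- rbind(c(1, 1, 1))
  expect_true(shape_mask("cube", corner))
  expect_false(shape_mask("octahedron", corner))
  expect_true(shape_mask("sphere", rbind(c(1, 0, 0))))  # boundary inclusive
  expect_false(shape_mask("sphere", corner))
  expect_error(shape_mask("pyramid", origin))
})

test_that("enclosure sampling respects the printed ranges", {
  set.seed(42)
  r <- 28
  specs <- replicate(2000, sample_enclosure(r), simplify = FALSE)
  s_all <- do.call(rbind, lapply(specs, `[[`, "s"))
  expect_gte(min(s_all), 0.1 * r)
  expect_lte(max(s_all), 0.8 * r)
  t_all <- do.call(rbind, lapply(specs, `[[`, "t"))
  expect_true(all(sqrt(t_all[, 1]^2 + t_all[, 2]^2) <= 0.8 * r))
  # contrast log-uniform on [-2, 2]
  lc <- log10(vapply(specs, `[[`, numeric(1), "contrast"))
  ks <- suppressWarnings(ks.test(lc, "punif", -2, 2))
  expect_gt(ks$p.value, 0.01)
  # all three kinds drawn
  expect_setequal(unique(vapply(specs, `[[`, character(1), "kind")),
                  c("sphere", "cube", "octahedron"))
  # determinism
  set.seed(7); a <- sample_enclosure(r)
  set.seed(7); b <- sample_enclosure(r)
  expect_identical(a, b)
})

test_that("background conductivity is log-uniform on [1e-5, 1]", {
  set.seed(11)
  draws <- replicate(5000, sample_background())
  expect_gte(min(draws), 1e-5)
  expect_lte(max(draws), 1)
  ks <- suppressWarnings(ks.test(log10(draws), "punif", -5, 0))
  expect_gt(ks$p.value, 0.01)
  set.seed(3); a <- sample_background()
  set.seed(3); b <- sample_background()
  expect_identical(a, b)
})

test_that("perturb_field is a unit-mean multiplicative jitter", {
  v <- rep(2, 10000)
  expect_identical(perturb_field(v, 0), v)
  set.seed(5)
  out <- perturb_field(v, 1e-2)
  expect_length(out, length(v))
  expect_true(all(out > 0))
  # CLT bound on the multiplier mean
  expect_lt(abs(mean(out / v) - 1), 3 * 1e-2 / sqrt(10000))
  expect_error(perturb_field(v, -1), "std")
})

test_that("build_phantom paints enclosures over the background", {
  m <- mesh_coarse()
  # no enclosures -> uniform
  ph <- build_phantom(m, phantom_spec(0.3, perturb_std = 0))
  expect_equal(ph$sigma, rep(0.3, m$n_elem))

  # one centred sphere at contrast 10
  enc <- shape_spec("sphere", s = c(8, 8, 8), contrast = 10, radius = 28)
  ph2 <- build_phantom(m, phantom_spec(0.1, list(enc), perturb_std = 0))
  r2 <- rowSums(m$centroid^2)
  expect_equal(ph2$sigma[r2 <= 8^2 * 0.9], rep(1.0, sum(r2 <= 8^2 * 0.9)))
  expect_equal(ph2$sigma[r2 > 8^2 * 1.1], rep(0.1, sum(r2 > 8^2 * 1.1)))

  # overlapping enclosures: later one wins
  enc_a <- shape_spec("sphere", s = c(8, 8, 8), contrast = 10, radius = 28)
  enc_b <- shape_spec("sphere", s = c(5, 5, 5), contrast = 0.1, radius = 28)
  ph3 <- build_phantom(m, phantom_spec(0.1, list(enc_a, enc_b),
                                       perturb_std = 0))
  expect_equal(ph3$sigma[r2 <= 5^2 * 0.9],
               rep(0.1 * 0.1, sum(r2 <= 5^2 * 0.9)))
  expect_true(all(ph3$sigma > 0))

  # deterministic given spec when perturbation is off
  expect_identical(ph2$sigma,
                   build_phantom(m, phantom_spec(0.1, list(enc),
                                                 perturb_std = 0))$sigma)
})

test_that("rasterize_target follows the pixel conventions", {
  ps <- phantom_spec(0.2)
  img <- rasterize_target(ps, 28)
  expect_equal(dim(img), c(64L, 64L))
  expect_true(all(img == 0.2))

  # centred disc area within 10% of analytic
  enc <- shape_spec("sphere", s = c(8, 8, 8), contrast = 10, radius = 28)
  img2 <- rasterize_target(phantom_spec(0.1, list(enc)), 28)
  rp <- 8 / (2 * 28 / 64)
  expect_lt(abs(sum(img2 == 1) - pi * rp^2) / (pi * rp^2), 0.1)

  # off-centre target lands at the converted pixel position (y-down)
  enc3 <- shape_spec("sphere", t = c(10, 4, 0), s = c(4, 4, 4),
                     contrast = 0.1, radius = 28)
  img3 <- rasterize_target(phantom_spec(0.1, list(enc3)), 28)
  idx <- which(img3 < 0.05, arr.ind = TRUE)
  cen <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)   # (x, y) 0-based
  expect_equal(cen, unname(position_to_pixels(c(10, 4), 28)),
               tolerance = 0.05)
})

test_that("phantom specs round-trip through YAML", {
  set.seed(9)
  spec <- sample_phantom_spec(28, n_enclosures = 2)
  txt <- phantom_spec_to_yaml(spec)
  back <- phantom_spec_from_yaml(yaml_text = txt)
  expect_equal(back$sigma_bg, spec$sigma_bg)
  expect_equal(length(back$enclosures), 2L)
  expect_equal(back$enclosures[[1]]$t, spec$enclosures[[1]]$t,
               tolerance = 1e-9)
  expect_equal(back$enclosures[[2]]$contrast, spec$enclosures[[2]]$contrast,
               tolerance = 1e-9)
})

test_that("mask membership is invariant under joint 22.5-degree rotations", {
  m <- mesh_coarse()
  pts <- cbind(m$centroid, 0)
  set.seed(21)
  for (rep in 1:5) {
    spec <- sample_enclosure(28)
    n <- sample(0:15, 1)
    inside <- shape_mask(spec$kind, inverse_transform(pts, spec))
    spec_r <- rotate_shape_spec(spec, n)
    phi <- 2 * pi * n / 16
    Rz <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    pts_r <- cbind(m$centroid %*% t(Rz), 0)
    inside_r <- shape_mask(spec_r$kind, inverse_transform(pts_r, spec_r))
    expect_equal(inside_r, inside)
  }
})
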