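test_that("the symmetric mesh discretizes the disc", {
  m <- mesh_coarse()
  expect_length(m$electrodes, 16L)
  expect_true(all(m$area > 0))
  # area converges to the disc from below; coarse polygons sit within ~2%
  expect_lt(abs(sum(m$area) - pi * 28^2) / (pi * 28^2), 0.02)
  mf <- mesh_fine()
  expect_lt(abs(sum(mf$area) - pi * 28^2) / (pi * 28^2), 0.01)
  # rotating the node set by one pitch maps it onto itself
  th <- 2 * pi / 16
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rotated <- m$nodes %*% t(R)
  expect_equal(rotated[order(m$node_perm), ], m$nodes, tolerance = 1e-10)
})

test_that("the forward solver obeys reciprocity", {
  m <- mesh_coarse()
  set.seed(10)
  sigma <- runif(m$n_elem, 0.01, 0.5)
  fr <- simulate_voltages(m, sigma)
  pat <- adjacent_pattern()
  V <- matrix(NA_real_, 16, 16)
  V[cbind(pat$inj + 1, pat$meas + 1)] <- as.numeric(fr)
  expect_lt(max(abs(V - t(V)) / pmax(abs(V), 1e-300), na.rm = TRUE), 1e-6)
})

test_that("scaling conductivity and contact impedance scales voltages", {
  m <- mesh_coarse()
  set.seed(11)
  sigma <- runif(m$n_elem, 0.05, 0.2)
  el <- electrode_model()
  f1 <- as.numeric(simulate_voltages(m, sigma, el))
  cc <- 7
  el2 <- electrode_model(contact_impedance = el$z / cc)
  f2 <- as.numeric(simulate_voltages(m, cc * sigma, el2))
  expect_lt(max(abs(f2 - f1 / cc) / abs(f1 / cc)), 1e-8)
})

test_that("a homogeneous phantom gives rotationally repeating injections", {
  m <- mesh_fine()
  fr <- simulate_voltages(m, rep(0.1, m$n_elem))
  e <- unclass(build_eim(fr))
  # measurement at fixed offset d from the injection pair is the same for
  # every injection on the symmetric mesh
  for (d in 2:14) {
    vals <- e[cbind(1:16, ((0:15 + d) %% 16) + 1)]
    expect_lt(max(abs(vals - vals[1]) / abs(vals[1])), 1e-6)
  }
})

test_that("rotating the phantom diagonally shifts the EIM", {
  m <- mesh_fine()
  ps <- single_target_phantom(t_xy = c(10, 4))
  e0 <- build_eim(simulate_voltages(m, build_phantom(m, ps)))
  for (n in c(1, 3, 8)) {
    ps_r <- rotate_phantom_spec(ps, n)
    e1 <- build_eim(simulate_voltages(m, build_phantom(m, ps_r)))
    shifted <- shift_eim(e0, n)
    expect_lt(max(abs(e1 - shifted) / pmax(abs(shifted), 1e-12)), 1e-3)
  }
})

test_that("contact impedance sampling is unit-mean and clamped positive", {
  expect_equal(sample_contact_impedance(1e-2, 0), rep(1e-2, 16))
  set.seed(12)
  draws <- replicate(1000, sample_contact_impedance(1, 1e-1))
  expect_lt(abs(mean(draws) - 1), 0.01)
  expect_true(all(draws > 0))
  set.seed(5); a <- sample_contact_impedance(1e-2, 1e-3)
  set.seed(5); b <- sample_contact_impedance(1e-2, 1e-3)
  expect_identical(a, b)
})

test_that("add_awgn_snr hits the requested SNR", {
  m <- mesh_coarse()
  fr <- simulate_voltages(m, rep(0.1, m$n_elem))
  v <- as.numeric(fr)
  set.seed(13)
  hi <- add_awgn_snr(fr, 200)
  expect_lt(sqrt(sum((as.numeric(hi) - v)^2)) / sqrt(sum(v^2)), 1e-9)
  # empirical SNR at 20 dB over repetitions
  set.seed(14)
  snr_hat <- replicate(300, {
    nz <- as.numeric(add_awgn_snr(fr, 20)) - v
    10 * log10(sum(v^2) / sum(nz^2))
  })
  expect_lt(abs(mean(snr_hat) - 20), 0.5)
  set.seed(6); a <- add_awgn_snr(fr, 30)
  set.seed(6); b <- add_awgn_snr(fr, 30)
  expect_identical(as.numeric(a), as.numeric(b))
})
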