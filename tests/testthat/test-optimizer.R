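cfg_small <- oes_config(pad_size = 256)

test_that("vessel image has one unit-magnitude voxel per vessel", {
  v1 <- vessel_set("a", 0, 0)
  img <- build_vessel_image(v1, 0)
  expect_equal(sum(abs(img)), 1)
  o <- attr(img, "origin")
  expect_equal(img[o[1], o[2]], 1 + 0i)
  # Euler identity at theta = pi/2
  img <- build_vessel_image(v1, pi / 2)
  expect_equal(img[o[1], o[2]], 0 + 1i)
  # four vessels -> exactly four nonzero voxels, each unit magnitude
  v4 <- neck_vessels()
  img4 <- build_vessel_image(v4, c(0.1, -0.2, 3, -3))
  nz <- abs(img4) > 0
  expect_equal(sum(nz), 4)
  expect_equal(abs(img4[nz]), rep(1, 4))
})

test_that("coincident vessels are rejected as unresolvable", {
  v <- vessel_set(c("a", "b"), c(0.2, -0.2), c(0, 0))  # both snap to origin
  expect_error(build_vessel_image(v, c(0, 0)), "same voxel")
  expect_error(optimize_encoding(v, c(0, 0)), "same voxel")
})

test_that("mask cutoff enforces the four-times-motion wavelength rule", {
  cfg <- oes_config(pad_size = 256, max_motion = 4)
  expect_equal(oesasl:::k_cutoff(cfg), 1 / 16)
  spec <- matrix(1 + 0i, 256, 256)
  out <- weight_and_mask(spec, cfg)
  fx <- oesasl:::fft_freqs(256)
  kr <- sqrt(outer(fx^2, fx^2, `+`))
  # any bin beyond the cutoff is exactly zero, e.g. |k| ~ 0.07 cycles/mm
  expect_true(all(abs(out[kr > 1 / 16 & kr < 0.08]) == 0))
  expect_true(all(abs(out[kr > 0.069 & kr < 0.071]) == 0))
  # weight is 1 at DC and radially non-increasing
  expect_equal(out[1, 1], 1 + 0i)
  r <- sort(unique(round(kr[kr <= 1 / 16], 10)))
  w <- oesasl:::k_weight(r, cfg)
  expect_true(all(diff(w) <= 0))
  # masked support is a discrete disc of the right area
  cnt <- sum(abs(out) > 0)
  rbin <- 256 / 16
  expect_lt(abs(cnt - pi * rbin^2), 2 * pi * rbin + 10)
  # the DC bin always survives the circular mask, even for extreme motion
  out2 <- weight_and_mask(spec, oes_config(max_motion = 1e6))
  expect_equal(sum(abs(out2) > 0), 1)
})

test_that("uniform desired phase yields the DC solution", {
  v1 <- vessel_set("a", 0, 0)
  s <- optimize_encoding(v1, 0, cfg_small)
  expect_equal(s$k, c(0, 0))
  expect_equal(s$phi0, 0)
  # all vessels sharing theta = c need no gradient, any geometry
  set.seed(4)
  for (i in 1:5) {
    inst <- random_instance()
    th <- runif(1, -3, 3)
    s <- optimize_encoding(inst$vessels, rep(th, nrow(inst$vessels)), cfg_small)
    expect_equal(s$k, c(0, 0))
    expect_equal(s$phi0, th, tolerance = 1e-12)
    expect_equal(max(abs(s$phase_error)), 0, tolerance = 1e-12)
  }
})

test_that("FFT peak equals the direct masked-lattice peak and the loop oracle", {
  set.seed(42)
  for (i in 1:12) {
    inst <- random_instance()
    sd_ <- optimize_encoding(inst$vessels, inst$theta, cfg_small,
                             method = "direct")
    sf <- optimize_encoding(inst$vessels, inst$theta, cfg_small,
                            method = "fft")
    expect_identical(sd_$k, sf$k)
    expect_equal(sd_$phi0, sf$phi0, tolerance = 1e-9)
    expect_equal(sd_$score, sf$score, tolerance = 1e-9)
    bf <- brute_force_peak(inst$vessels, inst$theta, cfg_small)
    expect_equal(sd_$k, bf$k, tolerance = 1e-12)
    expect_equal(sd_$phi0, bf$phi0, tolerance = 1e-9)
  }
  # and at the full 1024 padding
  set.seed(43)
  for (i in 1:3) {
    inst <- random_instance(4)
    sd_ <- optimize_encoding(inst$vessels, inst$theta, method = "direct")
    sf <- optimize_encoding(inst$vessels, inst$theta, method = "fft")
    expect_identical(sd_$k, sf$k)
    expect_equal(sd_$phi0, sf$phi0, tolerance = 1e-9)
  }
})

test_that("solution attains the maximum of the weighted objective", {
  set.seed(7)
  lat <- oesasl:::mask_lattice(cfg_small)
  for (i in 1:20) {
    inst <- random_instance()
    s <- optimize_encoding(inst$vessels, inst$theta, cfg_small)
    rs <- oesasl:::snap_pixels(inst$vessels, cfg_small) *
      cfg_small$base_resolution
    obj <- abs(as.vector(exp(-2i * pi * (outer(lat$kx, rs[, 1]) +
                                           outer(lat$ky, rs[, 2]))) %*%
                           exp(1i * inst$theta))) * lat$w
    expect_equal(s$score, max(obj), tolerance = 1e-12)
  }
})

test_that("translating all vessels shifts phi0 but preserves k", {
  set.seed(9)
  for (i in 1:8) {
    inst <- random_instance(4, span = 30)
    shift <- sample(-20:20, 2)  # integer mm: identical voxel snapping
    v2 <- vessel_set(inst$vessels$name, inst$vessels$x_mm + shift[1],
                     inst$vessels$y_mm + shift[2])
    s1 <- optimize_encoding(inst$vessels, inst$theta, cfg_small)
    s2 <- optimize_encoding(v2, inst$theta, cfg_small)
    expect_identical(s1$k, s2$k)
    expect_equal(wrap_phase(s2$phi0 -
                              (s1$phi0 - 2 * pi * sum(s1$k * shift))), 0,
                 tolerance = 1e-9)
  }
})

test_that("doubling the zero-padding refines k by at most one coarse bin", {
  set.seed(13)
  for (i in 1:5) {
    inst <- random_instance(4)
    s1 <- optimize_encoding(inst$vessels, inst$theta,
                            oes_config(pad_size = 1024))
    s2 <- optimize_encoding(inst$vessels, inst$theta,
                            oes_config(pad_size = 2048))
    expect_true(all(abs(s1$k - s2$k) <= 1 / 1024 + 1e-12))
  }
})

test_that("hardware conversion satisfies the phase-accrual round trip", {
  p <- pulse_train()
  set.seed(21)
  inst <- random_instance(4)
  s <- to_hardware(optimize_encoding(inst$vessels, inst$theta), p)
  r <- matrix(runif(200, -100, 100), ncol = 2)
  expect_lt(max(abs(predicted_phase(s, r) -
                      (2 * pi * as.vector(r %*% s$k) + s$phi0))), 1e-9)
  # unit consistency: gamma_bar * A recovers k exactly
  gbar <- p$gyromagnetic_ratio / 1000
  expect_equal(gbar * s$blip_area / 1000, s$k, tolerance = 1e-12)
  # zero solution -> zero hardware
  s0 <- to_hardware(optimize_encoding(vessel_set("a", 0, 0), 0), p)
  expect_equal(s0$blip_area, c(0, 0))
  expect_equal(s0$rf_increment, 0)
})

test_that("unipolar convention: a single signed blip per axis realizes k, phi0 via RF only", {
  set.seed(3)
  inst <- random_instance(4)
  s <- to_hardware(optimize_encoding(inst$vessels, inst$theta))
  expect_length(s$blip_area, 2)   # one constant-polarity blip area per axis
  expect_equal(s$rf_increment, -s$phi0)
})

test_that("blip areas beyond the hardware limit warn but do not fail", {
  v <- vessel_set(c("a", "b"), c(-8, 8), c(0, 0))
  s <- optimize_encoding(v, c(0, pi))
  expect_warning(to_hardware(s, blip_limit = 1e-6), "exceeds")
})
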