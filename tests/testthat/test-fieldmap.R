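test_that("synthetic fieldmaps hit the vessel-offset ceiling and scale linearly", {
  v <- neck_vessels()
  pos <- vessel_positions_mm(v)
  m0 <- synth_fieldmap(v, scale = 0)
  expect_true(all(m0$psi == 0))
  m1 <- synth_fieldmap(v, scale = 1)
  expect_equal(max(abs(sample_psi(m1, pos))), 1.2, tolerance = 1e-9)
  m2 <- synth_fieldmap(v, scale = 2)
  expect_equal(m2$psi, 2 * m1$psi, tolerance = 1e-12)
  expect_error(synth_fieldmap(v, linear_coeffs = c(0, 0), quad_coeff = 0),
               "zero")
})

test_that("vessel perturbation is Gaussian, seeded and identity at sd 0", {
  v <- neck_vessels()
  expect_equal(perturb_vessels(v, 0), v)
  a <- perturb_vessels(v, 2, seed = 123)
  b <- perturb_vessels(v, 2, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, perturb_vessels(v, 2, seed = 124)))
  # law of large numbers: empirical per-coordinate SD within 5% of nominal
  set.seed(77)
  base <- vessel_set("a", 0, 0)
  draws <- replicate(10000, {
    p <- perturb_vessels(base, 2)
    c(p$x_mm, p$y_mm)
  })
  expect_lt(abs(sd(draws[1, ]) - 2) / 2, 0.05)
  expect_lt(abs(sd(draws[2, ]) - 2) / 2, 0.05)
  expect_lt(abs(mean(draws)), 0.1)
})

test_that("matched echo spacing gives psi directly from the phase difference", {
  # Delta TE equals the RF interval: wrapped difference IS psi
  p1 <- matrix(0.2, 8, 8)
  p2 <- wrap_phase(p1 + 0.4)
  pair <- echo_pair(p1, p2, te1 = 5.19e-3, te2 = 6.19e-3, rf_interval = 1e-3)
  psi <- psi_from_echoes(pair)
  expect_true(all(abs(psi$psi - 0.4) < 1e-12))
  # zero off-resonance -> zero psi
  pair0 <- echo_pair(p1, p1, te1 = 5.19e-3, te2 = 6.19e-3)
  expect_true(all(psi_from_echoes(pair0)$psi == 0))
  expect_error(echo_pair(p1, matrix(0, 4, 4), 1e-3, 2e-3), "geometries")
  expect_error(echo_pair(p1, p1, 2e-3, 1e-3), "exceed")
})

test_that("unmatched echo spacing recovers the field after 2-D unwrapping", {
  # smooth synthetic field, zero near the centre (where quality peaks)
  n <- 48
  x <- seq(-24, 23, length.out = n)
  f <- outer(x, x, function(a, b) 0.004 * a^2 + 0.05 * b - 0.002 * a * b)
  f <- f - f[n / 2, n / 2]
  dte <- 2.46e-3
  rf <- 1e-3
  psi_true <- f                 # rad per RF interval
  dphi <- psi_true / rf * dte   # phase difference across Delta TE, then wrap
  p1 <- wrap_phase(matrix(0.3, n, n))
  p2 <- wrap_phase(p1 + dphi)
  mag <- exp(-(outer(x^2, x^2, `+`)) / 2000)  # centre-peaked quality
  pair <- echo_pair(p1, p2, te1 = 5.19e-3, te2 = 5.19e-3 + dte,
                    rf_interval = rf, magnitude = mag)
  psi <- psi_from_echoes(pair)
  expect_lt(max(abs(psi$psi - psi_true)), 1e-3)
})

test_that("direct and unwrap paths agree when both are applicable", {
  n <- 32
  x <- seq(-16, 15, length.out = n)
  psi_true <- outer(x, x, function(a, b) 0.04 * a + 0.002 * b^2)
  psi_true <- wrap_phase(psi_true - psi_true[n / 2, n / 2]) * 0.45  # |psi| < pi
  p1 <- matrix(-0.2, n, n)
  p2 <- wrap_phase(p1 + psi_true)
  pair <- echo_pair(p1, p2, te1 = 5e-3, te2 = 6e-3, rf_interval = 1e-3)
  direct <- psi_from_echoes(pair)$psi
  unwrapped <- unwrap2d(wrap_phase(p2 - p1))
  expect_lt(max(abs(direct - unwrapped)), 1e-6)
})

test_that("map sampling is nearest-voxel with optional 3x3 averaging", {
  m <- phase_offset_map(matrix(0.7, 21, 21), voxel_size = 2)
  expect_equal(sample_psi(m, cbind(c(0, 3, -10), c(0, -5, 8))),
               rep(0.7, 3))
  # linear map sampled on voxel centres is exact
  cc <- oesasl:::map_coords(m)
  lin <- outer(cc$x, cc$y, function(a, b) 0.01 * a + 0.02 * b)
  ml <- phase_offset_map(lin, voxel_size = 2)
  expect_equal(sample_psi(ml, cbind(4, -6)), 0.01 * 4 + 0.02 * -6)
  expect_error(sample_psi(m, cbind(100, 0)), "outside")
  # 3x3 averaging cuts noise variance about 9-fold
  set.seed(5)
  pts <- 0
  est_point <- replicate(400, {
    mn <- phase_offset_map(matrix(rnorm(441, 0.5, 0.3), 21, 21), 2)
    sample_psi(mn, cbind(0, 0))
  })
  set.seed(5)
  est_avg <- replicate(400, {
    mn <- phase_offset_map(matrix(rnorm(441, 0.5, 0.3), 21, 21), 2)
    sample_psi(mn, cbind(0, 0), average = TRUE)
  })
  ratio <- var(est_point) / var(est_avg)
  expect_gt(ratio, 6)
  expect_lt(ratio, 13)
})

test_that("fieldmaps round-trip through NIfTI", {
  m <- synth_fieldmap(neck_vessels(), shape = c(33, 33), voxel_size = 2,
                      scale = 1)
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_map(m, path)
  back <- read_nifti_slice(path)
  expect_equal(back$data, m$psi, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$voxel_size, 2)
})
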