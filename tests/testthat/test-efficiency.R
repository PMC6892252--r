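resp <- get_test_response()

test_that("achieved magnetization substitutes phases correctly", {
  v <- neck_vessels()
  fit <- oes(v, "pcasl", psi = 0)
  # perfect label cycle with psi = 0: every vessel at response(0)
  m <- achieved_magnetization(fit, v, resp, psi = rep(0, 4))
  expect_equal(m[1, ], rep(eval_response(resp, 0), 4), ignore_attr = TRUE)
  expect_equal(m[2, ], rep(eval_response(resp, pi), 4), ignore_attr = TRUE)
  # a vessel with psi = pi in an uncorrected label cycle lands on the control
  # state: labeling destroyed
  m2 <- achieved_magnetization(fit, v, resp, psi = c(pi, 0, 0, 0))
  expect_equal(m2[1, 1], eval_response(resp, pi), ignore_attr = TRUE)
  expect_gt(m2[1, 1], 0.8)
  expect_true(all(abs(m2) <= 1))
})

test_that("correction shrinks the net phase error at the vessels", {
  set.seed(31)
  v0 <- neck_vessels()
  for (i in 1:6) {
    va <- perturb_vessels(v0, 2)
    psi <- runif(4, -2, 2)
    fit_unc <- oes(va, "vepcasl", psi = 0)
    fit_cor <- oes(va, "vepcasl", psi = psi)
    pos <- vessel_positions_mm(va)
    err <- function(fit) {
      sapply(seq_along(fit$solutions), function(c) {
        s <- fit$solutions[[c]]
        ideal <- ifelse(fit$scheme[c, ] > 0, pi, 0)
        mean(abs(wrap_phase(2 * pi * as.vector(pos %*% s$k) + s$phi0 +
                              psi - ideal)))
      })
    }
    expect_lt(mean(err(fit_cor)), mean(err(fit_unc)))
    # and the efficiency benefit follows
    e_unc <- snr_efficiency(fit_unc, resp, psi = psi)$mean
    e_cor <- snr_efficiency(fit_cor, resp, psi = psi)$mean
    expect_gte(e_cor, e_unc)
  }
})

test_that("PCASL efficiency is the normalized label-control difference", {
  expect_equal(snr_efficiency_pcasl(rbind(rep(-1, 3), rep(1, 3)))$mean, 1)
  expect_equal(snr_efficiency_pcasl(rbind(-0.85, 0.95))$per_vessel, 0.90)
  expect_error(snr_efficiency_pcasl(matrix(1, 3, 2)), "exactly 2 cycles")
  m <- rbind(c(-0.8, -0.6), c(0.9, 0.7))
  r <- snr_efficiency_pcasl(m)
  expect_equal(r$per_vessel, c(0.85, 0.65), ignore_attr = TRUE)
  expect_equal(r$mean, 0.75)
})

test_that("ideal Hadamard design has unit VEPCASL efficiency", {
  h <- unclass(ideal_scheme("vepcasl", 4))
  r <- snr_efficiency_vepcasl(h)
  expect_equal(r$per_vessel, rep(1, 4), ignore_attr = TRUE)
  expect_equal(r$mean, 1)
})

test_that("2-cycle VEPCASL efficiency reduces to the PCASL formula", {
  set.seed(99)
  for (i in 1:1000) {
    lc <- sort(runif(2, -1, 1))  # label below control
    m <- matrix(lc, 2, 1)
    expect_equal(snr_efficiency_vepcasl(m)$mean,
                 snr_efficiency_pcasl(m)$mean, tolerance = 1e-6)
  }
  # with arbitrary ordering the identity holds up to the sign of the
  # difference (the decoding precision is direction-blind)
  set.seed(100)
  for (i in 1:50) {
    m <- matrix(runif(2, -1, 1), 2, 1)
    expect_equal(snr_efficiency_vepcasl(m)$mean,
                 abs(snr_efficiency_pcasl(m)$mean), tolerance = 1e-6)
  }
})

test_that("degenerate encodings give zero efficiency with a warning", {
  m <- cbind(c(-1, 1, -1, 1), c(-1, 1, -1, 1))  # two identical vessel columns
  expect_warning(r <- snr_efficiency_vepcasl(m), "singular|degenerate")
  expect_equal(r$per_vessel, c(0, 0), ignore_attr = TRUE)
})

test_that("efficiency is invariant to vessel reordering and rigid translation", {
  set.seed(55)
  v0 <- perturb_vessels(neck_vessels(), 2)
  psi <- runif(4, -1.5, 1.5)
  fit <- oes(v0, "vepcasl", psi = psi)
  m <- achieved_magnetization(fit, v0, resp, psi = psi)
  base <- snr_efficiency_vepcasl(m)
  # permuting the vessels permutes the per-vessel efficiencies with them
  ord <- c(3, 1, 4, 2)
  er <- snr_efficiency_vepcasl(m[, ord])
  expect_equal(er$per_vessel, base$per_vessel[ord], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(er$mean, base$mean, tolerance = 1e-12)
  # PCASL is fully order-blind end to end
  fp <- snr_efficiency(oes(v0, "pcasl", psi = psi), resp, psi = psi)
  vr <- vessel_set(v0$name[ord], v0$x_mm[ord], v0$y_mm[ord])
  fr <- snr_efficiency(oes(vr, "pcasl", psi = psi[ord]), resp,
                       psi = psi[ord])
  expect_equal(fr$mean, fp$mean, tolerance = 1e-12)
  # rigid translation of vessels together with the offsets (integer mm so
  # voxel snapping is congruent)
  vt <- vessel_set(v0$name, v0$x_mm + 12, v0$y_mm - 7)
  et <- snr_efficiency(oes(vt, "vepcasl", psi = psi), resp, psi = psi)
  expect_equal(et$per_vessel, base$per_vessel, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("encoding maps render plane waves and fold in the offset map", {
  # zero k, zero phi0, no offsets: uniform map at response(0)
  v1 <- vessel_set("a", 0, 0)
  s0 <- optimize_encoding(v1, 0)
  em0 <- encoding_map(s0, resp, xlim = c(-20, 20), ylim = c(-20, 20))
  expect_true(all(abs(em0$mz - eval_response(resp, 0)) < 1e-12))
  # nonzero k: periodic bands of wavelength 1/|k| along k
  v2 <- vessel_set(c("a", "b"), c(-16, 16), c(0, 0))
  s <- optimize_encoding(v2, c(0, pi))
  expect_gt(sqrt(sum(s$k^2)), 0)
  em <- encoding_map(s, resp, xlim = c(-64, 64), ylim = c(-2, 2))
  wav <- 1 / sqrt(sum(s$k^2))
  mid <- which(em$y == 0)
  prof <- em$mz[, mid]
  shift <- round(wav / (em$x[2] - em$x[1]))
  n <- length(prof)
  expect_equal(prof[1:(n - shift)], prof[(shift + 1):n], tolerance = 1e-6)
})

test_that("corrected encoding's label contour passes near the targeted vessels", {
  v <- neck_vessels()
  fmap <- synth_fieldmap(v, scale = 4)
  psi <- sample_psi(fmap, vessel_positions_mm(v))
  # label RICA and RVA, control the left-side vessels
  row <- c(-1, 1, -1, 1)
  th <- desired_phases(row, v, psi = psi)
  s <- optimize_encoding(v, th)
  em <- encoding_map(s, resp, psi_map = fmap)
  lab_pts <- do.call(rbind, lapply(Filter(function(c) c$level == "label",
                                          em$contours),
                                   function(c) cbind(c$x, c$y)))
  expect_gt(nrow(lab_pts), 0)
  for (j in which(row < 0)) {
    d <- sqrt((lab_pts[, 1] - v$x_mm[j])^2 + (lab_pts[, 2] - v$y_mm[j])^2)
    expect_lt(min(d), 1.5 * fmap$voxel_size)
  }
})
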