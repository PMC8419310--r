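test_that("fan filter concentrates a plane wave in its sector", {
  u <- simulate_plane_wave(3.0, 0, 1100, c(0, 1))  # +x wave
  comps <- directional_filter(u, 8)
  energy <- vapply(comps, function(m) sum(Mod(m)^2), numeric(1))
  total <- sum(Mod(u)^2)
  expect_gt(energy[1] / total, 0.9)
  expect_true(all(energy[-1] / total <= 0.01))
})

test_that("fan filter with one sector and full band is the identity", {
  u <- simulate_plane_wave(2.8, 0.3, 1200, c(1, 1))
  out <- directional_filter(u, 1, k_min = 0, k_max = Inf)
  expect_equal(out[[1]], u, tolerance = 1e-12)
  # the sectors form a partition of unity: summing reconstructs the input
  comps <- directional_filter(u, 8, k_min = 0, k_max = Inf)
  expect_equal(Reduce(`+`, comps), u, tolerance = 1e-10)
})

test_that("fan filter separates two crossing plane waves", {
  # lambda = 2.7 mm fits the 16.2 x 10.8 mm grid periodically (6 and 4
  # cycles), so each wave occupies a single spectral bin
  ux <- simulate_plane_wave(2.7, 0, 1000, c(0, 1))
  uy <- simulate_plane_wave(2.7, 0, 1000, c(1, 0))
  comps <- directional_filter(ux + uy, 8)
  # energy splits between the two carrier sectors ...
  energy <- vapply(comps, function(m) sum(Mod(m)^2), numeric(1)) / sum(Mod(ux + uy)^2)
  expect_gt(energy[1], 0.45); expect_gt(energy[3], 0.45)
  expect_true(all(energy[-c(1, 3)] < 0.02))
  # ... and each sector recovers its wave's amplitude within 5% (interior)
  expect_lt(mean(abs(Mod(comps[[1]]) - Mod(ux))) / mean(Mod(ux)), 0.05)
  expect_lt(mean(abs(Mod(comps[[3]]) - Mod(uy))) / mean(Mod(uy)), 0.05)
  # all-zero input passes through silently
  z <- directional_filter(matrix(0i, 60, 90), 4)
  expect_true(all(vapply(z, function(m) all(m == 0), logical(1))))
})

test_that("local wavenumber of an analytic plane wave is exact in the interior", {
  u <- simulate_plane_wave(3.0, 0, 1200, c(0, 1))
  est <- estimate_wavenumber(u, c(0.18, 0.18), 1)
  kt <- 2 * pi * 1200 / 3.0
  expect_lt(max(abs(est$k[5:55, 5:85] / kt - 1)), 1e-3)
})

test_that("wavenumber estimation is gauge invariant", {
  u <- simulate_plane_wave(3.0, 0.4, 1300, c(0, 1))
  a <- estimate_wavenumber(u)
  b <- estimate_wavenumber(u * (0.3 - 1.7i))
  expect_equal(a$k, b$k, tolerance = 1e-9)
})

test_that("two-region field yields a piecewise-constant wavenumber with a narrow interface", {
  sigma <- 1
  u <- simulate_plane_wave(3.0, 0, 1000, c(0, 1))
  u2 <- simulate_plane_wave(2.0, 0, 1000, c(0, 1))
  u[, 46:90] <- u2[, 46:90]  # speed steps down mid-image
  est <- estimate_wavenumber(u, c(0.18, 0.18), sigma)
  k1 <- 2 * pi * 1000 / 3.0; k2 <- 2 * pi * 1000 / 2.0
  expect_lt(max(abs(est$k[10:50, 10:40] / k1 - 1)), 0.01)
  expect_lt(max(abs(est$k[10:50, 52:80] / k2 - 1)), 0.01)
  # transition contained within 2x the smoothing kernel support of the jump
  half <- 2 * ceiling(3 * sigma)
  expect_lt(max(abs(est$k[30, seq_len(45 - half)] / k1 - 1)), 0.01)
  expect_lt(max(abs(est$k[30, seq(46 + half, 90)] / k2 - 1)), 0.01)
})

test_that("stiffness inversion recovers a homogeneous analytic medium within 1%", {
  wf <- plane_wavefield(3.0, 0)
  st <- invert_stiffness(wf)
  err <- abs(interior(st$c_map) / 3.0 - 1)
  expect_lt(mean(err, na.rm = TRUE), 0.01)
})

test_that("single frequency and one sector reduce to omega/k pointwise", {
  wf <- plane_wavefield(3.0, 0, frequencies = 1200)
  cfg <- inversion_config(n_directions = 1, bandpass_k_min = 0,
                          bandpass_k_max = Inf, edge_margin_px = 0)
  st <- invert_stiffness(wf, cfg)
  est <- estimate_wavenumber(matrix(wf$u[[1]][1, , ] / Mod(wf$u[[1]][1, , ]), 60, 90),
                             c(0.18, 0.18), cfg$smoothing_sigma_px)
  expect_equal(as.vector(st$c_map[1, , ]), as.vector(2 * pi * 1200 / est$k),
               tolerance = 1e-9)
})

test_that("loss-angle inversion is exact in the elastic limit and accurate at 0.70 rad", {
  la0 <- invert_loss_angle(plane_wavefield(3.0, 0))
  expect_lt(max(abs(interior(la0$phi_map)), na.rm = TRUE), 1e-6)
  la <- invert_loss_angle(plane_wavefield(3.0, 0.70))
  expect_lt(max(abs(interior(la$phi_map) - 0.70), na.rm = TRUE), 0.02)
})

test_that("parameter maps are invariant to rescaling the displacement field", {
  wf <- plane_wavefield(3.1, 0.5)
  m1 <- invert(wf)
  wf$u <- lapply(wf$u, function(a) a * 37.5)
  m2 <- invert(wf)
  expect_equal(m1$c_map, m2$c_map, tolerance = 1e-9)
  expect_equal(m1$phi_map, m2$phi_map, tolerance = 1e-9)
})

test_that("recovered speed scales linearly with the true speed", {
  med <- function(cc) {
    ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90), c_background = cc,
                                    lesions = list(), full_brain = TRUE))
    wf <- simulate_wavefield(ph, acq_freqs, method = "rays", seed = 3)
    median(invert_stiffness(wf)$c_map, na.rm = TRUE)
  }
  base <- med(3.15)
  scaled <- med(3.15 * 0.88)
  expect_equal(scaled / base, 0.88, tolerance = 0.01)
})

test_that("inversion is robust at 20 dB signal-to-noise", {
  ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90), lesions = list(),
                                  full_brain = TRUE))
  clean <- simulate_wavefield(ph, acq_freqs, method = "rays", seed = 4)
  rms <- sqrt(mean(Mod(unlist(clean$u))^2))
  noisy <- simulate_wavefield(ph, acq_freqs, method = "rays", seed = 4,
                              noise_sigma = rms / (10 * sqrt(2)))
  maps <- invert(noisy)
  inr_c <- interior(maps$c_map); inr_p <- interior(maps$phi_map)
  expect_lt(abs(median(inr_c, na.rm = TRUE) / 3.15 - 1), 0.05)
  expect_lt(abs(median(inr_p, na.rm = TRUE) - 0.69), 0.05)
})

test_that("joint inversion handles degenerate inputs and is deterministic", {
  wf <- plane_wavefield(3.0, 0.2)
  m1 <- invert(wf); m2 <- invert(wf)
  expect_identical(m1$c_map, m2$c_map)
  expect_identical(m1$phi_map, m2$phi_map)
  bad <- wf
  bad$u <- lapply(bad$u, function(a) { a[] <- NA_complex_; a })
  expect_error(invert(bad), "no finite values")
  empty <- wf; empty$frequencies_hz <- numeric(0); empty$u <- list()
  expect_error(invert(empty), "empty frequency")
})

test_that("physical range holds on attenuating media", {
  ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90), lesions = list(),
                                  phi_background = 0.9, full_brain = TRUE))
  wf <- simulate_wavefield(ph, acq_freqs, method = "rays", seed = 5)
  la <- invert_loss_angle(wf)
  vals <- la$phi_map[la$valid]
  expect_true(all(vals >= 0 & vals <= pi / 2 + 1e-9))
})
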