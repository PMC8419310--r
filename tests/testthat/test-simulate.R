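test_that("plane wave has the analytic phase gradient and elastic amplitude", {
  u <- simulate_plane_wave(3.0, 0, 1000, c(0, 1))
  # |grad(phase)| = 2*pi*1000/3.0 everywhere
  dphi <- Arg(u[30, 3:90] * Conj(u[30, 1:88])) / (2 * 0.18e-3)
  expect_equal(dphi, rep(2 * pi * 1000 / 3.0, 88), tolerance = 1e-12)
  expect_equal(max(abs(Mod(u) - 1)), 0, tolerance = 1e-12)
})

test_that("viscoelastic decay slope equals -Im(k), by numerical differentiation", {
  u <- simulate_plane_wave(3.0, 0.7, 1400, c(0, 1))
  slope <- diff(log(Mod(u[25, ]))) / 0.18e-3
  expect_equal(mean(slope), -Im(shear_wavenumber(3.0, 0.7, 1400)),
               tolerance = 1e-9)
})

test_that("plane wave rejects degenerate material parameters", {
  expect_error(simulate_plane_wave(0, 0.5, 1000), "> 0")
  expect_error(simulate_plane_wave(NaN, 0.5, 1000), "finite")
  expect_error(simulate_plane_wave(3, 1.6, 1000), "pi/2")
})

test_that("homogeneous Helmholtz solution matches the analytic plane wave", {
  ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90), lesions = list(),
                                  full_brain = TRUE))
  wf <- simulate_wavefield(ph, 1000, method = "helmholtz",
                           lateral_bc = "neumann", sources = "left",
                           supersample = 2, seed = 1)
  u <- matrix(wf$u[[1]][1, , ], 60, 90)
  ua <- simulate_plane_wave(3.15, 0.69, 1000, c(0, 1))
  ii <- 19:42; jj <- 19:72  # >= 1 wavelength from every boundary
  s <- sum(Conj(ua[ii, jj]) * u[ii, jj]) / sum(Mod(ua[ii, jj])^2)
  rel <- Mod(u[ii, jj] / s - ua[ii, jj]) / Mod(ua[ii, jj])
  expect_lt(mean(rel), 0.02)
})

test_that("wave simulation is deterministic under a fixed seed", {
  ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90)))
  a <- simulate_wavefield(ph, c(1000, 1200), method = "rays",
                          noise_sigma = 0.01, seed = 9)
  b <- simulate_wavefield(ph, c(1000, 1200), method = "rays",
                          noise_sigma = 0.01, seed = 9)
  expect_identical(a$u, b$u)
  d <- simulate_wavefield(ph, c(1000, 1200), method = "rays",
                          noise_sigma = 0.01, seed = 10)
  expect_false(identical(a$u, d$u))
})

test_that("wave simulation validates its inputs", {
  ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90)))
  expect_error(simulate_wavefield(ph, numeric(0)), "nonempty")
  expect_error(simulate_wavefield(ph, c(1000, -5)), "positive")
})

test_that("noiseless contrast pairs realize the exact enhancement semantics", {
  ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90)))
  gd <- simulate_contrast_pair(ph, "t1_gbca", 30, noise_sigma = 0)
  pc <- percent_change_si(gd)
  expect_true(all(abs(pc[ph$gd_contrast] - 30) < 1e-12))
  other <- ph$brain & !ph$gd_contrast & !ph$ventricles
  expect_true(all(abs(pc[other]) < 1e-12))

  vs <- simulate_contrast_pair(ph, "t2star_vsop", 40, noise_sigma = 0)
  ratio <- vs$post / vs$pre
  expect_true(all(abs(ratio[ph$vsop_contrast] - 0.6) < 1e-12))
  expect_error(simulate_contrast_pair(ph, "t1w_spgr"), "arg")
  expect_error(simulate_contrast_pair(ph, "t1_gbca", -5), "> 0")
})

test_that("Rician noise keeps SI nonnegative and biases the mean upward", {
  ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90), lesions = list()))
  clean <- simulate_contrast_pair(ph, "t1_gbca", 30, noise_sigma = 0)
  post_means <- vapply(1:20, function(s) {
    p <- simulate_contrast_pair(ph, "t1_gbca", 30, noise_sigma = 40, seed = s)
    expect_true(all(p$post >= 0))
    mean(p$post)
  }, numeric(1))
  # Rician bias: E[sqrt((A + n1)^2 + n2^2)] > A
  expect_gt(mean(post_means), mean(clean$post))
})
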