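test_that("phase-pair differences cancel shared additive background", {
  psf <- small_psf()
  ph <- make_phantom("texture", 32, 60, seed = 2)
  cfg <- illum_config(m = 0.8, k0_cycles_per_px = 4 / 32)
  st <- acquire_stack(ph, psf, cfg)

  # equal frames -> zero differences
  st_eq <- st
  for (j in 2:3) st_eq$frames[, , 1, j] <- st_eq$frames[, , 1, 1]
  pair <- phase_differences(st_eq, 1)
  expect_true(all(pair$d12 == 0) && all(pair$d23 == 0))

  # adding a constant to all three frames leaves the differences unchanged
  st_c <- st
  st_c$frames <- st_c$frames + 3.7
  p0 <- phase_differences(st, 2); pc <- phase_differences(st_c, 2)
  expect_lt(max(abs(p0$d12 - pc$d12)), 1e-12 * max(abs(p0$d12)))
  expect_lt(max(abs(p0$d23 - pc$d23)), 1e-12 * max(abs(p0$d23)))

  expect_error(phase_differences(st, 5), "out of range")
})

test_that("d12 matches the analytic sqrt(2) m I0 cos(. - pi/4) convolution oracle", {
  psf <- small_psf()
  S <- matrix(runif(32 * 32), 32)
  ph <- make_phantom("custom", 32, 60, list(density = S))
  phi0 <- 0.4; m <- 0.8; i0 <- 1.2
  cfg <- illum_config(i0 = i0, m = m, k0_cycles_per_px = 4 / 32,
                      thetas_deg = 0, phi0_rad = phi0)
  st <- acquire_stack(ph, psf, cfg, boundary = "periodic")
  pair <- phase_differences(st, 1)

  x <- matrix(rep(0:31, each = 32), 32)
  arg <- 2 * pi * (4 / 32) * x + phi0
  want <- sqrt(2) * m * i0 * direct_convolve(cos(arg - pi / 4) * S, psf$kernel)
  expect_lt(max(abs(pair$d12 - want)), 1e-6 * max(abs(want)))

  want23 <- -sqrt(2) * m * i0 * direct_convolve(sin(arg - pi / 4) * S, psf$kernel)
  expect_lt(max(abs(pair$d23 - want23)), 1e-6 * max(abs(want23)))
})

test_that("the complex analytic signal is z = d12 - i d23", {
  pair <- structure(list(d12 = matrix(3, 4, 4), d23 = matrix(4, 4, 4),
                         orientation_index = 1L), class = "difference_pair")
  z <- complex_signal(pair)
  expect_identical(Re(z$z), pair$d12)
  expect_identical(Im(z$z), -pair$d23)
  expect_equal(demodulate(z), matrix(5, 4, 4))

  zero <- structure(list(d12 = matrix(0, 4, 4), d23 = matrix(0, 4, 4),
                         orientation_index = 1L), class = "difference_pair")
  expect_true(all(demodulate(complex_signal(zero)) == 0))
})

test_that("modulus demodulation matches the frequency-domain oracle on random phantoms", {
  psf <- small_psf()
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    S <- matrix(runif(32 * 32), 32)
    ph <- make_phantom("custom", 32, 60, list(density = S))
    m <- runif(1, 0.5, 1); phi0 <- runif(1, 0, 2 * pi)
    cyc <- sample(2:4, 2)  # grid-commensurate oblique fringe below the cutoff
    k0 <- sqrt(sum((cyc / 32)^2))
    theta <- atan2(cyc[2], cyc[1]) * 180 / pi
    cfg <- illum_config(m = m, k0_cycles_per_px = k0, thetas_deg = theta,
                        phi0_rad = phi0)
    st <- acquire_stack(ph, psf, cfg, boundary = "periodic")
    got <- demodulate(complex_signal(phase_differences(st, 1)))
    want <- freq_oracle_modulus(S, psf, m, 1, cyc)
    worst <- max(worst, max(abs(got - want)) / max(want))
  }
  expect_lt(worst, 1e-6)
})

test_that("modulus removes the global fringe phase", {
  psf <- small_psf()
  ph <- make_phantom("beads", 64, 60, list(n = 3L, margin_px = 12L, min_sep_px = 10),
                     seed = 3)
  mk <- function(phi0) {
    cfg <- illum_config(k0_cycles_per_px = 0.66 * psf$cutoff_cycles_per_px,
                        phi0_rad = phi0)
    acquire_stack(ph, psf, cfg)
  }
  za <- complex_signal(phase_differences(mk(0), 1))
  zb <- complex_signal(phase_differences(mk(0.7), 1))
  expect_lt(max(abs(demodulate(za) - demodulate(zb))), 1e-6 * max(demodulate(za)))
})

test_that("orientation combination is a permutation-invariant sum", {
  x <- matrix(runif(16), 4); y <- matrix(runif(16), 4); z <- matrix(runif(16), 4)
  expect_equal(combine_orientations(list(x, x, x))$data, 3 * x)
  expect_equal(combine_orientations(list(x, y, z))$data,
               combine_orientations(list(z, x, y))$data)
  expect_equal(combine_orientations(list(x))$data, x)
  expect_error(combine_orientations(list()), "at least one")
  expect_error(combine_orientations(list(x, matrix(0, 3, 3))), "differ in shape")
})

test_that("reconstruction cancels arbitrary out-of-focus background", {
  fix <- bead_stack(96, 3, seed = 5)
  base <- reconstruct(fix$stack)
  # constant background
  st_c <- acquire_stack(fix$phantom, fix$psf, fix$cfg, b_out = 0.8)
  # smooth 2-D background map
  g <- expand.grid(y = 0:95, x = 0:95)
  bmap <- matrix(0.3 + 0.2 * sin(2 * pi * g$x / 96) * cos(2 * pi * g$y / 96), 96)
  st_m <- acquire_stack(fix$phantom, fix$psf, fix$cfg, b_out = bmap)
  for (demod in c("modulus", "carrier")) {
    r0 <- reconstruct(fix$stack, demod = demod)$data
    rc <- reconstruct(st_c, demod = demod)$data
    rm <- reconstruct(st_m, demod = demod)$data
    expect_lt(max(abs(rc - r0)), 1e-9 * max(r0))
    expect_lt(max(abs(rm - r0)), 1e-9 * max(r0))
  }
  # a zero phantom with background reconstructs to exactly zero
  psf <- fix$psf
  zero <- make_phantom("custom", 32, 30, list(density = matrix(0, 32, 32)))
  stz <- acquire_stack(zero, psf, fix$cfg, b_out = 0.5)
  expect_true(all(reconstruct(stz)$data == 0))
})

test_that("reconstruction is linear in modulation depth and signal scale", {
  psf <- small_psf()
  S <- matrix(runif(32 * 32), 32)
  mk <- function(m, scale = 1) {
    ph <- make_phantom("custom", 32, 60, list(density = scale * S))
    cfg <- illum_config(m = m, k0_cycles_per_px = 4 / 32)
    acquire_stack(ph, psf, cfg, boundary = "periodic")
  }
  for (demod in c("modulus", "carrier")) {
    r1 <- reconstruct(mk(0.4), demod = demod)$data
    r2 <- reconstruct(mk(0.8), demod = demod)$data
    expect_lt(max(abs(r2 - 2 * r1)), 1e-9 * max(r2))
    r3 <- reconstruct(mk(0.4, scale = 3), demod = demod)$data
    expect_lt(max(abs(r3 - 3 * r1)), 1e-9 * max(r3))
  }
})

test_that("reconstruct output is phi0-invariant in both demodulation modes", {
  a <- bead_stack(96, 3, seed = 5, phi0 = 0)
  b <- bead_stack(96, 3, seed = 5, phi0 = 0.7)
  for (demod in c("modulus", "carrier")) {
    ra <- reconstruct(a$stack, demod = demod)$data
    rb <- reconstruct(b$stack, demod = demod)$data
    expect_lt(max(abs(ra - rb)), 1e-6 * max(ra))
  }
})

test_that("carrier demodulation narrows isolated beads; modulus does not", {
  fix <- bead_stack(128, 4, seed = 9)
  centers <- fix$phantom$meta$centers
  wf <- bead_resolution(fix$stack$widefield, centers, 30, window_px = 12)
  car <- bead_resolution(reconstruct(fix$stack, demod = "carrier")$data,
                         centers, 30, window_px = 12)
  mod <- bead_resolution(reconstruct(fix$stack)$data, centers, 30, window_px = 12)
  expect_true(all(car$per_bead_fwhm_nm < wf$per_bead_fwhm_nm))
  expect_gt(wf$mean_fwhm_nm / car$mean_fwhm_nm, 1.3)
  expect_lt(wf$mean_fwhm_nm / car$mean_fwhm_nm, 1.9)
  # the modulus discards the carrier and keeps the wide-field width
  expect_equal(mod$mean_fwhm_nm / wf$mean_fwhm_nm, 1, tolerance = 0.05)
})

test_that("normalization clips to the 99.9th percentile and is recorded", {
  fix <- bead_stack(96, 3, seed = 5)
  sr <- reconstruct(fix$stack, normalize = TRUE)
  expect_true(max(sr$data) <= 1 && min(sr$data) >= 0)
  expect_true(sr$provenance$normalized)
})
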