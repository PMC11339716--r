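test_that("METF is the stapes displacement per ear-canal pressure in dB", {
  expect_equal(metf(1e-6, 1), 0)        # 1 um per Pa
  expect_equal(metf(1e-7, 1), -20)
  expect_equal(metf(1e-6 * (0.3 + 0.4i) / Mod(0.3 + 0.4i), 1), 0)
  expect_equal(metf(2e-6, 2), 0)
  expect_error(metf(1e-6, 0), "> 0")
})

test_that("impedance probes return the defining ratio", {
  z <- 3e10 * exp(1i * 0.4)
  u <- 2e-12 * exp(-1i * 1.1)
  expect_equal(cochlear_input_impedance(z * u, u), z)
  expect_equal(reverse_middle_ear_impedance(z * u, u), z)
  # magnitude invariant under source-level scaling
  expect_equal(Mod(cochlear_input_impedance(10 * z * u, 10 * u)), Mod(z))
  expect_error(cochlear_input_impedance(1 + 0i, 0 + 0i), "zero")
})

test_that("CF extraction refines the peak and handles degenerate profiles", {
  x <- seq(0, 1, length.out = 201)
  # parabolic profile with known analytic vertex
  for (vx in c(0.237, 0.5, 0.811)) {
    prof <- exp(-(x - vx)^2 / 0.02)
    expect_equal(extract_cf(prof, x), vx, tolerance = 1e-6)
  }
  # delta-like synthetic peak
  prof <- rep(1e-12, 201); prof[x == 0.4] <- 1
  expect_equal(extract_cf(prof, x), 0.4, tolerance = 0.01)
  # monotone profile: endpoint with a warning
  expect_warning(cf <- extract_cf(x + 1, x), "boundary")
  expect_equal(cf, 1)
  expect_error(extract_cf(rep(1, 201), x), "flat")
  # ties break toward the base
  tie <- rep(0.1, 201); tie[c(50, 150)] <- 1
  expect_lt(suppressWarnings(extract_cf(tie, x)), 0.5)
})

test_that("Greenwood map matches the human constants and is monotone", {
  expect_equal(greenwood_reference(1), 165.4 * (1 - 0.88))          # ~19.8 Hz
  expect_equal(greenwood_reference(0), 165.4 * (10^2.1 - 0.88))     # ~20.7 kHz
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(greenwood_reference(x)) < 0))
  expect_equal(greenwood_place(greenwood_reference(x[2:20])), x[2:20])
  expect_error(greenwood_reference(1.2), "\\[0, 1\\]")
  expect_error(greenwood_place(1e6), "range")
})

test_that("phase re base unwraps multi-cycle accumulation", {
  m <- build_model(small_config(120))
  sol <- solve_cochlea(m, frequency = 500)
  # overwrite the field with synthetic waves of known phase
  x <- sol$x_norm
  sol$d <- exp(-1i * 2 * pi * x)
  expect_equal(phase_re_base(sol, 0.5), -0.5 + x[1], tolerance = 1e-3)
  expect_equal(phase_re_base(sol)[1], 0)
  # three accumulated cycles recovered without 2 pi jumps
  sol$d <- exp(-1i * 2 * pi * 3 * x) * (1 + 0.2 * x)
  ph <- phase_re_base(sol)
  expect_equal(ph[length(ph)] - ph[1], -3 * (x[length(x)] - x[1]),
               tolerance = 0.01)
  expect_true(all(abs(diff(ph)) < 0.5))
})

test_that("relative amplitude is zero at the reference and tracks scaling", {
  m <- build_model(small_config(150))
  sol <- solve_cochlea(m, frequency = 1000)
  cf <- extract_cf(sol)
  amp <- approx(sol$x_norm, Mod(sol$d), xout = cf)$y
  ref_cf <- c("1000" = cf); ref_amp <- c("1000" = amp)
  expect_equal(relative_amplitude_at_cf(sol, ref_cf, ref_amp), 0)
  scaled <- sol; scaled$d <- sol$d * 10
  expect_equal(relative_amplitude_at_cf(scaled, ref_cf, ref_amp), 20)
  expect_error(relative_amplitude_at_cf(sol, c("250" = 0.8), c("250" = 1e-9)),
               "reference")
})

test_that("volume displacement ratio is near one on the sealed model", {
  m <- build_model(small_config(150))
  for (f in c(125, 1000, 4000)) {
    sol <- solve_cochlea(m, frequency = f)
    expect_equal(volume_displacement_ratio(sol), 1, tolerance = 1e-6)
  }
})

test_that("transfer metrics wrapper combines matched forward/reverse runs", {
  m <- build_model(small_config(150))
  fwd <- solve_cochlea(m, frequency = 1000, pathway = "forward")
  rev <- solve_cochlea(m, frequency = 1000, pathway = "reverse")
  tm <- transfer_metrics(fwd, rev, p_ec = spl_to_pressure(60))
  expect_equal(tm$metf_db, metf(fwd$d_stapes, spl_to_pressure(60)))
  expect_equal(tm$z_c, fwd$p_sv / fwd$u_ow)
  expect_equal(tm$z_me_r, rev$p_sv / rev$u_ow)
  expect_equal(tm$vol_ratio, 1, tolerance = 1e-6)
  expect_error(transfer_metrics(rev, fwd, 1), "forward")
})
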