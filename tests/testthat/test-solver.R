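test_that("partition impedance has the series resonance structure", {
  cfg <- small_config()
  m <- build_model(cfg)
  g <- m$geometry
  x <- g$bm_length / 2
  prof <- cochleabox:::partition_profiles_at(
    x, m$bm, g, m$damping, m$fluid,
    cfg$bm$stiffness_constant, cfg$bm$fluid_load_factor)
  f_res <- sqrt(prof$k / prof$m) / (2 * pi)
  z_res <- partition_impedance(x, f_res, m$bm, g, m$damping, m$fluid,
                               cfg$bm$stiffness_constant,
                               cfg$bm$fluid_load_factor)
  expect_lt(abs(Im(z_res)) / Mod(z_res), 1e-9)
  expect_equal(Re(z_res), prof$r + m$damping$c)
  # undamped variant is purely reactive
  und <- damping_spec(0, 0, 0)
  z0 <- partition_impedance(x, 2 * f_res, m$bm, g, und, m$fluid,
                            cfg$bm$stiffness_constant,
                            cfg$bm$fluid_load_factor)
  expect_equal(Re(z0), 0)
  # stiffness profile decreases strictly base -> apex on the grid
  k <- cochleabox:::partition_profiles_at(
    g$x, m$bm, g, m$damping, m$fluid,
    cfg$bm$stiffness_constant, cfg$bm$fluid_load_factor)$k
  expect_true(all(diff(k) < 0))
  expect_error(partition_impedance(x, 0, m$bm, g, m$damping), "> 0")
})

test_that("window impedance closed forms behave physically", {
  rwm <- isotropic_elasticity(5e6, 0.49)
  # low-frequency magnitude against the independent clamped-plate
  # deflection oracle (no hysteretic loss in this comparison)
  for (f in c(5, 20, 50)) {
    z <- window_boundary_impedance(rwm, 2.3e-6, 70e-6, "RWM-plate", f,
                                   loss_factor = 0)
    expect_equal(Mod(z), plate_deflection_oracle(5e6, 0.49, 70e-6, 2.3e-6, f),
                 tolerance = 0.01)
  }
  # 100-fold modulus multiplies the low-frequency (stiffness) part by 100
  z1 <- window_boundary_impedance(rwm, 2.3e-6, 70e-6, "RWM-plate", 10,
                                  loss_factor = 0)
  z100 <- window_boundary_impedance(isotropic_elasticity(5e8, 0.49),
                                    2.3e-6, 70e-6, "RWM-plate", 10,
                                    loss_factor = 0)
  expect_equal(Mod(z100) / Mod(z1), 100, tolerance = 1e-3)
  # ossification limit is effectively rigid
  z_oss <- window_boundary_impedance(isotropic_elasticity(2e11, 0.49),
                                     2.3e-6, 70e-6, "RWM-plate", 1000)
  expect_gt(Mod(z_oss) / Mod(window_boundary_impedance(
    rwm, 2.3e-6, 70e-6, "RWM-plate", 1000)), 1e3)
  # annulus kind scales with ring shear stiffness
  sal <- isotropic_elasticity(3e5, 0.49)
  za <- window_boundary_impedance(sal, 4.2e-6, 0.2e-3, "SAL-annulus", 100,
                                  attached_mass = 3e-6, loss_factor = 0)
  zb <- window_boundary_impedance(isotropic_elasticity(6e5, 0.49),
                                  4.2e-6, 0.2e-3, "SAL-annulus", 100,
                                  attached_mass = 3e-6, loss_factor = 0)
  expect_equal(Mod(zb) / Mod(za), 2, tolerance = 1e-2)
  expect_error(window_boundary_impedance(rwm, -1, 70e-6, "RWM-plate", 100),
               "nonphysical")
})

test_that("assembled system matches a dense factorization oracle", {
  m <- build_model(small_config(60))
  for (f in c(125, 1000, 4000)) {
    asm <- assemble_cochlea(m, f)
    A <- as.matrix(asm)
    b <- cochleabox:::assembly_rhs(asm, p_ow = spl_to_pressure(86))
    x_dense <- solve(A, b)                       # dense LAPACK oracle
    sol <- cochleabox:::solve_block_tridiag(asm, b)
    x_band <- rep(0i, 2 * asm$n)
    x_band[seq(1, 2 * asm$n, 2)] <- sol$p_sv
    x_band[seq(2, 2 * asm$n, 2)] <- sol$p_st
    expect_lt(max(Mod(x_band - x_dense)) / max(Mod(x_dense)), 1e-10)
    res <- cochleabox:::assembly_residual(asm, sol$p_sv, sol$p_st, b)
    expect_lt(sqrt(sum(Mod(res)^2)) / sqrt(sum(Mod(b)^2)), 1e-10)
  }
})

test_that("system matrix is pathway-independent; only the source differs", {
  m <- build_model(small_config(30))
  asm <- assemble_cochlea(m, 500)
  A1 <- as.matrix(asm)
  A2 <- as.matrix(assemble_cochlea(m, 500))
  expect_identical(A1, A2)
  b_f <- cochleabox:::assembly_rhs(asm, p_ow = 1)
  b_r <- cochleabox:::assembly_rhs(asm, p_rw = 1)
  expect_false(identical(b_f, b_r))
  expect_equal(sum(b_f != 0), 1)
  expect_equal(sum(b_r != 0), 1)
  # the operator is symmetric (reciprocity of the passive network)
  expect_equal(A1, t(A1))
  # zero source gives the zero solution
  sol0 <- cochleabox:::solve_block_tridiag(asm, rep(0i, 2 * asm$n))
  expect_true(all(Mod(c(sol0$p_sv, sol0$p_st)) == 0))
})

test_that("solutions are linear in the source and conserve volume velocity", {
  m <- build_model(small_config(80))
  s1 <- solve_cochlea(m, frequency = 700, pathway = "forward", level_db = 86)
  s2 <- solve_cochlea(m, frequency = 700, pathway = "forward",
                      level_db = 86 + 20 * log10(2))
  expect_equal(s2$d, 2 * s1$d, tolerance = 1e-12)
  expect_equal(s2$u_ow, 2 * s1$u_ow, tolerance = 1e-12)
  expect_lt(conservation_check(s1), 1e-6)
  # imbalance is invariant under source scaling
  expect_equal(conservation_check(s2), conservation_check(s1),
               tolerance = 1e-6)
  expect_lt(s1$residual_rel, 1e-10)
})

test_that("two-segment degenerate model matches the analytic circuit oracle", {
  cfg <- small_config(2)
  m <- build_model(cfg)
  m$z_heli <- function(f) Inf      # block the apical shunt for the oracle
  for (f in c(125, 1000, 4000)) {
    for (pw in c("forward", "reverse")) {
      sol <- solve_cochlea(m, frequency = f, pathway = pw)
      orc <- two_segment_oracle(m, f, sol$stimulus$pressure_pa, pw)
      expect_equal(sol$u_ow, orc$u_ow, tolerance = 1e-8)
      expect_equal(sol$u_rw, orc$u_rw, tolerance = 1e-8)
      omega <- 2 * pi * f
      d_orc <- orc$u_bm / (m$geometry$bm_width_profile * m$geometry$dx) /
        (1i * omega)
      expect_equal(sol$d, d_orc, tolerance = 1e-8)
      # the closed-form loop conserves volume velocity exactly
      expect_equal(Mod(orc$u_ow + orc$u_rw), 0)
    }
  }
})

test_that("characteristic place converges under grid refinement", {
  a <- max(Mod(solve_cochlea(build_model(small_config(500)),
                             frequency = 1000)$d))
  b <- max(Mod(solve_cochlea(build_model(small_config(1000)),
                             frequency = 1000)$d))
  expect_lt(abs(b - a) / a, 0.02)
})

test_that("solution CSV export writes profile and probe records", {
  m <- build_model(small_config(25))
  sol <- solve_cochlea(m, frequency = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_solution_csv(sol, path)
  prof <- read.csv(path)
  expect_named(prof, c("x_m", "x_norm", "re_d_m", "im_d_m", "abs_d_m",
                       "phase_cycles"))
  expect_equal(nrow(prof), 25)
  expect_equal(prof$abs_d_m, Mod(sol$d), tolerance = 1e-12)
  probes <- read.csv(sub("\\.csv$", "_probes.csv", path))
  expect_equal(probes$re_u_ow, Re(sol$u_ow), tolerance = 1e-12)
})
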