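# Shared fixtures and independent oracles.  Everything is generated in
# code; the oracles deliberately avoid the package's own assembly/solve
# path so that implementation and check stay independent.

# a small, fast configuration for unit tests
small_config <- function(n = 40, ...) {
  cochlea_config(overrides = modifyList(
    list(geometry = list(n_segments = n)), list(...)
  ))
}

# Two-mesh analytic circuit oracle for the degenerate two-segment cochlea
# with the helicotrema blocked: source P behind one window, loop currents
# I1 (window loop through the basal partition branch) and I2 (apical loop
# through the duct segments and the apical partition branch), solved by
# Cramer's rule.
#
#   (z_src + Z1 + z_other) I1 - Z1 I2 = P
#   -Z1 I1 + (Z1 + Zsv + Z2 + Zst) I2 = 0
#
# Returns window volume velocities (inward positive) and the partition
# branch fluxes.
two_segment_oracle <- function(model, f, p_src, pathway = "forward") {
  stopifnot(model$geometry$n_segments == 2L)
  omega <- 2 * pi * f
  g <- model$geometry
  rho <- model$fluid$rho
  mu <- model$fluid$mu
  duct_z <- function(A) g$dx * (1i * omega * rho / A + 8 * pi * mu / A^2)
  Zsv <- duct_z(g$scala_vestibuli_area)
  Zst <- duct_z(g$scala_tympani_area)
  z_p <- partition_impedance(g$x, f, model$bm, g, model$damping, model$fluid,
                             stiffness_constant = model$config$bm$stiffness_constant,
                             fluid_load_factor = model$config$bm$fluid_load_factor)
  Zbm <- z_p / (g$bm_width_profile * g$dx)
  z_ow <- model$z_ow(f); z_rw <- model$z_rw(f)

  a11 <- z_ow + Zbm[1] + z_rw
  a12 <- -Zbm[1]
  a21 <- -Zbm[1]
  a22 <- Zbm[1] + Zsv + Zbm[2] + Zst
  det <- a11 * a22 - a12 * a21
  I1 <- (p_src * a22) / det
  I2 <- (-a21 * p_src) / det
  # forward drives the SV side; reverse drives the ST side of the same loop
  sgn <- if (pathway == "forward") 1 else -1
  list(
    u_ow = if (pathway == "forward") I1 else -I1,
    u_rw = if (pathway == "forward") -I1 else I1,
    u_bm = sgn * c(I1 - I2, I2),    # flux SV -> ST per partition branch
    p_sv1 = if (pathway == "forward") p_src - z_ow * I1 else z_ow * I1
  )
}

# Independent clamped circular plate oracle: uniform load center deflection
# w0 = P a^4 / (64 D); parabolic (1 - r^2/a^2)^2 shape gives volume
# displacement V = pi a^2 w0 / 3, hence |z| ~ 1 / (omega V/P) at low
# frequency.
plate_deflection_oracle <- function(E, nu, thickness, area, f) {
  a <- sqrt(area / pi)
  D <- E * thickness^3 / (12 * (1 - nu^2))
  w0_per_p <- a^4 / (64 * D)
  vol_per_p <- pi * a^2 * w0_per_p / 3
  1 / (2 * pi * f * vol_per_p)
}

paper_frequencies <- c(125, 250, 500, 1000, 2000, 4000)
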