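# Reduced-order, frequency-domain two-duct cochlea.
#
# The cochlea is a pair of incompressible fluid columns (scala vestibuli,
# scala tympani; the scala media is merged into the vestibuli) coupled
# through a locally reacting basilar-membrane partition, terminated at the
# base by the stapes/annular-ligament impedance (oval window) and the
# round-window-membrane impedance, and shunted at the apex by the
# helicotrema.  Discretised on segment centres this is a ladder network:
# series acoustic masses (plus a Poiseuille viscous loss) along each duct,
# shunt partition branches between them, window branches to the exterior at
# the basal node.  Nodal analysis gives a block-tridiagonal complex system
# with 2x2 blocks, solved by a block Thomas elimination.
#
# Sign conventions: x runs from base (0) to apex (L); window volume
# velocities are positive into the cochlea; basilar-membrane displacement
# is positive toward the scala tympani; phase is reported in cycles,
# negative meaning lag, referenced to the basal segment.

# Partition stiffness constant C in k(x) = C * E_X * t(x)^3 / w(x)^4,
# calibrated once (see calibrate_bm_stiffness) so that the normal-model
# forward characteristic-frequency map meets the Greenwood curve at 1 kHz.
BM_STIFFNESS_CONSTANT <- 7176.14

#' Per-area impedance of the basilar-membrane partition
#'
#' Locally reacting series section
#' \deqn{z_p(x, f) = i \omega m(x) + r(x) + c + k(x) / (i \omega)}
#' with per-area mass `m(x)` (membrane mass `rho_bm * t(x)` plus a fluid
#' co-mass `fluid_load_factor * rho * w(x)`), per-area stiffness
#' `k(x) = C * E_X * t(x)^3 / w(x)^4` (clamped beam bending across the
#' width, which is the fibre direction), Rayleigh resistance
#' `r(x) = alpha m(x) + beta k(x)`, and the surface damping coefficient `c`.
#'
#' @param x Position(s) from the base (m), within `[0, bm_length]`.
#' @param f Frequency (Hz), > 0.
#' @param bm An [orthotropic_elasticity()] object for the basilar membrane.
#' @param geometry A `geometry_spec`.
#' @param damping A [damping_spec()].
#' @param fluid A [fluid_properties()] object (for the co-mass).
#' @param stiffness_constant Dimensionless bending constant `C`.
#' @param fluid_load_factor Co-mass factor times `rho * w(x)`.
#' @return Complex per-area impedance (Pa s/m), vectorized over `x`.
#' @export
partition_impedance <- function(x, f, bm, geometry, damping,
                                fluid = fluid_properties(),
                                stiffness_constant = BM_STIFFNESS_CONSTANT,
                                fluid_load_factor = pi / 4) {
  if (any(f <= 0)) stop("frequency must be > 0", call. = FALSE)
  omega <- 2 * pi * f
  prof <- partition_profiles_at(x, bm, geometry, damping, fluid,
                                stiffness_constant, fluid_load_factor)
  1i * omega * prof$m + (prof$r + damping$c) + prof$k / (1i * omega)
}

# m(x), k(x), r(x) per unit area at arbitrary positions.
partition_profiles_at <- function(x, bm, geometry, damping, fluid,
                                  stiffness_constant, fluid_load_factor) {
  xn <- x / geometry$bm_length
  if (any(xn < 0 | xn > 1)) stop("x outside the basilar membrane", call. = FALSE)
  w <- geometry$bm_width_base + (geometry$bm_width_apex - geometry$bm_width_base) * xn
  t <- geometry$bm_thickness_base +
    (geometry$bm_thickness_apex - geometry$bm_thickness_base) * xn
  m <- bm$density * t + fluid_load_factor * fluid$rho * w
  k <- stiffness_constant * bm$E_X * t^3 / w^4
  r <- rayleigh_damping(damping$alpha, damping$beta, m, k)
  list(w = w, t = t, m = m, k = k, r = r)
}

#' Lumped boundary impedance of a cochlear window
#'
#' Series stiffness-mass-damping impedance of a window closure in
#' volume-velocity convention (Pa s/m^3).  Two closed forms are provided:
#'
#' * `"RWM-plate"`: clamped circular plate of the membrane's area under
#'   uniform pressure.  Acoustic compliance `C_a = pi a^6 / (192 D)` with
#'   flexural rigidity `D = E t^3 / (12 (1 - nu^2))`; effective acoustic
#'   mass `(9/5) rho_m t / (pi a^2)` from the clamped static mode shape.
#' * `"SAL-annulus"`: stapes footplate suspended on an annular ligament
#'   ring sheared across its width; mechanical stiffness
#'   `K = G * (2 pi r_fp * ring thickness) / ring width`, with the attached
#'   (stapes) mass riding as a piston; both divided by the footplate area
#'   squared.
#'
#' Rayleigh damping `alpha * M_a + beta * K_a` supplies the resistive part.
#' Stiffening the membrane (100-fold or ossification to 200 GPa) scales the
#' stiffness part proportionally; in the ossified limit the window is
#' effectively rigid.
#'
#' @param membrane An [isotropic_elasticity()] object.
#' @param area Window (footplate for the annulus) area (m^2).
#' @param thickness Plate thickness, or ligament ring thickness (m).
#' @param kind `"RWM-plate"` or `"SAL-annulus"`.
#' @param f Frequency (Hz), > 0.
#' @param attached_mass Rigidly attached mass (kg), e.g. the stapes.
#' @param ring_width Ligament ring width (m), annulus kind only.
#' @param membrane_density Plate material density (kg/m^3), plate kind only.
#' @param damping A [damping_spec()] supplying `alpha`, `beta`.
#' @param loss_factor Structural loss factor of the closure (hysteretic
#'   damping, complex stiffness `K (1 + i eta)`); soft-tissue values are
#'   0.1-0.3.  Rayleigh damping alone leaves the lumped window resonances
#'   with quality factors of order 50, far sharper than measured window
#'   impedances.
#' @return Complex impedance (Pa s/m^3), vectorized over `f`.
#' @export
window_boundary_impedance <- function(membrane, area, thickness,
                                      kind = c("RWM-plate", "SAL-annulus"),
                                      f, attached_mass = 0,
                                      ring_width = 0.1e-3,
                                      membrane_density = 1200,
                                      damping = damping_spec(),
                                      loss_factor = 0.2) {
  kind <- match.arg(kind)
  stopifnot(inherits(membrane, "isotropic_elasticity"))
  if (any(c(area, thickness, f) <= 0) || attached_mass < 0 || ring_width <= 0)
    stop("nonphysical window parameters", call. = FALSE)
  omega <- 2 * pi * f
  if (kind == "RWM-plate") {
    a <- sqrt(area / pi)
    D <- membrane$E * thickness^3 / (12 * (1 - membrane$nu^2))
    K_a <- 192 * D / (pi * a^6)                       # 1 / acoustic compliance
    M_a <- (9 / 5) * membrane_density * thickness / (pi * a^2) +
      attached_mass / area^2
  } else {
    r_fp <- sqrt(area / pi)
    K_mech <- membrane$G * (2 * pi * r_fp * thickness) / ring_width
    K_a <- K_mech / area^2
    M_a <- attached_mass / area^2
  }
  R_a <- rayleigh_damping(damping$alpha, damping$beta, M_a, K_a)
  K_a * (1 + 1i * loss_factor) / (1i * omega) + 1i * omega * M_a + R_a
}

#' Build a discrete cochlea model from a configuration
#'
#' Resolves geometry, materials, the pathology scenario and the partition
#' profiles into a reusable model object.  The scenario stiffens only the
#' window boundaries: the annular ligament governs the oval window, the
#' round window membrane the round window; basilar-membrane properties are
#' scenario-independent.
#'
#' @param config A [cochlea_config()] object (or `NULL` for defaults).
#' @param scenario Optional scenario name or `scenario_spec`, overriding
#'   `config$scenario`.
#' @return Object of class `cochlea_model` with fields `config`, `geometry`,
#'   `scenario`, `bm`, `rwm`, `sal` (pathology applied), `fluid`, `damping`,
#'   per-area profiles `m`, `k`, `r` on segment centres, and window
#'   impedance functions `z_ow(f)`, `z_rw(f)`, `z_heli(f)`.
#' @examples
#' model <- build_model()
#' sol <- solve_cochlea(model, frequency = 1000, pathway = "forward")
#' @export
build_model <- function(config = NULL, scenario = NULL) {
  if (is.null(config)) config <- cochlea_config()
  stopifnot(inherits(config, "cochlea_config"))
  if (!is.null(scenario)) {
    if (inherits(scenario, "scenario_spec")) config$scenario <- scenario$name
    else config$scenario <- scenario
  }
  scen <- make_scenario(config$scenario)
  geometry <- geometry_from_config(config)

  bm <- orthotropic_elasticity(
    E_X = config$bm$E_X, E_Y = config$bm$E_Y, E_Z = config$bm$E_Z,
    nu_xy = config$bm$nu, nu_xz = config$bm$nu, nu_yz = config$bm$nu,
    density = config$bm$density
  )
  fluid <- fluid_properties(config$fluid$rho, config$fluid$mu)
  damping <- damping_spec(config$damping$alpha, config$damping$beta,
                          config$damping$c)

  # single documented calibration scalar on the unpublished SAL baseline
  sal_base <- isotropic_elasticity(config$sal$E * config$sal$stiffness_scale,
                                   config$sal$nu)
  sal <- apply_pathology(sal_base, scen$sal_stiffness_mode)
  rwm <- apply_pathology(isotropic_elasticity(config$rwm$E, config$rwm$nu),
                         scen$rwm_stiffness_mode)

  prof <- partition_profiles_at(geometry$x, bm, geometry, damping, fluid,
                                config$bm$stiffness_constant,
                                config$bm$fluid_load_factor)
  if (any(diff(prof$k) >= 0))
    stop("partition stiffness k(x) must decrease strictly base to apex",
         call. = FALSE)

  sal_cfg <- config$sal
  rwm_cfg <- config$rwm
  z_ow <- function(f) window_boundary_impedance(
    sal, area = geometry$a_fp, thickness = sal_cfg$ring_thickness,
    kind = "SAL-annulus", f = f, attached_mass = sal_cfg$stapes_mass,
    ring_width = sal_cfg$ring_width, damping = damping,
    loss_factor = sal_cfg$loss_factor
  )
  z_rw <- function(f) window_boundary_impedance(
    rwm, area = geometry$a_rw, thickness = rwm_cfg$thickness,
    kind = "RWM-plate", f = f, membrane_density = rwm_cfg$density,
    damping = damping, loss_factor = rwm_cfg$loss_factor
  )
  z_heli <- function(f) {
    A_h <- geometry$helicotrema_area
    geometry$helicotrema_length *
      (1i * 2 * pi * f * fluid$rho / A_h + 8 * pi * fluid$mu / A_h^2)
  }

  structure(list(
    config = config, geometry = geometry, scenario = scen,
    bm = bm, rwm = rwm, sal = sal, fluid = fluid, damping = damping,
    m = prof$m, k = prof$k, r = prof$r, w = prof$w, t = prof$t,
    z_ow = z_ow, z_rw = z_rw, z_heli = z_heli
  ), class = "cochlea_model")
}

#' @export
print.cochlea_model <- function(x, ...) {
  cat(sprintf("Two-duct cochlea model: %d segments over %.1f mm, scenario '%s'\n",
              x$geometry$n_segments, x$geometry$bm_length * 1e3,
              x$scenario$name))
  invisible(x)
}

#' Assemble the frequency-domain linear system
#'
#' Nodal (admittance) assembly of the two-duct ladder at one frequency:
#' series duct admittances with fluid inertia and a Poiseuille viscous
#' loss, partition shunt admittances `w dx / z_p`, window admittances at
#' the basal nodes and the helicotrema shunt at the apical nodes.  The
#' system matrix depends only on the model and frequency; forward and
#' reverse runs differ only in the source vector.
#'
#' @param model A [build_model()] object.
#' @param f Frequency (Hz), > 0.
#' @return Object of class `cochlea_assembly` holding the block-tridiagonal
#'   coefficients; see [as.matrix.cochlea_assembly()] for the dense form.
#' @export
assemble_cochlea <- function(model, f) {
  stopifnot(inherits(model, "cochlea_model"))
  if (f <= 0) stop("frequency must be > 0", call. = FALSE)
  g <- model$geometry
  n <- g$n_segments
  omega <- 2 * pi * f
  rho <- model$fluid$rho
  mu <- model$fluid$mu

  series_adm <- function(A) {
    1 / (g$dx * (1i * omega * rho / A + 8 * pi * mu / A^2))
  }
  g_sv <- rep(series_adm(g$scala_vestibuli_area), n - 1)
  g_st <- rep(series_adm(g$scala_tympani_area), n - 1)

  z_p <- 1i * omega * model$m + (model$r + model$damping$c) +
    model$k / (1i * omega)
  y_bm <- g$bm_width_profile * g$dx / z_p

  y_ow <- 1 / model$z_ow(f)
  y_rw <- 1 / model$z_rw(f)
  y_heli <- 1 / model$z_heli(f)

  if (any(!is.finite(c(g_sv, g_st, y_bm, y_ow, y_rw, y_heli))))
    stop(sprintf("singular assembly at f = %g Hz", f), call. = FALSE)

  structure(list(
    n = n, f = f, g_sv = g_sv, g_st = g_st, y_bm = y_bm,
    y_ow = y_ow, y_rw = y_rw, y_heli = y_heli, z_p = z_p,
    model = model
  ), class = "cochlea_assembly")
}

# Diagonal 2x2 blocks (d11, d12, d21, d22) of the nodal matrix.
assembly_blocks <- function(asm) {
  n <- asm$n
  gs_prev <- c(0, asm$g_sv); gs_next <- c(asm$g_sv, 0)
  gt_prev <- c(0, asm$g_st); gt_next <- c(asm$g_st, 0)
  cross <- asm$y_bm
  cross[n] <- cross[n] + asm$y_heli
  d11 <- gs_prev + gs_next + cross
  d22 <- gt_prev + gt_next + cross
  d11[1] <- d11[1] + asm$y_ow
  d22[1] <- d22[1] + asm$y_rw
  list(d11 = d11, d12 = -cross, d21 = -cross, d22 = d22)
}

#' Dense matrix form of an assembled system
#'
#' Interleaved ordering: unknowns `(p_sv[1], p_st[1], p_sv[2], ...)`.
#' Intended for small-n verification against dense factorizations.
#'
#' @param x A `cochlea_assembly`.
#' @param ... Unused.
#' @return A complex `2n x 2n` matrix.
#' @export
as.matrix.cochlea_assembly <- function(x, ...) {
  n <- x$n
  blk <- assembly_blocks(x)
  A <- matrix(0i, 2 * n, 2 * n)
  for (i in seq_len(n)) {
    ii <- 2 * i - 1
    A[ii, ii] <- blk$d11[i]; A[ii, ii + 1] <- blk$d12[i]
    A[ii + 1, ii] <- blk$d21[i]; A[ii + 1, ii + 1] <- blk$d22[i]
    if (i < n) {
      A[ii, ii + 2] <- -x$g_sv[i]; A[ii + 2, ii] <- -x$g_sv[i]
      A[ii + 1, ii + 3] <- -x$g_st[i]; A[ii + 3, ii + 1] <- -x$g_st[i]
    }
  }
  A
}

# Source vector in interleaved ordering for a window pressure source.
assembly_rhs <- function(asm, p_ow = 0, p_rw = 0) {
  b <- rep(0i, 2 * asm$n)
  b[1] <- asm$y_ow * p_ow
  b[2] <- asm$y_rw * p_rw
  b
}

# Block Thomas solve of the interleaved block-tridiagonal system.
solve_block_tridiag <- function(asm, b) {
  n <- asm$n
  blk <- assembly_blocks(asm)
  d11 <- blk$d11; d12 <- blk$d12; d21 <- blk$d21; d22 <- blk$d22
  e1 <- asm$g_sv; e2 <- asm$g_st       # off-diagonal blocks are -diag(e1, e2)
  b1 <- b[seq(1, 2 * n, by = 2)]
  b2 <- b[seq(2, 2 * n, by = 2)]

  for (i in 2:n) {
    det <- d11[i - 1] * d22[i - 1] - d12[i - 1] * d21[i - 1]
    # W = E %*% inv(D_{i-1}) with E = -diag(e1, e2)
    W11 <- -e1[i - 1] * d22[i - 1] / det
    W12 <- e1[i - 1] * d12[i - 1] / det
    W21 <- e2[i - 1] * d21[i - 1] / det
    W22 <- -e2[i - 1] * d11[i - 1] / det
    # D_i <- D_i - W %*% E ; E = -diag(e1, e2)
    d11[i] <- d11[i] + W11 * e1[i - 1]
    d12[i] <- d12[i] + W12 * e2[i - 1]
    d21[i] <- d21[i] + W21 * e1[i - 1]
    d22[i] <- d22[i] + W22 * e2[i - 1]
    b1[i] <- b1[i] - (W11 * b1[i - 1] + W12 * b2[i - 1])
    b2[i] <- b2[i] - (W21 * b1[i - 1] + W22 * b2[i - 1])
  }

  p_sv <- rep(0i, n); p_st <- rep(0i, n)
  det <- d11[n] * d22[n] - d12[n] * d21[n]
  p_sv[n] <- (d22[n] * b1[n] - d12[n] * b2[n]) / det
  p_st[n] <- (-d21[n] * b1[n] + d11[n] * b2[n]) / det
  for (i in (n - 1):1) {
    r1 <- b1[i] + e1[i] * p_sv[i + 1]
    r2 <- b2[i] + e2[i] * p_st[i + 1]
    det <- d11[i] * d22[i] - d12[i] * d21[i]
    p_sv[i] <- (d22[i] * r1 - d12[i] * r2) / det
    p_st[i] <- (-d21[i] * r1 + d11[i] * r2) / det
  }
  list(p_sv = p_sv, p_st = p_st)
}

# Residual A x - b evaluated through the band structure.
assembly_residual <- function(asm, p_sv, p_st, b) {
  n <- asm$n
  blk <- assembly_blocks(asm)
  r1 <- blk$d11 * p_sv + blk$d12 * p_st
  r2 <- blk$d21 * p_sv + blk$d22 * p_st
  r1[1:(n - 1)] <- r1[1:(n - 1)] - asm$g_sv * p_sv[2:n]
  r1[2:n] <- r1[2:n] - asm$g_sv * p_sv[1:(n - 1)]
  r2[1:(n - 1)] <- r2[1:(n - 1)] - asm$g_st * p_st[2:n]
  r2[2:n] <- r2[2:n] - asm$g_st * p_st[1:(n - 1)]
  res <- rep(0i, 2 * n)
  res[seq(1, 2 * n, by = 2)] <- r1
  res[seq(2, 2 * n, by = 2)] <- r2
  res - b
}

#' Stimulus specification
#'
#' @param pathway `"forward"` (oval window) or `"reverse"` (round window).
#' @param frequency Stimulus frequency (Hz), > 0.
#' @param level_db Level (dB SPL) at the driven window; if `NULL`, resolved
#'   from the configuration: `ec_level + ec_gain` at the oval window,
#'   converted by [equal_force_level()] for the round window, so both
#'   pathways carry equal force.
#' @param config A [cochlea_config()] used to resolve the default level.
#' @return Object of class `stimulus_spec` with fields `pathway`,
#'   `frequency`, `level_db`, `pressure_pa`, `force_n`.
#' @export
make_stimulus <- function(pathway = c("forward", "reverse"), frequency,
                          level_db = NULL, config = cochlea_config()) {
  pathway <- match.arg(pathway)
  if (frequency <= 0) stop("frequency must be > 0", call. = FALSE)
  geom <- geometry_from_config(config)
  if (is.null(level_db)) {
    level_ow <- config$stimulus$ec_level_db + config$stimulus$ec_gain_db
    level_db <- if (pathway == "forward") level_ow
                else equal_force_level(level_ow, geom$a_ow, geom$a_rw)
  }
  area <- if (pathway == "forward") geom$a_ow else geom$a_rw
  structure(list(
    pathway = pathway, frequency = frequency, level_db = level_db,
    pressure_pa = spl_to_pressure(level_db),
    force_n = stimulus_force(level_db, area)
  ), class = "stimulus_spec")
}

#' Solve the cochlea at one frequency
#'
#' Assembles and solves the two-duct system for a forward (pressure source
#' behind the oval window) or reverse (behind the round window) stimulus,
#' and fills every probe: basilar-membrane displacement along the length,
#' duct and transpartition pressures, window volume velocities, the
#' vestibule pressure 200 um from the oval window, and the stapes footplate
#' displacement (rigid piston, `d = u_ow / (i omega a_fp)`).
#'
#' @param model A [build_model()] object.
#' @param stimulus A [make_stimulus()] object; alternatively give
#'   `frequency` and `pathway` directly.
#' @param frequency,pathway,level_db Used when `stimulus` is `NULL`.
#' @return Object of class `cochlea_solution`; fields include `x`,
#'   `x_norm`, complex displacement `d`, `p_diff`, `p_sv_nodes`,
#'   `p_st_nodes`, `u_ow`, `u_rw`, `p_sv`, `d_stapes`, `frequency`,
#'   `pathway`, `residual_rel` and `conservation`.
#' @export
solve_cochlea <- function(model, stimulus = NULL, frequency = NULL,
                          pathway = "forward", level_db = NULL) {
  stopifnot(inherits(model, "cochlea_model"))
  if (is.null(stimulus)) {
    if (is.null(frequency)) stop("give a stimulus or a frequency", call. = FALSE)
    stimulus <- make_stimulus(pathway, frequency, level_db, model$config)
  }
  stopifnot(inherits(stimulus, "stimulus_spec"))
  f <- stimulus$frequency
  asm <- assemble_cochlea(model, f)
  p_src <- stimulus$pressure_pa
  p_ow_src <- if (stimulus$pathway == "forward") p_src else 0
  p_rw_src <- if (stimulus$pathway == "reverse") p_src else 0
  b <- assembly_rhs(asm, p_ow = p_ow_src, p_rw = p_rw_src)
  sol <- solve_block_tridiag(asm, b)

  res <- assembly_residual(asm, sol$p_sv, sol$p_st, b)
  residual_rel <- sqrt(sum(Mod(res)^2)) / sqrt(sum(Mod(b)^2))

  omega <- 2 * pi * f
  g <- model$geometry
  p_diff <- sol$p_sv - sol$p_st
  u_bm <- asm$y_bm * p_diff                       # volume flux SV -> ST
  v_bm <- u_bm / (g$bm_width_profile * g$dx)
  d <- v_bm / (1i * omega)

  u_ow <- asm$y_ow * (p_ow_src - sol$p_sv[1])     # positive into the SV
  u_rw <- asm$y_rw * (p_rw_src - sol$p_st[1])     # positive into the ST
  u_heli <- asm$y_heli * (sol$p_sv[g$n_segments] - sol$p_st[g$n_segments])

  p_sv_probe <- complex_interp(g$x, sol$p_sv, g$probe_distance_ow)
  d_stapes <- u_ow / (g$a_fp * 1i * omega)

  out <- structure(list(
    x = g$x, x_norm = g$x_norm, d = d, p_diff = p_diff,
    p_sv_nodes = sol$p_sv, p_st_nodes = sol$p_st,
    u_ow = u_ow, u_rw = u_rw, u_heli = u_heli,
    p_sv = p_sv_probe, d_stapes = d_stapes,
    frequency = f, pathway = stimulus$pathway, stimulus = stimulus,
    scenario = model$scenario$name,
    residual_rel = residual_rel
  ), class = "cochlea_solution")
  out$conservation <- conservation_check(out)
  if (any(!is.finite(Mod(d))))
    stop("non-finite solution field", call. = FALSE)
  out
}

#' Volume-velocity conservation check
#'
#' Relative imbalance of the window volume velocities,
#' `|u_ow + u_rw| / max(|u_ow|, |u_rw|)` (both positive into the cochlea;
#' rigid walls and incompressible lymph imply the sum is zero — what enters
#' one window must leave the other; the helicotrema carries flow between
#' the ducts but never out of the cochlea).
#'
#' @param solution A [solve_cochlea()] result.
#' @return Dimensionless relative imbalance.
#' @export
conservation_check <- function(solution) {
  stopifnot(inherits(solution, "cochlea_solution"))
  Mod(solution$u_ow + solution$u_rw) /
    max(Mod(solution$u_ow), Mod(solution$u_rw))
}

complex_interp <- function(x, y, xout) {
  complex(
    real = stats::approx(x, Re(y), xout = xout, rule = 2)$y,
    imaginary = stats::approx(x, Im(y), xout = xout, rule = 2)$y
  )
}

#' @export
print.cochlea_solution <- function(x, ...) {
  cat(sprintf("Cochlea solution: %s, %g Hz, scenario '%s'\n",
              x$pathway, x$frequency, x$scenario))
  cat(sprintf("  max |d| = %.3g m at x/L = %.3f\n",
              max(Mod(x$d)), x$x_norm[which.max(Mod(x$d))]))
  cat(sprintf("  |u_ow| = %.3g, |u_rw| = %.3g m^3/s, conservation = %.2g\n",
              Mod(x$u_ow), Mod(x$u_rw), x$conservation))
  invisible(x)
}

#' Write a solution field to a headered CSV
#'
#' One row per segment with columns `x_m`, `x_norm`, `re_d_m`, `im_d_m`,
#' `abs_d_m`, `phase_cycles` (unwrapped, re the basal segment), plus a
#' companion `<path>_probes.csv` scalar record with the window volume
#' velocities, vestibule probe pressure and stapes displacement.
#'
#' @param solution A [solve_cochlea()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  ph <- phase_re_base(solution)
  df <- data.frame(
    x_m = solution$x, x_norm = solution$x_norm,
    re_d_m = Re(solution$d), im_d_m = Im(solution$d),
    abs_d_m = Mod(solution$d), phase_cycles = ph
  )
  utils::write.csv(df, path, row.names = FALSE)
  probes <- data.frame(
    pathway = solution$pathway, frequency_hz = solution$frequency,
    scenario = solution$scenario,
    re_u_ow = Re(solution$u_ow), im_u_ow = Im(solution$u_ow),
    re_u_rw = Re(solution$u_rw), im_u_rw = Im(solution$u_rw),
    re_p_sv = Re(solution$p_sv), im_p_sv = Im(solution$p_sv),
    re_d_stapes = Re(solution$d_stapes), im_d_stapes = Im(solution$d_stapes),
    residual_rel = solution$residual_rel, conservation = solution$conservation
  )
  utils::write.csv(probes, sub("\\.csv$", "_probes.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Calibrate the partition stiffness constant against the Greenwood map
#'
#' Finds the bending constant `C` such that the normal-model forward
#' characteristic-frequency place at the calibration frequency (1 kHz by
#' default) coincides with the Greenwood place for that frequency.  The
#' peak place moves monotonically apex-ward as `C` grows, so the root is
#' bracketed and found by bisection on `log C`.  The package default
#' `BM_STIFFNESS_CONSTANT` was produced by this routine on the default
#' configuration and is frozen so ordinary model construction does not
#' repeat the search.
#'
#' @param config A [cochlea_config()]; its `bm$stiffness_constant` is
#'   ignored during the search.
#' @param f_cal Calibration frequency (Hz).
#' @param interval Search interval for `C`.
#' @param tol Relative tolerance on `C`.
#' @return The calibrated constant (numeric scalar).
#' @export
calibrate_bm_stiffness <- function(config = cochlea_config(), f_cal = 1000,
                                   interval = c(1, 1e6), tol = 1e-4) {
  target <- greenwood_place(f_cal, config$greenwood)
  peak_at <- function(C) {
    cfg <- config
    cfg$bm$stiffness_constant <- C
    model <- build_model(cfg, scenario = "normal")
    sol <- solve_cochlea(model, frequency = f_cal, pathway = "forward")
    extract_cf(sol)
  }
  fn <- function(logC) peak_at(exp(logC)) - target
  root <- stats::uniroot(fn, lower = log(interval[1]), upper = log(interval[2]),
                         tol = tol)
  exp(root$root)
}
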