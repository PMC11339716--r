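# Constitutive relations for the cochlear partition and window membranes:
# orthotropic shear moduli and Poisson symmetry, Rayleigh damping, the
# velocity-proportional surface damping of the basilar membrane, and the
# stiffness scalings used to model window pathology.

OSSIFIED_E <- 2.0e11  # Young's modulus of bone, Pa

#' Orthotropic shear moduli
#'
#' Shear moduli of an orthotropic material from its Young's moduli and
#' primary Poisson ratios, using the orthotropic stress-strain relations
#' \deqn{G_{xy} = \frac{E_x E_y}{E_x + E_y + 2 E_y \nu_{xy}}}
#' and likewise for the xz and yz planes.  When the two in-plane moduli are
#' equal this reduces to the isotropic identity \eqn{G = E / (2(1+\nu))}.
#'
#' @param E_X,E_Y,E_Z Young's moduli (Pa), strictly positive.
#' @param nu_xy,nu_xz,nu_yz Primary Poisson ratios, each in `[0, 0.5)`.
#' @return Named list with elements `G_xy`, `G_xz`, `G_yz` (Pa).
#' @examples
#' shear_moduli(2e6, 2e4, 2e6, 0.3, 0.3, 0.3)
#' @export
shear_moduli <- function(E_X, E_Y, E_Z, nu_xy, nu_xz, nu_yz) {
  check_moduli(E_X, E_Y, E_Z)
  check_poisson(nu_xy, nu_xz, nu_yz)
  list(
    G_xy = E_X * E_Y / (E_X + E_Y + 2 * E_Y * nu_xy),
    G_xz = E_X * E_Z / (E_X + E_Z + 2 * E_Z * nu_xz),
    G_yz = E_Y * E_Z / (E_Y + E_Z + 2 * E_Z * nu_yz)
  )
}

#' Complementary Poisson ratios of an orthotropic material
#'
#' Applies the orthotropic symmetry condition \eqn{\nu_{ij}/E_i =
#' \nu_{ji}/E_j} to obtain the complementary ratios from the primary ones.
#' For the yz plane a historical variant of the third relation
#' (\eqn{\nu_{yz}/\nu_{zy} = E_z/E_y}, i.e. the reciprocal of the standard
#' symmetry) is available behind `use_printed_symmetry`; the standard form
#' is the default and the discrepancy is documented in the methods vignette.
#'
#' A complementary ratio of 0.5 or more is thermodynamically suspicious for
#' the strongly orthotropic basilar membrane; it triggers a warning, not an
#' error, because the reduced-order model never consumes it.
#'
#' @inheritParams shear_moduli
#' @param use_printed_symmetry Use the variant third relation for
#'   \eqn{\nu_{zy}} (default `FALSE`).
#' @return Named list with elements `nu_yx`, `nu_zx`, `nu_zy`.
#' @export
complementary_poisson <- function(E_X, E_Y, E_Z, nu_xy, nu_xz, nu_yz,
                                  use_printed_symmetry = FALSE) {
  check_moduli(E_X, E_Y, E_Z)
  check_poisson(nu_xy, nu_xz, nu_yz)
  out <- list(
    nu_yx = nu_xy * E_Y / E_X,
    nu_zx = nu_xz * E_Z / E_X,
    nu_zy = if (use_printed_symmetry) nu_yz * E_Y / E_Z else nu_yz * E_Z / E_Y
  )
  high <- vapply(out, function(v) v >= 0.5, logical(1))
  if (any(high)) {
    warning(sprintf(
      "complementary Poisson ratio(s) %s >= 0.5 (thermodynamic admissibility)",
      paste(names(out)[high], collapse = ", ")
    ), call. = FALSE)
  }
  out
}

#' Orthotropic elasticity of the basilar membrane
#'
#' Constructor bundling the primary constants with the derived shear moduli
#' and complementary Poisson ratios, which are recomputed on construction so
#' the object always satisfies the orthotropic relations exactly.
#'
#' @inheritParams complementary_poisson
#' @param density Material density (kg/m^3).
#' @return Object of class `orthotropic_elasticity`.
#' @export
orthotropic_elasticity <- function(E_X, E_Y, E_Z,
                                   nu_xy = 0.3, nu_xz = 0.3, nu_yz = 0.3,
                                   density = 1000,
                                   use_printed_symmetry = FALSE) {
  stopifnot(density > 0)
  G <- shear_moduli(E_X, E_Y, E_Z, nu_xy, nu_xz, nu_yz)
  nu <- suppressWarnings(
    complementary_poisson(E_X, E_Y, E_Z, nu_xy, nu_xz, nu_yz,
                          use_printed_symmetry = use_printed_symmetry)
  )
  structure(
    c(list(E_X = E_X, E_Y = E_Y, E_Z = E_Z,
           nu_xy = nu_xy, nu_xz = nu_xz, nu_yz = nu_yz,
           density = density), G, nu),
    class = "orthotropic_elasticity"
  )
}

#' Isotropic elasticity
#'
#' @param E Young's modulus (Pa), strictly positive.
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @return Object of class `isotropic_elasticity` with the derived shear
#'   modulus `G = E / (2 (1 + nu))`.
#' @export
isotropic_elasticity <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) stop("Young's modulus must be > 0", call. = FALSE)
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
    stop("Poisson ratio must lie in [0, 0.5)", call. = FALSE)
  structure(list(E = E, nu = nu, G = E / (2 * (1 + nu))),
            class = "isotropic_elasticity")
}

#' Rayleigh (proportional) damping
#'
#' Resistive term `alpha * m + beta * k` combining mass- and
#' stiffness-proportional damping.  In the frequency-domain partition
#' impedance this is the resistive part `r(x) = alpha * m(x) + beta * k(x)`
#' of a locally reacting section with per-area mass `m` and stiffness `k`.
#'
#' @param alpha Mass-proportional coefficient (1/s), >= 0.
#' @param beta Stiffness-proportional coefficient (s), >= 0.
#' @param m Mass-like term (per-area mass, kg/m^2, in the partition use).
#' @param k Stiffness-like term (per-area stiffness, Pa/m).
#' @return Damping term in the units of `alpha * m`.
#' @export
rayleigh_damping <- function(alpha, beta, m, k) {
  if (any(c(alpha, beta) < 0)) stop("Rayleigh coefficients must be >= 0", call. = FALSE)
  if (any(m < 0) || any(k < 0)) stop("m and k must be >= 0", call. = FALSE)
  alpha * m + beta * k
}

#' Velocity-proportional surface damping pressure of the basilar membrane
#'
#' The additional damping pressure applied to the membrane surface opposite
#' to its velocity, `P = -c * v`.  In the frequency domain it contributes a
#' resistance `c` (Pa s/m) per unit area to the partition impedance.
#'
#' @param v_bm Membrane velocity (m/s); may be complex in frequency-domain use.
#' @param c Damping coefficient (Pa per m/s), >= 0.
#' @return Damping pressure (Pa), `-c * v_bm`.
#' @export
bm_damping_pressure <- function(v_bm, c) {
  if (c < 0) stop("damping coefficient must be >= 0", call. = FALSE)
  -c * v_bm
}

#' Apply a pathology stiffness mode to a window membrane or ligament
#'
#' Pathological stiffening is staged: `"x100"` multiplies the Young's
#' modulus by 100 (stiffness and modulus are proportional at fixed
#' geometry), and `"ossified"` replaces it with that of bone, 200 GPa.
#' The Poisson ratio is unchanged.
#'
#' @param elasticity An [isotropic_elasticity()] object.
#' @param mode One of `"normal"`, `"x100"`, `"ossified"`.
#' @return A new `isotropic_elasticity` object.
#' @examples
#' rwm <- isotropic_elasticity(5e6, 0.49)
#' apply_pathology(rwm, "x100")$E   # 5e8
#' @export
apply_pathology <- function(elasticity, mode) {
  stopifnot(inherits(elasticity, "isotropic_elasticity"))
  if (!is.character(mode) || length(mode) != 1L ||
      !(mode %in% c("normal", "x100", "ossified")))
    stop("unknown pathology mode; use 'normal', 'x100' or 'ossified'",
         call. = FALSE)
  E <- switch(mode,
    normal   = elasticity$E,
    x100     = elasticity$E * 100,
    ossified = OSSIFIED_E
  )
  isotropic_elasticity(E, elasticity$nu)
}

#' Fluid properties of the cochlear lymph
#'
#' @param rho Density (kg/m^3), > 0.
#' @param mu Dynamic viscosity (N s/m^2), > 0.
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1034, mu = 0.0028) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Damping specification
#'
#' Rayleigh coefficients applied to the structural parts plus the
#' velocity-proportional surface damping coefficient of the basilar
#' membrane (see [bm_damping_pressure()]).
#'
#' @param alpha Mass-proportional Rayleigh coefficient (1/s).
#' @param beta Stiffness-proportional Rayleigh coefficient (s).
#' @param c Basilar-membrane surface damping coefficient (Pa s/m).
#' @return Object of class `damping_spec`.
#' @export
damping_spec <- function(alpha = 100, beta = 6.43e-7, c = 5000) {
  if (any(c(alpha, beta, c) < 0)) stop("damping parameters must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, c = c), class = "damping_spec")
}

check_moduli <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Young's moduli must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

check_poisson <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals >= 0.5))
    stop("Poisson ratios must lie in [0, 0.5)", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.orthotropic_elasticity <- function(x, ...) {
  cat("Orthotropic elasticity\n")
  cat(sprintf("  E_X = %.3g Pa, E_Y = %.3g Pa, E_Z = %.3g Pa\n", x$E_X, x$E_Y, x$E_Z))
  cat(sprintf("  nu_xy = %.3g, nu_xz = %.3g, nu_yz = %.3g\n", x$nu_xy, x$nu_xz, x$nu_yz))
  cat(sprintf("  G_xy = %.4g Pa, G_xz = %.4g Pa, G_yz = %.4g Pa\n", x$G_xy, x$G_xz, x$G_yz))
  invisible(x)
}

#' @export
print.isotropic_elasticity <- function(x, ...) {
  cat(sprintf("Isotropic elasticity: E = %.3g Pa, nu = %.3g\n", x$E, x$nu))
  invisible(x)
}
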