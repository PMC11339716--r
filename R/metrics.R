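# Verification and comparison metrics: middle ear transfer function,
# cochlear input impedance (forward) and reverse middle ear impedance,
# window volume-displacement ratio, characteristic-frequency extraction and
# the Greenwood place-frequency reference, travelling-wave phase re the
# basal edge, and the relative amplitude at reference CF locations used as
# a hearing-threshold proxy.

#' Middle ear transfer function
#'
#' `METF = 20 log10(|d_stapes| / p_ec)` in dB ref um/Pa: stapes footplate
#' displacement (in micrometres) per ear-canal pressure (Pa).
#'
#' @param d_stapes Complex or absolute stapes footplate displacement (m).
#' @param p_ec Ear-canal pressure (Pa), > 0.
#' @return METF in dB ref um/Pa.
#' @export
metf <- function(d_stapes, p_ec) {
  if (any(p_ec <= 0)) stop("ear-canal pressure must be > 0", call. = FALSE)
  20 * log10((Mod(d_stapes) * 1e6) / p_ec)
}

#' Cochlear input impedance (forward stimulation)
#'
#' `Z_C = P_SV / U_stapes`: vestibule pressure at the 200 um probe over the
#' stapes volume velocity (piston velocity times the 4.2 mm^2 footplate
#' area, which in this model is the oval-window volume velocity).
#'
#' @param p_sv Complex vestibule pressure (Pa).
#' @param u_stapes Complex stapes volume velocity (m^3/s), nonzero.
#' @return Complex impedance (Pa s/m^3).
#' @export
cochlear_input_impedance <- function(p_sv, u_stapes) {
  if (any(Mod(u_stapes) == 0)) stop("stapes volume velocity is zero", call. = FALSE)
  p_sv / u_stapes
}

#' Reverse middle ear impedance (reverse stimulation)
#'
#' `Z_ME_R = P_SV_R / U_stapes_R`, the same probes as
#' [cochlear_input_impedance()] evaluated on a reverse-stimulation solution.
#'
#' @inheritParams cochlear_input_impedance
#' @return Complex impedance (Pa s/m^3).
#' @export
reverse_middle_ear_impedance <- function(p_sv, u_stapes) {
  cochlear_input_impedance(p_sv, u_stapes)
}

#' Round-window to oval-window volume displacement ratio
#'
#' `|u_rw| / |u_ow|` on a forward solution; at a fixed frequency the
#' displacement ratio equals the velocity ratio.  Incompressibility of the
#' lymph with rigid walls forces this ratio to 1 up to solver tolerance.
#'
#' @param solution A forward [solve_cochlea()] result.
#' @return Dimensionless ratio.
#' @export
volume_displacement_ratio <- function(solution) {
  stopifnot(inherits(solution, "cochlea_solution"))
  if (Mod(solution$u_ow) == 0) stop("zero oval-window volume velocity", call. = FALSE)
  Mod(solution$u_rw) / Mod(solution$u_ow)
}

#' Extract the characteristic-frequency place from a displacement profile
#'
#' Normalized location of the maximum of `|d(x)|` with parabolic sub-grid
#' refinement on `log |d|`; ties are broken toward the base.  A profile
#' whose maximum sits at either end is returned as that endpoint with a
#' warning (no interior peak); a flat profile is an error.
#'
#' @param profile A `cochlea_solution`, or a numeric vector `|d|`.
#' @param x_norm Normalized positions for a vector `profile`.
#' @return Normalized distance from the base in `[0, 1]`.
#' @export
extract_cf <- function(profile, x_norm = NULL) {
  if (inherits(profile, "cochlea_solution")) {
    x_norm <- profile$x_norm
    profile <- Mod(profile$d)
  }
  stopifnot(is.numeric(profile), length(profile) == length(x_norm))
  if (diff(range(profile)) == 0) stop("flat displacement profile", call. = FALSE)
  i <- which.max(profile)          # which.max takes the first (basal) tie
  n <- length(profile)
  if (i == 1L || i == n) {
    warning("displacement maximum at the domain boundary; no interior peak",
            call. = FALSE)
    return(x_norm[i])
  }
  # parabolic refinement through the three log-amplitudes around the peak
  y0 <- log(profile[i - 1]); y1 <- log(profile[i]); y2 <- log(profile[i + 1])
  denom <- y0 - 2 * y1 + y2
  delta <- if (denom == 0) 0 else 0.5 * (y0 - y2) / denom
  delta <- max(min(delta, 0.5), -0.5)
  x_norm[i] + delta * (x_norm[i + 1] - x_norm[i])
}

#' Greenwood place-frequency map (human)
#'
#' `f(x) = A (10^(a (1 - x)) - k)` with `x` the normalized distance from
#' the base, using the human constants `A = 165.4` Hz, `a = 2.1`,
#' `k = 0.88` (literature values, configurable).
#'
#' @param x Normalized distance from the base, in `[0, 1]`.
#' @param constants List with elements `A`, `a`, `k`.
#' @return Frequency (Hz), strictly decreasing in `x`.
#' @examples
#' greenwood_reference(0)   # ~20.7 kHz at the base
#' greenwood_reference(1)   # ~19.8 Hz at the apex
#' @export
greenwood_reference <- function(x, constants = list(A = 165.4, a = 2.1, k = 0.88)) {
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]", call. = FALSE)
  constants$A * (10^(constants$a * (1 - x)) - constants$k)
}

#' Inverse Greenwood map: place of a frequency
#'
#' @param f Frequency (Hz), within the range of the map.
#' @param constants List with elements `A`, `a`, `k`.
#' @return Normalized distance from the base in `[0, 1]`.
#' @export
greenwood_place <- function(f, constants = list(A = 165.4, a = 2.1, k = 0.88)) {
  arg <- f / constants$A + constants$k
  x <- 1 - log10(arg) / constants$a
  if (any(x < 0 | x > 1))
    stop("frequency outside the range of the Greenwood map", call. = FALSE)
  x
}

#' Unwrapped travelling-wave phase re the basal edge
#'
#' Phase of the complex basilar-membrane displacement, unwrapped base to
#' apex, referenced to the basal segment and expressed in cycles (negative
#' values are lags).
#'
#' @param solution A [solve_cochlea()] result.
#' @param location Optional normalized location(s) at which to report the
#'   phase (linear interpolation); `NULL` returns the full profile.
#' @return Phase in cycles, profile or at `location`.
#' @export
phase_re_base <- function(solution, location = NULL) {
  stopifnot(inherits(solution, "cochlea_solution"))
  ph <- unwrap_phase(Arg(solution$d))
  cycles <- (ph - ph[1]) / (2 * pi)
  if (is.null(location)) return(cycles)
  stats::approx(solution$x_norm, cycles, xout = location, rule = 2)$y
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

#' Relative amplitude at reference CF locations
#'
#' Hearing-threshold proxy: the change, in dB, of the basilar-membrane
#' amplitude at the characteristic-frequency place of the normal model
#' under forward stimulation, `20 log10(|d(x_ref)| / |d_ref(x_ref)|)`.
#' 0 dB is the normal-forward baseline at every frequency.
#'
#' @param solution A [solve_cochlea()] result at one frequency.
#' @param reference_cf_locations Named numeric vector of normal-forward CF
#'   places, names = frequency in Hz.
#' @param reference_amplitudes Named numeric vector of normal-forward
#'   amplitudes `|d_ref(x_ref)|` at those places, same names.
#' @return Relative amplitude (dB) at the solution's frequency.
#' @export
relative_amplitude_at_cf <- function(solution, reference_cf_locations,
                                     reference_amplitudes) {
  stopifnot(inherits(solution, "cochlea_solution"))
  key <- as.character(solution$frequency)
  if (!(key %in% names(reference_cf_locations)) ||
      !(key %in% names(reference_amplitudes)))
    stop(sprintf("no normal-forward reference at %s Hz", key), call. = FALSE)
  x_ref <- reference_cf_locations[[key]]
  amp <- stats::approx(solution$x_norm, Mod(solution$d), xout = x_ref,
                       rule = 2)$y
  20 * log10(amp / reference_amplitudes[[key]])
}

#' Transfer metrics of a matched forward/reverse pair
#'
#' Convenience wrapper computing the middle ear transfer function, the
#' cochlear input impedance, the reverse middle ear impedance and the
#' volume-displacement ratio at one frequency from a forward and a reverse
#' solution of the same model.
#'
#' @param forward,reverse Forward and reverse [solve_cochlea()] results at
#'   the same frequency.
#' @param p_ec Ear-canal pressure (Pa) behind the forward stimulus.
#' @return List with `metf_db`, `z_c`, `z_me_r`, `vol_ratio`, `frequency`.
#' @export
transfer_metrics <- function(forward, reverse, p_ec) {
  stopifnot(forward$pathway == "forward", reverse$pathway == "reverse",
            forward$frequency == reverse$frequency)
  omega <- 2 * pi * forward$frequency
  list(
    metf_db = metf(forward$d_stapes, p_ec),
    z_c = cochlear_input_impedance(forward$p_sv, forward$u_ow),
    z_me_r = reverse_middle_ear_impedance(reverse$p_sv, reverse$u_ow),
    vol_ratio = volume_displacement_ratio(forward),
    frequency = forward$frequency
  )
}
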