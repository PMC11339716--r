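# Model inputs: geometry, baseline materials, pathology scenarios,
# perturbation ensembles, and the nested key/value configuration that every
# other module consumes.  The five window/membrane areas are the study's
# middle-ear values; the duct geometry uses canonical human box-model
# defaults (documented in the methods vignette) since no mesh is published
# for this class of model.

#' Default straight-cochlea geometry
#'
#' Canonical human box-model geometry: a straight cochlea of length 35 mm,
#' basilar membrane width tapering linearly 0.10 -> 0.50 mm base to apex,
#' thickness 7 -> 2 um, uniform 1.0 mm^2 scalae, and a 0.3 mm^2
#' helicotrema.  The middle-ear areas are fixed at 80 mm^2 (tympanic
#' membrane), 5.1 mm^2 (oval window membrane), 4.2 mm^2 (stapes footplate),
#' 2.3 mm^2 (round window membrane) and 0.58 mm^2 (stapes head).  The
#' vestibule pressure probe sits 200 um from the oval window.
#'
#' @param n_segments Number of partition segments (>= 2).
#' @param bm_length Basilar membrane length (m).
#' @param bm_width_base,bm_width_apex BM width at base and apex (m); the
#'   profile is linear and must be nondecreasing toward the apex.
#' @param bm_thickness_base,bm_thickness_apex BM thickness at base/apex (m).
#' @param scala_vestibuli_area,scala_tympani_area Duct cross-sections (m^2),
#'   uniform along the length.
#' @param helicotrema_area Apical shunt cross-section (m^2).
#' @param helicotrema_length Effective length of the apical fluid plug (m).
#' @param a_tm,a_ow,a_fp,a_rw,a_sh Tympanic membrane, oval window membrane,
#'   stapes footplate, round window membrane and stapes head areas (m^2).
#' @param probe_distance_ow Distance of the vestibule pressure probe from
#'   the oval window (m).
#' @return Object of class `geometry_spec` carrying, in addition to the
#'   scalars above, the segment-centre positions `x`, the normalized
#'   positions `x_norm`, the segment length `dx`, and the length-indexed
#'   profiles `bm_width_profile` and `bm_thickness_profile`.
#' @examples
#' g <- default_geometry()
#' g$a_fp * 1e6   # footplate area in mm^2
#' @export
default_geometry <- function(n_segments = 500,
                             bm_length = 35e-3,
                             bm_width_base = 0.10e-3,
                             bm_width_apex = 0.50e-3,
                             bm_thickness_base = 7e-6,
                             bm_thickness_apex = 2e-6,
                             scala_vestibuli_area = 1.0e-6,
                             scala_tympani_area = 1.0e-6,
                             helicotrema_area = 0.3e-6,
                             helicotrema_length = 1.0e-3,
                             a_tm = 80e-6,
                             a_ow = 5.1e-6,
                             a_fp = 4.2e-6,
                             a_rw = 2.3e-6,
                             a_sh = 0.58e-6,
                             probe_distance_ow = 200e-6) {
  geometry_spec(
    n_segments = n_segments, bm_length = bm_length,
    bm_width_base = bm_width_base, bm_width_apex = bm_width_apex,
    bm_thickness_base = bm_thickness_base, bm_thickness_apex = bm_thickness_apex,
    scala_vestibuli_area = scala_vestibuli_area,
    scala_tympani_area = scala_tympani_area,
    helicotrema_area = helicotrema_area,
    helicotrema_length = helicotrema_length,
    a_tm = a_tm, a_ow = a_ow, a_fp = a_fp, a_rw = a_rw, a_sh = a_sh,
    probe_distance_ow = probe_distance_ow
  )
}

#' Geometry constructor with invariant checks
#'
#' @inheritParams default_geometry
#' @return Object of class `geometry_spec`.
#' @keywords internal
geometry_spec <- function(n_segments, bm_length,
                          bm_width_base, bm_width_apex,
                          bm_thickness_base, bm_thickness_apex,
                          scala_vestibuli_area, scala_tympani_area,
                          helicotrema_area, helicotrema_length,
                          a_tm, a_ow, a_fp, a_rw, a_sh,
                          probe_distance_ow) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) stop("n_segments must be >= 2", call. = FALSE)
  lengths_areas <- c(
    bm_length, bm_width_base, bm_width_apex,
    bm_thickness_base, bm_thickness_apex,
    scala_vestibuli_area, scala_tympani_area,
    helicotrema_area, helicotrema_length,
    a_tm, a_ow, a_fp, a_rw, a_sh, probe_distance_ow
  )
  if (any(!is.finite(lengths_areas)) || any(lengths_areas <= 0))
    stop("all lengths and areas must be finite and strictly positive", call. = FALSE)
  if (bm_width_apex < bm_width_base)
    stop("BM width profile must be nondecreasing from base to apex", call. = FALSE)

  dx <- bm_length / n_segments
  x <- (seq_len(n_segments) - 0.5) * dx
  x_norm <- x / bm_length
  structure(list(
    n_segments = n_segments, bm_length = bm_length, dx = dx,
    x = x, x_norm = x_norm,
    bm_width_base = bm_width_base, bm_width_apex = bm_width_apex,
    bm_thickness_base = bm_thickness_base, bm_thickness_apex = bm_thickness_apex,
    bm_width_profile = bm_width_base + (bm_width_apex - bm_width_base) * x_norm,
    bm_thickness_profile = bm_thickness_base +
      (bm_thickness_apex - bm_thickness_base) * x_norm,
    scala_vestibuli_area = scala_vestibuli_area,
    scala_tympani_area = scala_tympani_area,
    helicotrema_area = helicotrema_area,
    helicotrema_length = helicotrema_length,
    a_tm = a_tm, a_ow = a_ow, a_fp = a_fp, a_rw = a_rw, a_sh = a_sh,
    probe_distance_ow = probe_distance_ow
  ), class = "geometry_spec")
}

#' Default material set
#'
#' Baseline constitutive parameters: orthotropic basilar membrane with
#' E_X = E_Z = 2.0e6 Pa and E_Y = 2.0e4 Pa (collagen fibres run across the
#' width, the X direction); isotropic round window membrane with
#' E = 5.0e6 Pa, nu = 0.49; stapedial annular ligament (E = 1.0e5 Pa
#' baseline, see `sal_stiffness_scale` in [cochlea_config()]); lymph of
#' density 1034 kg/m^3 and viscosity 0.0028 N s/m^2; Rayleigh damping
#' alpha = 100 1/s, beta = 6.43e-7 s; BM surface damping c = 5000 Pa s/m.
#'
#' @param nu_bm Primary Poisson ratio used for all three BM planes
#'   (not measured for the human BM; structural mid-range default 0.3).
#' @return Named list with elements `bm` (orthotropic), `rwm`, `sal`
#'   (isotropic), `fluid` ([fluid_properties()]) and
#'   `damping` ([damping_spec()]).
#' @export
default_materials <- function(nu_bm = 0.3) {
  list(
    bm = orthotropic_elasticity(E_X = 2.0e6, E_Y = 2.0e4, E_Z = 2.0e6,
                                nu_xy = nu_bm, nu_xz = nu_bm, nu_yz = nu_bm),
    rwm = isotropic_elasticity(E = 5.0e6, nu = 0.49),
    sal = isotropic_elasticity(E = 1.0e5, nu = 0.49),
    fluid = fluid_properties(rho = 1034, mu = 0.0028),
    damping = damping_spec(alpha = 100, beta = 6.43e-7, c = 5000)
  )
}

SCENARIO_NAMES <- c("normal", "sal_x100", "sal_ossified", "rwm_x100", "rwm_ossified")

#' Construct a named pathology scenario
#'
#' The five study scenarios: `normal`; stapedial annular ligament stiffened
#' 100-fold (`sal_x100`, otosclerosis/tympanosclerosis staging) or ossified
#' to 200 GPa (`sal_ossified`); round window membrane stiffened 100-fold
#' (`rwm_x100`, fibrosis or a coupling layer) or ossified (`rwm_ossified`).
#' Each scenario stiffens exactly one window boundary; the basilar membrane
#' is never altered.
#'
#' @param name One of `r paste0('"', SCENARIO_NAMES, '"', collapse = ", ")`.
#' @return Object of class `scenario_spec` with fields `name`,
#'   `sal_stiffness_mode` and `rwm_stiffness_mode`.
#' @examples
#' make_scenario("sal_ossified")
#' @export
make_scenario <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% SCENARIO_NAMES))
    stop(sprintf("unknown scenario '%s'; valid scenarios: %s",
                 paste(name, collapse = ","),
                 paste(SCENARIO_NAMES, collapse = ", ")), call. = FALSE)
  sal <- switch(name, sal_x100 = "x100", sal_ossified = "ossified", "normal")
  rwm <- switch(name, rwm_x100 = "x100", rwm_ossified = "ossified", "normal")
  structure(list(name = name, sal_stiffness_mode = sal, rwm_stiffness_mode = rwm),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': SAL %s, RWM %s\n",
              x$name, x$sal_stiffness_mode, x$rwm_stiffness_mode))
  invisible(x)
}

#' Lognormal perturbation ensemble of a parameter set
#'
#' Robustness fixture: every positive numeric scalar in `base_params` is
#' multiplied by an independent lognormal factor with unit mean and the
#' given relative standard deviation (`sigma^2 = log(1 + rel_sd^2)`,
#' `meanlog = -sigma^2/2`).  Non-numeric and non-positive entries are left
#' untouched.  Reproducible for a fixed seed.
#'
#' @param base_params Named list of parameters (may be nested one level).
#' @param n Number of ensemble members (>= 1).
#' @param rel_sd Relative standard deviation of each factor (>= 0).
#' @param seed Integer RNG seed.
#' @return List of `n` parameter sets with the same shape as `base_params`.
#' @examples
#' perturb_ensemble(list(E = 2e6, rho = 1034), 3, 0.05, seed = 7)
#' @export
perturb_ensemble <- function(base_params, n, rel_sd, seed) {
  if (rel_sd < 0) stop("rel_sd must be >= 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sigma <- sqrt(log(1 + rel_sd^2))
  perturb_one <- function(p) {
    rapply(p, function(v) {
      if (is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0)
        v * exp(stats::rnorm(1L, mean = -sigma^2 / 2, sd = sigma))
      else v
    }, how = "replace")
  }
  lapply(seq_len(n), function(i) perturb_one(base_params))
}

# ---- configuration ---------------------------------------------------------

#' Resolved model configuration
#'
#' Builds the full nested configuration from package defaults, an optional
#' YAML file and an optional list of overrides (applied in that order; any
#' omitted key keeps its default).  All values are SI.  The resolved
#' configuration is what [build_model()] and [run_matrix()] consume and what
#' [write_resolved_config()] records.
#'
#' Sections: `geometry` (see [default_geometry()]), `bm`
#' (moduli, Poisson ratio, density, the fluid-loading factor, the
#' calibrated partition stiffness constant), `rwm` and `sal` (window
#' membranes), `fluid`, `damping`, `stimulus` (ear-canal level and gain,
#' run frequencies), `greenwood` (place-frequency constants) and
#' `scenario`.
#'
#' @param file Optional path to a YAML configuration file.
#' @param overrides Optional named nested list of overrides.
#' @return Object of class `cochlea_config` (a nested list).
#' @examples
#' cfg <- cochlea_config(overrides = list(scenario = "rwm_x100"))
#' cfg$geometry$a_rw
#' @export
cochlea_config <- function(file = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    cfg <- modify_nested(cfg, yaml::read_yaml(file))
  }
  if (!is.null(overrides)) cfg <- modify_nested(cfg, overrides)
  cfg$geometry$n_segments <- as.integer(cfg$geometry$n_segments)
  if (!(cfg$scenario %in% SCENARIO_NAMES))
    stop(sprintf("unknown scenario '%s'; valid scenarios: %s", cfg$scenario,
                 paste(SCENARIO_NAMES, collapse = ", ")), call. = FALSE)
  structure(cfg, class = "cochlea_config")
}

default_config <- function() {
  list(
    geometry = list(
      n_segments = 500L, bm_length = 35e-3,
      bm_width_base = 0.10e-3, bm_width_apex = 0.50e-3,
      bm_thickness_base = 7e-6, bm_thickness_apex = 2e-6,
      scala_vestibuli_area = 1.0e-6, scala_tympani_area = 1.0e-6,
      helicotrema_area = 0.3e-6, helicotrema_length = 1.0e-3,
      a_tm = 80e-6, a_ow = 5.1e-6, a_fp = 4.2e-6, a_rw = 2.3e-6,
      a_sh = 0.58e-6, probe_distance_ow = 200e-6
    ),
    bm = list(
      E_X = 2.0e6, E_Y = 2.0e4, E_Z = 2.0e6,
      nu = 0.3, density = 1000,
      fluid_load_factor = pi / 4,
      stiffness_constant = BM_STIFFNESS_CONSTANT
    ),
    rwm = list(E = 5.0e6, nu = 0.49, thickness = 70e-6, density = 1200,
               loss_factor = 0.2),
    sal = list(E = 1.0e5, nu = 0.49, ring_width = 0.1e-3,
               ring_thickness = 0.2e-3, stiffness_scale = 3.0,
               stapes_mass = 3e-6, loss_factor = 0.2),
    fluid = list(rho = 1034, mu = 0.0028),
    damping = list(alpha = 100, beta = 6.43e-7, c = 5000),
    stimulus = list(ec_level_db = 60, ec_gain_db = 26,
                    frequencies = c(125, 250, 500, 1000, 2000, 4000)),
    greenwood = list(A = 165.4, a = 2.1, k = 0.88),
    scenario = "normal"
  )
}

modify_nested <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_nested(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Write the resolved configuration to a YAML file
#'
#' Records every effective value (defaults plus overrides) so a run can be
#' reproduced from the emitted file alone.
#'
#' @param config A [cochlea_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  stopifnot(inherits(config, "cochlea_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Geometry from a resolved configuration
#' @param config A [cochlea_config()] object.
#' @return A `geometry_spec` object.
#' @export
geometry_from_config <- function(config) {
  g <- config$geometry
  geometry_spec(
    n_segments = g$n_segments, bm_length = g$bm_length,
    bm_width_base = g$bm_width_base, bm_width_apex = g$bm_width_apex,
    bm_thickness_base = g$bm_thickness_base, bm_thickness_apex = g$bm_thickness_apex,
    scala_vestibuli_area = g$scala_vestibuli_area,
    scala_tympani_area = g$scala_tympani_area,
    helicotrema_area = g$helicotrema_area,
    helicotrema_length = g$helicotrema_length,
    a_tm = g$a_tm, a_ow = g$a_ow, a_fp = g$a_fp, a_rw = g$a_rw, a_sh = g$a_sh,
    probe_distance_ow = g$probe_distance_ow
  )
}
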