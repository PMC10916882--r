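#' Physical configuration of the six-mass model
#'
#' Fixed model constants in the interface units used throughout the package
#' (mm, ms, g at the boundaries; the integrator itself works in SI units).
#' The defaults are the standard specification of the dimensionality-reduced
#' one-dimensional six-mass model: each vocal fold is a 3 (longitudinal) x 2
#' (vertical) grid of masses restricted to lateral motion, anchored to sampled
#' rest positions, coupled vertically and longitudinally by nonlinear springs,
#' and driven by a Bernoulli subglottal pressure force.
#'
#' Masses and anchor stiffnesses are per vertical level and already divided
#' over the three longitudinal sections (hence the `/3`). The collision spring
#' stiffness is `k_c_factor * xi_c * k_a` with `k_c_factor = 3`, the classical
#' two-mass-model collision convention relating contact stiffness to anchor
#' stiffness.
#'
#' @param mass_bottom,mass_top vertical-pair member masses in g (per section)
#' @param k_a_bottom,k_a_top anchor spring stiffnesses in N/m (per section)
#' @param p_s subglottal pressure in Pa
#' @param xi_c collision stiffness proportionality (unitless)
#' @param xi_l longitudinal stiffness proportionality (unitless); the stiffness
#'   of a longitudinal spring is `xi_l` times the summed adjacent anchor
#'   stiffnesses
#' @param k_v vertical coupling stiffness in N/m. The default is 1000 N/m
#'   (1 N/mm): with the much weaker values sometimes quoted for this constant
#'   the upper masses decouple from the driven lower masses and the extracted
#'   edge trajectories degenerate to rest; see the methods vignette for the
#'   identification of this value
#' @param r_a anchor damping in Ns/m
#' @param eta cubic anchor coefficient in 1/cm^2 (the anchor elastic term is
#'   multiplied by `1 + eta * x^2` with the deflection `x` in cm)
#' @param ell_l longitudinal free length in cm
#' @param ell_v vertical free length (and plate thickness) in cm
#' @param vf_length anterior-posterior vocal-fold elongation in cm; must equal
#'   `4 * ell_l`
#' @param anchor_lateral_posterior lateral position of the fixed posterior end
#'   of the longitudinal spring chain, in mm (magnitude; applied with the
#'   side's outward sign)
#' @param anchor_lateral_anterior same for the anterior end, in mm
#' @param dt integration time step in ms
#' @param n_steps number of time steps per simulation
#' @param initial_lower_deflection initial outward deflection of the lower
#'   masses in mm
#' @param k_c_factor multiple of `k_a` entering the collision stiffness
#' @param smooth_eps smoothing length (mm) of the sign function used for the
#'   direction of the lateral coupling response, `2 sigmoid(x / eps) - 1`
#'
#' @return an object of class `phys_config` (a validated named list)
#' @export
phys_config <- function(mass_bottom = 0.125 / 3,
                        mass_top = 0.025 / 3,
                        k_a_bottom = 80 / 3,
                        k_a_top = 8 / 3,
                        p_s = 800,
                        xi_c = 1,
                        xi_l = 0.2,
                        k_v = 1000,
                        r_a = 0.0002 / 3,
                        eta = 100,
                        ell_l = 0.5,
                        ell_v = 0.2,
                        vf_length = 2,
                        anchor_lateral_posterior = 0.05,
                        anchor_lateral_anterior = 0,
                        dt = 0.25,
                        n_steps = 1000L,
                        initial_lower_deflection = 1,
                        k_c_factor = 3,
                        smooth_eps = 1) {
  cfg <- list(
    mass_bottom = mass_bottom, mass_top = mass_top,
    k_a_bottom = k_a_bottom, k_a_top = k_a_top,
    p_s = p_s, xi_c = xi_c, xi_l = xi_l, k_v = k_v, r_a = r_a,
    eta = eta, ell_l = ell_l, ell_v = ell_v, vf_length = vf_length,
    anchor_lateral_posterior = anchor_lateral_posterior,
    anchor_lateral_anterior = anchor_lateral_anterior,
    dt = dt, n_steps = as.integer(n_steps),
    initial_lower_deflection = initial_lower_deflection,
    k_c_factor = k_c_factor, smooth_eps = smooth_eps
  )
  validate_phys_config(cfg)
  structure(cfg, class = "phys_config")
}

validate_phys_config <- function(cfg) {
  pos <- c("mass_bottom", "mass_top", "k_a_bottom", "k_a_top", "k_v",
           "ell_l", "ell_v", "vf_length", "dt", "smooth_eps")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      abort(sprintf("phys_config field '%s' must be a single positive number", f))
    }
  }
  nonneg <- c("p_s", "xi_c", "xi_l", "r_a", "eta", "k_c_factor",
              "anchor_lateral_posterior", "anchor_lateral_anterior")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] < 0) {
      abort(sprintf("phys_config field '%s' must be a single non-negative number", f))
    }
  }
  if (cfg$n_steps < 1L) abort("n_steps must be >= 1")
  if (abs(cfg$vf_length - 4 * cfg$ell_l) > 1e-12) {
    abort("vf_length must equal 4 * ell_l")
  }
  invisible(cfg)
}

#' @export
print.phys_config <- function(x, ...) {
  cat("<phys_config> six-mass model constants\n")
  cat(sprintf("  masses (g/section):   bottom %.5f, top %.5f\n",
              x$mass_bottom, x$mass_top))
  cat(sprintf("  anchors (N/m):        bottom %.3f, top %.3f (r_a %.3g Ns/m)\n",
              x$k_a_bottom, x$k_a_top, x$r_a))
  cat(sprintf("  P_S %.0f Pa, xi_c %.2f (x%.0f), xi_l %.2f, k_v %.2f N/m, eta %.0f /cm^2\n",
              x$p_s, x$xi_c, x$k_c_factor, x$xi_l, x$k_v, x$eta))
  cat(sprintf("  geometry (cm):        ell_l %.2f, ell_v %.2f, length %.2f\n",
              x$ell_l, x$ell_v, x$vf_length))
  cat(sprintf("  integration:          dt %.3g ms x %d steps (%.1f ms)\n",
              x$dt, x$n_steps, x$dt * x$n_steps))
  invisible(x)
}

# interface -> SI converters (single source of truth for unit handling)
MM <- 1e-3   # mm  -> m
CM <- 1e-2   # cm  -> m
G  <- 1e-3   # g   -> kg
MS <- 1e-3   # ms  -> s

# Internal SI snapshot of a phys_config, as a flat numeric vector consumed by
# both the R reference force assembly and the C++ integrator core.
config_si <- function(cfg) {
  c(
    m_bottom = cfg$mass_bottom * G,
    m_top = cfg$mass_top * G,
    k_a_bottom = cfg$k_a_bottom,
    k_a_top = cfg$k_a_top,
    p_s = cfg$p_s,
    xi_c = cfg$xi_c,
    xi_l = cfg$xi_l,
    k_v = cfg$k_v,
    r_a = cfg$r_a,
    eta = cfg$eta / CM^2,             # 1/cm^2 -> 1/m^2
    ell_l = cfg$ell_l * CM,
    ell_v = cfg$ell_v * CM,
    seg_width = cfg$vf_length * CM / 3,
    anchor_post = cfg$anchor_lateral_posterior * MM,
    anchor_ant = cfg$anchor_lateral_anterior * MM,
    dt = cfg$dt * MS,
    init_defl = cfg$initial_lower_deflection * MM,
    k_c_factor = cfg$k_c_factor,
    smooth_eps = cfg$smooth_eps * MM
  )
}

#' Read / write a physical configuration as YAML
#'
#' The YAML document mirrors the [phys_config()] fields with the units
#' documented there. A defaults file matching the standard model table ships
#' with the package (`system.file("extdata", "default_config.yaml",
#' package = "sixmass")`).
#'
#' @param path file path
#' @param cfg a `phys_config`
#' @return `read_phys_config()` returns a `phys_config`;
#'   `write_phys_config()` returns `path` invisibly.
#' @export
read_phys_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(phys_config, lst)
}

#' @rdname read_phys_config
#' @export
write_phys_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "phys_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' Construct a scaling vector
#'
#' The 14 positive multiplicative factors defining one six-mass model
#' instance: six reciprocal vertical-pair mass factors (the effective mass of
#' both members of a pair is the default mass divided by the factor), six
#' anchor stiffness factors (applied to both anchor springs of a pair), one
#' subglottal pressure factor and one collision proportionality factor. The
#' identity vector reproduces the model defaults.
#'
#' @param x numeric vector of length 14 (optionally named as
#'   [scaling_names()]), or missing for the identity vector
#' @return named numeric vector of class `scaling_vector`
#' @export
scaling_vector <- function(x = rep(1, 14)) {
  nm <- scaling_names()
  if (!is.numeric(x) || length(x) != 14L) {
    abort("a scaling vector has exactly 14 numeric components")
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), nm)) abort("unexpected scaling component names")
    x <- x[nm]
  } else {
    names(x) <- nm
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("all scaling components must be finite and strictly positive")
  }
  structure(x, class = c("scaling_vector", "numeric"))
}

#' Construct a rest-position grid
#'
#' Six signed lateral rest positions in mm, one per vertical mass pair,
#' ordered as [trajectory_row_labels()]. Left entries are non-positive and
#' right entries non-negative (left trajectories are signed negative by
#' convention).
#'
#' @param x numeric vector of length 6 (mm)
#' @return named numeric vector of class `rest_positions`
#' @export
rest_positions <- function(x) {
  if (!is.numeric(x) || length(x) != 6L) {
    abort("a rest-position grid has exactly 6 entries")
  }
  if (any(!is.finite(x))) abort("rest positions must be finite")
  if (any(x[1:3] > 0) || any(x[4:6] < 0)) {
    abort("left rest positions must be <= 0 and right rest positions >= 0")
  }
  names(x) <- trajectory_row_labels()
  structure(x, class = c("rest_positions", "numeric"))
}
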