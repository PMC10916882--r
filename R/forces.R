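#' Damped linear spring force
#'
#' Force of a damped linear spring with vectorial deflection `s`, free length
#' `ell`, stiffness `k` and damping factor `r`:
#' `-(k (||s|| - ell) + r (s/||s||) . sdot) * s/||s||`.
#' The force is antisymmetric under `s -> -s`, `sdot -> -sdot` and vanishes at
#' the free length with zero velocity.
#'
#' @param s deflection vector (length 3, or any length)
#' @param sdot deflection velocity vector, same length as `s`
#' @param k stiffness (N/m)
#' @param r damping factor (Ns/m)
#' @param ell free length (same unit as `s`)
#' @return force vector, same shape as `s`
#' @export
spring_force <- function(s, sdot, k, r, ell) {
  if (any(!is.finite(s)) || any(!is.finite(sdot)) ||
      !is.finite(k) || !is.finite(r) || !is.finite(ell)) {
    abort("spring_force: non-finite input")
  }
  ns <- sqrt(sum(s^2))
  if (ns == 0) {
    if (ell == 0) return(s * 0)
    abort("spring_force: zero deflection with non-zero free length is undefined")
  }
  shat <- s / ns
  -(k * (ns - ell) + r * sum(shat * sdot)) * shat
}

#' Lateral anchor force with cubic stiffening
#'
#' Scalar lateral force drawing a mass towards its rest position. The elastic
#' term is a linear spring multiplied by `(1 + eta * dx^2)`; with `eta = 0`
#' it reduces to the lateral form of [spring_force()] with zero free length.
#'
#' @param x lateral position
#' @param v lateral velocity
#' @param x_rest lateral rest position (same unit as `x`)
#' @param k_a anchor stiffness
#' @param r_a anchor damping
#' @param eta cubic coefficient in reciprocal squared units of `x`
#' @return scalar force
#' @export
anchor_force_lateral <- function(x, v, x_rest, k_a, r_a, eta) {
  if (any(!is.finite(c(x, v, x_rest, k_a, r_a, eta)))) {
    abort("anchor_force_lateral: non-finite input")
  }
  dx <- x - x_rest
  -k_a * dx * (1 + eta * dx^2) - r_a * v
}

#' Lateral coupling spring response
#'
#' Lateral force transmitted by a coupling spring of free length `ell` whose
#' ends are offset laterally by `dx`: magnitude `k (sqrt(dx^2 + ell^2) - ell)`
#' acting to restore `dx` towards zero. The sign is smoothed through
#' `2 sigmoid(dx / eps) - 1` so the force is continuous (and exactly zero) at
#' `dx = 0`; it is an odd function of `dx`.
#'
#' @param dx relative lateral deflection between the spring's ends
#' @param k stiffness
#' @param ell free length (>= 0, same unit as `dx`)
#' @param eps sign-smoothing length (same unit as `dx`)
#' @return scalar force (same sign convention as `-dx`)
#' @export
coupling_lateral_force <- function(dx, k, ell, eps = 1e-3) {
  stopifnot(ell >= 0, eps > 0)
  mag <- k * (sqrt(dx^2 + ell^2) - ell)
  dir <- 2 / (1 + exp(-dx / eps)) - 1
  -dir * mag
}

# internal: state <-> flat layout used by the C++ core
# arrays are [side (L,R), section (P,M,A), level (bottom, top)]
state_to_flat <- function(a) {
  stopifnot(length(dim(a)) == 3L, all(dim(a) == c(2L, 3L, 2L)))
  out <- numeric(12)
  for (s in 1:2) for (j in 1:3) for (l in 1:2) {
    out[(s - 1) * 6 + (j - 1) * 2 + l] <- a[s, j, l]
  }
  out
}

flat_to_state <- function(v) {
  a <- array(0, dim = c(2L, 3L, 2L),
             dimnames = list(SIDES, SECTIONS, c("bottom", "top")))
  for (s in 1:2) for (j in 1:3) for (l in 1:2) {
    a[s, j, l] <- v[(s - 1) * 6 + (j - 1) * 2 + l]
  }
  a
}

#' Construct a simulation state
#'
#' Lateral positions and velocities of the twelve masses as 2 x 3 x 2 arrays
#' (side x longitudinal section x vertical level), in SI units (m, m/s).
#'
#' @param x,v numeric 2 x 3 x 2 arrays
#' @param t time (s)
#' @return an object of class `sim_state`
#' @export
sim_state <- function(x, v = array(0, dim = c(2, 3, 2)), t = 0) {
  x <- as_state_array(x)
  v <- as_state_array(v)
  if (any(!is.finite(x)) || any(!is.finite(v)) || !is.finite(t)) {
    abort("sim_state entries must be finite")
  }
  structure(list(x = x, v = v, t = t), class = "sim_state")
}

as_state_array <- function(a) {
  if (is.null(dim(a))) {
    stopifnot(length(a) == 12L)
    a <- flat_to_state(a)
  }
  stopifnot(all(dim(a) == c(2L, 3L, 2L)))
  dimnames(a) <- list(SIDES, SECTIONS, c("bottom", "top"))
  a
}

# effective (scaled) parameters of one model instance, SI
effective_params <- function(q, cfg) {
  q <- scaling_vector(q)
  si <- config_si(cfg)
  qm <- matrix(q[1:6], nrow = 2, byrow = TRUE)    # [side, section]
  qk <- matrix(q[7:12], nrow = 2, byrow = TRUE)
  mass <- array(0, dim = c(2, 3, 2))
  ka <- array(0, dim = c(2, 3, 2))
  for (l in 1:2) {
    mass[, , l] <- (if (l == 1) si[["m_bottom"]] else si[["m_top"]]) / qm
    ka[, , l] <- (if (l == 1) si[["k_a_bottom"]] else si[["k_a_top"]]) * qk
  }
  list(si = si, mass = mass, k_a = ka,
       p_s = si[["p_s"]] * q[["p_s"]],
       xi_c = si[["xi_c"]] * q[["xi_c"]])
}

#' Collision forces
#'
#' Push-back force handling vocal-fold overlap. For every (section, level)
#' where the left mass has crossed the right one, a zero-free-length spring of
#' stiffness `k_c = k_c_factor * xi_c * k_a` (the mean anchor stiffness of the
#' two colliding masses) acts on the half-penetration depth, with equal
#' magnitude and opposite sign on the paired masses; zero otherwise.
#'
#' @param state a [sim_state()]
#' @param q a [scaling_vector()]
#' @param cfg a [phys_config()]
#' @return 2 x 3 x 2 array of lateral forces (N)
#' @export
collision_force <- function(state, q = scaling_vector(), cfg = phys_config()) {
  ep <- effective_params(q, cfg)
  F <- array(0, dim = c(2, 3, 2))
  for (j in 1:3) for (l in 1:2) {
    pen <- state$x[1, j, l] - state$x[2, j, l]
    if (pen > 0) {
      kc <- ep$si[["k_c_factor"]] * ep$xi_c * 0.5 * (ep$k_a[1, j, l] + ep$k_a[2, j, l])
      F[1, j, l] <- -kc * pen / 2
      F[2, j, l] <- kc * pen / 2
    }
  }
  F
}

#' Bernoulli driving force
#'
#' Subglottal pressure force opening the glottis, applied per longitudinal
#' column: when the lower gap `w1` of a column is open, the lower masses feel
#' an outward force `P1 * A` over the plate area `A = (vf_length/3) * ell_v`,
#' with `P1 = P_S` when the upper section is closed, `P1 = P_S (1 -
#' (w2/w1)^2)` in a convergent channel (`w2 < w1`), and zero in a divergent
#' channel or above the point of closure (upper masses never feel pressure).
#' The force is linear in `P_S`.
#'
#' @inheritParams collision_force
#' @param p_s subglottal pressure (Pa); defaults to the scaled configuration
#'   value
#' @return 2 x 3 x 2 array of lateral forces (N)
#' @export
driving_force <- function(state, q = scaling_vector(), cfg = phys_config(),
                          p_s = NULL) {
  ep <- effective_params(q, cfg)
  if (is.null(p_s)) p_s <- ep$p_s
  stopifnot(p_s >= 0)
  plate <- ep$si[["seg_width"]] * ep$si[["ell_v"]]
  F <- array(0, dim = c(2, 3, 2))
  for (j in 1:3) {
    w1 <- state$x[2, j, 1] - state$x[1, j, 1]
    w2 <- state$x[2, j, 2] - state$x[1, j, 2]
    if (w1 > 0) {
      p1 <- if (w2 <= 0) p_s else if (w2 < w1) p_s * (1 - (w2 / w1)^2) else 0
      F[1, j, 1] <- -p1 * plate
      F[2, j, 1] <- p1 * plate
    }
  }
  F
}

#' Total lateral acceleration
#'
#' Assembles anchor, vertical-coupling, longitudinal-coupling, collision and
#' driving forces and divides by the effective masses (`m` scaled by the
#' reciprocal of the mass factors). The stiffness of each longitudinal spring
#' is `xi_l` times the summed adjacent anchor stiffnesses; chain ends attach
#' to fixed lateral positions (posterior `+-anchor_lateral_posterior`,
#' anterior `anchor_lateral_anterior`, outward sign per side).
#'
#' This is the plain-R reference implementation; the integrator uses an
#' equivalent compiled version, and the two are held together by tests.
#'
#' @inheritParams collision_force
#' @param rest a [rest_positions()] grid (mm)
#' @return 2 x 3 x 2 array of accelerations (m/s^2)
#' @export
total_acceleration <- function(state, q = scaling_vector(),
                               rest = rest_positions(numeric(6)),
                               cfg = phys_config()) {
  ep <- effective_params(q, cfg)
  si <- ep$si
  eps <- si[["smooth_eps"]]
  rest_m <- matrix(as.numeric(rest) * MM, nrow = 2, byrow = TRUE)  # [side, sec]

  F <- array(0, dim = c(2, 3, 2))
  # anchor
  for (s in 1:2) for (j in 1:3) for (l in 1:2) {
    F[s, j, l] <- F[s, j, l] + anchor_force_lateral(
      state$x[s, j, l], state$v[s, j, l], rest_m[s, j],
      ep$k_a[s, j, l], si[["r_a"]], si[["eta"]]
    )
  }
  # vertical coupling
  for (s in 1:2) for (j in 1:3) {
    d <- state$x[s, j, 2] - state$x[s, j, 1]
    f <- coupling_lateral_force(d, si[["k_v"]], si[["ell_v"]], eps)
    F[s, j, 2] <- F[s, j, 2] + f
    F[s, j, 1] <- F[s, j, 1] - f
  }
  # longitudinal chains
  for (s in 1:2) {
    sgn <- if (s == 1) -1 else 1
    for (l in 1:2) {
      node <- c(sgn * si[["anchor_post"]], state$x[s, , l], sgn * si[["anchor_ant"]])
      kk <- si[["xi_l"]] * c(2 * ep$k_a[s, 1, l],
                             ep$k_a[s, 1, l] + ep$k_a[s, 2, l],
                             ep$k_a[s, 2, l] + ep$k_a[s, 3, l],
                             2 * ep$k_a[s, 3, l])
      for (sp in 1:4) {
        d <- node[sp] - node[sp + 1]
        f <- coupling_lateral_force(d, kk[sp], si[["ell_l"]], eps)
        # force -f on upstream node (restores d), +f reaction on downstream
        if (sp > 1) F[s, sp - 1, l] <- F[s, sp - 1, l] + f
        if (sp < 4) F[s, sp, l] <- F[s, sp, l] - f
      }
    }
  }
  F <- F + collision_force(state, q, cfg) + driving_force(state, q, cfg)
  if (any(!is.finite(F))) {
    abort(sprintf("non-finite force at t = %g s (components: %s)", state$t,
                  paste(which(!is.finite(F)), collapse = ", ")))
  }
  F / ep$mass
}

#' One classical fourth-order Runge-Kutta step
#'
#' Advances a [sim_state()] by `dt` under an acceleration function
#' `accel_fn(state)` returning a 2 x 3 x 2 array. Fourth-order accurate on
#' smooth force segments.
#'
#' @param state a [sim_state()]
#' @param dt time step (s)
#' @param accel_fn function of a `sim_state` returning accelerations
#' @return the advanced `sim_state`
#' @export
rk4_step <- function(state, dt, accel_fn) {
  stopifnot(dt > 0)
  x <- state$x; v <- state$v; t <- state$t
  a1 <- accel_fn(state)
  k1x <- v; k1v <- a1
  s2 <- sim_state(x + dt / 2 * k1x, v + dt / 2 * k1v, t + dt / 2)
  a2 <- accel_fn(s2)
  k2x <- s2$v; k2v <- a2
  s3 <- sim_state(x + dt / 2 * k2x, v + dt / 2 * k2v, t + dt / 2)
  a3 <- accel_fn(s3)
  k3x <- s3$v; k3v <- a3
  s4 <- sim_state(x + dt * k3x, v + dt * k3v, t + dt)
  a4 <- accel_fn(s4)
  k4x <- s4$v; k4v <- a4
  sim_state(x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x),
            v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v),
            t + dt)
}
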