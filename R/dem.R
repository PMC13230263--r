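# Discrete element phase: particle containers, Hertzian soft-sphere contact
# parameters, the DEM stability time scales, and thin wrappers over the
# compiled contact/integration kernels.

#' Create a particle set
#'
#' Particles are RBC-surrogate solid spheres (volume-equivalent to the cell);
#' the moment of inertia is the solid-sphere value `I_p = m_p d_p^2 / 10`.
#'
#' @param pos n x 3 matrix of positions \[m\].
#' @param d_p Particle diameter \[m\].
#' @param rho_p Particle density \[kg/m^3\].
#' @param vel Optional n x 3 initial velocities (default zero).
#' @return A data.frame of class `rbc_particles` with positions, velocities,
#'   angular velocities and cached closure outputs.
#' @export
make_particles <- function(pos, d_p, rho_p = 1100, vel = NULL) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  m_p <- rho_p * pi * d_p^3 / 6
  zed <- numeric(n)
  out <- data.frame(id = seq_len(n),
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
                    ox = zed, oy = zed, oz = zed)
  attr(out, "d_p") <- d_p
  attr(out, "rho_p") <- rho_p
  attr(out, "m_p") <- m_p
  attr(out, "I_p") <- m_p * d_p^2 / 10
  attr(out, "V_p") <- pi * d_p^3 / 6
  out$DI <- rep(NA_real_, n); out$C_d <- rep(NA_real_, n)
  out$C_l <- rep(NA_real_, n); out$Re_p <- rep(NA_real_, n)
  class(out) <- c("rbc_particles", "data.frame")
  out
}

#' Soft-sphere contact parameters
#'
#' Hertz normal contact with restitution-based damping and a regularised
#' Coulomb tangential force. The defaults are a soft-cell surrogate chosen to
#' keep the Rayleigh time tractable; all are configuration-overridable.
#'
#' @param E_eff Effective Young's modulus \[Pa\].
#' @param poisson Poisson ratio.
#' @param restitution Restitution coefficient `e` in `(0, 1]`.
#' @param friction Sliding friction coefficient `mu_f >= 0`.
#' @return A list of class `contact_params`.
#' @export
contact_params <- function(E_eff = 1000, poisson = 0.3, restitution = 0.5,
                           friction = 0.1) {
  stopifnot(E_eff > 0, poisson > 0, poisson < 0.5,
            restitution > 0, restitution <= 1, friction >= 0)
  structure(list(E_eff = E_eff, poisson = poisson,
                 restitution = restitution, friction = friction),
            class = "contact_params")
}

#' Rayleigh time of a particle
#'
#' Elastic (surface) wave propagation time across a particle,
#' `t_Ray = pi (d_p/2) sqrt(rho_p / G) / (0.1631 nu_P + 0.8766)` with the
#' shear modulus `G = E / (2 (1 + nu_P))`. The stable DEM step must satisfy
#' `dt_DEM < 0.1 min(t_Ray, t_Her)`.
#'
#' @param d_p Particle diameter \[m\].
#' @param rho_p Particle density \[kg/m^3\].
#' @param params [contact_params()].
#' @return Time \[s\].
#' @export
rayleigh_time <- function(d_p, rho_p, params = contact_params()) {
  G <- params$E_eff / (2 * (1 + params$poisson))
  pi * (d_p / 2) * sqrt(rho_p / G) / (0.1631 * params$poisson + 0.8766)
}

#' Hertz contact duration
#'
#' `t_Her = 2.87 (m_eff^2 / (R_eff E*^2 v))^{1/5}` for a binary collision at
#' impact speed `v`, with `E* = E / (2 (1 - nu_P^2))` the pair modulus,
#' `m_eff = m_p / 2`, `R_eff = d_p / 4`. Zero impact speed is replaced by
#' `v_floor` (the case bulk velocity in the simulator).
#'
#' @inheritParams rayleigh_time
#' @param v_impact Impact speed \[m/s\].
#' @param v_floor Floor used when `v_impact` is zero.
#' @return Time \[s\].
#' @export
hertz_time <- function(d_p, rho_p, params = contact_params(), v_impact,
                       v_floor = 1e-3) {
  v <- if (v_impact <= 0) v_floor else v_impact
  m_eff <- rho_p * pi * d_p^3 / 6 / 2
  R_eff <- d_p / 4
  E_star <- params$E_eff / (2 * (1 - params$poisson^2))
  2.87 * (m_eff^2 / (R_eff * E_star^2 * v))^0.2
}

# Geometry descriptor consumed by the compiled kernels.
# type 0: none (free space); 1: cylinder wall r = R_c, periodic z of length L;
# 2: planar slot |y| <= h(x), periodic x of length L and depth of length W.
geometry_descriptor <- function(spec = NULL, n_h = 256L) {
  if (is.null(spec)) {
    return(list(type = 0L, R_c = 0, L = 0, W = 0,
                h_table = numeric(0), dx_table = 0))
  }
  if (spec$topology == "axisymmetric") {
    list(type = 1L, R_c = spec$R_c, L = spec$L, W = 0,
         h_table = numeric(0), dx_table = 0)
  } else {
    xs <- (seq_len(n_h) - 0.5) * spec$L / n_h
    list(type = 2L, R_c = spec$R_c, L = spec$L, W = spec$depth,
         h_table = channel_half_height(spec, xs), dx_table = spec$L / n_h)
  }
}

#' Evaluate soft-sphere contact forces
#'
#' Hertz normal force with restitution-based damping and regularised Coulomb
#' friction, for particle-particle and particle-wall contacts. Pair forces
#' are equal and opposite by construction. Overlaps beyond `0.1 d_p` trigger
#' a time-step warning.
#'
#' @param particles A [make_particles()] set.
#' @param spec A [channel_spec()] providing the wall geometry, or `NULL` for
#'   free space (no walls).
#' @param params [contact_params()].
#' @return List with `F` (n x 3 forces \[N\]), `torque` (n x 3 \[N m\]) and
#'   `max_overlap` (relative to `d_p`).
#' @export
contact_forces <- function(particles, spec = NULL, params = contact_params()) {
  geom <- geometry_descriptor(spec)
  out <- cpp_contact_forces(
    as.matrix(particles[, c("x", "y", "z")]),
    as.matrix(particles[, c("vx", "vy", "vz")]),
    as.matrix(particles[, c("ox", "oy", "oz")]),
    attr(particles, "d_p"), attr(particles, "m_p"),
    unlist(params[c("E_eff", "poisson", "restitution", "friction")]),
    geom$type, geom$R_c, geom$L, geom$W, geom$h_table, geom$dx_table)
  if (out$max_overlap > 0.1)
    warning("contact overlap exceeds 0.1 d_p: DEM time step too large")
  out
}

#' Single explicit DEM substep under prescribed forces
#'
#' Reference symplectic (semi-implicit Euler) update used for elementary
#' checks: `v <- v + dt F / m_p`, `x <- x + dt v`. The production integrator
#' (velocity-Verlet with contacts and fluid closures) lives in the compiled
#' kernel used by [run_coupled()].
#'
#' @param particles A [make_particles()] set.
#' @param forces n x 3 force matrix \[N\].
#' @param dt_dem Time step \[s\].
#' @param dt_max Stability bound; `dt_dem` must stay below it (default
#'   `Inf`, i.e. unchecked).
#' @return The advanced particle set.
#' @export
dem_substep <- function(particles, forces, dt_dem, dt_max = Inf) {
  if (dt_dem >= dt_max)
    stop(sprintf("dt_dem = %.3e violates the stability bound %.3e", dt_dem, dt_max))
  m_p <- attr(particles, "m_p")
  v <- as.matrix(particles[, c("vx", "vy", "vz")]) + dt_dem * forces / m_p
  particles[, c("vx", "vy", "vz")] <- v
  particles[, c("x", "y", "z")] <-
    as.matrix(particles[, c("x", "y", "z")]) + dt_dem * v
  particles
}
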