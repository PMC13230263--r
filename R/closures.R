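# RBC closure models: deformation index, drag/lift coefficients and the
# resulting fluid-particle forces, evaluated from the local flow state.

#' Default numerical guards for the RBC closures
#'
#' The closure correlations were fitted on single-cell data spanning
#' dimensionless shear rates 0.02-0.35 and particle Reynolds numbers
#' 0.01-0.12. Outside that envelope the rational forms misbehave (the drag
#' correlation grows like `Re_p^-3`, the lift like `1/DI^3`), so before
#' coefficient evaluation `Re_p` is clamped to the fitted envelope and `DI`
#' is floored. The force expressions themselves always use the true relative
#' velocity, so forces still vanish smoothly with the slip.
#'
#' The lift correlation carries a `0.0008 Re_p / DI^3` term whose unchecked
#' growth below the fitted deformation range would let lift outgrow drag at
#' large slip (both scale with the slip squared once `Re_p` is clamped), so
#' the deformation index entering the lift coefficient is floored at
#' `di_floor_lift`, the lower edge of the fitted deformation range.
#'
#' @return Named list with `di_floor`, `di_ceil`, `re_p_min`, `re_p_max`,
#'   `di_floor_lift`.
#' @export
closure_guards <- function() {
  list(di_floor = 1e-3, di_ceil = 0.999, re_p_min = 0.01, re_p_max = 0.12,
       di_floor_lift = 0.01)
}

#' Local flow state at a particle centre
#'
#' Bundles the undisturbed fluid velocity interpolated at the particle centre,
#' the particle velocity, the local shear rate (magnitude of the wall-normal
#' gradient of the streamwise velocity), the unit vector pointing from the
#' particle toward the channel axis, and the fluid/particle scales needed by
#' the closures.
#'
#' @param u_fluid Fluid velocity vector at the particle centre \[m/s\].
#' @param u_particle Particle velocity vector \[m/s\].
#' @param shear_rate Scalar shear rate, >= 0 \[1/s\].
#' @param radial_unit Unit vector toward the channel axis (zero vector exactly
#'   on the axis).
#' @param u_av Cross-section bulk velocity \[m/s\].
#' @param nu Kinematic viscosity \[m^2/s\].
#' @param rho Fluid density \[kg/m^3\].
#' @param d_p Particle diameter \[m\].
#' @param R_c Channel radius (half-height for planar channels) \[m\].
#' @return An object of class `local_flow`.
#' @export
local_flow <- function(u_fluid, u_particle, shear_rate, radial_unit,
                       u_av, nu, rho, d_p, R_c) {
  stopifnot(length(u_fluid) == length(u_particle),
            length(radial_unit) == length(u_fluid))
  if (shear_rate < 0) stop("shear_rate must be >= 0")
  if (nu <= 0) stop("nu must be > 0")
  if (d_p <= 0 || R_c <= 0) stop("d_p and R_c must be > 0")
  nr <- sqrt(sum(radial_unit^2))
  if (nr > 0 && abs(nr - 1) > 1e-8)
    stop("radial_unit must be a unit vector (or exactly zero on the axis)")
  structure(list(u_fluid = u_fluid, u_particle = u_particle,
                 shear_rate = shear_rate, radial_unit = radial_unit,
                 u_av = u_av, nu = nu, rho = rho, d_p = d_p, R_c = R_c),
            class = "local_flow")
}

#' Dimensionless flow state at a particle
#'
#' Computes the dimensionless shear rate `gamma_plus = shear_rate * R_c^2 / nu`,
#' the signed dimensionless slip `u_r_plus = (u_p - u) . e_flow / u_av`, and the
#' particle Reynolds number `Re_p = d_p |u_p - u| / nu`.
#'
#' @param flow A [local_flow()] object.
#' @param flow_direction Unit vector along the local flow direction.
#' @return An object of class `dimensionless_state` with fields `gamma_plus`,
#'   `u_r_plus`, `Re_p`.
#' @export
dimensionless_state <- function(flow, flow_direction) {
  stopifnot(inherits(flow, "local_flow"))
  if (abs(sqrt(sum(flow_direction^2)) - 1) > 1e-8)
    stop("flow_direction must be a unit vector")
  if (flow$u_av <= 0) stop("u_av must be > 0 to form u_r_plus")
  if (flow$nu <= 0) stop("nu must be > 0")
  rel <- flow$u_particle - flow$u_fluid
  s <- structure(list(
    gamma_plus = flow$shear_rate * flow$R_c^2 / flow$nu,
    u_r_plus   = sum(rel * flow_direction) / flow$u_av,
    Re_p       = flow$d_p * sqrt(sum(rel^2)) / flow$nu), class = "dimensionless_state")
  if (!all(vapply(s, is.finite, logical(1)))) stop("non-finite dimensionless state")
  s
}

#' RBC deformation index closure
#'
#' Evaluates the deformation-index correlation
#' \deqn{DI = \frac{\dot\gamma^{+3}}{\dot\gamma^{+3}(10 + u_r^{+3}) +
#'   0.117\,\dot\gamma^{+2}(u_r^{+} - u_r^{+4}) + 0.0026}}
#' and clamps the result to `[di_floor, di_ceil]`. A non-positive denominator
#' (possible only far outside the fitted range of `u_r_plus`) returns
#' `di_floor` with a warning. Vectorised over its inputs.
#'
#' @param gamma_plus Dimensionless shear rate(s) (>= 0).
#' @param u_r_plus Signed dimensionless slip velocity (default 0).
#' @param guards Guard list, see [closure_guards()].
#' @return Deformation index in `[di_floor, di_ceil]`, same length as inputs.
#' @export
deformation_index <- function(gamma_plus, u_r_plus = 0, guards = closure_guards()) {
  n <- max(length(gamma_plus), length(u_r_plus))
  g <- rep_len(gamma_plus, n); ur <- rep_len(u_r_plus, n)
  if (any(!is.finite(g)) || any(!is.finite(ur))) stop("non-finite closure input")
  den <- g^3 * (10 + ur^3) + 0.117 * g^2 * (ur - ur^4) + 0.0026
  di <- ifelse(den <= 0, guards$di_floor, g^3 / pmax(den, .Machine$double.xmin))
  if (any(den <= 0))
    warning("deformation_index: non-positive denominator (input outside fitted envelope); floored")
  pmin(pmax(di, guards$di_floor), guards$di_ceil)
}

#' RBC drag coefficient closure
#'
#' \deqn{C_d(DI, Re_p) = \frac{169\,Re_p^2\,(DI + 1) + 0.00146}{Re_p^3}}
#' Raises on non-positive `Re_p`; callers are expected to clamp `Re_p` into the
#' fitted envelope first (see [closure_guards()]). Vectorised.
#'
#' @param DI Deformation index in `[0, 1)`.
#' @param Re_p Particle Reynolds number (> 0).
#' @return Drag coefficient(s), >= 0.
#' @export
drag_coefficient <- function(DI, Re_p) {
  if (any(Re_p <= 0)) stop("drag_coefficient: Re_p must be > 0 (clamp before calling)")
  if (any(DI < 0 | DI >= 1)) stop("drag_coefficient: DI must be in [0, 1)")
  (169 * Re_p^2 * (DI + 1) + 0.00146) / Re_p^3
}

#' RBC lift coefficient closure
#'
#' \deqn{C_l(DI, Re_p) = \frac{-3.19\,DI^4}{Re_p} + \frac{2.48\,DI}{Re_p} +
#'   \frac{0.0008\,Re_p}{DI^3}}
#' Signed; raises on non-positive `DI` or `Re_p` (the correlation is singular
#' at `DI = 0`, so the caller must floor `DI` first). Vectorised.
#'
#' @inheritParams drag_coefficient
#' @return Lift coefficient(s) (may be negative).
#' @export
lift_coefficient <- function(DI, Re_p) {
  if (any(Re_p <= 0)) stop("lift_coefficient: Re_p must be > 0 (clamp before calling)")
  if (any(DI <= 0)) stop("lift_coefficient: DI must be > 0 (floor before calling)")
  -3.19 * DI^4 / Re_p + 2.48 * DI / Re_p + 0.0008 * Re_p / DI^3
}

#' Drag force on a particle
#'
#' \deqn{F_{drag} = 0.125\,C_d\,\rho\,\pi\,d_p^2\,|u - u_p|\,(u - u_p)}
#' The force is directed along the relative velocity `u - u_p`.
#'
#' @param flow A [local_flow()] object.
#' @param C_d Drag coefficient (>= 0).
#' @return Force vector \[N\].
#' @export
drag_force <- function(flow, C_d) {
  stopifnot(inherits(flow, "local_flow"), C_d >= 0)
  rel <- flow$u_fluid - flow$u_particle
  0.125 * C_d * flow$rho * pi * flow$d_p^2 * sqrt(sum(rel^2)) * rel
}

#' Deformability-induced lift force on a particle
#'
#' \deqn{F_{lift} = C_l\,\rho\,d_p^4\,\left(\dot\gamma^2 +
#'   \frac{|u_p - u|^2}{d_p^2}\right) r}
#' where `r` is the unit vector pointing from the particle toward the channel
#' axis, so a positive `C_l` drives centerward migration. On the axis the
#' radial unit vector is zero and so is the lift.
#'
#' @param flow A [local_flow()] object.
#' @param C_l Lift coefficient (signed).
#' @return Force vector \[N\].
#' @export
lift_force <- function(flow, C_l) {
  stopifnot(inherits(flow, "local_flow"))
  rel <- flow$u_particle - flow$u_fluid
  mag <- C_l * flow$rho * flow$d_p^4 * (flow$shear_rate^2 + sum(rel^2) / flow$d_p^2)
  mag * flow$radial_unit
}

#' Evaluate all RBC closures with envelope guards applied
#'
#' Convenience wrapper used by the simulator and the command line: floors and
#' clamps per [closure_guards()], then evaluates the deformation index and the
#' drag and lift coefficients. Vectorised.
#'
#' @param gamma_plus Dimensionless shear rate(s).
#' @param u_r_plus Signed dimensionless slip(s).
#' @param Re_p Particle Reynolds number(s) (any sign; clamped internally).
#' @param guards Guard list, see [closure_guards()].
#' @return A data.frame with columns `DI`, `C_d`, `C_l`, `Re_p_eff`.
#' @export
closure_eval <- function(gamma_plus, u_r_plus = 0, Re_p = 0.01,
                         guards = closure_guards()) {
  n <- max(length(gamma_plus), length(u_r_plus), length(Re_p))
  di <- deformation_index(rep_len(gamma_plus, n), rep_len(u_r_plus, n), guards)
  rp <- pmin(pmax(rep_len(Re_p, n), guards$re_p_min), guards$re_p_max)
  data.frame(DI = di,
             C_d = drag_coefficient(di, rp),
             C_l = lift_coefficient(pmax(di, guards$di_floor_lift), rp),
             Re_p_eff = rp)
}
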