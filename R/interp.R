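# Fluid-to-particle transfers: interpolation of the staggered velocity field,
# the local shear rate, and the pressure-gradient / viscous-Laplacian samples
# needed by the four-term fluid force.

# Pad the streamwise velocity with wall/axis ghost rows for interpolation:
# symmetric across the axis (axisymmetric low boundary), antisymmetric (no
# slip halfway) across walls.
pad_us <- function(state, grid) {
  u <- state$u_s
  lo <- if (grid$topology == "axisymmetric") u[1L, , drop = FALSE] else -u[1L, , drop = FALSE]
  hi <- -u[grid$n1, , drop = FALSE]
  rbind(lo, u, hi)
}

#' Interpolate the fluid state to points
#'
#' Bilinear (quadratic in the wall-normal direction for the streamwise
#' component) interpolation of the staggered velocity field, the wall-normal
#' shear of the streamwise velocity, the pressure gradient and the discrete
#' viscous Laplacian, at arbitrary interior points.
#'
#' @param state A [fluid_state()].
#' @param grid The grid.
#' @param rn Wall-normal coordinates of the query points (radius for
#'   axisymmetric grids, signed `y` for planar).
#' @param s Streamwise coordinates (wrapped periodically).
#' @return A list of vectors: `u_s`, `u_n`, `dudn` (signed shear
#'   `d u_s / d rn`), `shear` (its magnitude), `gradp_s`, `gradp_n`
#'   (pressure-fluctuation gradients), `lap_s` (viscous Laplacian of the
#'   streamwise velocity).
#' @export
interpolate_velocity <- function(state, grid, rn, s) {
  n1 <- grid$n1; n2 <- grid$n2; dr <- grid$dr; ds <- grid$ds
  rn_lo <- grid$rn_f[1]; rn_hi <- grid$rn_f[n1 + 1L]
  if (any(rn < rn_lo - 1e-12) || any(rn > rn_hi + 1e-12))
    stop("interpolate_velocity: point outside the grid")
  rn <- pmin(pmax(rn, rn_lo), rn_hi)
  s <- s %% grid$L
  np <- length(rn)
  pu <- pad_us(state, grid)                      # (n1+2) x n2, rows at rn_c[0..n1+1]
  # discrete viscous Laplacian of u_s at its native locations
  lap <- matrix(0, n1, n2)
  dun_hi <- (pu[3:(n1 + 2L), , drop = FALSE] - pu[2:(n1 + 1L), , drop = FALSE]) / dr
  dun_lo <- (pu[2:(n1 + 1L), , drop = FALSE] - pu[1:n1, , drop = FALSE]) / dr
  if (grid$topology == "axisymmetric") {
    lap <- (grid$rn_f[2:(n1 + 1L)] * dun_hi - grid$rn_f[1:n1] * dun_lo) /
      (grid$rn_c * dr)
  } else {
    lap <- (dun_hi - dun_lo) / dr
  }
  us <- state$u_s
  lap <- lap + (shift_s(us, 1L) - 2 * us + shift_s(us, -1L)) / ds^2
  # wall-normal velocity padded with the zero boundary faces
  un_full <- rbind(0, state$u_n, 0)              # (n1+1) x n2 at rn_f, s_c

  # -- streamwise direction weights --
  # u_s and lap columns live at s_f = k*ds (periodic)
  k0 <- floor(s / ds)                            # 0 .. n2-1
  ws <- s / ds - k0
  kA <- ifelse(k0 == 0L, n2, k0)                 # face at k0*ds (face n2 == 0)
  kB <- ifelse(k0 + 1L > n2, 1L, k0 + 1L)
  # u_n and p columns live at s_c = (k-1/2) ds
  kc0 <- floor(s / ds + 0.5)
  wc <- s / ds + 0.5 - kc0
  kcA <- ((kc0 - 1L) %% n2) + 1L
  kcB <- (kc0 %% n2) + 1L

  # -- wall-normal quadratic on padded rows (exact for parabolic profiles) --
  jc <- pmin(pmax(round((rn - grid$rn_c[1]) / dr) + 1L, 1L), n1)  # centre row
  xj <- grid$rn_c[1] + (jc - 1) * dr
  t <- rn - xj
  qval <- function(Mpad, cols) {
    u0 <- Mpad[cbind(jc + 1L, cols)]
    ulo <- Mpad[cbind(jc, cols)]
    uhi <- Mpad[cbind(jc + 2L, cols)]
    list(v = u0 + t * (uhi - ulo) / (2 * dr) + t^2 * (uhi - 2 * u0 + ulo) / (2 * dr^2),
         d = (uhi - ulo) / (2 * dr) + t * (uhi - 2 * u0 + ulo) / dr^2)
  }
  qA <- qval(pu, kA); qB <- qval(pu, kB)
  u_s_out <- (1 - ws) * qA$v + ws * qB$v
  dudn <- (1 - ws) * qA$d + ws * qB$d
  lap_pad <- rbind(lap[1L, ], lap, lap[n1, ])    # constant-extrapolated ghosts
  lA <- qval(lap_pad, kA); lB <- qval(lap_pad, kB)
  lap_out <- (1 - ws) * lA$v + ws * lB$v

  # -- u_n bilinear on rn_f rows --
  jf <- pmin(pmax(floor((rn - rn_lo) / dr) + 1L, 1L), n1)  # face interval
  wf <- (rn - grid$rn_f[jf]) / dr
  un_out <- (1 - wc) * ((1 - wf) * un_full[cbind(jf, kcA)] + wf * un_full[cbind(jf + 1L, kcA)]) +
    wc * ((1 - wf) * un_full[cbind(jf, kcB)] + wf * un_full[cbind(jf + 1L, kcB)])

  # -- pressure gradients --
  p <- state$p
  dps_face <- (shift_s(p, 1L) - p) / ds          # at (rn_c, s_f)
  dpA <- dps_face[cbind(jc, kA)]; dpB <- dps_face[cbind(jc, kB)]
  gradp_s <- (1 - ws) * dpA + ws * dpB
  dpn_face <- rbind(0, (p[-1L, , drop = FALSE] - p[-n1, , drop = FALSE]) / dr, 0)
  gradp_n <- (1 - wc) * ((1 - wf) * dpn_face[cbind(jf, kcA)] + wf * dpn_face[cbind(jf + 1L, kcA)]) +
    wc * ((1 - wf) * dpn_face[cbind(jf, kcB)] + wf * dpn_face[cbind(jf + 1L, kcB)])

  list(u_s = u_s_out, u_n = un_out, dudn = dudn, shear = abs(dudn),
       gradp_s = gradp_s, gradp_n = gradp_n, lap_s = lap_out)
}

# Light conservative smoothing of the fields used for particle sampling:
# the particle's own single-cell momentum sink leaves a velocity dip whose
# raw interpolated shear and Laplacian would feed the closures with the
# self-disturbance instead of the undisturbed flow.
smoothed_state <- function(state, grid, passes = 2L) {
  sm <- function(M, lo_ghost, hi_ghost) {
    for (p in seq_len(passes)) {
      n1 <- nrow(M)
      lo <- if (identical(lo_ghost, "mirror")) M[1L, ] else
        if (identical(lo_ghost, "anti")) -M[1L, ] else rep(0, ncol(M))
      hi <- if (identical(hi_ghost, "mirror")) M[n1, ] else
        if (identical(hi_ghost, "anti")) -M[n1, ] else rep(0, ncol(M))
      up <- rbind(M[-1L, , drop = FALSE], hi)
      dn <- rbind(lo, M[-n1, , drop = FALSE])
      M <- M + 0.125 * (up + dn + shift_s(M, 1L) + shift_s(M, -1L) - 4 * M)
    }
    M
  }
  lo_us <- if (grid$topology == "axisymmetric") "mirror" else "anti"
  out <- state
  out$u_s <- sm(state$u_s, lo_us, "anti")
  if (nrow(state$u_n)) out$u_n <- sm(state$u_n, "zero", "zero")
  out$p <- sm(state$p, "mirror", "mirror")
  out
}

# Sample everything the closures and the fluid force need at the particle
# centres, in 3D vectors. Returns a list of matrices/vectors.
sample_local_flow <- function(state, grid, spec, particles, smooth_passes = 2L) {
  pos <- as.matrix(particles[, c("x", "y", "z")])
  n <- nrow(pos)
  cc <- particle_grid_coords(grid, pos)
  if (smooth_passes > 0L) state <- smoothed_state(state, grid, smooth_passes)
  itp <- interpolate_velocity(state, grid, cc$rn, cc$s)
  if (grid$topology == "axisymmetric") {
    r <- cc$rn
    ex <- ifelse(r > 1e-15, pos[, 1] / pmax(r, 1e-300), 0)
    ey <- ifelse(r > 1e-15, pos[, 2] / pmax(r, 1e-300), 0)
    rad_out <- cbind(ex, ey, 0)                  # outward radial unit vector
    flow_dir <- matrix(rep(c(0, 0, 1), each = n), n, 3)
    u_fluid <- itp$u_n * rad_out + itp$u_s * flow_dir
    toward_axis <- -rad_out
  } else {
    rad_out <- matrix(rep(c(0, 1, 0), each = n), n, 3)  # +y
    flow_dir <- matrix(rep(c(1, 0, 0), each = n), n, 3)
    u_fluid <- cbind(itp$u_s, itp$u_n, 0)
    toward_axis <- cbind(0, -sign(pos[, 2]), 0)
    toward_axis[pos[, 2] == 0, 2] <- 0
  }
  list(u_fluid = u_fluid, shear = itp$shear, rad_out = rad_out,
       toward_axis = toward_axis, flow_dir = flow_dir,
       gradp_s = itp$gradp_s, gradp_n = itp$gradp_n, lap_s = itp$lap_s,
       rn = cc$rn, s = cc$s)
}
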