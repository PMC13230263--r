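# Two-way coupling: solid-fraction deposition, the four-term fluid force on
# a particle, assembly of the per-cell momentum-exchange field, and the
# coupled CFD-DEM time loop.

#' Deposit the particle solid fraction onto the grid
#'
#' Each particle's volume is distributed over the (wall-normal, streamwise)
#' cells its bounding extent overlaps (divided scheme, weights proportional
#' to the 1D overlap lengths, normalised to conserve volume exactly),
#' followed by one conservative smoothing pass. In axisymmetric mode a 3D
#' particle contributes to the annular ring of cells at its radius
#' (azimuthal averaging). The fluid fraction is `phi = 1 - solid/V_cell`,
#' clamped below at `phi_min`.
#'
#' @param particles A [make_particles()] set.
#' @param grid The grid.
#' @param phi_min Lower clamp on the fluid fraction.
#' @param smooth Logical; apply the conservative smoothing pass.
#' @return List with `phi` (n1 x n2), `solid` (deposited solid volume per
#'   cell \[m^3\]) and `clamped` (was the clamp active anywhere).
#' @export
deposit_solid_fraction <- function(particles, grid, phi_min = 0.3, smooth = TRUE) {
  n1 <- grid$n1; n2 <- grid$n2
  solid <- matrix(0, n1, n2)
  np <- nrow(particles)
  if (np > 0L) {
    a <- attr(particles, "d_p") / 2
    V_p <- attr(particles, "V_p")
    cc <- particle_grid_coords(grid, as.matrix(particles[, c("x", "y", "z")]))
    solid <- cpp_deposit(cc$rn, cc$s, a, V_p, grid$rn_f, grid$ds,
                         n1, n2, grid$L)
  }
  if (smooth && np > 0L) solid <- smooth_conservative(solid, grid)
  # conservative capacity redistribution: cells whose deposited solid would
  # push phi below phi_min (possible in the small annular cells near the
  # axis) push the excess to their neighbours instead of losing it to the
  # clamp, so the global continuity source stays volume-conserving
  cap <- (1 - phi_min) * grid$V_cell
  cap[grid$solid] <- 0                    # masked cells hold no solid
  clamped <- FALSE
  open <- !grid$solid
  recv_up <- rbind(open[-1L, , drop = FALSE], FALSE)   # can cell i give upward?
  recv_dn <- rbind(FALSE, open[-n1, , drop = FALSE])
  recv_sp <- shift_s(open, 1L); recv_sm <- shift_s(open, -1L)
  for (sweep in 1:80) {
    excess <- pmax(solid - cap, 0)
    if (max(excess) <= 1e-9 * max(grid$V_cell)) break
    clamped <- TRUE
    solid <- solid - excess
    give <- excess / 4
    g_hi <- give * recv_up; g_lo <- give * recv_dn     # to (i+1,k) / (i-1,k)
    g_sp <- give * recv_sp; g_sm <- give * recv_sm     # to (i,k+1) / (i,k-1)
    # undeliverable shares (walls, masked neighbours) return to the giver
    ret <- 4 * give - g_hi - g_lo - g_sp - g_sm
    from_below <- rbind(0, g_hi[-n1, , drop = FALSE])
    from_above <- rbind(g_lo[-1L, , drop = FALSE], 0)
    solid <- solid + ret + from_below + from_above +
      shift_s(g_sp, -1L) + shift_s(g_sm, 1L)
  }
  phi <- 1 - solid / grid$V_cell
  phi <- pmax(phi, phi_min)
  phi[grid$solid] <- 1
  list(phi = phi, solid = solid, clamped = clamped)
}

# One conservative smoothing pass: antisymmetric exchange of the deposited
# quantity between wall-normal/streamwise neighbours (no-flux at walls and
# masked cells, periodic streamwise). Conserves the column sum exactly.
smooth_conservative <- function(M, grid) {
  n1 <- grid$n1; n2 <- grid$n2
  th <- 1 / 8
  sp <- shift_s(M, 1L); sm <- shift_s(M, -1L)
  nsp <- matrix(1, n1, n2); nsm <- matrix(1, n1, n2)
  if (any(grid$solid)) {
    bsp <- shift_s(grid$solid, 1L) | grid$solid
    bsm <- shift_s(grid$solid, -1L) | grid$solid
    sp[bsp] <- 0; nsp[bsp] <- 0
    sm[bsm] <- 0; nsm[bsm] <- 0
  }
  nb_sum <- sp + sm
  nnb <- nsp + nsm
  up <- rbind(M[-1L, , drop = FALSE], 0); nup <- rbind(matrix(1, n1 - 1L, n2), 0)
  dn <- rbind(0, M[-n1, , drop = FALSE]); ndn <- rbind(0, matrix(1, n1 - 1L, n2))
  if (any(grid$solid)) {
    blocked_up <- grid$solid[c(2:n1, n1), , drop = FALSE] | grid$solid
    blocked_dn <- grid$solid[c(1L, 1:(n1 - 1L)), , drop = FALSE] | grid$solid
    up[blocked_up] <- 0; nup[blocked_up] <- 0
    dn[blocked_dn] <- 0; ndn[blocked_dn] <- 0
  }
  nb_sum <- nb_sum + up + dn
  nnb <- nnb + nup + ndn
  M + th * (nb_sum - nnb * M)
}

#' Four-term fluid force on one particle
#'
#' The unresolved fluid-particle force is the sum of the pressure force
#' `-V_p grad p` (the driving body force enters as a mean-pressure-gradient
#' surrogate), the viscous force `V_p mu lap(u)`, and the closure drag and
#' lift forces.
#'
#' @param flow A [local_flow()] object.
#' @param grad_p Pressure gradient vector at the particle (same length as the
#'   velocity vectors), including the driving-gradient surrogate \[Pa/m\].
#' @param lap_u Viscous Laplacian of the velocity at the particle \[1/(m s)\].
#' @param mu Dynamic viscosity \[Pa s\].
#' @param guards Closure guards.
#' @return List with the force components `F_pressure`, `F_viscous`,
#'   `F_drag`, `F_lift` and their sum `F_total` \[N\].
#' @export
particle_fluid_force <- function(flow, grad_p, lap_u, mu, guards = closure_guards()) {
  stopifnot(inherits(flow, "local_flow"))
  V_p <- pi * flow$d_p^3 / 6
  rel <- flow$u_particle - flow$u_fluid
  Re_p <- flow$d_p * sqrt(sum(rel^2)) / flow$nu
  dir <- if (sqrt(sum((flow$u_fluid)^2)) > 0) flow$u_fluid / sqrt(sum(flow$u_fluid^2)) else c(1, rep(0, length(rel) - 1))
  urp <- if (flow$u_av > 0) sum(rel * dir) / flow$u_av else 0
  gp <- flow$shear_rate * flow$R_c^2 / flow$nu
  cl <- closure_eval(gp, urp, Re_p, guards)
  Fp <- -V_p * grad_p
  Fv <- V_p * mu * lap_u
  Fd <- drag_force(flow, cl$C_d)
  Fl <- lift_force(flow, cl$C_l)
  list(F_pressure = Fp, F_viscous = Fv, F_drag = Fd, F_lift = Fl,
       F_total = Fp + Fv + Fd + Fl, closure = cl)
}

#' Assemble the momentum-exchange coupling field
#'
#' Per grid cell: `K = |sum_i (F_drag,i + F_lift,i)| / (V_cell |u - <u_p>|)`
#' with the denominator regularised by `eps_u`, and `<u_p>` the
#' volume-weighted mean particle velocity in the cell. The momentum source
#' on the fluid is reconstructed in the solver as `K u - K <u_p>` (implicit /
#' explicit split).
#'
#' @param grid The grid.
#' @param state The fluid state (for the cell-centred fluid velocity).
#' @param particles The [make_particles()] set (positions and the deposition
#'   kernel extent).
#' @param F_dl n x 2 matrix of per-particle drag+lift forces in (wall-normal,
#'   streamwise) components \[N\].
#' @param up n x 2 matrix of particle velocities in the same components.
#' @param eps_u Slip regulariser \[m/s\].
#' @param k_cap Optional per-cell upper bound on `K` \[kg/(m^3 s)\]. The
#'   implicit part `K u` of the exchange acts as a relaxation of the fluid
#'   toward `<u_p>` at rate `K / (rho phi)`; without a bound, vanishing cell
#'   slip sends `K` to the regulariser ceiling and the fluid is pinned to the
#'   particle velocity, removing far more momentum than the closure forces
#'   deliver to the particles (breaking action-reaction). Capping `K` at
#'   `rho phi / dt` limits the exchange to one time step's worth of momentum
#'   relaxation, which keeps the per-step exchange equal to the drag+lift
#'   impulse whenever that impulse is physically realisable.
#' @param smooth Optionally apply the same conservative smoothing pass as the
#'   solid-fraction deposition. Off by default: the exchange definition is
#'   the volume-weighted per-cell mean over the particle extents (divided
#'   kernel), with no extra spreading.
#' @return List of n1 x n2 matrices: `K`, `up_n`, `up_s`, `Fmag` (per-cell
#'   `|sum F|`, for the momentum audit) plus `F_n`, `F_s` (per-cell vector
#'   sums).
#' @export
assemble_Rpf <- function(grid, state, particles, F_dl, up, eps_u = 1e-12,
                         smooth = FALSE, k_cap = NULL) {
  n1 <- grid$n1; n2 <- grid$n2
  zero <- matrix(0, n1, n2)
  np <- nrow(particles)
  if (np == 0L)
    return(list(K = zero, up_n = zero, up_s = zero, Fmag = zero,
                F_n = zero, F_s = zero))
  V_p <- attr(particles, "V_p")
  cc <- particle_grid_coords(grid, as.matrix(particles[, c("x", "y", "z")]))
  payload <- cbind(F_dl[, 1], F_dl[, 2], V_p * up[, 1], V_p * up[, 2],
                   rep(V_p, np))
  dep <- cpp_deposit_fields(cc$rn, cc$s, attr(particles, "d_p") / 2, payload,
                            grid$rn_f, grid$ds, n1, n2, grid$L)
  flds <- lapply(seq_len(5L), function(j) {
    M <- dep[, , j]
    if (smooth) M <- smooth_conservative(M, grid)
    M
  })
  F_n <- flds[[1]]; F_s <- flds[[2]]
  vol <- flds[[5]]
  laden <- vol > 1e-12 * V_p
  up_n <- ifelse(laden, flds[[3]] / pmax(vol, 1e-300), 0)
  up_s <- ifelse(laden, flds[[4]] / pmax(vol, 1e-300), 0)
  # cell-centred fluid velocity
  uc_s <- 0.5 * (state$u_s + shift_s(state$u_s, -1L))
  uc_n <- if (n1 > 1L) 0.5 * (rbind(state$u_n, 0) + rbind(0, state$u_n)) else zero
  slip <- sqrt((uc_n - up_n)^2 + (uc_s - up_s)^2)
  Fmag <- sqrt(F_n^2 + F_s^2)
  K <- Fmag / (grid$V_cell * pmax(slip, eps_u))
  if (!is.null(k_cap)) K <- pmin(K, k_cap)
  K[!laden] <- 0
  list(K = K, up_n = up_n, up_s = up_s, Fmag = Fmag, F_n = F_n, F_s = F_s)
}

# dense grouped sum: sum x by integer index over 1..nbin
tapply2 <- function(x, idx, nbin) {
  out <- numeric(nbin)
  s <- rowsum(x, idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# particle cell indices (i, k) on the grid
particle_cells <- function(grid, particles) {
  cc <- particle_grid_coords(grid, as.matrix(particles[, c("x", "y", "z")]))
  i <- pmin(pmax(ceiling((cc$rn - grid$rn_f[1]) / grid$dr), 1L), grid$n1)
  k <- pmin(pmax(floor(cc$s / grid$ds) + 1L, 1L), grid$n2)
  cbind(i, k)
}

#' Set up a coupled CFD-DEM case
#'
#' Collects the channel specification, the particle phase and the numerical
#' controls into a single case object consumed by [run_coupled()].
#'
#' @param spec A [channel_spec()].
#' @param d_p Particle (RBC volume-equivalent sphere) diameter \[m\].
#' @param rho_p Particle density \[kg/m^3\].
#' @param contact [contact_params()].
#' @param resolution Grid resolution, see [build_grid()].
#' @param seed Integer seed for the particle seeding.
#' @param n_coupling DEM substeps per CFD step; `"auto"` fills the Courant
#'   budget with DEM-stable substeps.
#' @param Co Courant target in `(0, 1)`.
#' @param phi_min Fluid-fraction clamp.
#' @param eps_u Exchange-denominator regulariser \[m/s\].
#' @param guards Closure guards, see [closure_guards()].
#' @param gravity Gravity vector (default zero: horizontal microflows).
#' @param lift_on,drag_on Closure switches (mechanism isolation).
#' @param init Initial fluid field, `"poiseuille"` or `"rest"`.
#' @param window_flowthroughs Steady-state window length in domain
#'   flow-through times.
#' @param steady_tol Relative drift tolerance of the steadiness detector.
#' @return An object of class `rbc_case`.
#' @export
case_setup <- function(spec, d_p = 5.6e-6, rho_p = 1100,
                       contact = contact_params(), resolution = c(16L, 32L),
                       seed = 1L, n_coupling = "auto", Co = 0.15,
                       phi_min = 0.3, eps_u = 1e-12, guards = closure_guards(),
                       gravity = c(0, 0, 0), lift_on = TRUE, drag_on = TRUE,
                       init = "poiseuille", window_flowthroughs = 20,
                       steady_tol = 0.01) {
  structure(list(spec = spec, d_p = d_p, rho_p = rho_p, contact = contact,
                 resolution = resolution, seed = seed, n_coupling = n_coupling,
                 Co = Co, phi_min = phi_min, eps_u = eps_u, guards = guards,
                 gravity = gravity, lift_on = lift_on, drag_on = drag_on,
                 init = init, window_flowthroughs = window_flowthroughs,
                 steady_tol = steady_tol),
            class = "rbc_case")
}

#' Time-step controls for a case
#'
#' `dt_DEM` is set just below `0.1 min(t_Ray, t_Her)`; the coupling interval
#' either follows the configuration or (`"auto"`) fills the Courant budget,
#' and `dt_CFD = n_coupling dt_DEM`, shrunk if the Courant condition would be
#' violated.
#'
#' @param case An [case_setup()] case.
#' @param grid The grid.
#' @return List with `dt_dem`, `dt_cfd`, `n_coupling`, `courant_dt`.
#' @export
time_controls <- function(case, grid) {
  spec <- case$spec
  t_ray <- rayleigh_time(case$d_p, case$rho_p, case$contact)
  t_her <- hertz_time(case$d_p, case$rho_p, case$contact, v_impact = 0,
                      v_floor = spec$u_av)
  dt_dem <- 0.99 * 0.1 * min(t_ray, t_her)
  courant_dt <- case$Co * grid$ds / (1.05 * spec$U_max)
  n_cpl <- if (identical(case$n_coupling, "auto")) {
    max(1L, floor(courant_dt / dt_dem))
  } else as.integer(case$n_coupling)
  dt_cfd <- n_cpl * dt_dem
  while (dt_cfd > courant_dt && n_cpl > 1L) {
    n_cpl <- n_cpl - 1L
    dt_cfd <- n_cpl * dt_dem
  }
  list(dt_dem = dt_dem, dt_cfd = dt_cfd, n_coupling = n_cpl,
       courant_dt = courant_dt, t_ray = t_ray, t_her = t_her)
}

#' Run a coupled CFD-DEM simulation
#'
#' The per-step loop follows the standard unresolved coupling sequence:
#' deposit the solid fraction, interpolate the fluid at the particle centres,
#' evaluate the closures and per-particle drag/lift, assemble the
#' momentum-exchange field, advance the fluid one CFD step (PISO), then run
#' `n_coupling` DEM substeps (velocity-Verlet with Hertz contacts,
#' semi-implicit drag, frozen local flow). Cross-section fluxes are sampled
#' every CFD step; the run ends at `T_end` or when the steadiness criterion
#' (relative drift of discharge hematocrit and relative viscosity below
#' `steady_tol` over two consecutive windows) is met.
#'
#' @param case An [case_setup()] case.
#' @param T_end Maximum physical time to simulate \[s\].
#' @param particles Optional pre-seeded particle set (default: seeded from
#'   the case spec and seed).
#' @param stop_when_steady Stop early once steady (default `TRUE`).
#' @param record_trajectory Record particle positions every
#'   `trajectory_every` CFD steps.
#' @param trajectory_every Cadence of trajectory records.
#' @param verbose Print progress.
#' @return A list of class `rbc_run` with the final `state`, `particles`,
#'   the `metrics` data.frame (one row per CFD step: `t`, `Q_blood`,
#'   `Q_RBCs`), window summaries (`windows`), audit diagnostics and the run
#'   manifest.
#' @export
run_coupled <- function(case, T_end, particles = NULL, stop_when_steady = TRUE,
                        record_trajectory = FALSE, trajectory_every = 50L,
                        verbose = FALSE) {
  spec <- case$spec
  grid <- build_grid(spec, case$resolution)
  state <- fluid_state(grid, spec, init = case$init)
  if (is.null(particles))
    particles <- seed_particles(spec, case$d_p, seed = case$seed,
                                rho_p = case$rho_p)
  tc <- time_controls(case, grid)
  np <- nrow(particles)
  if (np > 0L) {
    # particles start as local-flow tracers, and phi starts deposited so the
    # first continuity step sees no spurious global volume source
    sl0 <- sample_local_flow(state, grid, spec, particles)
    particles[, c("vx", "vy", "vz")] <- sl0$u_fluid
    state$phi <- deposit_solid_fraction(particles, grid, phi_min = case$phi_min)$phi
  }
  geom <- geometry_descriptor(spec)
  d_p <- attr(particles, "d_p"); m_p <- attr(particles, "m_p")
  I_p <- attr(particles, "I_p"); V_p <- attr(particles, "V_p")
  k_plane <- max(1L, round(grid$n2 / 2))
  s_plane <- grid$s_f[k_plane]
  n_steps <- ceiling(T_end / tc$dt_cfd)
  met <- data.frame(t = numeric(n_steps), Q_blood = numeric(n_steps),
                    Q_RBCs = numeric(n_steps), DI_mean = NA_real_)
  windows <- list()
  flowthrough <- spec$L / spec$u_av
  window_time <- case$window_flowthroughs * flowthrough
  audit <- c(max_rel_err = 0)
  traj <- list()
  t_now <- 0
  win_start_step <- 1L
  steady <- FALSE
  cpv <- unlist(case$contact[c("E_eff", "poisson", "restitution", "friction")])
  guards_v <- unlist(case$guards)
  for (step in seq_len(n_steps)) {
    phi_old <- state$phi
    dep <- deposit_solid_fraction(particles, grid, phi_min = case$phi_min)
    state$phi <- dep$phi
    cpl <- NULL
    if (np > 0L) {
      sl <- sample_local_flow(state, grid, spec, particles)
      upm <- as.matrix(particles[, c("vx", "vy", "vz")])
      slip <- upm - sl$u_fluid
      smag <- sqrt(rowSums(slip^2))
      Re_p <- d_p * smag / spec$nu
      urp <- rowSums(slip * sl$flow_dir) / max(spec$u_av, 1e-300)
      gp <- sl$shear * spec$R_c^2 / spec$nu
      clz <- closure_eval(gp, urp, Re_p, case$guards)
      Fd3 <- if (case$drag_on)
        0.125 * clz$C_d * spec$rho * pi * d_p^2 * smag * (-slip) else matrix(0, np, 3)
      Fl3 <- if (case$lift_on)
        (clz$C_l * spec$rho * d_p^4 * (sl$shear^2 + smag^2 / d_p^2)) * sl$toward_axis
      else matrix(0, np, 3)
      # project to (wall-normal, streamwise) cell-plane components
      F3 <- Fd3 + Fl3
      if (grid$topology == "axisymmetric") {
        Fn2 <- rowSums(F3[, 1:2, drop = FALSE] * sl$rad_out[, 1:2, drop = FALSE])
        Fs2 <- F3[, 3]
        upn2 <- rowSums(upm[, 1:2, drop = FALSE] * sl$rad_out[, 1:2, drop = FALSE])
        ups2 <- upm[, 3]
      } else {
        Fn2 <- F3[, 2]; Fs2 <- F3[, 1]
        upn2 <- upm[, 2]; ups2 <- upm[, 1]
      }
      cpl <- assemble_Rpf(grid, state, particles, cbind(Fn2, Fs2),
                          cbind(upn2, ups2), eps_u = case$eps_u)
    }
    state <- advance_fluid(state, grid, cpl, tc$dt_cfd, phi_old = phi_old)
    diag_f <- attr(state, "diagnostics")
    if (np > 0L) {
      # momentum audit: |R_p,f| vs |sum(F_drag + F_lift)| per step
      tot_F <- sum(cpl$Fmag)
      if (tot_F > 0) {
        rel <- abs(diag_f$exchange_mag - tot_F) / tot_F
        audit["max_rel_err"] <- max(audit["max_rel_err"], rel)
      }
      # DEM substeps on the updated field, frozen local flow
      sl <- sample_local_flow(state, grid, spec, particles)
      fconst <- (-V_p) * (sl$gradp_s - state$G) * sl$flow_dir +
        (-V_p) * sl$gradp_n * sl$rad_out +
        V_p * spec$mu * sl$lap_s * sl$flow_dir
      res <- cpp_dem_substeps(
        as.matrix(particles[, c("x", "y", "z")]),
        as.matrix(particles[, c("vx", "vy", "vz")]),
        as.matrix(particles[, c("ox", "oy", "oz")]),
        d_p, m_p, I_p, spec$rho, spec$nu, spec$u_av, spec$R_c,
        guards_v, sl$u_fluid, sl$shear, sl$toward_axis,
        if (grid$topology == "axisymmetric") c(0, 0, 1) else c(1, 0, 0),
        fconst, case$gravity, cpv,
        geom$type, geom$R_c, geom$L, geom$W, geom$h_table, geom$dx_table,
        tc$dt_dem, tc$n_coupling,
        TRUE, case$drag_on, case$lift_on, s_plane, V_p)
      particles[, c("x", "y", "z")] <- res$pos
      particles[, c("vx", "vy", "vz")] <- res$vel
      particles[, c("ox", "oy", "oz")] <- res$omega
      particles$DI <- res$DI; particles$C_d <- res$C_d
      particles$C_l <- res$C_l; particles$Re_p <- res$Re_p
      q_rbc <- res$crossing_volume / tc$dt_cfd
    } else q_rbc <- 0
    t_now <- t_now + tc$dt_cfd
    met$t[step] <- t_now
    met$Q_RBCs[step] <- q_rbc
    met$Q_blood[step] <- fluid_flux(state, grid, k_plane) + q_rbc
    if (np > 0L) met$DI_mean[step] <- mean(particles$DI, na.rm = TRUE)
    if (record_trajectory && step %% trajectory_every == 0L)
      traj[[length(traj) + 1L]] <-
        cbind(t = t_now, as.matrix(particles[, c("x", "y", "z")]))
    if (met$t[step] - met$t[win_start_step] >= window_time) {
      wrows <- win_start_step:step
      qb <- mean(met$Q_blood[wrows]); qr <- mean(met$Q_RBCs[wrows])
      windows[[length(windows) + 1L]] <- data.frame(
        t_end = t_now, Ht_d = qr / qb,
        mu_rel = plasma_flux(spec) / qb)
      win_start_step <- step + 1L
      nw <- length(windows)
      if (nw >= 2L) {
        w1 <- windows[[nw - 1L]]; w2 <- windows[[nw]]
        drift <- function(a, b) abs(b - a) / max(abs(a), 1e-12)
        dH <- if (abs(w1$Ht_d) < 1e-9 && abs(w2$Ht_d) < 1e-9) 0 else drift(w1$Ht_d, w2$Ht_d)
        if (dH < case$steady_tol && drift(w1$mu_rel, w2$mu_rel) < case$steady_tol) {
          steady <- TRUE
          if (stop_when_steady) { met <- met[seq_len(step), , drop = FALSE]; break }
        }
      }
      if (verbose)
        message(sprintf("t = %.3g s  Ht_d = %.4f  mu_rel = %.4f",
                        t_now, windows[[nw]]$Ht_d, windows[[nw]]$mu_rel))
    }
    if (step == n_steps) met <- met[seq_len(step), , drop = FALSE]
  }
  structure(list(case = case, grid = grid, state = state,
                 particles = particles, metrics = met,
                 windows = if (length(windows)) do.call(rbind, windows) else NULL,
                 steady = steady, time_controls = tc, audit = audit,
                 trajectory = traj,
                 manifest = list(seed = case$seed, dt_dem = tc$dt_dem,
                                 dt_cfd = tc$dt_cfd, n_coupling = tc$n_coupling,
                                 n_particles = np, resolution = case$resolution)),
            class = "rbc_run")
}

#' Theoretical pure-plasma flux for a channel case
#'
#' Hagen-Poiseuille (axisymmetric) or plane-Poiseuille (planar) volumetric
#' flux at the case's driving body force; the reference numerator of the
#' relative apparent viscosity.
#'
#' @param spec A [channel_spec()].
#' @return Flux \[m^3/s\].
#' @export
plasma_flux <- function(spec) {
  if (spec$topology == "axisymmetric") {
    pi * spec$G * spec$R_c^4 / (8 * spec$mu)
  } else {
    2 * spec$G * spec$R_c^3 / (3 * spec$mu) * spec$depth
  }
}
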