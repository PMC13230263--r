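# Two-way coupling: solid-fraction deposition, the four-term fluid force,
# the momentum-exchange field, the per-step momentum audit, lateral
# migration and determinism.

test_that("solid-fraction deposition conserves particle volume exactly", {
  spec <- test_spec(R_c = 25e-6, L = 200e-6, Ht_c = 0.05)
  grid <- build_grid(spec, c(16L, 32L))
  P <- seed_particles(spec, 5.6e-6, seed = 3L)
  dep <- deposit_solid_fraction(P, grid)
  expect_equal(sum(dep$solid), nrow(P) * attr(P, "V_p"),
               tolerance = 1e-10)
  expect_equal(sum((1 - dep$phi) * grid$V_cell), nrow(P) * attr(P, "V_p"),
               tolerance = 1e-10)
  expect_true(all(dep$phi >= 0.3 & dep$phi <= 1))
  # no particles -> phi identically 1
  dep0 <- deposit_solid_fraction(make_particles(matrix(0, 0, 3), 5.6e-6), grid)
  expect_true(all(dep0$phi == 1))
})

test_that("a small particle wholly inside one cell deposits its volume there", {
  spec <- test_spec(R_c = 25e-6, L = 200e-6)
  grid <- build_grid(spec, c(16L, 32L))
  d_p <- 1.0e-6   # smaller than a cell
  # centre of cell (8, 16)
  rn <- grid$rn_c[8]; s <- grid$s_c[16]
  P <- make_particles(matrix(c(rn, 0, s), 1, 3), d_p)
  dep <- deposit_solid_fraction(P, grid, smooth = FALSE)
  expect_equal(dep$solid[8, 16], pi * d_p^3 / 6, tolerance = 1e-12)
  expect_equal(sum(dep$solid), pi * d_p^3 / 6, tolerance = 1e-12)
})

test_that("four-term fluid force composes correctly in simple fields", {
  # uniform pressure, uniform velocity, matched particle: zero total force
  fl0 <- local_flow(c(0, 0, 1e-3), c(0, 0, 1e-3), 0, c(-1, 0, 0),
                    1e-3, 1.2e-6, 1000, 5.6e-6, 25e-6)
  f0 <- particle_fluid_force(fl0, grad_p = c(0, 0, 0), lap_u = c(0, 0, 0),
                             mu = 1.2e-3)
  expect_equal(f0$F_total, c(0, 0, 0))
  # linear pressure field with everything else zero: F = -V_p grad p exactly
  fl1 <- local_flow(c(0, 0, 0), c(0, 0, 0), 0, c(-1, 0, 0),
                    1e-3, 1.2e-6, 1000, 5.6e-6, 25e-6)
  gp <- c(0, 0, 100)
  f1 <- particle_fluid_force(fl1, grad_p = gp, lap_u = c(0, 0, 0), mu = 1.2e-3)
  V_p <- pi * (5.6e-6)^3 / 6
  expect_equal(f1$F_pressure, -V_p * gp)
  expect_equal(f1$F_drag, c(0, 0, 0))
  # stationary particle in a sheared flow: drag along the flow, lift centerward
  fl2 <- local_flow(c(0, 0, 3e-3), c(0, 0, 0), 200, c(-1, 0, 0),
                    3.6e-3, 1.2e-6, 1000, 5.6e-6, 25e-6)
  f2 <- particle_fluid_force(fl2, grad_p = c(0, 0, 0), lap_u = c(0, 0, 0),
                             mu = 1.2e-3)
  expect_gt(f2$F_drag[3], 0)
  expect_lt(f2$F_lift[1], 0)   # radial_unit points toward the axis (-x here)
})

test_that("exchange field satisfies the per-cell closure identity", {
  spec <- test_spec(R_c = 25e-6, L = 200e-6)
  grid <- build_grid(spec, c(16L, 32L))
  st <- fluid_state(grid, spec, init = "poiseuille")
  # one small particle wholly inside a cell, no smoothing: Eq. identity
  d_p <- 1.0e-6
  rn <- grid$rn_c[8]; s <- grid$s_c[16]
  P <- make_particles(matrix(c(rn, 0, s), 1, 3), d_p)
  Fd <- c(1e-13, 3e-13)                      # (wall-normal, streamwise)
  up <- cbind(0, 1e-3)
  cpl <- assemble_Rpf(grid, st, P, rbind(Fd), up)
  i <- 8L; k <- 16L
  expect_equal(cpl$Fmag[i, k], sqrt(sum(Fd^2)), tolerance = 1e-12)
  # K |u - <u_p>| V_cell = |F_drag + F_lift| (Eq. rearranged)
  uc_s <- 0.5 * (st$u_s[i, k] + st$u_s[i, if (k == 1) grid$n2 else k - 1])
  slip <- sqrt((0 - 0)^2 + (uc_s - 1e-3)^2)
  expect_equal(cpl$K[i, k] * slip * grid$V_cell[i, k], sqrt(sum(Fd^2)),
               tolerance = 1e-10)
  # no particles -> zero field
  cpl0 <- assemble_Rpf(grid, st, make_particles(matrix(0, 0, 3), d_p),
                       matrix(0, 0, 2), matrix(0, 0, 2))
  expect_equal(max(cpl0$K), 0)
})

test_that("cell particle-velocity average is the volume-weighted mean", {
  spec <- test_spec(R_c = 25e-6, L = 200e-6)
  grid <- build_grid(spec, c(16L, 32L))
  st <- fluid_state(grid, spec, init = "rest")
  d_p <- 1.0e-6
  rn <- grid$rn_c[8]; s <- grid$s_c[16]
  # two equal-volume particles in the same cell with opposite slips
  P <- make_particles(rbind(c(rn, 0, s - 1e-6), c(rn, 0, s + 1e-6)), d_p)
  up <- cbind(c(0, 0), c(2e-3, -1e-3))
  cpl <- assemble_Rpf(grid, st, P, matrix(1e-13, 2, 2), up)
  expect_equal(cpl$up_s[8, 16], 0.5e-3, tolerance = 1e-12)
})

test_that("momentum removed from the fluid equals the drag+lift impulse", {
  # explicit regime: moderate K, one step; the implicit exchange must hand
  # the closure impulse to the fluid within 1 percent
  spec <- test_spec(R_c = 25e-6, L = 200e-6)
  grid <- build_grid(spec, c(16L, 32L))
  st <- fluid_state(grid, spec, init = "poiseuille")
  P <- seed_particles(test_spec(R_c = 25e-6, L = 200e-6, Ht_c = 0.02),
                      5.6e-6, seed = 8L)
  np <- nrow(P)
  # prescribed per-particle forces and a particle velocity with O(10%) slip
  sl <- rbcdem:::sample_local_flow(st, grid, spec, P)
  up_s <- sl$u_fluid[, 3] * 0.9
  F_dl <- cbind(rep(1e-14, np), rep(5e-13, np))
  cpl <- assemble_Rpf(grid, st, P, F_dl, cbind(0, up_s))
  dt <- 1e-5
  st2 <- advance_fluid(st, grid, cpl, dt)
  d <- attr(st2, "diagnostics")
  expect_equal(d$exchange_mag, sum(cpl$Fmag), tolerance = 0.01)
  # and the per-cell assembly magnitude matches the deposited forces
  expect_equal(sum(cpl$Fmag), sqrt(sum(colSums(F_dl)^2)), tolerance = 0.05)
})

test_that("single particle migrates centerward; removing lift abolishes it", {
  spec <- test_spec(R_c = 25e-6, L = 100e-6, Ht_c = 0)
  case <- case_setup(spec, seed = 2L)
  P <- make_particles(matrix(c(12.5e-6, 0, 50e-6), 1, 3), case$d_p, case$rho_p)
  run <- run_coupled(case, T_end = 0.03, particles = P,
                     stop_when_steady = FALSE, record_trajectory = TRUE,
                     trajectory_every = 20L)
  r_t <- sapply(run$trajectory, function(m) sqrt(m[1, "x"]^2 + m[1, "y"]^2))
  expect_true(all(diff(r_t) < 0))               # monotone centerward
  drift_lift <- r_t[length(r_t)] - r_t[1]
  case0 <- case_setup(spec, seed = 2L, lift_on = FALSE)
  run0 <- run_coupled(case0, T_end = 0.03, particles = P,
                      stop_when_steady = FALSE, record_trajectory = TRUE,
                      trajectory_every = 20L)
  r0 <- sapply(run0$trajectory, function(m) sqrt(m[1, "x"]^2 + m[1, "y"]^2))
  drift_nolift <- r0[length(r0)] - r0[1]
  # lift-driven migration dominates the residual numerical drift
  expect_gt(abs(drift_lift), 20 * abs(drift_nolift))
})

test_that("runs are deterministic for a fixed seed", {
  spec <- test_spec(R_c = 25e-6, L = 100e-6, Ht_c = 0.03)
  case <- case_setup(spec, seed = 6L)
  r1 <- run_coupled(case, T_end = 3e-3, stop_when_steady = FALSE)
  r2 <- run_coupled(case, T_end = 3e-3, stop_when_steady = FALSE)
  expect_identical(r1$particles$x, r2$particles$x)
  expect_identical(r1$particles$vz, r2$particles$vz)
  expect_identical(r1$metrics$Q_blood, r2$metrics$Q_blood)
})

test_that("cells deform more in the stenosis throat than upstream", {
  sp <- stenosis_case(D = 50e-6, throat = 30e-6, L = 200e-6, Re = 0.3,
                      Ht_c = 0.04)
  case <- case_setup(sp, seed = 3L, resolution = c(16L, 32L), init = "rest")
  run <- run_coupled(case, T_end = 0.04, stop_when_steady = FALSE)
  st <- di_statistics(run$particles, sp, n_stream = 8L)
  throat <- abs(st$profile$s - sp$mask$x0) < sp$mask$width / 2
  upstream <- st$profile$s < sp$mask$x0 - sp$mask$width
  expect_gt(mean(st$profile$DI_mean[throat], na.rm = TRUE),
            mean(st$profile$DI_mean[upstream], na.rm = TRUE))
})

test_that("zero particles reduces run_coupled to the clean Poiseuille flow", {
  spec <- test_spec(R_c = 25e-6, L = 100e-6, Ht_c = 0)
  case <- case_setup(spec, seed = 1L)
  run <- run_coupled(case, T_end = 5e-3, stop_when_steady = FALSE)
  expect_equal(nrow(run$particles), 0)
  q <- mean(run$metrics$Q_blood)
  expect_equal(q, plasma_flux(spec), tolerance = 0.01)
  expect_equal(mean(run$metrics$Q_RBCs), 0)
})
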