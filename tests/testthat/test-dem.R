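# DEM phase: stability time scales, Hertzian contacts, the integrator, and
# drag relaxation.

cp_default <- contact_params()

test_that("Rayleigh and Hertz times follow their stated scalings", {
  t1 <- rayleigh_time(5.6e-6, 1100, cp_default)
  t2 <- rayleigh_time(11.2e-6, 1100, cp_default)
  expect_equal(t2 / t1, 2, tolerance = 1e-12)
  # Hertz time decreases with impact speed as v^-0.2
  h1 <- hertz_time(5.6e-6, 1100, cp_default, v_impact = 1e-3)
  h2 <- hertz_time(5.6e-6, 1100, cp_default, v_impact = 2e-3)
  expect_equal(h2 / h1, 2^-0.2, tolerance = 1e-12)
  # frozen direct evaluation for the reference RBC diameter
  G <- 1000 / (2 * (1 + 0.3))
  tray <- pi * (7.82e-6 / 2) * sqrt(1100 / G) / (0.1631 * 0.3 + 0.8766)
  expect_equal(rayleigh_time(7.82e-6, 1100, cp_default), tray)
  expect_equal(rayleigh_time(7.82e-6, 1100, cp_default), 2.2451e-5,
               tolerance = 1e-4)
  m_eff <- 1100 * pi * (7.82e-6)^3 / 6 / 2
  E_star <- 1000 / (2 * (1 - 0.09))
  ther <- 2.87 * (m_eff^2 / ((7.82e-6 / 4) * E_star^2 * 1e-3))^0.2
  expect_equal(hertz_time(7.82e-6, 1100, cp_default, 1e-3), ther)
  # zero impact speed falls back to the floor
  expect_equal(hertz_time(7.82e-6, 1100, cp_default, 0, v_floor = 1e-3), ther)
})

test_that("separated spheres and wall-clear particles feel no contact force", {
  spec <- test_spec()
  P <- make_particles(rbind(c(0, 0, 20e-6), c(10e-6, 0, 60e-6)), 5.6e-6)
  out <- contact_forces(P, spec, cp_default)
  expect_equal(max(abs(out$F)), 0)
  expect_equal(out$max_overlap, 0)
})

test_that("pair forces are antisymmetric at machine precision", {
  d_p <- 5.6e-6
  set.seed(9)
  # several random near-touching pairs with random velocities and spins
  for (rep in 1:5) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- rbind(c(0, 0, 0), dir * d_p * 0.97)
    P <- make_particles(pos + 30e-6, d_p, vel = matrix(rnorm(6) * 1e-3, 2, 3))
    P[, c("ox", "oy", "oz")] <- matrix(rnorm(6) * 10, 2, 3)
    out <- contact_forces(P, NULL, cp_default)
    expect_equal(out$F[1, ] + out$F[2, ], c(0, 0, 0), tolerance = 1e-25)
    expect_gt(max(abs(out$F)), 0)
  }
})

test_that("head-on binary collision conserves momentum; energy at e = 1 within 1 percent", {
  d_p <- 5.6e-6; rho_p <- 1100; v0 <- 1e-3
  run_collision <- function(e) {
    cp <- contact_params(restitution = e, friction = 0)
    P <- make_particles(rbind(c(-d_p / 2 - 2e-7, 0, 0), c(d_p / 2 + 2e-7, 0, 0)),
                        d_p, rho_p, vel = rbind(c(v0, 0, 0), c(-v0, 0, 0)))
    tH <- hertz_time(d_p, rho_p, cp, v_impact = 2 * v0)
    dt <- tH / 50
    n <- ceiling(3 * (4e-7 / v0 + tH) / dt)
    geom <- rbcdem:::geometry_descriptor(NULL)
    res <- rbcdem:::cpp_dem_substeps(
      as.matrix(P[, c("x", "y", "z")]), as.matrix(P[, c("vx", "vy", "vz")]),
      as.matrix(P[, c("ox", "oy", "oz")]),
      d_p, attr(P, "m_p"), attr(P, "I_p"), 1000, 1.2e-6, 1e-3, 25e-6,
      unlist(closure_guards()), matrix(0, 2, 3), c(0, 0), matrix(0, 2, 3),
      c(0, 0, 1), matrix(0, 2, 3), c(0, 0, 0), unlist(cp),
      geom$type, geom$R_c, geom$L, geom$W, geom$h_table, geom$dx_table,
      dt, n, FALSE, FALSE, FALSE, -1, attr(P, "V_p"))
    list(v = res$vel, m = attr(P, "m_p"))
  }
  el <- run_collision(1)
  # exact momentum conservation
  expect_equal(sum(el$v[, 1]) * el$m, 0, tolerance = 1e-30)
  # kinetic energy conserved within 1 percent at dt = t_Her / 50
  KE0 <- 0.5 * el$m * 2 * v0^2
  KE1 <- 0.5 * el$m * sum(el$v^2)
  expect_lt(abs(KE1 - KE0) / KE0, 0.01)
  # particles rebound
  expect_lt(el$v[1, 1], 0); expect_gt(el$v[2, 1], 0)
  # damped collision: outgoing speed ratio close to the restitution setting
  inel <- run_collision(0.5)
  expect_equal(abs(inel$v[1, 1]) / v0, 0.5, tolerance = 0.05)
  # energy never increases when e < 1
  expect_lt(0.5 * inel$m * sum(inel$v^2), KE0)
})

test_that("integrator: force-free flight and constant-force increments are exact", {
  P <- make_particles(matrix(c(1e-6, 2e-6, 3e-6), 1, 3), 5.6e-6,
                      vel = matrix(c(1e-3, -2e-3, 5e-4), 1, 3))
  dt <- 1e-6
  # zero force: uniform straight-line motion
  P1 <- dem_substep(P, matrix(0, 1, 3), dt)
  expect_equal(unlist(P1[1, c("vx", "vy", "vz")], use.names = FALSE),
               c(1e-3, -2e-3, 5e-4))
  expect_equal(P1$x, 1e-6 + 1e-3 * dt)
  # constant force for n steps: velocity increment n dt F / m exactly
  Fc <- matrix(c(1e-12, 0, 0), 1, 3)
  Pn <- P
  for (i in 1:20) Pn <- dem_substep(Pn, Fc, dt)
  expect_equal(Pn$vx - P$vx, 20 * dt * 1e-12 / attr(P, "m_p"), tolerance = 1e-12)
  expect_error(dem_substep(P, Fc, dt, dt_max = dt / 2), "stability")
})

test_that("a moving particle in quiescent fluid decelerates monotonically", {
  spec <- test_spec()
  P <- make_particles(matrix(c(10e-6, 0, 50e-6), 1, 3), 5.6e-6,
                      vel = matrix(c(0, 0, 2e-3), 1, 3))
  geom <- rbcdem:::geometry_descriptor(spec)
  dt <- 1e-6
  v <- numeric(30)
  st <- list(pos = as.matrix(P[, c("x", "y", "z")]),
             vel = as.matrix(P[, c("vx", "vy", "vz")]),
             om = as.matrix(P[, c("ox", "oy", "oz")]))
  for (i in 1:30) {
    res <- rbcdem:::cpp_dem_substeps(
      st$pos, st$vel, st$om, 5.6e-6, attr(P, "m_p"), attr(P, "I_p"),
      spec$rho, spec$nu, spec$u_av, spec$R_c, unlist(closure_guards()),
      matrix(0, 1, 3), 0, matrix(0, 1, 3), c(0, 0, 1), matrix(0, 1, 3),
      c(0, 0, 0), unlist(cp_default),
      geom$type, geom$R_c, geom$L, geom$W, geom$h_table, geom$dx_table,
      dt, 10L, TRUE, TRUE, FALSE, -1, attr(P, "V_p"))
    st <- list(pos = res$pos, vel = res$vel, om = res$omega)
    v[i] <- sqrt(sum(res$vel^2))
  }
  expect_true(all(diff(v) < 0))
  expect_gt(v[30], 0)
})

test_that("wall contact pushes a particle back inside the cylinder", {
  spec <- test_spec()
  r0 <- spec$R_c - 5.6e-6 / 2 + 0.02 * 5.6e-6   # slight wall overlap
  P <- make_particles(matrix(c(r0, 0, 50e-6), 1, 3), 5.6e-6)
  out <- contact_forces(P, spec, cp_default)
  expect_lt(out$F[1, 1], 0)   # inward (negative x) push
  expect_gt(out$max_overlap, 0)
})
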