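# RBC closure correlations: frozen scalar evaluations, algebraic identities,
# clamping behaviour and force scalings.

test_that("deformation index matches hand-evaluated values and limits", {
  # zero-shear limit: numerator zero -> floored
  expect_equal(deformation_index(0, 0), closure_guards()$di_floor)
  # hand evaluation at the envelope maximum
  expect_equal(deformation_index(0.35, 0), 0.35^3 / (10 * 0.35^3 + 0.0026))
  expect_equal(round(deformation_index(0.35, 0), 4), 0.0994)
  # large-shear asymptote 1/10
  expect_equal(deformation_index(1e6, 0), 0.1, tolerance = 1e-6)
})

test_that("deformation index is monotone in shear at zero slip and clamped", {
  g <- seq(0, 0.35, length.out = 200)
  di <- deformation_index(g, 0)
  expect_true(all(diff(di) >= -1e-15))
  expect_true(all(di >= closure_guards()$di_floor & di < 1))
  # far outside the fitted slip range the denominator can go non-positive
  expect_warning(di_bad <- deformation_index(0.3, -8),
                 "denominator")
  expect_equal(di_bad, closure_guards()$di_floor)
})

test_that("drag coefficient matches hand evaluations and its identity", {
  expect_equal(drag_coefficient(0, 0.1), (169 * 0.01 + 0.00146) / 1e-3)
  expect_equal(round(drag_coefficient(0, 0.1), 2), 1691.46)
  expect_equal(drag_coefficient(0.1, 0.05),
               (169 * 0.05^2 * 1.1 + 0.00146) / 0.05^3)
  expect_equal(round(drag_coefficient(0.1, 0.05), 1), 3729.7)
  # C_d Re_p^3 - 169 Re_p^2 (DI+1) = 0.00146 for any admissible input
  set.seed(42)
  DI <- runif(50, 0, 0.99); Rp <- runif(50, 0.01, 0.12)
  lhs <- drag_coefficient(DI, Rp) * Rp^3 - 169 * Rp^2 * (DI + 1)
  expect_equal(lhs, rep(0.00146, 50), tolerance = 1e-12)
  # at fixed large Re_p the (DI+1) factor dominates: ratio -> 2
  expect_equal(drag_coefficient(1 - 1e-12, 100) / drag_coefficient(0, 100), 2,
               tolerance = 1e-4)
  expect_error(drag_coefficient(0.1, 0), "Re_p")
})

test_that("lift coefficient matches hand evaluations and changes sign", {
  expect_equal(lift_coefficient(0.1, 0.1), -0.00319 + 2.48 + 0.08)
  expect_equal(lift_coefficient(1, 1), -3.19 + 2.48 + 0.0008)
  # for Re_p = 1 a root lies between DI = 0.1 (positive) and DI = 1 (negative)
  f <- function(di) lift_coefficient(di, 1)
  expect_gt(f(0.1), 0); expect_lt(f(1), 0)
  root <- uniroot(f, c(0.1, 1), tol = 1e-12)$root
  expect_lt(abs(f(root)), 1e-9)
  expect_error(lift_coefficient(0, 0.1), "DI")
})

test_that("rigid-cell limit: constant DI makes both coefficients functions of Re_p only", {
  Rp <- c(0.01, 0.05, 0.12)
  cd1 <- drag_coefficient(0.05, Rp); cd2 <- drag_coefficient(0.05, Rp)
  expect_identical(cd1, cd2)
  # and they vary with Re_p
  expect_true(all(diff(drag_coefficient(0.05, Rp)) != 0))
})

test_that("drag force follows the quadratic law and its sign structure", {
  fl <- local_flow(u_fluid = c(1e-4, 0, 0), u_particle = c(0, 0, 0),
                   shear_rate = 0, radial_unit = c(0, 0, 0),
                   u_av = 1e-3, nu = 1.2e-6, rho = 1000, d_p = 7.82e-6,
                   R_c = 25e-6)
  F <- drag_force(fl, 1691.46)
  # hand evaluation of the quadratic drag law at these inputs
  expect_equal(F[1], 0.125 * 1691.46 * 1000 * pi * (7.82e-6)^2 * 1e-8)
  expect_equal(F[1], 4.0619e-13, tolerance = 1e-4)
  expect_equal(F[2:3], c(0, 0))
  # antiparallel to (u_p - u) always
  set.seed(7)
  for (i in 1:5) {
    up <- rnorm(3) * 1e-3
    fl2 <- local_flow(u_fluid = c(0, 0, 0), u_particle = up, shear_rate = 0,
                      radial_unit = c(0, 0, 0), u_av = 1e-3, nu = 1.2e-6,
                      rho = 1000, d_p = 5.6e-6, R_c = 25e-6)
    Fd <- drag_force(fl2, 10)
    expect_lt(sum(Fd * up), 0)
  }
  # zero relative velocity -> zero force
  fl0 <- local_flow(c(1e-3, 0, 0), c(1e-3, 0, 0), 0, c(0, 0, 0),
                    1e-3, 1.2e-6, 1000, 5.6e-6, 25e-6)
  expect_equal(drag_force(fl0, 100), c(0, 0, 0))
})

test_that("lift force scaling, direction and magnitude", {
  mk <- function(d_p, shear) local_flow(c(0, 0, 1e-3), c(0, 0, 1e-3), shear,
                                        c(-1, 0, 0), 1e-3, 1.2e-6, 1000, d_p, 25e-6)
  # hand evaluation at u_p = u
  F <- lift_force(mk(7.82e-6, 100), 2.5568)
  expect_equal(sqrt(sum(F^2)), 2.5568 * 1000 * (7.82e-6)^4 * 1e4)
  expect_equal(sqrt(sum(F^2)), 9.5614e-14, tolerance = 1e-4)
  # points toward the axis for positive C_l
  expect_lt(F[1], 0)
  # d_p^4 scaling at fixed shear, zero slip: doubling d_p multiplies by 16
  F2 <- lift_force(mk(2 * 7.82e-6, 100), 2.5568)
  expect_equal(sqrt(sum(F2^2)) / sqrt(sum(F^2)), 16, tolerance = 1e-12)
  # zero shear and zero slip -> zero force
  expect_equal(lift_force(mk(7.82e-6, 0), 2.5568), c(0, 0, 0))
})

test_that("dimensionless state reduces correctly and validates inputs", {
  fl <- local_flow(u_fluid = c(0, 0, 2e-3), u_particle = c(0, 0, 2.5e-3),
                   shear_rate = 200, radial_unit = c(-1, 0, 0),
                   u_av = 1.8e-3, nu = 1.2e-6, rho = 1000, d_p = 5.6e-6,
                   R_c = 25e-6)
  s <- dimensionless_state(fl, c(0, 0, 1))
  expect_equal(s$gamma_plus, 200 * (25e-6)^2 / 1.2e-6)
  expect_equal(s$u_r_plus, 5e-4 / 1.8e-3)
  expect_equal(s$Re_p, 5.6e-6 * 5e-4 / 1.2e-6)
  # zero relative velocity
  fl0 <- local_flow(c(0, 0, 2e-3), c(0, 0, 2e-3), 200, c(-1, 0, 0),
                    1.8e-3, 1.2e-6, 1000, 5.6e-6, 25e-6)
  s0 <- dimensionless_state(fl0, c(0, 0, 1))
  expect_equal(s0$u_r_plus, 0); expect_equal(s0$Re_p, 0)
  expect_error(dimensionless_state(fl, c(0, 0, 2)), "unit")
  flbad <- fl; flbad$u_av <- 0
  expect_error(dimensionless_state(flbad, c(0, 0, 1)), "u_av")
})

test_that("compiled closure kernel agrees with the R implementation", {
  set.seed(11)
  g <- runif(200, 0, 0.5); ur <- runif(200, -1, 1); rp <- runif(200, 1e-4, 0.2)
  r_side <- closure_eval(g, ur, rp)
  c_side <- rbcdem:::cpp_closures(g, ur, rp, unlist(closure_guards()))
  expect_equal(c_side[, 1], r_side$DI, tolerance = 1e-14)
  expect_equal(c_side[, 2], r_side$C_d, tolerance = 1e-14)
  expect_equal(c_side[, 3], r_side$C_l, tolerance = 1e-14)
})
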