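# Macroscopic observables: Pries reference correlations, flux ratios,
# percentage errors, skewness quadrature and DI statistics.

test_that("Pries correlations match hand evaluations at D = 50 um, Ht_c = 0.05", {
  pr <- pries_reference(50, 0.05)
  X <- 1 + 1.7 * exp(-17.5) - 0.6 * exp(-0.5)
  expect_equal(pr$X, X)
  expect_equal(round(pr$X, 4), 0.6361)
  Htd <- -X / (2 - 2 * X) + sqrt((X / (2 - 2 * X))^2 + 0.05 / (1 - X))
  expect_equal(pr$Ht_d_ref, Htd)
  expect_equal(round(pr$Ht_d_ref, 3), 0.075)
})

test_that("Pries asymptotes and algebraic zeros hold", {
  # Ht_c = 0 -> Ht_d = 0 for any diameter
  for (D in c(10, 50, 300)) expect_equal(pries_reference(D, 0)$Ht_d_ref, 0)
  # D -> infinity: mu_rel_045 -> 3.2 and C -> -0.8
  big <- pries_reference(5000, 0.05)
  expect_equal(big$mu_rel_045, 3.2, tolerance = 1e-6)
  expect_equal(big$C, -0.8, tolerance = 1e-6)
  # D -> 0+: C -> 1
  expect_equal(pries_reference(1e-4, 0.05)$C, 1, tolerance = 1e-3)
  # monotone: Ht_d_ref increases with Ht_c at fixed D
  hts <- seq(0.01, 0.45, by = 0.02)
  refs <- vapply(hts, function(h) pries_reference(50, h)$Ht_d_ref, numeric(1))
  expect_true(all(diff(refs) > 0))
  # physical ranges
  expect_true(all(refs > 0 & refs < 1))
  expect_gte(pries_reference(50, 0.05)$mu_rel_ref, 1)
})

test_that("discharge hematocrit and percentage error are the stated ratios", {
  s <- data.frame(Q_blood = rep(1.0, 10), Q_RBCs = rep(0.06, 10))
  expect_equal(discharge_hematocrit(s), 0.06)
  s0 <- data.frame(Q_blood = rep(2.5, 4), Q_RBCs = rep(0, 4))
  expect_equal(discharge_hematocrit(s0), 0)
  expect_equal(percentage_error(0.075, 0.075), 0)
  expect_equal(percentage_error(0.0754, 0.075), 100 * 0.0004 / 0.075)
  expect_equal(round(percentage_error(0.0754, 0.075), 2), 0.53)
  # symmetric in overshoot / undershoot
  expect_equal(percentage_error(0.08, 0.075), percentage_error(0.07, 0.075))
  expect_error(percentage_error(1, 0), "zero")
})

test_that("skewness index matches closed forms", {
  w <- seq(-0.5, 0.5, length.out = 401)
  # uniform profile: symmetric -> 0
  expect_equal(skewness_index(w, rep(1, length(w))), 0, tolerance = 1e-12)
  # support entirely on w > 0 -> 0.5
  Ht <- ifelse(w > 0.2, 1, 0)
  expect_equal(skewness_index(w, Ht), 0.5, tolerance = 1e-6)
  # linear profile Ht = 1 + w: int_0^0.5 = 0.625, total = 1 -> |0.625 - 0.5|
  expect_equal(skewness_index(w, 1 + w), 0.125, tolerance = 1e-6)
  expect_error(skewness_index(w, rep(0, length(w))), "zero")
})

test_that("DI statistics: mean, histogram and streamwise profile", {
  spec <- test_spec(L = 160e-6)
  P <- make_particles(rbind(c(5e-6, 0, 20e-6), c(5e-6, 0, 140e-6)), 5.6e-6)
  P$DI <- c(0.0, 0.2)
  st <- di_statistics(P, spec, n_bins = 20, n_stream = 4)
  expect_equal(st$mean, 0.1)
  expect_equal(sum(st$histogram$count), 2)
  # all-equal population: single occupied bin
  P$DI <- c(0.15, 0.15)
  st2 <- di_statistics(P, spec, n_bins = 20, n_stream = 4)
  expect_equal(st2$mean, 0.15)
  expect_equal(sum(st2$histogram$count > 0), 1)
  # streamwise bins place the two particles in bins 1 and 4
  expect_equal(which(st$profile$n > 0), c(1, 4))
  P$DI <- NA_real_
  expect_error(di_statistics(P, spec), "deformation")
})

test_that("hematocrit profiles feed the skewness index with the right asymmetry", {
  spec <- test_spec(R_c = 25e-6, L = 100e-6, topology = "planar")
  # particles stacked on the y > 0 side of a planar channel
  ys <- seq(5e-6, 20e-6, length.out = 12)
  P <- make_particles(cbind(50e-6, ys, 0), 5.6e-6)
  prof <- hematocrit_profile(P, spec, n_bins = 20)
  expect_equal(nrow(prof), 20)
  sH <- skewness_index(prof$w, prof$Ht)
  expect_gt(sH, 0.4)
  # symmetric population: near-zero skewness
  P2 <- make_particles(cbind(50e-6, c(ys, -ys), 0), 5.6e-6)
  prof2 <- hematocrit_profile(P2, spec, n_bins = 20)
  expect_lt(skewness_index(prof2$w, prof2$Ht), 0.03)
})

test_that("relative viscosity of a clean Poiseuille solve is 1 within solver tolerance", {
  spec <- test_spec()
  sf <- steady_fluid(spec, c(16L, 16L), n_steps = 150L)
  q <- fluid_flux(sf$state, sf$grid, 8L)
  samples <- data.frame(Q_blood = q, Q_RBCs = 0)
  mu_rel <- relative_viscosity(samples, spec)
  expect_equal(mu_rel, 1, tolerance = 0.01)
  expect_equal(discharge_hematocrit(samples), 0)
})

test_that("steady-state detector flags drifting and settled windows", {
  spec <- test_spec()
  qp <- plasma_flux(spec)
  t <- seq(0, 1, by = 1e-3)
  # settled stream
  m1 <- data.frame(t = t, Q_blood = qp, Q_RBCs = 0.06 * qp)
  s1 <- steady_state(m1, spec, window_time = 0.3)
  expect_true(s1$steady)
  # strongly drifting stream
  m2 <- data.frame(t = t, Q_blood = qp * (1 + t), Q_RBCs = 0.06 * qp)
  s2 <- steady_state(m2, spec, window_time = 0.3)
  expect_false(s2$steady)
})
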