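# Shared fixtures: small channel specs and particle sets built in code.

test_spec <- function(R_c = 25e-6, L = 100e-6, Re = 0.3, Ht_c = 0, ...) {
  channel_spec(R_c = R_c, L = L, Re = Re, Ht_c = Ht_c, ...)
}

# drive a particle-free fluid state to steady Poiseuille
steady_fluid <- function(spec, resolution = c(16L, 16L), n_steps = 120L,
                         dt = 1e-4, init = "rest", phi = NULL) {
  grid <- build_grid(spec, resolution)
  st <- fluid_state(grid, spec, init = init)
  if (!is.null(phi)) st$phi <- matrix(phi, grid$n1, grid$n2)
  for (i in seq_len(n_steps)) st <- advance_fluid(st, grid, NULL, dt)
  list(state = st, grid = grid)
}

# analytic Hagen-Poiseuille profile at the grid rows
poiseuille_profile <- function(spec, grid) {
  spec$G * (spec$R_c^2 - grid$rn_c^2) / (4 * spec$mu)
}
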