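# rbcdem

Unresolved CFD–DEM simulation of red blood cell (RBC) suspensions in
microchannels.

Cell-resolved blood simulation is accurate but costs too much to scale past
a handful of cells; single-phase non-Newtonian models scale but lose the
cells entirely. `rbcdem` implements the intermediate, *unresolved* strategy
for people studying microscale blood flow (Fåhraeus–Lindqvist effect,
cell-free layers, microfluidic device design, stenosed vessels): each RBC is
a sub-grid sphere whose deformation, drag and lift come from closure
correlations fitted on resolved single-cell data, two-way coupled to a
volume-fraction incompressible Navier–Stokes solver.

The closures are functions of the local dimensionless state
(γ̇⁺ = γ̇R²/ν, u⁺ᵣ = (uₚ−u)·ê/u_av, Reₚ = dₚ|uₚ−u|/ν):

    DI = γ̇⁺³ / (γ̇⁺³(10 + u⁺ᵣ³) + 0.117 γ̇⁺²(u⁺ᵣ − u⁺ᵣ⁴) + 0.0026)
    C_d = (169 Reₚ²(DI+1) + 0.00146) / Reₚ³
    C_l = −3.19 DI⁴/Reₚ + 2.48 DI/Reₚ + 0.0008 Reₚ/DI³

    F_drag = 0.125 C_d ρ π dₚ² |u−uₚ| (u−uₚ)
    F_lift = C_l ρ dₚ⁴ (γ̇² + |uₚ−u|²/dₚ²) r̂        (r̂ toward the axis)

The fluid solves the φ-weighted Navier–Stokes equations on a staggered
structured grid (axisymmetric or planar, PISO pressure–velocity coupling)
with the per-cell momentum exchange `R = K u − K⟨uₚ⟩`,
`K = |Σ(F_drag+F_lift)| / (V_cell |u−⟨uₚ⟩|)`. Particles integrate Newton–Euler
equations with soft-sphere Hertzian contacts under Rayleigh/Hertz time-step
control. Built-in validation metrics: discharge hematocrit, relative
apparent viscosity, the Pries in-vitro reference correlations, hematocrit
skewness, and deformation-index statistics.

## Worked example

The single-cell campaign that underlies the closures spans six radial
stations and five channel Reynolds numbers; for pipe Poiseuille flow the
dimensionless shear rate at a station is simply `Re * r_star`:

```r
library(rbcdem)
g <- campaign_grid()
range(g$gamma_plus)
#> [1] 0.02 0.35
```

Evaluating the closures along that range (at Reₚ = 0.05):

```r
closure_eval(gamma_plus = c(0.02, 0.15, 0.35), u_r_plus = 0, Re_p = 0.05)
#>            DI      C_d       C_l Re_p_eff
#> 1 0.002985075 3401.770 40.495999     0.05
#> 2 0.092847318 3705.504  4.650461     0.05
#> 3 0.099397241 3727.643  4.964608     0.05
```

A cell at mid-radius of a 50 um channel deforms to DI ≈ 0.09 — a mildly
elongated cell — and feels a strong positive (centerward) lift, the
mechanism that depletes the wall region and produces the
Fåhraeus–Lindqvist effect. The in-vitro reference values for that channel:

```r
pr <- pries_reference(D_um = 50, Ht_c = 0.05)
c(Ht_d = pr$Ht_d_ref, mu_rel = pr$mu_rel_ref)
#>      Ht_d    mu_rel
#> 0.0753573 1.1095170
```

i.e. the discharge hematocrit should exceed the channel hematocrit by ~50%
and the apparent viscosity should sit ~11% above plasma. A full coupled
validation run (periodic 50 um channel, ~214 cells, run to steadiness —
several minutes of compute):

```r
spec <- channel_spec(R_c = 25e-6, L = 200e-6, Re = 0.3, Ht_c = 0.05)
run <- run_coupled(case_setup(spec, seed = 1), T_end = 4.5)
tail(run$windows, 1)
```

Smaller building blocks are exported individually: `seed_particles()`,
`build_grid()`, `advance_fluid()`, `contact_forces()`, `detect_period()`,
`stenosis_case()`, `bifurcation_case()`, and so on. A thin command-line
front end lives in `inst/cli/rbcdem` (`closures eval`, `run --config`,
`calibrate period`, `scenario build`; case files are YAML, see
`read_case_config()`).

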