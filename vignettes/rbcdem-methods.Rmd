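---
title: "Unresolved CFD-DEM simulation of red blood cell suspensions: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unresolved CFD-DEM simulation of red blood cell suspensions: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcdem)
```

## The model

`rbcdem` simulates dilute suspensions of red blood cells (RBCs) in
microchannels at channel Reynolds numbers below one. Each RBC is represented
as a sub-grid sphere of the cell's volume-equivalent diameter; the membrane
deformation, drag and lift that a resolved cell-level solver would compute
are replaced by closure correlations in the local dimensionless flow state:

* the dimensionless shear rate $\dot\gamma^{+} = \dot\gamma R_c^2/\nu$, with
  $\dot\gamma$ the magnitude of the wall-normal gradient of the streamwise
  velocity at the particle centre,
* the signed dimensionless slip $u_r^{+} = (u_p - u)\cdot \hat e_{flow} /
  u_{av}$, and
* the particle Reynolds number $Re_p = d_p\,|u_p - u|/\nu$.

The deformation index $DI \in [0,1)$ (elongation of the cell,
$(L-B)/(L+B)$ in terms of its longest and shortest axes) follows a rational
correlation in $(\dot\gamma^{+}, u_r^{+})$; the drag coefficient
$C_d(DI, Re_p)$ and the signed lift coefficient $C_l(DI, Re_p)$ then give
the fluid-particle forces

$$F_{drag} = 0.125\,C_d\,\rho\,\pi\,d_p^2\,|u-u_p|\,(u-u_p), \qquad
  F_{lift} = C_l\,\rho\,d_p^4\left(\dot\gamma^2 +
  \frac{|u_p-u|^2}{d_p^2}\right)\hat r,$$

with $\hat r$ the unit vector pointing from the particle toward the channel
axis. A positive lift coefficient therefore drives centerward migration,
which is the microscale mechanism behind the Fåhraeus-Lindqvist effect the
package validates against. The correlations were fitted on single-cell data
spanning $\dot\gamma^{+} \in [0.02, 0.35]$ and $Re_p \in [0.01, 0.12]$ at
channel Reynolds numbers $Re \in [0.1, 0.5]$ and radial stations
$r^* \in [0.2, 0.7]$ (`campaign_grid()` reproduces that design; for pipe
Poiseuille flow $\dot\gamma^{+} = Re\,r^*$).

The plasma is an incompressible Newtonian fluid carrying a fluid volume
fraction $\phi$ (one minus the deposited RBC solid fraction):

$$\partial_t \phi + \nabla\cdot(\phi u) = 0, \qquad
\rho\left(\partial_t(\phi u) + \nabla\cdot(\phi u u)\right) =
  -\phi\nabla p + \phi\mu\nabla^2 u - R_{p,f}.$$

The momentum exchange field is split into an implicit and an explicit part,
$R_{p,f} = K_{p,f}\,u - K_{p,f}\,\langle u_p\rangle$, with

$$K_{p,f} = \frac{\left|\sum_i (F_{drag,i} + F_{lift,i})\right|}
  {V_{cell}\,\left|u - \langle u_p\rangle\right|}$$

per grid cell. Particles obey linear and angular momentum balances with
soft-sphere Hertzian contacts (normal spring with restitution-based damping,
regularised Coulomb friction) against each other and the channel wall.

## Numerical method

**Fluid.** A staggered structured grid — axisymmetric $(r,z)$ for
cylindrical channels, planar $(y,x)$ with solid masks for stenosed
channels — with PISO pressure-velocity coupling: an implicit momentum
predictor (viscous terms and the implicit exchange $K u$ on the matrix;
pressure gradient, body force, explicit exchange and first-order upwind
advection on the right-hand side) followed by two pressure-correction
passes that enforce the discrete $\phi$-continuity equation. The pressure
system is solved by a cached sparse Cholesky factorisation (the sparsity
pattern is fixed; only values change per step) and the discrete continuity
residual is verified against a $10^{-8}$-class tolerance each step. The
correction coefficient uses the transient-plus-exchange part of the
momentum diagonal; including the viscous diagonal would over-relax the
pressure and is unstable at the viscous-dominated time steps used here.
Periodic streamwise boundaries with a constant axial body force stand in
for the mean pressure gradient. Because the body force is a
pressure-gradient surrogate, particles feel it through their pressure
force, $F_{p,p} = -V_p(\nabla p' - G\hat e_z)$: without this the particle
phase acquires an artificial axial lag that has no counterpart in a
pressure-driven channel.

**DEM.** Velocity-Verlet with one force evaluation per substep and
semi-implicit (linearised) drag in each half-kick, which is
unconditionally stable against the stiff drag correlation. Contacts are
found with a cell list at the particle diameter. The DEM step is set just
below $0.1\,\min(t_{Ray}, t_{Her})$ and the coupling interval either
follows the configuration or fills the Courant budget
(`Co = 0.15` by default) with DEM-stable substeps.

**Coupling.** Per coupling step: deposit the solid fraction, interpolate
the fluid at particle centres, evaluate the closures, assemble $K_{p,f}$
and $\langle u_p\rangle$, advance the fluid one CFD step, then run
`n_coupling` DEM substeps against the frozen local flow. Deposition uses a
divided scheme — each particle's volume is spread over the cells its
extent overlaps, pro rata by overlap length, conserving volume to machine
precision — followed by one conservative smoothing pass; cells whose
fluid fraction would fall below $\phi_{min} = 0.3$ push the excess solid
to their neighbours conservatively. The exchange fields (forces,
volume-weighted particle velocity) are deposited with the same divided
kernel, which is the volume-weighted per-cell mean the exchange
definition calls for when particles are larger than grid cells.

## Guarding the closures outside their fitted envelope

The fitted correlations are rational functions that misbehave outside
their data support, and a freely advecting particle reaches slips far
below the fitted $Re_p$ range. Three guards keep the evaluation inside
the envelope (all collected in `closure_guards()`):

* $Re_p$ is clamped to $[0.01, 0.12]$ before evaluating $C_d$ and $C_l$.
  Unclamped, the $0.00146/Re_p^3$ drag term makes the drag *force* diverge
  as the slip vanishes, which pins particles to the fluid and suppresses
  the lateral migration the model exists to capture. The force formulas
  always use the true relative velocity, so forces still vanish smoothly
  with slip.
* $DI$ is clamped to $[10^{-3}, 0.999]$ (the correlation can leave
  $[0,1)$ far outside its fitted slip range; such inputs are floored with
  a warning rather than extrapolated silently).
* The deformation index entering the *lift* coefficient is floored at
  $0.01$, the lower edge of the fitted deformation range. The
  $0.0008\,Re_p/DI^3$ lift term otherwise grows without bound at small
  deformation; since both lift and drag scale with the slip squared once
  $Re_p$ is clamped, an unguarded lift coefficient above roughly
  $0.125\,\pi\,C_d$ makes the radial dynamics self-accelerating. The floor
  keeps the lift subdominant to drag at every admissible state, which is a
  stability requirement, not a fit to any validation target.

## Sampling the undisturbed flow

The closures are defined on the *undisturbed* fluid velocity at the
particle centre. A particle's own momentum sink leaves a dip in the cell
it occupies; interpolating shear and the viscous Laplacian from the raw
field would feed the closures with this self-disturbance. Particle
sampling therefore interpolates from a lightly smoothed copy of the field
(two conservative passes), while the solver itself always works on the
raw field. The wall-normal reconstruction is quadratic, so parabolic
profiles and their shear are reproduced exactly; the streamwise direction
is linear (second order).

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `d_p` | 5.6 um | volume-equivalent RBC sphere diameter (90 fL cell volume; the undeformed discocyte diameter is 7.82 um) |
| `rho_p` | 1100 kg/m3 | RBC density |
| `rho`, `mu` | 1000 kg/m3, 1.2 mPa s | plasma density and viscosity |
| `E_eff`, `poisson` | 1 kPa, 0.3 | soft-cell contact stiffness (keeps the Rayleigh time tractable) |
| `restitution`, `friction` | 0.5, 0.1 | contact damping and sliding friction |
| `Co` | 0.15 | Courant target |
| `phi_min` | 0.3 | fluid-fraction clamp |
| `eps_u` | 1e-12 m/s | exchange-denominator regulariser |

The contact parameters and the equivalent-sphere diameter are modelling
choices (no cell-level reference values are fixed by the closure data);
all are configuration-overridable.

## The synthetic cases and what passing them shows

The straight-channel validation seeds non-overlapping spheres uniformly at
channel hematocrit $Ht_c = 0.05$ in a periodic cylindrical channel
(default $D = 50\ \mu m$, $L = 200\ \mu m$, about 214 particles,
$Re = 0.3$, a coarse $16 \times 32$ axisymmetric grid) and runs to a
steadiness criterion: windows of 20 domain flow-through times, steady when
the discharge hematocrit and relative viscosity drift less than 1% over
two consecutive windows. Discharge hematocrit is the ratio of the
particle-volume crossing flux to the whole-suspension flux at a fixed
interior plane; relative viscosity is the analytic clean-plasma flux at
the same driving force divided by the measured suspension flux. Both are
compared to the Pries in-vitro correlations at the same diameter and
hematocrit.

What this exercises: lift-driven migration, volume exclusion, two-way
momentum exchange and the flux bookkeeping. What it does not show: real
RBC deformability (cells here are spheres with a deformation *index*, not
deformed shapes), cell-cell hydrodynamic interactions beyond the
volume-fraction field, aggregation, and hematocrits beyond the dilute
regime — the closures are single-cell based and are validated only up to
about 15% hematocrit, and exercised here around 5%.

## Known limitations and an honest accuracy note

At desk scale the grid cells are comparable to (radially, smaller than)
the particle diameter, a regime at the edge of the unresolved-coupling
premise. The measured accuracy is asymmetric in the two validation
metrics, and the coupling discretisation choice matters:

* with the per-cell exchange assembled from the kernel-deposited
  (volume-weighted) particle fields — the definition adopted here — the
  suspension flux is essentially unaffected by the exchange and the
  migrating cells over-concentrate near the axis: the discharge
  hematocrit overshoots the Pries reference by roughly 20% and the
  relative viscosity undershoots by roughly 10% in the default run;
* assigning each particle wholly to its centre cell instead makes the
  implicit exchange saturate (the denominator slip vanishes, $K$ grows to
  the regulariser ceiling, and the fluid is pinned cell-by-cell to
  individual particle velocities): the discharge hematocrit then matches
  the reference to better than 1%, but the pinning removes far more
  momentum than the closure forces deliver to the particles, breaking
  per-step action-reaction and inflating the relative viscosity by about
  35%.

The published accuracy of this class of model (both metrics within 5%)
sits between these two regimes and is evidently sensitive to the ratio of
cell size to particle size in the exchange assembly; resolving that
properly would need the original multi-particle-per-cell mesh scale,
which is outside desk scale. The acceptance machinery reports the
kernel-deposited result without adjustment.

Further limitations: no RBC orientation model (the single-cell data show
tumbling with no preferred inclination); no dependence on the elastic
capillary number or the viscosity ratio (held constant in the closure
data); the bifurcation geometry is planar and its hematocrit-skewness
comparisons across branch angles are qualitative only; wall contacts in
masked channels ignore the local wall slope (gentle cosine constrictions).

## Problem sizes used by the test-suite and acceptance runs

Module tests use 8-32 cells across the radius and runs of a few
milliseconds of physical time; the migration and collision checks use one
or two particles. The straight-channel validation runs about 214 particles
on the $16\times32$ grid for up to 4.5 s of physical time (three to four
steadiness windows), which is the configuration the acceptance script
reproduces from scratch with the seed it is given.
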