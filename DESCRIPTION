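Package: rbcdem
Title: Unresolved CFD-DEM Simulation of Red Blood Cell Suspensions in Microchannels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-way coupled unresolved CFD-DEM simulator for dilute red blood
    cell (RBC) suspensions in microchannels. RBCs are sub-grid soft spheres whose
    deformation index, drag and lift follow closure correlations in the local
    dimensionless shear rate, slip velocity and particle Reynolds number; the
    plasma is solved as a volume-fraction incompressible Navier-Stokes fluid on a
    staggered structured grid (axisymmetric or planar) with PISO pressure-velocity
    coupling. Includes soft-sphere Hertzian contacts with Rayleigh/Hertz time-step
    control, momentum-exchange coupling fields, validation metrics (discharge
    hematocrit, relative apparent viscosity, Pries empirical correlations,
    hematocrit skewness, deformation-index statistics), channel/stenosis/
    bifurcation scenario builders, and period-detection utilities for oscillating
    drag and deformation signals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
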