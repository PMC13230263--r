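# Case generation: channel specifications, the resolved-campaign grid,
# particle seeding at a target hematocrit, stenosis and bifurcation masks.

#' Channel specification
#'
#' Geometry and driving conditions for a microchannel case. The channel
#' Reynolds number is `Re = rho * D * U_max / mu` with `D = 2 * R_c`; the
#' driving axial body force (mean-pressure-gradient surrogate) and the bulk
#' velocity are derived from it for the clean (particle-free) Poiseuille flow.
#'
#' @param R_c Channel radius (axisymmetric) or half-height (planar) \[m\].
#' @param L Channel length along the flow \[m\].
#' @param Re Channel Reynolds number, in `[0.1, 0.5]` for the fitted closures.
#' @param Ht_c Channel hematocrit (RBC volume fraction), warned above 0.05,
#'   rejected above 0.15 (outside the validated dilute regime).
#' @param rho Fluid density \[kg/m^3\].
#' @param mu Dynamic viscosity \[Pa s\].
#' @param topology `"axisymmetric"` or `"planar"`.
#' @param depth Out-of-plane depth for planar channels \[m\] (defaults to `2 R_c`).
#' @param mask Optional mask specification from [stenosis_case()] or
#'   [bifurcation_case()].
#' @return An object of class `channel_spec` with derived fields `D`, `U_max`,
#'   `u_av`, `G` (axial body force \[N/m^3\]) and `nu`.
#' @export
channel_spec <- function(R_c, L, Re, Ht_c = 0, rho = 1000, mu = 1.2e-3,
                         topology = c("axisymmetric", "planar"),
                         depth = NULL, mask = NULL) {
  topology <- match.arg(topology)
  stopifnot(R_c > 0, L > 0, Re > 0, rho > 0, mu > 0)
  if (Ht_c < 0 || Ht_c > 0.15)
    stop("Ht_c must lie in [0, 0.15]: the closures are single-cell based")
  if (Ht_c > 0.05)
    warning("Ht_c above 0.05: closures validated in the dilute regime only")
  D <- 2 * R_c
  U_max <- Re * mu / (rho * D)
  spec <- list(R_c = R_c, L = L, Re = Re, Ht_c = Ht_c, rho = rho, mu = mu,
               nu = mu / rho, topology = topology, D = D, U_max = U_max,
               mask = mask,
               depth = if (topology == "planar") (if (is.null(depth)) D else depth) else NULL)
  if (topology == "axisymmetric") {
    spec$u_av <- U_max / 2
    spec$G <- 4 * mu * U_max / R_c^2
  } else {
    spec$u_av <- 2 * U_max / 3
    spec$G <- 2 * mu * U_max / R_c^2
  }
  structure(spec, class = "channel_spec")
}

#' Resolved-simulation campaign grid
#'
#' The Cartesian grid of dimensionless radial positions
#' `r* = (0.2, 0.3, ..., 0.7)` and channel Reynolds numbers
#' `Re = (0.1, ..., 0.5)` on which the single-cell closure data were
#' collected. For pipe Poiseuille flow the dimensionless shear rate at the
#' particle reduces to `gamma_plus = Re * r*` (since
#' `gamma = 2 U_max r / R_c^2` and `Re = 2 rho R_c U_max / mu`), spanning
#' 0.02 to 0.35 over the grid.
#'
#' @return A data.frame with columns `Re`, `r_star`, `gamma_plus` (30 rows).
#' @export
campaign_grid <- function() {
  g <- expand.grid(r_star = seq(0.2, 0.7, by = 0.1),
                   Re = seq(0.1, 0.5, by = 0.1),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("Re", "r_star")]
  g$gamma_plus <- g$Re * g$r_star
  rownames(g) <- NULL
  g
}

#' Poiseuille dimensionless shear rate at a radial station
#'
#' Evaluates `gamma_plus` through the full [dimensionless_state()] pathway on
#' the analytic Poiseuille profile (used to cross-check the `Re * r_star`
#' reduction of [campaign_grid()]).
#'
#' @param spec A [channel_spec()].
#' @param r_star Dimensionless radial position `r / R_c`.
#' @return `gamma_plus` at that station.
#' @export
poiseuille_gamma_plus <- function(spec, r_star) {
  r <- r_star * spec$R_c
  shear <- 2 * spec$U_max * r / spec$R_c^2
  fl <- local_flow(u_fluid = c(0, 0, spec$U_max * (1 - r_star^2)),
                   u_particle = c(0, 0, spec$U_max * (1 - r_star^2)),
                   shear_rate = shear, radial_unit = c(-1, 0, 0),
                   u_av = spec$u_av, nu = spec$nu, rho = spec$rho,
                   d_p = 5.6e-6, R_c = spec$R_c)
  dimensionless_state(fl, c(0, 0, 1))$gamma_plus
}

# Local half-height h(x) of a planar channel (mask-aware); vectorised over x.
channel_half_height <- function(spec, x) {
  h0 <- spec$R_c
  m <- spec$mask
  if (is.null(m) || m$type != "stenosis") return(rep(h0, length(x)))
  ht <- m$throat / 2
  inb <- abs(x - m$x0) < m$width / 2
  h <- rep(h0, length(x))
  h[inb] <- h0 - (h0 - ht) / 2 * (1 + cos(2 * pi * (x[inb] - m$x0) / m$width))
  h
}

#' Seed non-overlapping particles at a target hematocrit
#'
#' Uniform random placement of `N = round(Ht_c V_channel / V_p)` spheres
#' inside the geometry with wall clearance `d_p / 2`, by rejection sampling.
#' Deterministic for a given `seed` (the caller's RNG state is preserved).
#'
#' @param spec A [channel_spec()].
#' @param d_p Particle diameter \[m\].
#' @param seed Integer seed.
#' @param rho_p Particle density \[kg/m^3\].
#' @param max_attempts Rejection budget per particle.
#' @return A data.frame of particles (see [make_particles()]).
#' @export
seed_particles <- function(spec, d_p, seed = 1L, rho_p = 1100,
                           max_attempts = 2000L) {
  V_p <- pi * d_p^3 / 6
  if (spec$topology == "axisymmetric") {
    V_ch <- pi * spec$R_c^2 * spec$L
  } else {
    xs <- seq(0, spec$L, length.out = 4096L)
    V_ch <- 2 * mean(channel_half_height(spec, xs)) * spec$L * spec$depth
  }
  n <- round(spec$Ht_c * V_ch / V_p)
  if (n == 0L) return(make_particles(matrix(numeric(0), 0, 3), d_p, rho_p))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  a <- d_p / 2
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts * n)
      stop("seed_particles: rejection budget exhausted; lower Ht_c or d_p")
    if (spec$topology == "axisymmetric") {
      r <- sqrt(runif(1)) * (spec$R_c - a)
      th <- runif(1, 0, 2 * pi)
      cand <- c(r * cos(th), r * sin(th), runif(1, 0, spec$L))
    } else {
      x <- runif(1, 0, spec$L)
      h <- channel_half_height(spec, x) - a
      if (h <= 0) next
      cand <- c(x, runif(1, -h, h), runif(1, -spec$depth / 2, spec$depth / 2))
    }
    ok <- TRUE
    if (placed > 0L) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
      # periodic along the flow (x3 axisymmetric, x1 planar) and planar depth
      per_i <- if (spec$topology == "axisymmetric") 3L else 1L
      d[, per_i] <- d[, per_i] - spec$L * round(d[, per_i] / spec$L)
      if (spec$topology == "planar")
        d[, 3] <- d[, 3] - spec$depth * round(d[, 3] / spec$depth)
      ok <- all(rowSums(d^2) >= d_p^2)
    }
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  make_particles(pos, d_p, rho_p)
}

#' Stenosed planar channel case
#'
#' A planar channel of height `D` with a smooth (cosine) symmetric
#' constriction down to `throat` at mid-length. The open fraction at the
#' throat plane is `throat / D`.
#'
#' @param D Channel height \[m\].
#' @param throat Minimum channel height at the constriction \[m\].
#' @param L Channel length (default `4 D`).
#' @param width Streamwise extent of the constriction (default `D`).
#' @param Re Channel Reynolds number.
#' @param Ht_c Channel hematocrit.
#' @param ... Passed to [channel_spec()].
#' @return A planar [channel_spec()] carrying the stenosis mask.
#' @export
stenosis_case <- function(D, throat, L = 4 * D, width = D, Re = 0.3,
                          Ht_c = 0.05, ...) {
  if (throat > D) stop("throat must not exceed the channel height D")
  mask <- if (throat == D) NULL else
    list(type = "stenosis", throat = throat, x0 = L / 2, width = width)
  channel_spec(R_c = D / 2, L = L, Re = Re, Ht_c = Ht_c,
               topology = "planar", mask = mask, ...)
}

#' Bifurcated planar channel geometry
#'
#' Planar approximation of a bifurcating microfluidic device: a parent
#' channel along `x` splitting at `x_b` into a main outlet (continuing along
#' `x`) and a daughter branch at angle `alpha` from the parent axis.
#' Measurement cuts are placed at `cut_distance` downstream of the
#' bifurcation in each branch. The mask is returned as a point-membership
#' function plus the cut geometry; it is a planar stand-in for the 3D device,
#' so skewness comparisons across `alpha` are qualitative.
#'
#' @param alpha Bifurcation angle in degrees, in `(0, 90]`.
#' @param D Channel height of every branch \[m\].
#' @param L_parent,L_branch Lengths of parent and branches \[m\].
#' @param cut_distance Distance of the measurement cuts from the bifurcation \[m\].
#' @return A list of class `bifurcation_case` with `inside(x, y)`, the two
#'   measurement cuts, and the geometric parameters.
#' @export
bifurcation_case <- function(alpha, D = 100e-6, L_parent = 4 * D,
                             L_branch = 6 * D, cut_distance = 200e-6) {
  if (alpha <= 0 || alpha > 90) stop("alpha must be in (0, 90] degrees")
  h <- D / 2
  a <- alpha * pi / 180
  x_b <- L_parent
  dir_d <- c(cos(a), sin(a))
  inside <- function(x, y) {
    in_parent <- x <= x_b & x >= 0 & abs(y) <= h
    in_main <- x > x_b & x <= x_b + L_branch & abs(y) <= h
    # daughter: strip of half-width h around the centreline from (x_b, 0)
    sx <- x - x_b
    t <- sx * dir_d[1] + y * dir_d[2]           # along-branch coordinate
    nrm <- -sx * dir_d[2] + y * dir_d[1]        # normal coordinate
    in_daughter <- t > 0 & t <= L_branch & abs(nrm) <= h
    in_parent | in_main | in_daughter
  }
  cuts <- list(
    main = list(point = c(x_b + cut_distance, 0), normal = c(1, 0),
                halfwidth = h),
    daughter = list(point = c(x_b + cut_distance * dir_d[1],
                              cut_distance * dir_d[2]),
                    normal = dir_d, halfwidth = h))
  structure(list(alpha = alpha, D = D, x_b = x_b, L_parent = L_parent,
                 L_branch = L_branch, inside = inside, cuts = cuts,
                 daughter_direction = dir_d),
            class = "bifurcation_case")
}
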