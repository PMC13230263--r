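# Staggered structured grids: axisymmetric (r, z) for cylindrical channels,
# planar (y, x) with solid masks for stenosis/bifurcation demonstrations.

#' Build a staggered structured grid for a channel
#'
#' Axisymmetric grids cover `r` in `[0, R_c]`, `z` in `[0, L]` with annular
#' cell volumes; planar grids cover `y` in `[-R_c, R_c]`, `x` in `[0, L]` with
#' an out-of-plane depth. Cell centres carry pressure and fluid volume
#' fraction; face-normal velocities live on the staggered faces. Solid masks
#' (stenosis) blank cells whose centre falls outside the open channel.
#'
#' @param spec A [channel_spec()].
#' @param resolution Integer vector `c(n_wall_normal, n_streamwise)`; a single
#'   number is taken as cells across the radius with a streamwise count
#'   keeping cells near-isotropic. At least 8 cells across the radius.
#' @return An object of class `rbc_grid`.
#' @export
build_grid <- function(spec, resolution = c(16L, 32L)) {
  stopifnot(inherits(spec, "channel_spec"))
  if (length(resolution) == 1L)
    resolution <- c(resolution, max(8L, round(resolution * spec$L / (2 * spec$R_c))))
  n1 <- as.integer(resolution[1]); n2 <- as.integer(resolution[2])
  axi <- spec$topology == "axisymmetric"
  n_across_radius <- if (axi) n1 else n1 / 2
  if (n_across_radius < 8) stop("resolution too coarse: need >= 8 cells across the radius")
  if (axi) {
    dr <- spec$R_c / n1
    rn_f <- seq(0, spec$R_c, length.out = n1 + 1L)
  } else {
    dr <- 2 * spec$R_c / n1
    rn_f <- seq(-spec$R_c, spec$R_c, length.out = n1 + 1L)
  }
  ds <- spec$L / n2
  rn_c <- (rn_f[-1] + rn_f[-(n1 + 1L)]) / 2
  s_c <- (seq_len(n2) - 0.5) * ds
  s_f <- seq_len(n2) * ds  # streamwise face k sits between cells k and k+1 (wrap)
  W <- if (axi) NA_real_ else spec$depth
  if (axi) {
    A_sf <- 2 * pi * rn_c * dr            # streamwise-face area per row
    A_nf <- 2 * pi * rn_f * ds            # wall-normal-face area per face radius
    V_row <- pi * (rn_f[-1]^2 - rn_f[-(n1 + 1L)]^2) * ds
  } else {
    A_sf <- rep(dr * W, n1)
    A_nf <- rep(ds * W, n1 + 1L)
    V_row <- rep(dr * ds * W, n1)
  }
  V_cell <- matrix(V_row, n1, n2)
  solid <- matrix(FALSE, n1, n2)
  if (!axi && !is.null(spec$mask)) {
    h <- channel_half_height(spec, s_c)
    solid <- outer(abs(rn_c), h, `>`)
  }
  structure(list(topology = spec$topology, n1 = n1, n2 = n2, dr = dr, ds = ds,
                 rn_f = rn_f, rn_c = rn_c, s_c = s_c, s_f = s_f,
                 A_sf = A_sf, A_nf = A_nf, V_cell = V_cell, solid = solid,
                 R_c = spec$R_c, L = spec$L, depth = W),
            class = "rbc_grid")
}

#' Total fluid-accessible volume of a grid
#'
#' Sum of unmasked cell volumes; for an unmasked axisymmetric grid this
#' tessellates the cylinder volume `pi R_c^2 L` exactly.
#'
#' @param grid An [build_grid()] object.
#' @return Volume \[m^3\].
#' @export
grid_volume <- function(grid) sum(grid$V_cell[!grid$solid])

# Map 3D particle positions to grid (rn, s) coordinates.
# Axisymmetric: rn = sqrt(x^2 + y^2), s = z. Planar: rn = y, s = x.
particle_grid_coords <- function(grid, pos) {
  if (grid$topology == "axisymmetric") {
    list(rn = sqrt(pos[, 1]^2 + pos[, 2]^2), s = pos[, 3] %% grid$L)
  } else {
    list(rn = pos[, 2], s = pos[, 1] %% grid$L)
  }
}
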