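# Output writers: VTK legacy structured grids for field snapshots, CSV for
# particles and metrics, YAML manifests, and the case-configuration reader.

#' Write a fluid field snapshot as a VTK legacy structured grid
#'
#' Cell-centred pressure, fluid fraction and (face-averaged) velocity on an
#' ASCII `STRUCTURED_POINTS` legacy VTK file readable by ParaView.
#'
#' @param state A [fluid_state()].
#' @param grid The grid.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_vtk_fields <- function(state, grid, path) {
  n1 <- grid$n1; n2 <- grid$n2
  uc_s <- 0.5 * (state$u_s + shift_s(state$u_s, -1L))
  uc_n <- if (n1 > 1L) 0.5 * (rbind(state$u_n, 0) + rbind(0, state$u_n)) else
    matrix(0, n1, n2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "rbcdem field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", n2, n1),
               sprintf("ORIGIN %g %g 0", grid$s_c[1], grid$rn_c[1]),
               sprintf("SPACING %g %g 1", grid$ds, grid$dr),
               sprintf("POINT_DATA %d", n1 * n2)), con)
  wfield <- function(name, M) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(t(M)), digits = 9), con)
  }
  wfield("pressure", state$p)
  wfield("phi", state$phi)
  wfield("u_streamwise", uc_s)
  wfield("u_wallnormal", uc_n)
  invisible(path)
}

#' Write a particle snapshot as CSV
#'
#' @param particles A [make_particles()] set (with cached closure columns).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_particles_csv <- function(particles, path) {
  utils::write.csv(as.data.frame(particles), path, row.names = FALSE)
  invisible(path)
}

#' Write the metrics stream of a run as CSV
#'
#' @param run An [run_coupled()] result.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_metrics_csv <- function(run, path) {
  spec <- run$case$spec
  m <- run$metrics
  pr <- pries_reference(spec$D * 1e6, spec$Ht_c)
  m$Ht_d <- cumsum(m$Q_RBCs) / cumsum(m$Q_blood)
  m$mu_rel <- plasma_flux(spec) / (cumsum(m$Q_blood) / seq_len(nrow(m)))
  m$Ht_d_pries <- pr$Ht_d_ref
  m$mu_rel_pries <- pr$mu_rel_ref
  m$err_Htd_pct <- ifelse(pr$Ht_d_ref > 0, 100 * abs(m$Ht_d - pr$Ht_d_ref) / pr$Ht_d_ref, NA)
  m$err_murel_pct <- 100 * abs(m$mu_rel - pr$mu_rel_ref) / pr$mu_rel_ref
  if (nrow(run$particles) > 0) {
    prof <- hematocrit_profile(run$particles, spec)
    m$S_H <- tryCatch(skewness_index(prof$w, prof$Ht), error = function(e) NA_real_)
  }
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read a case configuration file (YAML)
#'
#' Maps a plain-text configuration onto [channel_spec()] and [case_setup()].
#' Recognised top-level blocks: `channel` (R_c, L, Re, Ht_c, rho, mu,
#' topology, depth), `particles` (d_p, rho_p), `contact` (E_eff, poisson,
#' restitution, friction), `numerics` (resolution, Co, n_coupling, phi_min),
#' `seed`.
#'
#' @param path Path to the YAML file.
#' @return An [case_setup()] object.
#' @export
read_case_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ch <- cfg$channel
  spec <- channel_spec(R_c = ch$R_c, L = ch$L, Re = ch$Re,
                       Ht_c = if (is.null(ch$Ht_c)) 0 else ch$Ht_c,
                       rho = if (is.null(ch$rho)) 1000 else ch$rho,
                       mu = if (is.null(ch$mu)) 1.2e-3 else ch$mu,
                       topology = if (is.null(ch$topology)) "axisymmetric" else ch$topology,
                       depth = ch$depth)
  cp <- do.call(contact_params, if (is.null(cfg$contact)) list() else cfg$contact)
  nm <- cfg$numerics
  case_setup(spec,
             d_p = if (is.null(cfg$particles$d_p)) 5.6e-6 else cfg$particles$d_p,
             rho_p = if (is.null(cfg$particles$rho_p)) 1100 else cfg$particles$rho_p,
             contact = cp,
             resolution = if (is.null(nm$resolution)) c(16L, 32L) else as.integer(nm$resolution),
             seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
             n_coupling = if (is.null(nm$n_coupling)) "auto" else nm$n_coupling,
             Co = if (is.null(nm$Co)) 0.15 else nm$Co,
             phi_min = if (is.null(nm$phi_min)) 0.3 else nm$phi_min)
}

#' Write the resolved run manifest (YAML)
#'
#' @param run An [run_coupled()] result.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(run, path) {
  yaml::write_yaml(run$manifest, path)
  invisible(path)
}
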