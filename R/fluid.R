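# Volume-fraction incompressible Navier-Stokes solver on the staggered grid:
# implicit viscous/exchange momentum step + PISO-style double pressure
# correction enforcing the phi-continuity equation. Sparse patterns are
# assembled once per state and only their values are refreshed each step.

#' Initialise a fluid state on a grid
#'
#' @param grid An [build_grid()] grid.
#' @param spec The [channel_spec()] the grid was built from.
#' @param init `"poiseuille"` starts from the analytic clean-channel profile,
#'   `"rest"` from zero velocity.
#' @return An object of class `fluid_state` holding staggered velocities
#'   `u_s` (streamwise, on streamwise faces), `u_n` (wall-normal, on interior
#'   wall-normal faces), cell pressures `p`, cell fluid fraction `phi`, and
#'   the fluid constants.
#' @export
fluid_state <- function(grid, spec, init = c("poiseuille", "rest")) {
  init <- match.arg(init)
  n1 <- grid$n1; n2 <- grid$n2
  u_s <- matrix(0, n1, n2)
  if (init == "poiseuille") {
    prof <- spec$U_max * (1 - (grid$rn_c / spec$R_c)^2)
    u_s <- matrix(prof, n1, n2)
    u_s[us_mask(grid)] <- 0
  }
  structure(list(u_s = u_s, u_n = matrix(0, max(n1 - 1L, 0L), n2),
                 p = matrix(0, n1, n2), phi = matrix(1, n1, n2),
                 rho = spec$rho, mu = spec$mu, G = spec$G,
                 cache = new.env(parent = emptyenv())),
            class = "fluid_state")
}

# Face masks: a staggered velocity is blanked when either adjacent cell is solid.
us_mask <- function(grid) grid$solid | grid$solid[, c(2:grid$n2, 1L), drop = FALSE]
un_mask <- function(grid) {
  n1 <- grid$n1
  grid$solid[-n1, , drop = FALSE] | grid$solid[-1L, , drop = FALSE]
}

# value at streamwise neighbour k+1 (or k-1) with periodic wrap
shift_s <- function(M, by) {
  n2 <- ncol(M)
  if (by == 1L) M[, c(2:n2, 1L), drop = FALSE] else M[, c(n2, 1:(n2 - 1L)), drop = FALSE]
}

# Sparse matrix with a cached pattern: the (i, j) structure is built once,
# subsequent calls only refresh the numeric values (duplicates accumulated).
cached_sparse <- function(cache, key, ti, tj, tx, nunk) {
  pat <- cache[[key]]
  if (is.null(pat)) {
    lin <- (tj - 1) * nunk + ti
    ukey <- sort(unique(lin))
    slot <- match(lin, ukey)
    A <- Matrix::sparseMatrix(i = ti, j = tj, x = seq_along(ti),
                              dims = c(nunk, nunk))
    stopifnot(length(A@x) == length(ukey))
    pat <- list(A = A, slot = slot)
    cache[[key]] <- pat
  }
  xs <- rowsum(tx, pat$slot, reorder = TRUE)[, 1L]
  A <- pat$A
  A@x <- xs
  A
}

# Static assembly geometry (index vectors, masks, multipliers); built once.
assembly_geometry <- function(grid) {
  n1 <- grid$n1; n2 <- grid$n2
  axi <- grid$topology == "axisymmetric"
  idx <- function(i, k) i + (k - 1L) * n1
  ii <- rep(seq_len(n1), n2); kk <- rep(seq_len(n2), each = n1)
  m <- idx(ii, kk)
  kp <- ifelse(kk == n2, 1L, kk + 1L); km <- ifelse(kk == 1L, n2, kk - 1L)
  mskv <- as.vector(us_mask(grid))
  nb_s_hi <- idx(ii, kp); nb_s_lo <- idx(ii, km)
  ok_s_hi <- as.numeric(!mskv[nb_s_hi]); ok_s_lo <- as.numeric(!mskv[nb_s_lo])
  nb_hi <- idx(pmin(ii + 1L, n1), kk); nb_lo <- idx(pmax(ii - 1L, 1L), kk)
  hi_int <- ii < n1
  hi_wall <- !hi_int | mskv[nb_hi]
  fhi <- ifelse(hi_wall, 2, 1)
  ohi <- as.numeric(hi_int & !hi_wall)
  lo_int <- ii > 1L
  lo_wall <- (if (axi) rep(FALSE, length(m)) else !lo_int) | (lo_int & mskv[nb_lo])
  flo <- ifelse(lo_wall, 2, ifelse(lo_int, 1, 0))
  olo <- as.numeric(lo_int & !lo_wall)
  keep <- as.numeric(!mskv)
  us <- list(m = m, ii = ii, nb_s_hi = nb_s_hi, nb_s_lo = nb_s_lo,
             nb_hi = nb_hi, nb_lo = nb_lo, ok_s_hi = ok_s_hi,
             ok_s_lo = ok_s_lo, fhi = fhi, flo = flo, ohi = ohi, olo = olo,
             keep = keep, mskv = mskv,
             As = grid$A_sf[ii], Ah = grid$A_nf[ii + 1L], Al = grid$A_nf[ii],
             Vv = grid$V_cell[cbind(ii, 1L)])
  un <- NULL
  if (n1 > 1L) {
    nf <- n1 - 1L
    idn <- function(i, k) i + (k - 1L) * nf
    iin <- rep(seq_len(nf), n2); kkn <- rep(seq_len(n2), each = nf)
    mn <- idn(iin, kkn)
    mskn <- as.vector(un_mask(grid))
    kpn <- ifelse(kkn == n2, 1L, kkn + 1L); kmn <- ifelse(kkn == 1L, n2, kkn - 1L)
    nbs_hi <- idn(iin, kpn); nbs_lo <- idn(iin, kmn)
    oks_hi <- as.numeric(!mskn[nbs_hi]); oks_lo <- as.numeric(!mskn[nbs_lo])
    hi_nb <- idn(pmin(iin + 1L, nf), kkn); lo_nb <- idn(pmax(iin - 1L, 1L), kkn)
    dr <- grid$dr
    if (axi) {
      rcn <- grid$rn_c
      c_hi <- ifelse(iin < nf, grid$rn_f[iin + 2L] / (rcn[iin + 1L] * dr^2), 0)
      c_lo <- ifelse(iin > 1L, grid$rn_f[iin] / (rcn[iin] * dr^2), 0)
      c_dg <- grid$rn_f[iin + 1L] * (1 / rcn[iin + 1L] + 1 / rcn[iin]) / dr^2
      Vfn <- (pi * (grid$rn_c[2:n1]^2 - grid$rn_c[1:nf]^2) * grid$ds)[iin]
      A_sfn <- (2 * pi * grid$rn_f[2:n1] * dr)[iin]
    } else {
      c_hi <- rep(1 / dr^2, length(mn)); c_lo <- c_hi; c_dg <- rep(2 / dr^2, length(mn))
      Vfn <- rep(dr * grid$ds * grid$depth, length(mn))
      A_sfn <- rep(dr * grid$depth, length(mn))
    }
    o_hi <- as.numeric(iin < nf & !mskn[hi_nb])
    o_lo <- as.numeric(iin > 1L & !mskn[lo_nb])
    un <- list(nf = nf, mn = mn, iin = iin, nbs_hi = nbs_hi, nbs_lo = nbs_lo,
               oks_hi = oks_hi, oks_lo = oks_lo, hi_nb = hi_nb, lo_nb = lo_nb,
               c_hi = c_hi, c_lo = c_lo, c_dg = c_dg, o_hi = o_hi, o_lo = o_lo,
               keep = as.numeric(!mskn), mskn = mskn, Vfn = Vfn, A_sfn = A_sfn)
  }
  # pressure pattern: s faces (m)-(nb_s_hi) and n faces (low)-(high)
  pp <- list(mP = m, hiP = nb_s_hi)
  if (n1 > 1L) {
    iiN <- rep(seq_len(n1 - 1L), n2); kkN <- rep(seq_len(n2), each = n1 - 1L)
    pp$lowC <- idx(iiN, kkN); pp$highC <- idx(iiN + 1L, kkN)
  }
  pp$fluidc <- !as.vector(grid$solid)
  pp$pin <- which(pp$fluidc)[1L]
  list(us = us, un = un, pp = pp)
}

# First-order upwind advection term for the streamwise momentum CV,
# returned as (volume-integrated) rho * div(phi u u) per u_s unknown.
advect_us <- function(state, grid) {
  n1 <- grid$n1; n2 <- grid$n2
  u_s <- state$u_s; u_n <- state$u_n; phi <- state$phi; rho <- state$rho
  ubar <- 0.5 * (u_s + shift_s(u_s, -1L))
  mflx <- rho * phi * ubar * grid$A_sf           # n1 x n2, at cell centres
  uup <- ifelse(mflx >= 0, shift_s(u_s, -1L), u_s)
  Fs <- mflx * uup
  adv <- shift_s(Fs, 1L) - Fs
  if (n1 > 1L) {
    unbar <- 0.5 * (u_n + shift_s(u_n, 1L))      # (n1-1) x n2, at corners
    phic <- 0.25 * (phi[-n1, ] + phi[-1L, ] +
                    shift_s(phi, 1L)[-n1, ] + shift_s(phi, 1L)[-1L, ])
    mfn <- rho * phic * unbar * grid$A_nf[2:n1]
    uupn <- ifelse(mfn >= 0, u_s[-n1, , drop = FALSE], u_s[-1L, , drop = FALSE])
    Fn <- mfn * uupn
    adv <- adv + rbind(Fn, 0) - rbind(0, Fn)
  }
  adv
}

#' Advance the fluid by one time step (PISO)
#'
#' One implicit momentum predictor (transient, viscous and the implicit part
#' `K u` of the momentum exchange on the matrix; pressure gradient, body
#' force, explicit exchange `K <u_p>` and upwind advection on the right-hand
#' side) followed by two pressure-correction passes enforcing the discrete
#' volume-fraction continuity equation.
#'
#' @param state A [fluid_state()].
#' @param grid The grid.
#' @param cpl Optional coupling field from [assemble_Rpf()] (`NULL` for a
#'   particle-free fluid).
#' @param dt Time step \[s\]; must satisfy the Courant condition.
#' @param phi_old Cell fluid fraction at the previous step (defaults to the
#'   current `state$phi`, i.e. a frozen fraction field).
#' @return The updated `fluid_state`, with a `diagnostics` attribute holding
#'   the continuity residual, the Courant number, and the momentum exchanged
#'   with the particle phase during the step.
#' @export
advance_fluid <- function(state, grid, cpl = NULL, dt, phi_old = state$phi) {
  n1 <- grid$n1; n2 <- grid$n2
  rho <- state$rho; mu <- state$mu; G <- state$G
  dr <- grid$dr; ds <- grid$ds
  phi <- state$phi
  Co <- (max(abs(state$u_s)) / ds +
         (if (length(state$u_n)) max(abs(state$u_n)) else 0) / dr) * dt
  if (!is.finite(Co) || Co >= 1)
    stop(sprintf("Courant violation: Co = %.3f >= 1 for dt = %.3e", Co, dt))
  K <- if (is.null(cpl)) matrix(0, n1, n2) else cpl$K
  up_s <- if (is.null(cpl)) matrix(0, n1, n2) else cpl$up_s
  up_n <- if (is.null(cpl)) matrix(0, n1, n2) else cpl$up_n
  cache <- state$cache
  if (is.null(cache$geo)) cache$geo <- assembly_geometry(grid)
  gus <- cache$geo$us; gun <- cache$geo$un; gpp <- cache$geo$pp

  ## ---- streamwise momentum ------------------------------------------------
  phif <- 0.5 * (phi + shift_s(phi, 1L))
  phif_old <- 0.5 * (phi_old + shift_s(phi_old, 1L))
  Kf <- 0.5 * (K + shift_s(K, 1L))
  upf <- 0.5 * (up_s + shift_s(up_s, 1L))
  phv <- as.vector(phif)
  cs <- phv * mu * gus$As / ds
  crh <- phv * mu * gus$Ah / dr
  crl <- phv * mu * gus$Al / dr
  diag0 <- (rho * phv / dt + as.vector(Kf)) * gus$Vv
  kp <- gus$keep
  tx <- c(ifelse(gus$mskv, 1, diag0),
          cs * kp, cs * kp, crh * gus$fhi * kp, crl * gus$flo * kp,
          -cs * gus$ok_s_hi * kp, -cs * gus$ok_s_lo * kp,
          -crh * gus$ohi * kp, -crl * gus$olo * kp)
  if (is.null(cache$ti_s)) {
    m <- gus$m
    cache$ti_s <- rep(m, 9L)
    cache$tj_s <- c(m, m, m, m, m, gus$nb_s_hi, gus$nb_s_lo, gus$nb_hi, gus$nb_lo)
  }
  A <- cached_sparse(cache, "A_s", cache$ti_s, cache$tj_s, tx, n1 * n2)
  dps <- (shift_s(state$p, 1L) - state$p) / ds
  rhs <- (rho * as.vector(phif_old) * as.vector(state$u_s) / dt +
          phv * (G - as.vector(dps)) +
          as.vector(Kf) * as.vector(upf)) * gus$Vv -
    as.vector(advect_us(state, grid))
  rhs[gus$mskv] <- 0
  # pressure-correction response coefficient: transient + exchange part of
  # the diagonal (the viscous part would over-relax the pressure update)
  a_v_s <- rho * phif / dt + Kf
  u_s <- matrix(as.numeric(Matrix::solve(A, rhs)), n1, n2)

  ## ---- wall-normal momentum ----------------------------------------------
  if (n1 > 1L) {
    nf <- gun$nf
    phifn <- 0.5 * (phi[-n1, , drop = FALSE] + phi[-1L, , drop = FALSE])
    phifn_old <- 0.5 * (phi_old[-n1, , drop = FALSE] + phi_old[-1L, , drop = FALSE])
    Kfn <- 0.5 * (K[-n1, , drop = FALSE] + K[-1L, , drop = FALSE])
    upfn <- 0.5 * (up_n[-n1, , drop = FALSE] + up_n[-1L, , drop = FALSE])
    phvn <- as.vector(phifn)
    csn <- phvn * mu * gun$A_sfn / ds
    diagn <- (rho * phvn / dt + as.vector(Kfn)) * gun$Vfn
    cscale <- phvn * mu * gun$Vfn
    kpn <- gun$keep
    txn <- c(ifelse(gun$mskn, 1, diagn),
             csn * kpn, csn * kpn, cscale * gun$c_dg * kpn,
             -csn * gun$oks_hi * kpn, -csn * gun$oks_lo * kpn,
             -cscale * gun$c_hi * gun$o_hi * kpn,
             -cscale * gun$c_lo * gun$o_lo * kpn)
    if (is.null(cache$ti_n)) {
      mn <- gun$mn
      cache$ti_n <- rep(mn, 8L)
      cache$tj_n <- c(mn, mn, mn, mn, gun$nbs_hi, gun$nbs_lo, gun$hi_nb, gun$lo_nb)
    }
    An <- cached_sparse(cache, "A_n", cache$ti_n, cache$tj_n, txn, nf * n2)
    dpn <- (state$p[-1L, , drop = FALSE] - state$p[-n1, , drop = FALSE]) / dr
    rhsn <- (rho * as.vector(phifn_old) * as.vector(state$u_n) / dt +
             phvn * (-as.vector(dpn)) +
             as.vector(Kfn) * as.vector(upfn)) * gun$Vfn
    rhsn[gun$mskn] <- 0
    a_v_n <- rho * phifn / dt + Kfn
    u_n <- matrix(as.numeric(Matrix::solve(An, rhsn)), nf, n2)
  } else {
    u_n <- state$u_n; a_v_n <- matrix(1, 0L, n2)
    phifn <- matrix(0, 0L, n2)
  }

  ## ---- pressure correction (two PISO passes) ------------------------------
  dphidt <- (phi - phi_old) / dt
  p <- state$p
  cS <- phif^2 * matrix(grid$A_sf, n1, n2) / (a_v_s * ds)
  cS[us_mask(grid)] <- 0
  if (n1 > 1L) {
    cN <- phifn^2 * matrix(grid$A_nf[2:n1], n1 - 1L, n2) / (a_v_n * dr)
    cN[un_mask(grid)] <- 0
  } else cN <- matrix(0, 0L, n2)
  cSv <- as.vector(cS)
  reg <- mean(cSv[cSv > 0])
  dreg <- numeric(n1 * n2); dreg[gpp$pin] <- reg; dreg[!gpp$fluidc] <- 1
  if (n1 > 1L) {
    cNv <- as.vector(cN)
    txP <- c(cSv, cSv, -cSv, -cSv, cNv, cNv, -cNv, -cNv, dreg)
    if (is.null(cache$ti_P)) {
      cache$ti_P <- c(gpp$mP, gpp$hiP, gpp$mP, gpp$hiP,
                      gpp$lowC, gpp$highC, gpp$lowC, gpp$highC, seq_len(n1 * n2))
      cache$tj_P <- c(gpp$mP, gpp$hiP, gpp$hiP, gpp$mP,
                      gpp$lowC, gpp$highC, gpp$highC, gpp$lowC, seq_len(n1 * n2))
    }
  } else {
    txP <- c(cSv, cSv, -cSv, -cSv, dreg)
    if (is.null(cache$ti_P)) {
      cache$ti_P <- c(gpp$mP, gpp$hiP, gpp$mP, gpp$hiP, seq_len(n1 * n2))
      cache$tj_P <- c(gpp$mP, gpp$hiP, gpp$hiP, gpp$mP, seq_len(n1 * n2))
    }
  }
  AP <- cached_sparse(cache, "A_P", cache$ti_P, cache$tj_P, txP, n1 * n2)
  ch <- cache$chol
  if (is.null(ch)) {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(AP), LDL = FALSE, perm = TRUE)
  } else {
    ch <- Matrix::update(ch, Matrix::forceSymmetric(AP))
  }
  cache$chol <- ch
  msk_s <- us_mask(grid); msk_n <- un_mask(grid)
  div_phi_u <- function(u_s, u_n) {
    fs <- phif * u_s * matrix(grid$A_sf, n1, n2)
    out <- fs - shift_s(fs, -1L)
    if (n1 > 1L) {
      fn <- phifn * u_n * matrix(grid$A_nf[2:n1], n1 - 1L, n2)
      out <- out + rbind(fn, 0) - rbind(0, fn)
    }
    out
  }
  fluidc <- gpp$fluidc
  for (pass in 1:2) {
    rhsP <- -(as.vector(div_phi_u(u_s, u_n)) + as.vector(dphidt * grid$V_cell))
    rhsP[!fluidc] <- 0
    rhsP[fluidc] <- rhsP[fluidc] - mean(rhsP[fluidc])
    pc <- matrix(as.numeric(Matrix::solve(ch, rhsP)), n1, n2)
    u_s <- u_s - phif / (a_v_s * ds) * (shift_s(pc, 1L) - pc)
    u_s[msk_s] <- 0
    if (n1 > 1L) {
      u_n <- u_n - phifn / (a_v_n * dr) * (pc[-1L, , drop = FALSE] - pc[-n1, , drop = FALSE])
      u_n[msk_n] <- 0
    }
    p <- p + pc
  }
  div_final <- div_phi_u(u_s, u_n) + dphidt * grid$V_cell
  flux_scale <- max(sum(abs(phif * u_s * matrix(grid$A_sf, n1, n2))), .Machine$double.eps)
  resid <- max(abs(div_final[!grid$solid])) / flux_scale * n1 * n2
  if (!is.finite(resid) || resid > 1e-5)
    stop(sprintf("pressure solve failed: relative continuity residual %.3e", resid))

  ## ---- exchange diagnostics ----------------------------------------------
  ucell_s <- 0.5 * (u_s + shift_s(u_s, -1L))
  ucell_n <- if (n1 > 1L) 0.5 * (rbind(u_n, 0) + rbind(0, u_n)) else matrix(0, n1, n2)
  ex_s <- K * (ucell_s - up_s) * grid$V_cell
  ex_n <- K * (ucell_n - up_n) * grid$V_cell
  diagnostics <- list(courant = Co, continuity_residual = resid,
                      exchange_s = sum(ex_s), exchange_n = sum(ex_n),
                      exchange_mag = sum(sqrt(ex_s^2 + ex_n^2)))
  state$u_s <- u_s; state$u_n <- u_n; state$p <- p
  attr(state, "diagnostics") <- diagnostics
  state
}

#' Volumetric fluid flux through a cross-section plane
#'
#' Flux of the fluid phase `sum(phi_f u_s A)` through the streamwise face
#' plane `k_plane`.
#'
#' @param state A [fluid_state()].
#' @param grid The grid.
#' @param k_plane Index of the streamwise face plane (1..n2).
#' @return Flux \[m^3/s\].
#' @export
fluid_flux <- function(state, grid, k_plane) {
  phif <- 0.5 * (state$phi[, k_plane] +
                 state$phi[, if (k_plane == grid$n2) 1L else k_plane + 1L])
  sum(phif * state$u_s[, k_plane] * grid$A_sf)
}

#' Bulk (cross-section average) streamwise velocity
#'
#' @param state A [fluid_state()].
#' @param grid The grid.
#' @return Area-averaged streamwise fluid velocity \[m/s\].
#' @export
bulk_velocity <- function(state, grid) {
  open <- !us_mask(grid)
  sum((state$u_s * matrix(grid$A_sf, grid$n1, grid$n2))[open]) /
    sum(matrix(grid$A_sf, grid$n1, grid$n2)[open])
}
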