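# Macroscopic observables: flux-based discharge hematocrit and relative
# apparent viscosity, the Pries empirical reference correlations, percentage
# errors, hematocrit skewness and deformation-index statistics.

#' Discharge hematocrit from a flux-sample window
#'
#' `Ht_d = mean(Q_RBCs) / mean(Q_blood)` over the window: the ratio of the
#' RBC volumetric flux to the whole-suspension flux through a cross-section.
#'
#' @param samples data.frame with columns `Q_blood`, `Q_RBCs` (one steady
#'   window of samples).
#' @return Discharge hematocrit (dimensionless).
#' @export
discharge_hematocrit <- function(samples) {
  qb <- mean(samples$Q_blood)
  if (!is.finite(qb) || qb <= 0) stop("discharge_hematocrit: non-positive blood flux")
  mean(samples$Q_RBCs) / qb
}

#' Relative apparent viscosity from a flux-sample window
#'
#' Ratio of the theoretical pure-plasma flux at the case's driving conditions
#' to the measured suspension flux.
#'
#' @param samples data.frame with a `Q_blood` column.
#' @param spec The [channel_spec()] that drove the run.
#' @return Relative apparent viscosity (>= 0).
#' @export
relative_viscosity <- function(samples, spec) {
  qb <- mean(samples$Q_blood)
  if (!is.finite(qb) || qb <= 0) stop("relative_viscosity: non-positive blood flux")
  plasma_flux(spec) / qb
}

#' Pries empirical reference correlations
#'
#' In-vitro fits of discharge hematocrit and relative apparent viscosity for
#' blood flowing in tubes, as functions of tube diameter `D` (micrometres)
#' and channel hematocrit:
#' \deqn{X = 1 + 1.7 e^{-0.35 D} - 0.6 e^{-0.01 D}}
#' \deqn{Ht_d = -\frac{X}{2-2X} + \left[\left(\frac{X}{2-2X}\right)^2 +
#'   \frac{Ht_c}{1-X}\right]^{0.5}}
#' \deqn{\mu_{rel} = 1 + (\mu_{rel,0.45} - 1)\frac{(1-Ht_d)^C - 1}{(1-0.45)^C - 1}}
#' with `mu_rel_045` and `C` the printed diameter-dependent coefficients.
#'
#' @param D_um Tube diameter in micrometres.
#' @param Ht_c Channel hematocrit in `[0, 0.6]`.
#' @return List with `D`, `Ht_c`, `X`, `Ht_d_ref`, `mu_rel_045`, `C`,
#'   `mu_rel_ref`.
#' @export
pries_reference <- function(D_um, Ht_c) {
  stopifnot(D_um > 0, Ht_c >= 0, Ht_c <= 0.6)
  D <- D_um
  X <- 1 + 1.7 * exp(-0.35 * D) - 0.6 * exp(-0.01 * D)
  Ht_d <- if (Ht_c == 0) 0 else
    -X / (2 - 2 * X) + sqrt((X / (2 - 2 * X))^2 + Ht_c / (1 - X))
  mu45 <- 3.2 + 220 * exp(-1.3 * D) - 2.44 * exp(-0.06 * D^0.645)
  C <- (0.8 + exp(-0.075 * D)) * (-1 + 1 / (1 + 1e-11 * D^12)) +
    1 / (1 + 1e-11 * D^12)
  mu_rel <- 1 + (mu45 - 1) * ((1 - Ht_d)^C - 1) / ((1 - 0.45)^C - 1)
  list(D = D, Ht_c = Ht_c, X = X, Ht_d_ref = Ht_d, mu_rel_045 = mu45, C = C,
       mu_rel_ref = mu_rel)
}

#' Percentage error against a reference value
#'
#' `100 |x_sim - x_ref| / x_ref`.
#'
#' @param x_sim Simulated value.
#' @param x_pries Reference (non-zero).
#' @return Percentage error (>= 0).
#' @export
percentage_error <- function(x_sim, x_pries) {
  if (any(x_pries == 0)) stop("percentage_error: reference value is zero")
  100 * abs(x_sim - x_pries) / abs(x_pries)
}

#' Hematocrit skewness index of a profile
#'
#' \deqn{S_H = \left|\frac{\int_0^{0.5} Ht(w) dw}{\int_{-0.5}^{0.5} Ht(w) dw}
#'   - 0.5\right|}
#' by trapezoidal quadrature on the sampled profile; `w` is the normalised
#' coordinate along the cut.
#'
#' @param w Normalised coordinates covering `[-0.5, 0.5]`.
#' @param Ht Local hematocrit samples (>= 0).
#' @return Skewness index in `[0, 0.5]`.
#' @export
skewness_index <- function(w, Ht) {
  stopifnot(length(w) == length(Ht), all(Ht >= 0))
  o <- order(w); w <- w[o]; Ht <- Ht[o]
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  total <- trapz(w, Ht)
  if (total <= 0) stop("skewness_index: profile integrates to zero")
  # restrict to w >= 0 with an interpolated node at w = 0 if needed
  if (!any(w == 0)) {
    wpos <- c(0, w[w > 0])
    Hpos <- c(stats::approx(w, Ht, xout = 0)$y, Ht[w > 0])
  } else {
    wpos <- w[w >= 0]; Hpos <- Ht[w >= 0]
  }
  abs(trapz(wpos, Hpos) / total - 0.5)
}

#' Hematocrit profile across the channel
#'
#' Bins particle volume across the wall-normal coordinate to produce the
#' local hematocrit profile `Ht(w)` on the normalised coordinate
#' `w in [-0.5, 0.5]` used by [skewness_index()].
#'
#' @param particles A [make_particles()] set.
#' @param spec The [channel_spec()].
#' @param n_bins Number of bins across the cut.
#' @return data.frame with `w` (bin centres) and `Ht`.
#' @export
hematocrit_profile <- function(particles, spec, n_bins = 20L) {
  V_p <- attr(particles, "V_p")
  if (spec$topology == "axisymmetric") {
    # symmetric cut through the axis: w = r/D in [-0.5, 0.5] using x-side sign
    w_par <- particles$x / (2 * spec$R_c)
  } else {
    w_par <- particles$y / (2 * spec$R_c)
  }
  edges <- seq(-0.5, 0.5, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(w_par, edges, rightmost.closed = TRUE), 1L), n_bins)
  vol <- tapply2(rep(V_p, length(idx)), idx, n_bins)
  # bin slab volumes for normalisation
  if (spec$topology == "axisymmetric") {
    slab <- abs(diff(edges)) * 2 * spec$R_c
    Vbin <- slab * spec$L * 2 * spec$R_c      # crude slab volume, uniform
  } else {
    Vbin <- abs(diff(edges)) * 2 * spec$R_c * spec$L * spec$depth
  }
  data.frame(w = (edges[-1] + edges[-(n_bins + 1L)]) / 2, Ht = vol / Vbin)
}

#' Deformation-index population statistics
#'
#' Population mean, fixed-bin histogram on `[0, 1)`, and the spatially
#' averaged deformation index per streamwise bin.
#'
#' @param particles A [make_particles()] set with cached `DI` values.
#' @param spec The [channel_spec()] (for the streamwise extent).
#' @param n_bins Histogram bins on `[0, 1)`.
#' @param n_stream Streamwise bins.
#' @return List with `mean`, `histogram` (data.frame `mid`, `count`),
#'   `profile` (data.frame `s`, `DI_mean`, `n`).
#' @export
di_statistics <- function(particles, spec, n_bins = 20L, n_stream = 16L) {
  di <- particles$DI
  if (nrow(particles) == 0L || all(is.na(di)))
    stop("di_statistics: no particles with evaluated deformation index")
  di <- di[!is.na(di)]
  edges <- seq(0, 1, length.out = n_bins + 1L)
  hidx <- pmin(pmax(findInterval(di, edges, rightmost.closed = TRUE), 1L), n_bins)
  hist_df <- data.frame(mid = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                        count = as.numeric(tapply2(rep(1, length(hidx)), hidx, n_bins)))
  s <- if (spec$topology == "axisymmetric") particles$z else particles$x
  s <- s[!is.na(particles$DI)] %% spec$L
  sed <- seq(0, spec$L, length.out = n_stream + 1L)
  sidx <- pmin(pmax(findInterval(s, sed, rightmost.closed = TRUE), 1L), n_stream)
  cnt <- tapply2(rep(1, length(sidx)), sidx, n_stream)
  tot <- tapply2(di, sidx, n_stream)
  prof <- data.frame(s = (sed[-1] + sed[-(n_stream + 1L)]) / 2,
                     DI_mean = ifelse(cnt > 0, tot / pmax(cnt, 1), NA_real_),
                     n = cnt)
  list(mean = mean(di), histogram = hist_df, profile = prof)
}

#' Steady-state detection over flux windows
#'
#' Splits the metrics stream into consecutive windows of `window_time` and
#' declares steadiness when the relative drift of both the discharge
#' hematocrit and the relative viscosity between the last two windows is
#' below `tol`.
#'
#' @param metrics data.frame with `t`, `Q_blood`, `Q_RBCs`.
#' @param spec The [channel_spec()].
#' @param window_time Window length \[s\].
#' @param tol Relative drift tolerance.
#' @return List with `steady` (logical), `windows` (data.frame per window).
#' @export
steady_state <- function(metrics, spec, window_time, tol = 0.01) {
  if (nrow(metrics) == 0L) return(list(steady = FALSE, windows = NULL))
  wid <- floor((metrics$t - metrics$t[1]) / window_time)
  full <- wid < max(wid) | (max(metrics$t) - metrics$t[1]) %% window_time == 0
  agg <- do.call(rbind, lapply(split(metrics, wid), function(d)
    data.frame(t_end = max(d$t), Ht_d = mean(d$Q_RBCs) / mean(d$Q_blood),
               mu_rel = plasma_flux(spec) / mean(d$Q_blood))))
  steady <- FALSE
  if (nrow(agg) >= 2L) {
    a <- agg[nrow(agg) - 1L, ]; b <- agg[nrow(agg), ]
    drift <- function(x, y) abs(y - x) / max(abs(x), 1e-12)
    dH <- if (abs(a$Ht_d) < 1e-9 && abs(b$Ht_d) < 1e-9) 0 else drift(a$Ht_d, b$Ht_d)
    steady <- dH < tol && drift(a$mu_rel, b$mu_rel) < tol
  }
  list(steady = steady, windows = agg)
}
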