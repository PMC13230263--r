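# Post-processing of oscillating per-period signals (drag coefficient,
# deformation index under tumbling / tank-treading): period detection from
# the autocorrelation and per-period averaging.

#' Detect the dominant period of a uniformly sampled signal
#'
#' Computes the unbiased normalised autocorrelation of the demeaned signal
#' and returns the lag of its first dominant local maximum beyond lag zero,
#' refined to sub-sample precision by parabolic interpolation. Fails cleanly
#' when no peak exceeds the significance threshold (aperiodic or constant
#' signals).
#'
#' @param t Sample times, uniformly spaced.
#' @param y Signal values (at least ~3 putative periods).
#' @param threshold Significance threshold on the normalised autocorrelation
#'   peak.
#' @return The period, in the units of `t`.
#' @export
detect_period <- function(t, y, threshold = 0.2) {
  n <- length(y)
  stopifnot(length(t) == n, n >= 8L)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * abs(dt[1]))
    stop("detect_period: sampling must be uniform")
  dt <- dt[1]
  y0 <- y - mean(y)
  v <- sum(y0^2) / n
  if (v <= .Machine$double.eps * max(abs(y), 1)^2)
    stop("detect_period: constant signal has no period")
  maxlag <- floor(n / 2)
  r <- vapply(seq_len(maxlag), function(k)
    sum(y0[1:(n - k)] * y0[(k + 1):n]) / ((n - k) * v), numeric(1))
  # significance is judged on the biased (tapered) estimate, which does not
  # inflate at large lags; the unbiased value locates the peak
  r_sig <- r * (n - seq_len(maxlag)) / n
  peaks <- which(r_sig > threshold &
                 r >= c(r[1] + 1, head(r, -1)) &
                 r >= c(tail(r, -1), -Inf))
  # skip any peak glued to lag zero (monotone decay start)
  peaks <- peaks[peaks > 1L]
  if (length(peaks) == 0L)
    stop("detect_period: no significant periodicity found")
  k <- peaks[1L]
  # parabolic refinement
  if (k > 1L && k < maxlag) {
    a <- r[k - 1L]; b <- r[k]; cc <- r[k + 1L]
    den <- a - 2 * b + cc
    k <- k + if (den < 0) 0.5 * (a - cc) / den else 0
  }
  k * dt
}

#' Per-period means of an oscillating signal
#'
#' Splits the trace into consecutive whole periods from its first sample,
#' discards the trailing partial period, and returns the mean over each whole
#' period plus the grand mean of those means. At least three whole periods
#' are required.
#'
#' @param t Sample times, uniformly spaced.
#' @param y Signal values.
#' @param period Period length (e.g. from [detect_period()]).
#' @return List with `period_means`, `grand_mean`, `n_periods`.
#' @export
period_average <- function(t, y, period) {
  stopifnot(length(t) == length(y), period > 0)
  rel <- t - t[1]
  k <- floor(rel / period)
  n_whole <- floor((rel[length(rel)] + (t[2] - t[1])) / period)
  if (n_whole < 3)
    stop("period_average: need at least three whole periods")
  keep <- k < n_whole
  means <- as.numeric(tapply(y[keep], k[keep], mean))
  list(period_means = means, grand_mean = mean(means), n_periods = n_whole)
}
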