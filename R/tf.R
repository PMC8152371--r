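#' Build a time-frequency analysis grid
#'
#' Frequencies are log-spaced and inclusive of both endpoints; the time grid
#' is arithmetic with step `tstep`, starting at `tmin`, with the last point
#' at or before `tmax` (documented rather than silently truncated).  The
#' defaults give 50 frequencies from 3 to 100 Hz and 66 time points from
#' -0.6 to 0.7 s in 20 ms steps.
#'
#' @param fmin,fmax Frequency range in Hz (`fmin > 0`).
#' @param n_freqs Number of log-spaced frequencies.
#' @param tmin,tmax Time range in seconds.
#' @param tstep Time step in seconds.
#' @param window_cycles Sliding-window length in oscillation cycles
#'   (window duration `window_cycles / f` seconds at frequency f).
#' @param smoothing Spectral half-bandwidth as a fraction of the analysis
#'   frequency (half-bandwidth `smoothing * f` Hz).
#' @return An object of class `tf_grid`.
#' @export
build_tf_grid <- function(fmin = 3, fmax = 100, n_freqs = 50,
                          tmin = -0.6, tmax = 0.7, tstep = 0.02,
                          window_cycles = 2, smoothing = 0.4) {
  if (fmin <= 0 || fmax <= fmin) stopf("need 0 < fmin < fmax")
  if (n_freqs < 1) stopf("`n_freqs` must be >= 1")
  if (tmin >= tmax) stopf("need tmin < tmax")
  if (tstep <= 0) stopf("`tstep` must be positive")
  freqs <- if (n_freqs == 1L) fmin
           else exp(seq(log(fmin), log(fmax), length.out = n_freqs))
  times <- tmin + tstep * (0:floor((tmax - tmin) / tstep + 1e-9))
  structure(list(freqs = freqs, times = times, window_cycles = window_cycles,
                 smoothing = smoothing),
            class = "tf_grid")
}

#' @export
print.tf_grid <- function(x, ...) {
  cat(sprintf("<tf_grid> %d freqs [%.3g, %.3g] Hz x %d times [%.3g, %.3g] s; %g cycles, smoothing %g*f\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              min(x$times), max(x$times), x$window_cycles, x$smoothing))
  invisible(x)
}

#' Number of multitapers per window
#'
#' With window duration `T = window_cycles / f` and half-bandwidth
#' `W = smoothing * f`, the taper count is `max(1, floor(2 T W - 1))`: the
#' time-bandwidth product is independent of frequency, and the default
#' parameters (`2 * 2 * 0.4 - 1 = 0.6 < 1`) fall back to a single prolate
#' taper rather than erroring.
#'
#' @param window_cycles Window length in cycles.
#' @param smoothing Relative spectral half-bandwidth.
#' @return Integer taper count.
#' @export
taper_count <- function(window_cycles, smoothing) {
  max(1L, as.integer(floor(2 * window_cycles * smoothing - 1 + 1e-9)))
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose top eigenvectors are the Slepian sequences, ordered by decreasing
#' spectral concentration.  Each taper is normalized to unit energy; the
#' leading taper is sign-fixed to have a positive sum.
#'
#' @param n Window length in samples.
#' @param nw Time-bandwidth product (window duration times half-bandwidth).
#' @param k Number of tapers.
#' @return An `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k = 1L) {
  if (n < 2) stopf("taper length must be >= 2 samples")
  if (k < 1 || k > n) stopf("invalid taper count %d", k)
  w <- nw / n
  i <- seq_len(n)
  dg <- ((n - 1 - 2 * (i - 1)) / 2)^2 * cos(2 * pi * w)
  od <- i[-n] * (n - i[-n]) / 2
  m <- diag(dg)
  m[cbind(i[-n], i[-n] + 1L)] <- od
  m[cbind(i[-n] + 1L, i[-n])] <- od
  ev <- eigen(m, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  h <- sweep(h, 2L, sqrt(colSums(h^2)), "/")
  for (j in seq_len(k)) {
    s <- sum(h[, j])
    if (s < 0 || (s == 0 && h[1, j] < 0)) h[, j] <- -h[, j]
  }
  h
}

#' Complex multitaper time-frequency transform of epoched data
#'
#' For each grid coordinate (f, t) a window of `window_cycles / f` seconds
#' is centered on the sample nearest to t; `taper_count()` Slepian tapers
#' with half-bandwidth `smoothing * f` weight the data, which is demodulated
#' at f (phase referenced to absolute time 0, so a planted
#' `cos(2 pi f t + phi)` yields phase `phi`).  The coefficient is the
#' taper-averaged transform.  Coordinates whose window overruns the epoch
#' are masked (`valid = FALSE`, coefficients `NA`), never zero-filled.
#'
#' @param epochs An `epoch_set`.
#' @param grid A `tf_grid`; all frequencies must be below the Nyquist
#'   frequency `sfreq / 2`.
#' @return An object of class `complex_tfr`: `coefficients` (complex array
#'   conditions x trials x sensors x freqs x times), `valid` (freqs x times
#'   logical), `grid`, `conditions`, `sfreq`.
#' @export
multitaper_tfr <- function(epochs, grid) {
  if (!inherits(epochs, "epoch_set")) stopf("`epochs` must be an epoch_set")
  if (!inherits(grid, "tf_grid")) stopf("`grid` must be a tf_grid")
  bad <- grid$freqs >= epochs$sfreq / 2
  if (any(bad))
    stopf("grid frequency %.4g Hz is at or above the Nyquist frequency %.4g Hz",
          min(grid$freqs[bad]), epochs$sfreq / 2)
  d <- dim(epochs$data)
  C <- d[1]; R <- d[2]; S <- d[3]; N <- d[4]
  M <- matrix(epochs$data, C * R * S, N)   # rows = (condition, trial, sensor)
  nf <- length(grid$freqs); nt <- length(grid$times)
  coef <- array(NA_complex_, dim = c(C, R, S, nf, nt))
  valid <- matrix(FALSE, nf, nt)
  nw <- grid$window_cycles * grid$smoothing
  K <- taper_count(grid$window_cycles, grid$smoothing)
  for (fi in seq_len(nf)) {
    f <- grid$freqs[fi]
    half <- floor(grid$window_cycles / f * epochs$sfreq / 2)
    len <- 2L * half + 1L
    if (len > N) next
    tapers <- dpss_tapers(len, nw, K)
    scale <- 2 / sum(tapers[, 1])   # |coef| ~ amplitude for a pure sinusoid
    for (ti in seq_len(nt)) {
      i0 <- which.min(abs(epochs$times - grid$times[ti]))
      if (abs(epochs$times[i0] - grid$times[ti]) > 0.5 / epochs$sfreq + 1e-12) next
      lo <- i0 - half; hi <- i0 + half
      if (lo < 1L || hi > N) next
      idx <- lo:hi
      phasor <- exp(-2i * pi * f * epochs$times[idx])
      w <- (tapers * phasor) %*% rep(1 / K, K)  # taper-averaged weight vector
      coef[, , , fi, ti] <- matrix(M[, idx, drop = FALSE] %*% (w * scale),
                                   nrow = C * R * S)
      valid[fi, ti] <- TRUE
    }
  }
  if (!any(valid))
    stopf("no (frequency, time) coordinate has a window inside the epoch")
  structure(list(coefficients = coef, valid = valid, grid = grid,
                 conditions = epochs$conditions, sfreq = epochs$sfreq),
            class = "complex_tfr")
}

#' @export
print.complex_tfr <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("<complex_tfr> %d cond x %d trials x %d sensors x %d freqs x %d times (%d/%d coords valid)\n",
              d[1], d[2], d[3], d[4], d[5], sum(x$valid), length(x$valid)))
  invisible(x)
}

new_pattern_set <- function(kind, values, valid, grid, conditions) {
  structure(list(kind = kind, values = values, valid = valid, grid = grid,
                 conditions = conditions),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pattern_set:%s> %d conditions x %d features x %d freqs x %d times\n",
              x$kind, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Condition power patterns from a complex TFR
#'
#' Per trial the power is `|coef|^2`, expressed in decibels as
#' `10 log10(power + db_floor)` and then averaged across trials (in that
#' order), yielding one S-dimensional pattern vector per condition at each
#' valid coordinate.  The floor avoids `-Inf` on silent synthetic channels.
#'
#' @param tfr A `complex_tfr`.
#' @param db_floor Additive floor in squared-amplitude units.
#' @return A `pattern_set` of kind `"power"` with values
#'   conditions x sensors x freqs x times.
#' @export
condition_power_patterns <- function(tfr, db_floor = 1e-20) {
  if (!inherits(tfr, "complex_tfr")) stopf("`tfr` must be a complex_tfr")
  db <- 10 * log10(Mod(tfr$coefficients)^2 + db_floor)
  d <- dim(db)
  vals <- array(NA_real_, d[-2])
  for (fi in seq_len(d[4])) for (ti in seq_len(d[5])) {
    if (!tfr$valid[fi, ti]) next
    vals[, , fi, ti] <- apply(db[, , , fi, ti, drop = FALSE], c(1, 3), mean)
  }
  new_pattern_set("power", vals, tfr$valid, tfr$grid, tfr$conditions)
}

#' Condition phase patterns from a complex TFR
#'
#' Per sensor and condition each trial coefficient is normalized to unit
#' length in the complex plane (trials with an exactly zero coefficient are
#' excluded from the resultant), the unit vectors are averaged across trials,
#' and the resultant is renormalized to unit length.  The pattern vector
#' concatenates the real parts for all sensors followed by the imaginary
#' parts, giving 2S features (612 for 306 sensors).  A coordinate where a
#' resultant has zero length (or all trials are zero) is flagged degenerate
#' and masked.
#'
#' @param tfr A `complex_tfr`.
#' @return A `pattern_set` of kind `"phase"` with values
#'   conditions x 2*sensors x freqs x times.  Each per-sensor (cos, sin)
#'   sub-pair has unit norm in the non-degenerate case.
#' @export
condition_phase_patterns <- function(tfr) {
  if (!inherits(tfr, "complex_tfr")) stopf("`tfr` must be a complex_tfr")
  d <- dim(tfr$coefficients)
  C <- d[1]; R <- d[2]; S <- d[3]
  vals <- array(NA_real_, c(C, 2L * S, d[4], d[5]))
  valid <- tfr$valid
  n_degen <- 0L
  for (fi in seq_len(d[4])) for (ti in seq_len(d[5])) {
    if (!valid[fi, ti]) next
    cf <- array(tfr$coefficients[, , , fi, ti], c(C, R, S))
    mag <- Mod(cf)
    unit <- cf / mag
    unit[mag == 0] <- NA_complex_          # excluded from the resultant
    res <- apply(unit, c(1, 3), function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_complex_)
      mean(v)
    })
    rmag <- Mod(res)
    if (any(!is.finite(rmag)) || any(rmag == 0)) {
      valid[fi, ti] <- FALSE
      n_degen <- n_degen + 1L
      next
    }
    u <- res / rmag
    vals[, , fi, ti] <- cbind(Re(u), Im(u))
  }
  if (n_degen)
    warnf("%d coordinate(s) had degenerate phase resultants and were masked", n_degen)
  new_pattern_set("phase", vals, valid, tfr$grid, tfr$conditions)
}
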