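new_timescale_estimate <- function(tau_samples, fs, method, curve = NULL,
                                   degenerate = FALSE) {
  structure(list(tau_samples = as.numeric(tau_samples),
                 seconds = as.numeric(tau_samples) / fs,
                 fs = fs, method = method, curve = curve,
                 degenerate = isTRUE(degenerate)),
            class = "timescale_estimate")
}

#' @export
print.timescale_estimate <- function(x, ...) {
  cat(sprintf("<timescale_estimate> %s: tau = %g samples = %.6g s (fs = %g Hz)%s\n",
              x$method, x$tau_samples, x$seconds, x$fs,
              if (x$degenerate) " [degenerate minimum]" else ""))
  invisible(x)
}

#' @export
coef.timescale_estimate <- function(object, ...) {
  c(tau_samples = object$tau_samples, seconds = object$seconds)
}

#' @export
plot.timescale_estimate <- function(x, ...) {
  if (is.null(x$curve)) stop("estimate carries no backing curve")
  if (inherits(x$curve, "pe_curve")) {
    plot(x$curve, ...)
  } else {
    plot(x$curve$lags, x$curve$r, type = "l", xlab = "lag (samples)",
         ylab = "autocorrelation", ...)
    abline(h = 0, lty = 3)
  }
  abline(v = x$tau_samples, col = "red", lty = 2)
  invisible(x)
}

# smallest tau attaining the global minimum (plateaus resolved to the left,
# equality within 1e-12)
argmin_tau <- function(taus, pe) {
  m <- min(pe)
  taus[which(pe <= m + 1e-12)[1L]]
}

#' PE-TD: timescale as the delay minimizing permutation entropy
#'
#' Computes the PE-vs-delay curve (see [pe_curve()]) and returns the
#' smallest delay attaining its global minimum, converted to seconds via
#' `seconds = tau / fs`.  The intuition: when the embedding delay matches
#' the signal's dominant timescale, successive windows sample the same
#' phases of the recurring motif, the ordinal-pattern distribution narrows,
#' and entropy dips.
#'
#' If the searched part of the curve is flat (all values equal within
#' 1e-12, e.g. a constant input) the estimate falls back to the smallest
#' searched delay and is flagged `degenerate = TRUE`, with a warning.
#'
#' `tau_min` restricts the search floor.  The published rule searches from
#' `tau_min = 1`; on noise-free, heavily oversampled model traces the
#' absolute minimum can degenerate to the smallest delays, where windows of
#' near-consecutive samples are trivially monotone — raising the floor
#' excludes that regime (see the methods vignette).  The backing curve is
#' always computed over the full `1:tau_max` range.
#'
#' @param x a `timeseries`, or numeric vector with `fs` supplied.
#' @param fs sampling rate in Hz (taken from `x` when it is a `timeseries`).
#' @param D embedding dimension; default 5.
#' @param tau_max largest delay searched, in samples; default 100.
#' @param tau_min smallest delay searched, in samples; default 1 (the
#'   published rule).
#' @return A `"timescale_estimate"` (method `"PE-TD"`) carrying the backing
#'   `pe_curve`.
#' @examples
#' x <- timeseries(sin(2 * pi * ((0:5000) %% 20) / 20), fs = 250)
#' pe_td(x, tau_max = 40)  # tau = 20 samples = 0.08 s
#' @export
pe_td <- function(x, fs = NULL, D = 5, tau_max = 100, tau_min = 1) {
  x <- as_timeseries(x, fs)
  if (tau_min < 1L || tau_min > tau_max)
    stop("'tau_min' must satisfy 1 <= tau_min <= tau_max")
  pc <- pe_curve(x, D = D, tau_max = tau_max)
  sel <- pc$taus >= tau_min
  degenerate <- (max(pc$pe[sel]) - min(pc$pe[sel])) <= 1e-12
  if (degenerate)
    warning("flat PE curve: degenerate minimum, returning smallest tau")
  tau <- if (degenerate) pc$taus[sel][1L]
         else argmin_tau(pc$taus[sel], pc$pe[sel])
  new_timescale_estimate(tau, x$fs, "PE-TD", curve = pc,
                         degenerate = degenerate)
}

#' Autocorrelation function (biased estimator)
#'
#' Sample autocorrelation \eqn{r_l = c_l / c_0} with the biased
#' autocovariance \eqn{c_l = N^{-1} \sum_t (x_t - \bar x)(x_{t+l} - \bar x)}
#' (the classical divide-by-N estimator, as computed by [stats::acf()]).
#'
#' @param x a `timeseries` or numeric vector.
#' @param max_lag largest lag, `1 <= max_lag < N`.
#' @return An object of class `"acf_result"`: `lags` (`0:max_lag`) and `r`.
#' @export
acf_biased <- function(x, max_lag) {
  v <- if (inherits(x, "timeseries")) x$values else as.numeric(x)
  n <- length(v)
  if (max_lag < 1L || max_lag >= n)
    stop("'max_lag' must satisfy 1 <= max_lag < N")
  if (stats::var(v) == 0)
    stop("constant series: autocorrelation undefined (zero variance)")
  r <- as.numeric(stats::acf(v, lag.max = max_lag, plot = FALSE,
                             demean = TRUE, type = "correlation")$acf)
  structure(list(lags = 0:max_lag, r = r), class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result> lags 0..%d; r[1] = %.4f\n",
              max(x$lags), x$r[2]))
  invisible(x)
}

#' ACW-0: first zero-crossing of the autocorrelation function
#'
#' The autocorrelation window at zero: the smallest lag `l >= 1` at which
#' `r[l] <= 0` (first touch or crossing of zero, integer lags, no
#' interpolation), converted to seconds via `seconds = l / fs`.
#'
#' @inheritParams pe_td
#' @param max_lag largest lag searched; default half the series length.
#' @return A `"timescale_estimate"` (method `"ACW-0"`) carrying the backing
#'   `acf_result`.
#' @examples
#' x <- timeseries(sin(2 * pi * (0:5000) / 40), fs = 250)
#' acw0(x)  # 10 samples: the quarter period
#' @export
acw0 <- function(x, fs = NULL, max_lag = NULL) {
  x <- as_timeseries(x, fs)
  n <- length(x$values)
  if (is.null(max_lag)) max_lag <- max(1L, n %/% 2L)
  ac <- acf_biased(x, max_lag)
  hit <- which(ac$r[-1L] <= 0)
  if (length(hit) == 0L)
    stop(sprintf("no zero-crossing of the ACF within lags 1..%d", max_lag))
  new_timescale_estimate(ac$lags[-1L][hit[1L]], x$fs, "ACW-0", curve = ac)
}

#' Sliding-window ACW-0
#'
#' ACW-0 computed in sliding windows (default 20 s with 50% overlap, i.e. a
#' 10 s step) and averaged: the per-window first zero-crossings, in samples,
#' are combined by their arithmetic mean.  The maximum ACF lag searched in
#' each window is half the window length.  Incomplete trailing windows are
#' dropped.
#'
#' @inheritParams pe_td
#' @param window_s window length in seconds; default 20.
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)`; default 0.5.
#' @return A `"timescale_estimate"` (method `"ACW-0"`); the `curve` slot
#'   holds the per-window crossings (`windows` element).
#' @export
windowed_acw0 <- function(x, fs = NULL, window_s = 20, overlap = 0.5) {
  x <- as_timeseries(x, fs)
  n <- length(x$values)
  wlen <- floor(window_s * x$fs)
  if (wlen < 4L) stop("window too short for the sampling rate")
  if (n < wlen)
    stop(sprintf("series (%d samples) shorter than one %g s window (%d samples)",
                 n, window_s, wlen))
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  step <- max(1L, floor(wlen * (1 - overlap)))
  starts <- seq(1L, n - wlen + 1L, by = step)
  taus <- vapply(starts, function(s) {
    seg <- timeseries(x$values[s:(s + wlen - 1L)], x$fs)
    acw0(seg, max_lag = wlen %/% 2L)$tau_samples
  }, numeric(1))
  est <- new_timescale_estimate(mean(taus), x$fs, "ACW-0")
  est$curve <- list(windows = taus, window_s = window_s, overlap = overlap)
  est
}
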