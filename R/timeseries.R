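#' Sampled time series
#'
#' Lightweight container for a real-valued, uniformly sampled signal: the
#' universal currency of the package.  `values` are in whatever unit the
#' source uses (mV for the integrate-and-fire membrane potential, arbitrary
#' units for the Mackey-Glass oscillator or EEG); `fs` is the sampling rate
#' in Hz.
#'
#' @param values numeric vector, all finite, length >= 1.
#' @param fs sampling rate in Hz, a single positive number.
#' @return An object of class `"timeseries"`: a list with elements `values`
#'   and `fs`.
#' @examples
#' x <- timeseries(sin(2 * pi * (0:999) / 20), fs = 250)
#' x
#' @export
timeseries <- function(values, fs) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("'values' must contain at least one sample")
  if (!all(is.finite(values)))
    stop("'values' must be finite (no NA/NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  structure(list(values = values, fs = as.numeric(fs)),
            class = "timeseries")
}

#' Coerce to a time series
#'
#' Numeric vectors are wrapped with the supplied sampling rate; existing
#' `timeseries` objects are returned unchanged (a supplied `fs` must agree).
#'
#' @param x a `timeseries` or numeric vector.
#' @param fs sampling rate in Hz; required when `x` is a bare vector.
#' @return A `timeseries` object.
#' @export
as_timeseries <- function(x, fs = NULL) {
  if (inherits(x, "timeseries")) {
    if (!is.null(fs) && abs(fs - x$fs) > 1e-9)
      stop("'fs' disagrees with the sampling rate carried by 'x'")
    return(x)
  }
  if (is.null(fs))
    stop("'fs' is required when 'x' is a plain numeric vector")
  timeseries(x, fs)
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries> %d samples @ %g Hz (%.4g s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.timeseries <- function(x) length(x$values)

#' Multichannel recording
#'
#' A set of equally sampled channels, stored as a channels-by-samples
#' matrix with channel labels.  Used by the channel-map and group-statistics
#' functions and by the CSV reader.
#'
#' @param values numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param labels optional character vector of channel labels (defaults to
#'   `ch1`, `ch2`, ...).
#' @return An object of class `"multichannel"`.
#' @export
multichannel <- function(values, fs, labels = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("channel values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(values)))
  if (length(labels) != nrow(values))
    stop("one label per channel required")
  rownames(values) <- labels
  structure(list(values = values, fs = as.numeric(fs),
                 labels = as.character(labels)),
            class = "multichannel")
}

#' @export
print.multichannel <- function(x, ...) {
  cat(sprintf("<multichannel> %d channels x %d samples @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

#' Extract one channel of a multichannel recording
#'
#' @param x a `multichannel` object.
#' @param channel channel label or index.
#' @return A `timeseries`.
#' @export
get_channel <- function(x, channel) {
  stopifnot(inherits(x, "multichannel"))
  timeseries(x$values[channel, ], x$fs)
}
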