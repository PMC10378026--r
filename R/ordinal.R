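#' Ordinal (rank) pattern of a window
#'
#' Returns the rank pattern of a length-`D` window: each entry is replaced
#' by its 0-based ascending rank.  Ties are broken by temporal order
#' (stable ranking — the earlier sample receives the lower rank), so a
#' constant window maps to the identity pattern `(0, 1, ..., D-1)`.
#'
#' @param window numeric vector of length >= 2, all finite.
#' @return Integer vector of 0-based ranks, a permutation of `0:(D-1)`.
#' @examples
#' ordinal_pattern(c(1.2, 3.4, 2.1))  # 0 2 1
#' ordinal_pattern(c(5, 5, 5))        # 0 1 2 (stable tie-break)
#' @export
ordinal_pattern <- function(window) {
  window <- as.numeric(window)
  if (length(window) < 2L) stop("a window needs at least 2 values")
  if (!all(is.finite(window))) stop("window values must be finite")
  as.integer(rank(window, ties.method = "first") - 1L)
}

#' Lexicographic index of a rank pattern
#'
#' Fixed bijection between rank patterns and `0:(D!-1)`: the Lehmer code of
#' the pattern read as a permutation, i.e. patterns sorted lexicographically
#' — `(0,1,...,D-1)` maps to 0 and `(D-1,...,1,0)` to `D!-1`.  This is the
#' indexing used by [symbolize()] and [pattern_distribution()].
#'
#' @param pattern integer vector: a permutation of `0:(D-1)`.
#' @return Single integer in `0:(factorial(D)-1)`.
#' @export
pattern_index <- function(pattern) {
  D <- length(pattern)
  if (!setequal(pattern, 0:(D - 1L)))
    stop("'pattern' must be a permutation of 0:(D-1)")
  idx <- 0L
  for (p in seq_len(D - 1L)) {
    smaller <- sum(pattern[(p + 1L):D] < pattern[p])
    idx <- idx + smaller * factorial(D - p)
  }
  as.integer(idx)
}

#' Rank pattern for a lexicographic index
#'
#' Inverse of [pattern_index()].
#'
#' @param idx integer in `0:(factorial(D)-1)`.
#' @param D embedding dimension.
#' @return Integer rank pattern of length `D`.
#' @export
index_to_pattern <- function(idx, D) {
  if (idx < 0 || idx >= factorial(D)) stop("'idx' out of range for D")
  remaining <- 0:(D - 1L)
  out <- integer(D)
  for (p in seq_len(D)) {
    f <- factorial(D - p)
    k <- idx %/% f
    idx <- idx %% f
    out[p] <- remaining[k + 1L]
    remaining <- remaining[-(k + 1L)]
  }
  out
}

check_embedding <- function(n, D, tau, what = "series") {
  if (!is.numeric(D) || D < 2L || D != round(D))
    stop("'D' must be an integer >= 2")
  if (D > 8L) stop("'D' larger than 8 is not supported")
  if (!is.numeric(tau) || tau < 1L || tau != round(tau))
    stop("'tau' must be an integer >= 1")
  need <- (D - 1L) * tau + 1L
  if (n < need)
    stop(sprintf("%s too short for (D = %d, tau = %d): need N >= %d, got %d",
                 what, D, tau, need, n))
  invisible(TRUE)
}

#' Ordinal symbolization of a time series
#'
#' Slides a window of `D` samples spaced `tau` apart along the series and
#' maps each window to the lexicographic index of its ordinal pattern
#' (stable tie-break; see [ordinal_pattern()] and [pattern_index()]).
#'
#' @param x a `timeseries` or numeric vector.
#' @param D embedding dimension (integer >= 2).
#' @param tau embedding delay in samples (integer >= 1).
#' @return Integer vector of `N - (D-1)*tau` pattern indices in
#'   `0:(factorial(D)-1)`.
#' @examples
#' symbolize(c(1, 2, 3, 4), D = 3, tau = 1)  # 0 0 : identity pattern twice
#' @export
symbolize <- function(x, D, tau) {
  x <- if (inherits(x, "timeseries")) x$values else as.numeric(x)
  if (!all(is.finite(x))) stop("series values must be finite")
  check_embedding(length(x), D, tau)
  symbolize_cpp(x, as.integer(D), as.integer(tau))
}

#' Ordinal pattern distribution
#'
#' Counts every one of the `D!` possible patterns (zeros included) in a
#' symbol sequence and normalizes to probabilities.
#'
#' @param symbols integer vector of pattern indices (from [symbolize()]).
#' @param D embedding dimension the symbols were produced with.
#' @return A list of class `"pattern_distribution"`: `counts` (length `D!`),
#'   `probs` (sums to 1), `n_symbols`, `D`.
#' @export
pattern_distribution <- function(symbols, D) {
  if (length(symbols) == 0L) stop("empty symbol sequence")
  nf <- factorial(D)
  if (any(symbols < 0L | symbols >= nf))
    stop("symbol indices out of range for D")
  counts <- tabulate(symbols + 1L, nbins = nf)
  structure(list(counts = counts, probs = counts / length(symbols),
                 n_symbols = length(symbols), D = as.integer(D)),
            class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("<pattern_distribution> D = %d, %d symbols, %d/%d patterns observed\n",
              x$D, x$n_symbols, sum(x$counts > 0), length(x$counts)))
  invisible(x)
}

#' Permutation entropy
#'
#' Shannon entropy, in nats, of the ordinal-pattern distribution of a series
#' at embedding `(D, tau)`:
#' \deqn{PE = -\sum_{i=1}^{D!} p_i \ln p_i}
#' with `0 ln 0 = 0`.  Unnormalized; the value lies in `[0, ln D!]`.
#'
#' @inheritParams symbolize
#' @return Single numeric, the entropy in nats.
#' @examples
#' permutation_entropy(seq_len(100), D = 3, tau = 1)  # 0: one pattern only
#' @export
permutation_entropy <- function(x, D, tau) {
  x <- if (inherits(x, "timeseries")) x$values else as.numeric(x)
  if (!all(is.finite(x))) stop("series values must be finite")
  check_embedding(length(x), D, tau)
  counts <- ordinal_counts_cpp(x, as.integer(D), as.integer(tau))
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Permutation entropy as a function of the embedding delay
#'
#' Computes PE at every delay `tau = 1, ..., tau_max` with fixed embedding
#' dimension `D`.  The argmin of this curve is the PE-TD timescale estimate
#' (see [pe_td()]).
#'
#' @param x a `timeseries` or numeric vector (with `fs` for unit conversion
#'   downstream; plain vectors get `fs = NA`).
#' @param D embedding dimension; default 5.
#' @param tau_max largest delay, in samples; default 100.
#' @return An object of class `"pe_curve"`: list with `taus` (`1:tau_max`),
#'   `pe` (nats), `D`, `fs`.
#' @examples
#' x <- timeseries(sin(2 * pi * (0:2000) / 20), fs = 250)
#' pc <- pe_curve(x, D = 5, tau_max = 40)
#' pc$taus[which.min(pc$pe)]  # 20, the period in samples
#' @export
pe_curve <- function(x, D = 5, tau_max = 100) {
  fs <- if (inherits(x, "timeseries")) x$fs else NA_real_
  v <- if (inherits(x, "timeseries")) x$values else as.numeric(x)
  if (!all(is.finite(v))) stop("series values must be finite")
  if (tau_max < 1L || tau_max != round(tau_max))
    stop("'tau_max' must be an integer >= 1")
  max_feasible <- (length(v) - 1L) %/% (D - 1L)
  if (tau_max > max_feasible)
    stop(sprintf(
      "'tau_max' = %d infeasible for N = %d at D = %d: max feasible tau is %d",
      tau_max, length(v), D, max_feasible))
  check_embedding(length(v), D, 1L)
  pe <- pe_curve_cpp(v, as.integer(D), as.integer(tau_max))
  structure(list(taus = seq_len(tau_max), pe = pe,
                 D = as.integer(D), fs = fs),
            class = "pe_curve")
}

#' @export
print.pe_curve <- function(x, ...) {
  i <- which.min(x$pe)
  cat(sprintf("<pe_curve> D = %d, tau = 1..%d; min PE = %.4f nats at tau = %d\n",
              x$D, length(x$taus), x$pe[i], x$taus[i]))
  invisible(x)
}

#' @export
plot.pe_curve <- function(x, ...) {
  plot(x$taus, x$pe, type = "l", xlab = "embedding delay tau (samples)",
       ylab = "permutation entropy (nats)", ...)
  i <- which.min(x$pe)
  points(x$taus[i], x$pe[i], pch = 8, col = "red")
  invisible(x)
}
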