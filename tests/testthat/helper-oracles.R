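# Independent, naive reference implementations used as oracles.
# These deliberately share no code with the package internals.

# dictionary-counting permutation entropy: build every window explicitly,
# rank it stably, tabulate the pattern strings
naive_pe <- function(x, D, tau) {
  n <- length(x) - (D - 1) * tau
  pats <- character(n)
  for (i in seq_len(n)) {
    w <- x[i + (0:(D - 1)) * tau]
    pats[i] <- paste(rank(w, ties.method = "first"), collapse = "-")
  }
  p <- as.numeric(table(pats)) / n
  -sum(p * log(p))
}

# textbook biased autocorrelation: c_l = (1/N) sum (x_t - m)(x_{t+l} - m)
naive_acf <- function(x, max_lag) {
  n <- length(x)
  m <- mean(x)
  cl <- vapply(0:max_lag, function(l)
    sum((x[1:(n - l)] - m) * (x[(1 + l):n] - m)) / n, numeric(1))
  cl / cl[1]
}

# loop-based first zero-crossing of the naive ACF
naive_acw0 <- function(x, max_lag) {
  r <- naive_acf(x, max_lag)
  for (l in 1:max_lag) if (r[l + 1] <= 0) return(l)
  NA_integer_
}

# exactly periodic sine: phase computed modulo the integer period, so
# values recur bit-identically every P samples
exact_sine <- function(n, P, fs = 250) {
  timeseries(sin(2 * pi * ((0:(n - 1)) %% P) / P), fs = fs)
}

# seeded AR(1) draw
ar1 <- function(n, phi, seed = 1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}
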