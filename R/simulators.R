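#' Leaky integrate-and-fire neuron parameters
#'
#' Default values are the standard parameterization used throughout the
#' validation experiments: resting potential -70 mV, reset -75 mV, threshold
#' -50 mV, membrane resistance 10 MOhm, membrane time constant 10 ms,
#' sampling rate 10 kHz.
#'
#' @param v_rest resting potential, mV.
#' @param v_reset post-spike reset potential, mV (must satisfy
#'   `v_reset <= v_rest < v_th`).
#' @param v_th spike threshold, mV.
#' @param fs sampling rate, Hz.
#' @param R membrane resistance, MOhm.
#' @param tau_m membrane time constant, ms.
#' @return An object of class `"iaf_params"`.
#' @export
iaf_params <- function(v_rest = -70, v_reset = -75, v_th = -50,
                       fs = 10000, R = 10, tau_m = 10) {
  if (fs <= 0) stop("'fs' must be positive")
  if (tau_m <= 0) stop("'tau_m' must be positive")
  if (R <= 0) stop("'R' must be positive")
  if (!(v_reset <= v_rest && v_rest < v_th))
    stop("require v_reset <= v_rest < v_th")
  structure(list(v_rest = v_rest, v_reset = v_reset, v_th = v_th,
                 fs = fs, R = R, tau_m = tau_m),
            class = "iaf_params")
}

#' Input specification for the integrate-and-fire simulator
#'
#' The drive is `I(t) = I_dc + xi(t)` (nA): a DC component drawn once per
#' segment from `Normal(dc_mean, dc_sd)` plus white noise `xi(t)` drawn
#' i.i.d. per sample from `Normal(noise_mean, noise_var)`.  With the default
#' neuron, `I_dc = 4` nA drives the asymptotic potential to -30 mV, well
#' above threshold, producing tonic firing; the per-segment DC draw makes
#' successive segments fire at different rates, which is what the
#' nonstationarity experiment exploits.
#'
#' `mode = "either_or"` is an alternative reading kept for sensitivity
#' checks: each segment is randomly either pure DC (no per-sample noise) or
#' pure zero-mean noise.
#'
#' @param dc_mean,dc_sd mean and sd (nA) of the per-segment DC draw.
#' @param noise_mean,noise_var mean (nA) and variance of the per-sample
#'   white noise.
#' @param mode `"dc_plus_noise"` (default) or `"either_or"`.
#' @return An object of class `"iaf_input"`.
#' @export
iaf_input <- function(dc_mean = 4, dc_sd = 1, noise_mean = 0,
                      noise_var = 1, mode = c("dc_plus_noise", "either_or")) {
  if (noise_var < 0) stop("'noise_var' must be >= 0")
  if (dc_sd < 0) stop("'dc_sd' must be >= 0")
  structure(list(dc_mean = dc_mean, dc_sd = dc_sd, noise_mean = noise_mean,
                 noise_var = noise_var, mode = match.arg(mode)),
            class = "iaf_input")
}

#' Simulate a leaky integrate-and-fire neuron
#'
#' Euler integration of `tau_m dV/dt = -(V - v_rest) + R * I(t)` at step
#' `1/fs`; when the updated potential reaches `v_th` a spike is recorded
#' and the potential resets to `v_reset`.  All randomness (DC draw, white
#' noise) is generated from R's RNG, so results are bit-reproducible under
#' `set.seed()` or the `seed` argument.
#'
#' @param params an [iaf_params()] object.
#' @param input an [iaf_input()] object.
#' @param n_samples number of samples to simulate (>= 1).
#' @param seed optional integer seed.
#' @return An object of class `"iaf_sim"`: `trace` (a `timeseries` of the
#'   membrane potential, mV), `spikes` (spike times in seconds, strictly
#'   increasing), `i_dc` (the realized DC current, nA), plus the inputs.
#' @examples
#' sim <- simulate_iaf(iaf_params(), iaf_input(dc_sd = 0, noise_var = 0),
#'                     n_samples = 5000)
#' mean_isi(sim)  # ~ 0.00811 s: 10 * log(45/20) ms
#' @export
simulate_iaf <- function(params = iaf_params(), input = iaf_input(),
                         n_samples, seed = NULL) {
  stopifnot(inherits(params, "iaf_params"), inherits(input, "iaf_input"))
  if (n_samples < 1L) stop("'n_samples' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  i_dc <- rnorm(1L, input$dc_mean, input$dc_sd)
  noise <- rnorm(n_samples, input$noise_mean, sqrt(input$noise_var))
  if (input$mode == "either_or") {
    I <- if (runif(1L) < 0.5) rep(i_dc, n_samples) else
      rnorm(n_samples, 0, sqrt(input$noise_var))
  } else {
    I <- i_dc + noise
  }
  dt_ms <- 1000 / params$fs
  res <- iaf_simulate_cpp(I, dt_ms, params$v_rest, params$v_reset,
                          params$v_th, params$R, params$tau_m)
  structure(list(trace = timeseries(res$V, params$fs),
                 spikes = res$spike_idx / params$fs,
                 i_dc = i_dc, params = params, input = input, seed = seed),
            class = "iaf_sim")
}

#' @export
print.iaf_sim <- function(x, ...) {
  cat(sprintf("<iaf_sim> %d samples @ %g Hz, %d spikes, I_dc = %.3f nA\n",
              length(x$trace$values), x$params$fs, length(x$spikes), x$i_dc))
  invisible(x)
}

#' Mean inter-spike interval
#'
#' @param spikes an `iaf_sim` object or a strictly increasing numeric
#'   vector of spike times in seconds (at least 2 spikes).
#' @return Mean of successive spike-time differences, in seconds.
#' @export
mean_isi <- function(spikes) {
  if (inherits(spikes, "iaf_sim")) spikes <- spikes$spikes
  if (length(spikes) < 2L)
    stop("at least 2 spikes are required to define a mean ISI")
  if (any(diff(spikes) <= 0)) stop("spike times must be strictly increasing")
  mean(diff(spikes))
}

#' Closed-form tonic inter-spike interval of the leaky IAF neuron
#'
#' For a constant suprathreshold current `I` the membrane relaxes toward
#' `V_inf = v_rest + R * I`; the ISI is
#' `tau_m * log((V_inf - v_reset) / (V_inf - v_th))` (ms, converted to s).
#' Used as the analytic ground truth in validation.
#'
#' @param params an [iaf_params()] object.
#' @param I constant input current, nA.
#' @return ISI in seconds; `Inf` when the current is subthreshold.
#' @export
iaf_isi_analytic <- function(params = iaf_params(), I) {
  v_inf <- params$v_rest + params$R * I
  if (v_inf <= params$v_th) return(Inf)
  params$tau_m * log((v_inf - params$v_reset) / (v_inf - params$v_th)) / 1000
}

#' Concatenate stationary segments into a nonstationary signal
#'
#' Each of the `k` segments is truncated to `floor(target_len / k)` samples
#' (any remainder goes to the last segment) and the truncations are
#' concatenated in order, producing a piecewise-stationary signal of exactly
#' `target_len` samples.
#'
#' @param segments list of `timeseries` (>= 2, equal sampling rates).
#' @param target_len total length of the concatenation, in samples.
#' @return A `timeseries` of length `target_len`.
#' @export
make_nonstationary <- function(segments, target_len) {
  if (length(segments) < 2L) stop("need at least 2 segments")
  segments <- lapply(segments, function(s) {
    if (inherits(s, "iaf_sim")) s$trace else as_timeseries(s)
  })
  fs <- vapply(segments, function(s) s$fs, numeric(1))
  if (any(abs(fs - fs[1L]) > 1e-9))
    stop("segments have mismatched sampling rates")
  k <- length(segments)
  base <- target_len %/% k
  lens <- rep(base, k)
  lens[k] <- lens[k] + target_len - base * k
  if (any(vapply(segments, length, integer(1)) < lens))
    stop("segments too short for the requested target length")
  values <- unlist(mapply(function(s, l) s$values[seq_len(l)],
                          segments, lens, SIMPLIFY = FALSE))
  timeseries(values, fs[1L])
}

#' Mackey-Glass oscillator parameters
#'
#' The scalar delay differential equation
#' \deqn{dx/dt = -x + a\,x(t-\tau_s) / (1 + x(t-\tau_s)^c)}
#' with feedback strength `a`, nonlinearity degree `c` and delay `tau_s`
#' expressed in integration steps of size `dt`.  The trivial fixed point
#' `x = 0` is stable for `a <= 1`; for `a > 1` the nontrivial equilibrium is
#' `x* = (a - 1)^(1/c)`, which loses stability to a delay-induced
#' oscillation for sufficiently strong nonlinearity.
#'
#' @param a feedback strength (> 0).
#' @param c degree of nonlinearity (>= 1).
#' @param tau_s feedback delay, in integration steps (integer >= 1).
#' @param dt integration step; default 0.001.
#' @param duration simulated time; default 5 (i.e. 5000 steps at the
#'   default `dt`).
#' @param x0 constant initial history; default 0.5.
#' @return An object of class `"mg_params"`.
#' @export
mg_params <- function(a, c, tau_s, dt = 0.001, duration = 5, x0 = 0.5) {
  if (a <= 0) stop("'a' must be > 0")
  if (c < 1) stop("'c' must be >= 1")
  if (tau_s < 1L || tau_s != round(tau_s))
    stop("'tau_s' must be an integer >= 1 (integration steps)")
  if (dt <= 0) stop("'dt' must be > 0")
  n <- round(duration / dt)
  if (n < tau_s) stop("duration/dt must be >= tau_s")
  structure(list(a = a, c = c, tau_s = as.integer(tau_s), dt = dt,
                 duration = duration, x0 = x0, n = as.integer(n)),
            class = "mg_params")
}

#' Simulate the Mackey-Glass delay oscillator
#'
#' Euler integration of the delay equation in [mg_params()] with a constant
#' pre-history `x0`.  The integration is deterministic.  `discard` drops an
#' initial transient: the default `"auto"` removes `10 * tau_s` steps,
#' capped at half the run, so the analyzed trace reflects the attractor
#' rather than the approach to it.
#'
#' @param params an [mg_params()] object.
#' @param discard `"none"`, `"auto"`, or a number of initial steps to drop.
#' @return A `timeseries` with `fs = 1/dt` (so one sample = one integration
#'   step and delays in samples equal delays in steps).
#' @examples
#' x <- simulate_mackey_glass(mg_params(a = 2, c = 10, tau_s = 100))
#' tail(x$values, 1)  # ~ 1: the fixed point (a-1)^(1/c)
#' @export
simulate_mackey_glass <- function(params, discard = "none") {
  stopifnot(inherits(params, "mg_params"))
  x <- mg_simulate_cpp(params$n, params$dt, params$a, params$c,
                       params$tau_s, params$x0)
  if (isTRUE(attr(x, "diverged")))
    stop(sprintf("Mackey-Glass integration diverged (a = %g, c = %g, tau_s = %d)",
                 params$a, params$c, params$tau_s))
  n_drop <- if (identical(discard, "auto")) {
    min(10L * params$tau_s, params$n %/% 2L)
  } else if (identical(discard, "none")) 0L else as.integer(discard)
  if (n_drop >= params$n) stop("'discard' leaves no samples")
  out <- timeseries(x[(n_drop + 1L):params$n], 1 / params$dt)
  attr(out, "params") <- params
  attr(out, "discarded") <- n_drop
  out
}
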