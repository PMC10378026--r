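#' Signed timescale estimation error, in integration steps
#'
#' Plain algebraic subtraction: estimate (converted to steps of size `dt`)
#' minus ground truth.  Positive values are overestimates.
#'
#' @param true_tau ground-truth delay, in steps (>= 1).
#' @param estimate a `timescale_estimate`.
#' @param dt integration step length in seconds; default `1/fs` of the
#'   estimate, in which case samples and steps coincide.
#' @return Signed error in steps.
#' @export
estimation_error <- function(true_tau, estimate, dt = NULL) {
  if (true_tau < 1) stop("'true_tau' must be >= 1")
  stopifnot(inherits(estimate, "timescale_estimate"))
  if (is.null(dt)) dt <- 1 / estimate$fs
  estimate$seconds / dt - true_tau
}

# simulate one IAF segment, redrawing until it is usable for PE-TD scoring:
# at least 2 spikes and a realized mean ISI inside the search grid
# [tau_min, tau_max] samples -- the experiment presumes the ground truth is
# recoverable by the estimator in the first place.
simulate_valid_segment <- function(params, input, seg_len, tau_max,
                                   tau_min = 1, max_tries = 100L) {
  for (k in seq_len(max_tries)) {
    sim <- simulate_iaf(params, input, seg_len)
    if (length(sim$spikes) >= 2L) {
      isi_samples <- mean_isi(sim) * params$fs
      if (isi_samples >= tau_min && isi_samples <= tau_max)
        return(list(sim = sim, redraws = k - 1L))
    }
  }
  stop("could not draw a valid IAF segment in ", max_tries, " attempts")
}

#' Nonstationarity-robustness experiment
#'
#' Per iteration: simulate `n_segments` stationary integrate-and-fire
#' segments of `seg_len` samples, each with a freshly drawn DC input;
#' estimate each segment's timescale with PE-TD from the membrane trace and
#' record the error against that segment's realized mean inter-spike
#' interval (pooled into `rmse_stationary`).  Then truncate the segments to
#' `seg_len / n_segments` samples, concatenate them into one nonstationary
#' signal of `seg_len` samples, and record the difference between the
#' concatenation's PE-TD and the mean of the segments' PE-TD values
#' (`rmse_nonstationary`, the robustness figure: small means concatenation
#' barely perturbs the estimate).
#'
#' Segments whose spike train cannot ground-truth the estimator (fewer than
#' 2 spikes, or a mean ISI outside the `[tau_min, tau_max]`-sample search
#' grid) are redrawn and counted in `n_redraws`; with the default
#' "either_or" input this also redraws the silent pure-noise segments,
#' whose subthreshold drive produces no spikes to score against.
#'
#' @param n_iter number of iterations; default 500.
#' @param n_segments segments per iteration; default 8.
#' @param seg_len samples per segment (and length of the concatenated
#'   signal); default 40000 (4 s at 10 kHz).
#' @param params,input neuron and input specification; defaults
#'   [iaf_params()] and [iaf_input()] in `"either_or"` mode (the segment's
#'   drive is either a fresh DC level or pure zero-mean noise), the reading
#'   under which the membrane trace keeps its ordinal dip at the
#'   inter-spike interval — per-sample noise on a suprathreshold drive
#'   erases it (see the methods vignette).
#' @param D,tau_max PE-TD settings; defaults 5 and 200 samples (20 ms at
#'   10 kHz, about 2.5x the tonic ISI of the default drive).
#' @param tau_min PE-TD search floor in samples; default 50 (half the
#'   membrane time constant at Table-parameter settings), the scale below
#'   which the RC-smoothed trace is trivially ordered and the absolute PE
#'   minimum degenerates.
#' @param seed integer seed; the whole experiment is a pure function of
#'   (config, seed).
#' @return An object of class `"nonstat_result"`: `rmse_stationary` and
#'   `rmse_nonstationary` (seconds), `rmse_stationary_iter` (stationary
#'   errors averaged within iteration before the RMSE), per-iteration
#'   details, `n_redraws`, and the configuration echo.
#' @export
run_nonstationarity_experiment <- function(n_iter = 500, n_segments = 8,
                                           seg_len = 40000,
                                           params = iaf_params(),
                                           input = iaf_input(mode = "either_or"),
                                           D = 5, tau_max = 200,
                                           tau_min = 50, seed = 1) {
  if (n_iter < 1L) stop("'n_iter' must be >= 1")
  set.seed(seed)
  stat_err <- matrix(NA_real_, n_iter, n_segments)  # PE-TD - mean ISI, s
  nonstat_diff <- numeric(n_iter)                   # concat PE-TD - mean segment PE-TD
  n_redraws <- 0L
  for (it in seq_len(n_iter)) {
    seg_petd <- numeric(n_segments)
    segs <- vector("list", n_segments)
    for (s in seq_len(n_segments)) {
      drawn <- simulate_valid_segment(params, input, seg_len, tau_max,
                                      tau_min)
      n_redraws <- n_redraws + drawn$redraws
      sim <- drawn$sim
      est <- pe_td(sim$trace, D = D, tau_max = tau_max, tau_min = tau_min)
      seg_petd[s] <- est$seconds
      stat_err[it, s] <- est$seconds - mean_isi(sim)
      segs[[s]] <- sim$trace
    }
    concat <- make_nonstationary(segs, target_len = seg_len)
    est_c <- pe_td(concat, D = D, tau_max = tau_max, tau_min = tau_min)
    nonstat_diff[it] <- est_c$seconds - mean(seg_petd)
  }
  structure(list(
    rmse_stationary = sqrt(mean(stat_err^2)),
    rmse_stationary_iter = sqrt(mean(rowMeans(stat_err)^2)),
    rmse_nonstationary = sqrt(mean(nonstat_diff^2)),
    stationary_errors = stat_err,
    nonstationary_diffs = nonstat_diff,
    n_redraws = n_redraws,
    n_iter = n_iter, n_segments = n_segments, seg_len = seg_len,
    D = D, tau_max = tau_max, tau_min = tau_min,
    params = params, input = input, seed = seed),
    class = "nonstat_result")
}

#' @export
print.nonstat_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<nonstat_result> %d iterations x %d segments of %d samples\n",
    "  RMSE stationary (PE-TD vs mean ISI):        %.3g s\n",
    "  RMSE nonstationary (concat vs segment mean): %.3g s\n",
    "  redrawn segments: %d, seed: %d\n"),
    x$n_iter, x$n_segments, x$seg_len,
    x$rmse_stationary, x$rmse_nonstationary, x$n_redraws, x$seed))
  invisible(x)
}

mg_one_run <- function(a, c, tau_s, dt, duration, x0, D, tau_max) {
  out <- list(petd_steps = NA_real_, acw0_steps = NA_real_, note = "")
  tr <- tryCatch(
    simulate_mackey_glass(mg_params(a, c, tau_s, dt, duration, x0),
                          discard = "auto"),
    error = function(e) e)
  if (inherits(tr, "error")) {
    out$note <- conditionMessage(tr)
    return(out)
  }
  p <- tryCatch(suppressWarnings(pe_td(tr, D = D, tau_max = tau_max)),
                error = function(e) e)
  if (inherits(p, "error")) out$note <- conditionMessage(p)
  else if (p$degenerate) out$note <- "degenerate PE minimum"
  else out$petd_steps <- p$tau_samples
  a0 <- tryCatch(acw0(tr), error = function(e) e)
  if (!inherits(a0, "error")) out$acw0_steps <- a0$tau_samples
  else out$note <- paste(out$note, conditionMessage(a0), sep = "; ")
  out
}

#' Mackey-Glass nonlinearity sweep
#'
#' Holds the delay fixed (default 160 steps), sweeps the nonlinearity
#' degree `c`, and records each estimator's signed error (estimate minus
#' true delay, in steps).  The feedback strength is a nuisance parameter:
#' by default the sweep marginalizes it over a small grid of mid-range
#' oscillatory values (`seq(8, 28, by = 4)`, all above the `a ~ 6`
#' threshold below which the delay cannot be tracked) and the summary
#' reports the per-`c` mean error across that grid; pass a scalar
#' `a_fixed` for a single-strength sweep.  Divergent or degenerate runs
#' are recorded as `NA` with a note.
#'
#' @param c_grid grid of nonlinearity values; default `1:30`.
#' @param tau_fixed true delay, steps; default 160.
#' @param a_fixed feedback strength(s); default `seq(8, 28, by = 4)`.
#' @param dt,duration,x0 integration settings; defaults 0.001, 5, 0.5.
#' @param D PE embedding dimension; default 5.
#' @param tau_max PE-TD search limit; default `2 * tau_fixed` so the grid
#'   brackets the truth.
#' @return An object of class `"mg_sweep"` wrapping a data.frame with one
#'   row per `(a, c)` cell: estimates and signed errors (in steps and
#'   seconds) for PE-TD and ACW-0.  `summary()` returns the per-`c` mean
#'   errors and the `c` minimizing each estimator's (and their combined)
#'   mean absolute error.
#' @export
run_mg_c_sweep <- function(c_grid = 1:30, tau_fixed = 160,
                           a_fixed = seq(8, 28, by = 4),
                           dt = 0.001, duration = 5, x0 = 0.5,
                           D = 5, tau_max = 2 * tau_fixed) {
  if (length(c_grid) == 0L) stop("'c_grid' must be non-empty")
  if (length(a_fixed) == 0L) stop("'a_fixed' must be non-empty")
  rows <- list()
  i <- 0L
  for (a in a_fixed) for (cc in c_grid) {
    r <- mg_one_run(a, cc, tau_fixed, dt, duration, x0, D, tau_max)
    i <- i + 1L
    rows[[i]] <- data.frame(c = cc, a = a, tau_true = tau_fixed,
                            petd_steps = r$petd_steps,
                            err_petd = r$petd_steps - tau_fixed,
                            err_petd_s = (r$petd_steps - tau_fixed) * dt,
                            acw0_steps = r$acw0_steps,
                            err_acw0 = r$acw0_steps - tau_fixed,
                            err_acw0_s = (r$acw0_steps - tau_fixed) * dt,
                            note = r$note, stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), sweep = "c",
                 tau_fixed = tau_fixed, a_fixed = a_fixed, dt = dt),
            class = "mg_sweep")
}

#' Mackey-Glass feedback-strength / delay sweep
#'
#' Full grid over feedback strength `a` and delay `tau_s` at fixed
#' nonlinearity `c` (default 16), recording both estimators' signed errors.
#' The full grid of the validation study is `a = 1:46`,
#' `tau = seq(50, 300)`; pass coarser grids for quick looks.  The sweep is
#' deterministic.
#'
#' @param a_grid feedback strengths; default `1:46`.
#' @param tau_grid delays in steps; default `seq(50, 300)`.
#' @param c nonlinearity degree; default 16.
#' @param dt,duration,x0,D as in [run_mg_c_sweep()].
#' @param tau_max_factor PE-TD search limit as a multiple of the true
#'   delay; default 2.
#' @return An `"mg_sweep"` object with one row per (a, tau) cell.
#' @export
run_mg_a_tau_sweep <- function(a_grid = 1:46, tau_grid = seq(50L, 300L),
                               c = 16, dt = 0.001, duration = 5, x0 = 0.5,
                               D = 5, tau_max_factor = 2) {
  if (length(a_grid) == 0L || length(tau_grid) == 0L)
    stop("grids must be non-empty")
  rows <- list()
  i <- 0L
  for (a in a_grid) for (tau_s in tau_grid) {
    i <- i + 1L
    r <- mg_one_run(a, c, tau_s, dt, duration, x0, D,
                    tau_max = ceiling(tau_max_factor * tau_s))
    rows[[i]] <- data.frame(a = a, tau_true = tau_s, c = c,
                            petd_steps = r$petd_steps,
                            err_petd = r$petd_steps - tau_s,
                            acw0_steps = r$acw0_steps,
                            err_acw0 = r$acw0_steps - tau_s,
                            note = r$note, stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), sweep = "a_tau",
                 c = c, dt = dt),
            class = "mg_sweep")
}

#' @export
print.mg_sweep <- function(x, ...) {
  tb <- x$table
  cat(sprintf("<mg_sweep> %s sweep, %d runs\n", x$sweep, nrow(tb)))
  if (x$sweep == "c") {
    am <- summary(x)$argmin
    cat(sprintf(
      "  argmin of mean |error|: ACW-0 at c = %g, PE-TD at c = %g, combined at c = %g\n",
      am[["acw0"]], am[["petd"]], am[["combined"]]))
  }
  invisible(x)
}

#' @export
summary.mg_sweep <- function(object, ...) {
  tb <- object$table
  if (object$sweep != "c") return(invisible(tb))
  cs <- sort(unique(tb$c))
  agg <- function(v) vapply(cs, function(cc)
    mean(v[tb$c == cc], na.rm = TRUE), numeric(1))
  mean_err <- data.frame(c = cs,
                         err_petd = agg(tb$err_petd),
                         err_acw0 = agg(tb$err_acw0),
                         abs_petd = agg(abs(tb$err_petd)),
                         abs_acw0 = agg(abs(tb$err_acw0)))
  mean_err$abs_combined <- rowMeans(mean_err[c("abs_petd", "abs_acw0")],
                                    na.rm = TRUE)
  pick <- function(v) if (all(is.na(v))) NA_real_ else cs[which.min(v)]
  list(mean_error = mean_err,
       argmin = c(petd = pick(mean_err$abs_petd),
                  acw0 = pick(mean_err$abs_acw0),
                  combined = pick(mean_err$abs_combined)))
}
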