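#' Channel-wise timescale maps
#'
#' Estimates one timescale per channel (in seconds) for each subject and
#' averages channel-wise across subjects into a group map.  PE-TD uses the
#' whole recording; ACW-0 uses the sliding-window protocol (per-channel
#' window mean) when the recording is long enough for at least one window,
#' and the whole-trace variant otherwise.
#'
#' @param subjects a `multichannel` object or a list of them (one per
#'   subject); all must share channel labels and sampling rate.
#' @param method `"PE-TD"` or `"ACW-0"`.
#' @param D,tau_max PE-TD settings; defaults 5 and 100.
#' @param window_s,overlap windowed ACW-0 settings; defaults 20 s, 0.5.
#' @return An object of class `"channel_map"`: `labels`, `values` (group
#'   map, seconds), `per_subject` (subjects x channels matrix), `method`.
#' @export
channel_maps <- function(subjects, method = c("PE-TD", "ACW-0"),
                         D = 5, tau_max = 100,
                         window_s = 20, overlap = 0.5) {
  method <- match.arg(method)
  if (inherits(subjects, "multichannel")) subjects <- list(subjects)
  stopifnot(length(subjects) >= 1L,
            all(vapply(subjects, inherits, logical(1), "multichannel")))
  labels <- subjects[[1L]]$labels
  if (length(labels) < 2L) stop("need at least 2 channels")
  for (s in subjects) {
    if (!identical(s$labels, labels))
      stop("channel labels differ across subjects")
    if (abs(s$fs - subjects[[1L]]$fs) > 1e-9)
      stop("sampling rates differ across subjects")
  }
  est_one <- function(ts) {
    if (method == "PE-TD") {
      suppressWarnings(pe_td(ts, D = D, tau_max = tau_max)$seconds)
    } else if (length(ts$values) >= window_s * ts$fs) {
      windowed_acw0(ts, window_s = window_s, overlap = overlap)$seconds
    } else {
      acw0(ts)$seconds
    }
  }
  per_subject <- t(vapply(subjects, function(s)
    vapply(labels, function(ch) est_one(get_channel(s, ch)), numeric(1)),
    numeric(length(labels))))
  structure(list(labels = labels, values = colMeans(per_subject),
                 per_subject = per_subject, method = method,
                 n_subjects = length(subjects)),
            class = "channel_map")
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("<channel_map> %s, %d channels, %d subject(s); mean = %.4g s\n",
              x$method, length(x$labels), x$n_subjects, mean(x$values)))
  invisible(x)
}

#' Correlation between two channel maps
#'
#' Channel-wise correlation (Spearman by default, the rank-based choice;
#' Pearson available) between two maps over matched channel labels.
#'
#' @param map_a,map_b `channel_map` objects (or plain named numeric
#'   vectors) with identical label sets.
#' @param kind `"spearman"` (default) or `"pearson"`.
#' @return List with `r` and `p` (two-sided).
#' @export
map_correlation <- function(map_a, map_b, kind = c("spearman", "pearson")) {
  kind <- match.arg(kind)
  va <- if (inherits(map_a, "channel_map")) {
    stats::setNames(map_a$values, map_a$labels)
  } else map_a
  vb <- if (inherits(map_b, "channel_map")) {
    stats::setNames(map_b$values, map_b$labels)
  } else map_b
  if (!is.null(names(va)) && !is.null(names(vb))) {
    if (!setequal(names(va), names(vb))) stop("channel labels do not match")
    vb <- vb[names(va)]
  } else if (length(va) != length(vb)) {
    stop("maps must have equal length")
  }
  if (length(va) < 3L) stop("need at least 3 channels")
  if (sd(va) == 0 || sd(vb) == 0)
    stop("constant map: correlation undefined")
  ct <- suppressWarnings(cor.test(va, vb, method = kind, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, kind = kind,
       n = length(va))
}

boot_cor <- function(x, y, kind) suppressWarnings(cor(x, y, method = kind))

#' Bootstrap test for a difference between two correlations
#'
#' Channel indices are resampled with replacement independently within each
#' group; each replicate recomputes `r1* - r2*`.  The null distribution is
#' the bootstrap distribution shifted to zero (centered on the observed
#' difference), and the two-sided p-value is the add-one-corrected fraction
#' of replicates at least as extreme as the observed difference,
#' `(k + 1) / (n_boot + 1)`.  Replicates in which a resampled vector is
#' constant (correlation undefined) are redrawn and counted.
#'
#' @param x1,y1 paired vectors for group 1 (length >= 3).
#' @param x2,y2 paired vectors for group 2.
#' @param n_boot bootstrap iterations; default 10000.
#' @param kind correlation flavour, `"spearman"` (default) or `"pearson"`.
#' @param seed integer seed; default 1.
#' @return An object of class `"corr_comparison"`: `r1`, `r2`, `diff`,
#'   `p_boot`, `p_fisher` (the closed-form check from [fisher_z_test()]),
#'   `n1`, `n2`, `n_boot`, `n_degenerate`, `seed`, `kind`.
#' @export
bootstrap_corr_difference <- function(x1, y1, x2, y2, n_boot = 10000,
                                      kind = c("spearman", "pearson"),
                                      seed = 1) {
  kind <- match.arg(kind)
  stopifnot(length(x1) == length(y1), length(x2) == length(y2),
            length(x1) >= 3L, length(x2) >= 3L)
  set.seed(seed)
  r1 <- boot_cor(x1, y1, kind)
  r2 <- boot_cor(x2, y2, kind)
  d_obs <- r1 - r2
  n1 <- length(x1); n2 <- length(x2)
  d_star <- numeric(n_boot)
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      i1 <- sample.int(n1, n1, replace = TRUE)
      i2 <- sample.int(n2, n2, replace = TRUE)
      if (sd(x1[i1]) > 0 && sd(y1[i1]) > 0 &&
          sd(x2[i2]) > 0 && sd(y2[i2]) > 0) break
      n_degenerate <- n_degenerate + 1L
    }
    d_star[b] <- boot_cor(x1[i1], y1[i1], kind) -
      boot_cor(x2[i2], y2[i2], kind)
  }
  null_dist <- d_star - d_obs  # shift to the null of equal correlations
  k <- sum(abs(null_dist) >= abs(d_obs))
  fz <- fisher_z_test(r1, n1, r2, n2)
  structure(list(r1 = r1, r2 = r2, diff = d_obs,
                 p_boot = (k + 1) / (n_boot + 1),
                 p_fisher = fz$p, z_fisher = fz$z,
                 n1 = n1, n2 = n2, n_boot = n_boot,
                 n_degenerate = n_degenerate, seed = seed, kind = kind),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<corr_comparison> %s r1 = %.3f (n = %d) vs r2 = %.3f (n = %d)\n",
    "  bootstrap p = %.4g (%d iterations, seed %d); Fisher-z p = %.4g\n"),
    x$kind, x$r1, x$n1, x$r2, x$n2, x$p_boot, x$n_boot, x$seed, x$p_fisher))
  invisible(x)
}

#' Fisher z test for a difference between two correlations
#'
#' Two-sided normal test of `atanh(r1) - atanh(r2)` with standard error
#' `sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 sample sizes (> 3).
#' @return List with `z` and two-sided `p`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must lie strictly inside (-1, 1)")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test on subject-level values
#' (normal approximation with continuity correction, so tied values are
#' handled by the standard tie correction; fully tied data trigger a
#' warning).
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @return List with `statistic` (W) and two-sided `p`.
#' @export
ranksum_groups <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty")
  if (length(unique(c(values_a, values_b))) == 1L)
    warning("all values tied; rank-sum test is uninformative")
  wt <- suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Synthetic multichannel generator
#'
#' Stand-in for resting-state multichannel recordings: each channel carries
#' a phase-coherent, exactly periodic oscillation (a fundamental plus a
#' second harmonic, with per-channel amplitude and phase) whose period
#' follows a spatial gradient across channels (from `period_range[1]` to
#' `period_range[2]` seconds, emulating the posterior-to-anterior
#' lengthening of intrinsic timescales).  Periods are integer numbers of
#' samples: the PE-TD ordinal dip rests on exact value recurrence at the
#' period lag, which additive noise destroys (see the methods vignette),
#' so the default is noise-free.
#'
#' Two regimes are generated:
#' * `"conscious-like"` - each channel is stationary, so the PE-TD and
#'   ACW-0 channel maps are both clean monotone functions of the injected
#'   gradient and correlate highly with each other;
#' * `"uws-like"` - a random subset of channels (probability `switch_prob`
#'   per channel and subject) switches period, amplitude and phase between
#'   piecewise-stationary segments, the kind of nonstationarity that
#'   perturbs the two estimators differently: the windowed ACW-0 map still
#'   tracks the mean period while the PE-TD minimum of a switching channel
#'   collapses away from the period lag, degrading the correlation between
#'   the two maps.
#'
#' This generator emulates the timescale gradient and the stationarity
#' contrast only; it makes no attempt to reproduce EEG spectra or
#' topographies.
#'
#' @param n_subjects number of subjects; default 5.
#' @param n_channels channels per subject (>= 2); default 32.
#' @param fs sampling rate, Hz; default 250.
#' @param duration recording length per subject, seconds; default 40.
#' @param period_range dominant-period gradient endpoints, seconds;
#'   default `c(0.10, 0.30)`.
#' @param regime `"conscious-like"` or `"uws-like"`.
#' @param noise_sd additive white-noise sd relative to unit oscillation
#'   amplitude; default 0 (any appreciable noise removes the ordinal
#'   recurrence the PE-TD map rests on).
#' @param n_segments segments for the uws-like switching; default 8.
#' @param switch_sd log-sd of the per-segment period jitter in the
#'   uws-like regime; default 0.35.
#' @param switch_prob probability that a channel is unstable (switching)
#'   in the uws-like regime; default 0.6.
#' @param seed integer seed.
#' @return List of `multichannel` objects, one per subject, with the
#'   injected per-channel periods (seconds) attached as attribute
#'   `"true_period"`.
#' @export
synth_multichannel <- function(n_subjects = 5, n_channels = 32, fs = 250,
                               duration = 40,
                               period_range = c(0.10, 0.30),
                               regime = c("conscious-like", "uws-like"),
                               noise_sd = 0, n_segments = 8,
                               switch_sd = 0.35, switch_prob = 0.6,
                               seed = 1) {
  regime <- match.arg(regime)
  if (n_channels < 2L) stop("need at least 2 channels")
  set.seed(seed)
  n <- round(duration * fs)
  periods <- round(seq(period_range[1L] * fs, period_range[2L] * fs,
                       length.out = n_channels))  # integer samples
  # exactly periodic waveform: fundamental + second harmonic, integer period
  waveform <- function(len, p, amp, phase_idx, h2) {
    ph <- ((seq_len(len) - 1L + phase_idx) %% p) / p
    amp * (sin(2 * pi * ph) + h2 * sin(4 * pi * ph))
  }
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    mat <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      p_ch <- max(8L, periods[ch] + sample(-1L:1L, 1L))  # subject jitter
      h2 <- runif(1L, 0.1, 0.4)
      if (regime == "conscious-like" || runif(1L) >= switch_prob) {
        x <- waveform(n, p_ch, exp(rnorm(1L, 0, 0.3)),
                      sample.int(p_ch, 1L), h2)
      } else {
        bounds <- floor(seq(0L, n, length.out = n_segments + 1L))
        x <- numeric(n)
        for (g in seq_len(n_segments)) {
          idx <- (bounds[g] + 1L):bounds[g + 1L]
          p_seg <- max(8L, round(p_ch * exp(rnorm(1L, 0, switch_sd))))
          x[idx] <- waveform(length(idx), p_seg, exp(rnorm(1L, 0, 0.4)),
                             sample.int(p_seg, 1L), h2)
        }
      }
      if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
      mat[ch, ] <- x
    }
    mc <- multichannel(mat, fs)
    attr(mc, "true_period") <- periods / fs
    subjects[[s]] <- mc
  }
  subjects
}
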