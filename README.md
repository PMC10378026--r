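# petd — permutation-entropy time-delay estimation of intrinsic timescales

Spontaneous neural activity stays correlated with itself over a
characteristic temporal window, its *intrinsic neural timescale* (INT).
`petd` estimates a signal's dominant timescale with two methods:

* **PE-TD** — permutation entropy computed over ordinal patterns of the
  signal as a function of the embedding delay τ,

  PE(τ) = −Σᵢ pᵢ ln pᵢ,  i = 1..D!,

  where pᵢ are the frequencies of the D-point rank patterns at spacing τ;
  the estimate is the delay at which PE(τ) attains its global minimum,
  in seconds τ/fs.  Defaults D = 5, τ = 1..100.
* **ACW-0** — the established benchmark: the first zero-crossing of the
  autocorrelation function rₗ = cₗ/c₀ (biased estimator), optionally in
  sliding 20 s windows with 50% overlap.

The package is aimed at researchers analyzing resting-state
electrophysiology or simulated neural signals who want an
information-theoretic timescale estimator next to the standard
autocorrelation window, together with the validation machinery: a leaky
integrate-and-fire (IAF) neuron simulator with an analytic ground-truth
inter-spike interval, the Mackey–Glass delay oscillator, a
nonstationarity-robustness experiment built from concatenated stationary
segments, channel-wise timescale maps, and group statistics (Spearman
map correlation, bootstrap and Fisher-z tests for a difference of
correlations, Wilcoxon rank-sum).

## Worked example

A tonic IAF neuron driven by a constant 4 nA current fires with the
closed-form interval 10·ln(45/20) ≈ 8.11 ms.  PE-TD recovers it from the
membrane trace alone:

```r
library(petd)
sim <- simulate_iaf(iaf_params(), iaf_input(dc_sd = 0, noise_var = 0),
                    n_samples = 40000, seed = 1)
sim
#> <iaf_sim> 40000 samples @ 10000 Hz, 493 spikes, I_dc = 4.000 nA
mean_isi(sim)
#> [1] 0.0081
est <- pe_td(sim$trace, tau_max = 200)
est
#> <timescale_estimate> PE-TD: tau = 81 samples = 0.0081 s (fs = 10000 Hz)
```

The estimate (81 samples at 10 kHz = 8.1 ms) matches the realized mean
inter-spike interval exactly: at τ = ISI every ordinal window samples
identical phases of the spike cycle, and the pattern distribution
collapses.  `plot(est)` shows the PE-vs-τ curve with its minimum.

For a periodic signal the two estimators stand in a 4:1 relation —
PE-TD returns the period, ACW-0 the quarter period:

```r
x <- timeseries(sin(2 * pi * ((0:4999) %% 50) / 50), fs = 250)
pe_td(x)
#> <timescale_estimate> PE-TD: tau = 50 samples = 0.2 s (fs = 250 Hz)
acw0(x)
#> <timescale_estimate> ACW-0: tau = 13 samples = 0.052 s (fs = 250 Hz)
```

Multichannel workflows mirror this per channel: `read_timeseries()`
loads a CSV/TSV matrix (sampling rate from a flag or JSON sidecar),
`channel_maps()` produces one estimate per channel (in seconds),
`map_correlation()` / `bootstrap_corr_difference()` /
`fisher_z_test()` / `ranksum_groups()` compare maps and groups, and
`synth_multichannel()` generates gradient-bearing synthetic recordings
in a stationary ("conscious-like") or piecewise-stationary
("uws-like") regime.

## Command line

A thin CLI wraps the same functions (`inst/cli/petd`, or call
`petd::petd_cli()` directly):

```sh
petd pe-td --input rec.csv --fs 250 --D 5 --tau-max 100 --out est.json
petd sim-mg --a 4 --c 16 --tau 160 --out mg.csv
petd exp-nonstat --n-iter 100 --seed 1 --out nonstat.json
```

Every output embeds the resolved configuration and seed; exit codes are
0 (success), 2 (usage error), 1 (runtime error).

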