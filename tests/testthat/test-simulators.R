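tonic_input <- iaf_input(dc_sd = 0, noise_var = 0)

test_that("tonic IAF firing matches the closed-form ISI within one sample", {
  p <- iaf_params()
  expect_equal(iaf_isi_analytic(p, 4), 10 * log(45 / 20) / 1000)
  sim <- simulate_iaf(p, tonic_input, n_samples = 40000, seed = 1)
  expect_gt(length(sim$spikes), 400)
  expect_equal(mean_isi(sim), iaf_isi_analytic(p, 4),
               tolerance = 1 / p$fs / iaf_isi_analytic(p, 4))
  expect_true(all(diff(sim$spikes) > 0))
})

test_that("subthreshold drive produces no spikes", {
  sim <- simulate_iaf(iaf_params(),
                      iaf_input(dc_mean = 1, dc_sd = 0, noise_var = 0),
                      n_samples = 20000, seed = 1)
  expect_length(sim$spikes, 0L)
  # V_inf = -60 mV: trace approaches it from rest
  expect_equal(tail(sim$trace$values, 1), -60, tolerance = 0.01)
})

test_that("IAF simulation is bit-reproducible from a seed", {
  a <- simulate_iaf(n_samples = 5000, seed = 99)
  b <- simulate_iaf(n_samples = 5000, seed = 99)
  expect_identical(a$trace$values, b$trace$values)
  expect_identical(a$spikes, b$spikes)
})

test_that("membrane potential stays within reset/threshold bounds", {
  sim <- simulate_iaf(iaf_params(), iaf_input(), n_samples = 40000,
                      seed = 7)
  p <- iaf_params()
  # one Euler step may overshoot the threshold before the reset applies
  max_step <- (abs(p$v_reset - p$v_rest) + p$R * 10) / p$tau_m * (1000 / p$fs)
  expect_gte(min(sim$trace$values), p$v_reset - max_step)
  expect_lte(max(sim$trace$values), p$v_th + max_step)
})

test_that("firing rate grows with suprathreshold DC current", {
  rates <- vapply(c(3, 4, 5), function(I) {
    sim <- simulate_iaf(iaf_params(),
                        iaf_input(dc_mean = I, dc_sd = 0, noise_var = 0),
                        n_samples = 20000, seed = 1)
    length(sim$spikes)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("mean_isi reduces to the telescoping identity", {
  expect_equal(mean_isi(c(0.01, 0.02, 0.03)), 0.01)
  set.seed(2)
  t <- cumsum(runif(50, 0.005, 0.02))
  expect_equal(mean_isi(t), (t[50] - t[1]) / 49)
  expect_error(mean_isi(0.5), "2 spikes")
})

test_that("make_nonstationary truncates and concatenates exactly", {
  segs <- lapply(1:8, function(i) timeseries(rep(i, 40000), 10000))
  cc <- make_nonstationary(segs, 40000)
  expect_length(cc$values, 40000L)
  expect_equal(unname(table(cc$values)), rep(5000L, 8),
               ignore_attr = TRUE)
  # remainder goes to the last segment
  cc2 <- make_nonstationary(segs[1:3], 10000)
  expect_length(cc2$values, 10000L)
  expect_equal(sum(cc2$values == 3), 10000 - 2 * 3333)
  expect_error(make_nonstationary(list(timeseries(1:10, 100),
                                       timeseries(1:10, 200)), 10),
               "mismatched")
  # two identical segments concatenate into a stationary signal
  s <- exact_sine(4000, 20)
  cc3 <- make_nonstationary(list(s, s), 4000)
  expect_identical(cc3$values, c(s$values[1:2000], s$values[1:2000]))
})

test_that("Mackey-Glass decays for weak feedback and holds its fixed point", {
  tr <- simulate_mackey_glass(mg_params(a = 0.5, c = 10, tau_s = 100,
                                        duration = 20))
  expect_lt(tail(tr$values, 1), 1e-3)
  # nontrivial equilibrium x* = (a-1)^(1/c): exact under Euler
  xstar <- (2 - 1)^(1 / 10)
  tr2 <- simulate_mackey_glass(mg_params(a = 2, c = 10, tau_s = 100,
                                         x0 = xstar))
  expect_lt(max(abs(tr2$values - xstar)), 1e-9)
})

test_that("Mackey-Glass run is deterministic and transient discard works", {
  a <- simulate_mackey_glass(mg_params(a = 4, c = 16, tau_s = 160))
  b <- simulate_mackey_glass(mg_params(a = 4, c = 16, tau_s = 160))
  expect_identical(a$values, b$values)
  d <- simulate_mackey_glass(mg_params(a = 4, c = 16, tau_s = 160),
                             discard = "auto")
  expect_length(d$values, 5000L - 1600L)
  expect_identical(d$values, a$values[1601:5000])
  expect_equal(d$fs, 1000)
})

test_that("halving the Euler step changes the trajectory by O(dt)", {
  tr1 <- simulate_mackey_glass(mg_params(a = 0.5, c = 10, tau_s = 100,
                                         dt = 0.001, duration = 2))
  tr2 <- simulate_mackey_glass(mg_params(a = 0.5, c = 10, tau_s = 200,
                                         dt = 0.0005, duration = 2))
  diff <- max(abs(tr1$values - tr2$values[seq(1, 4000, by = 2)]))
  expect_lt(diff, 1e-3)
})

test_that("PE-TD recovers the tonic IAF timescale from the membrane trace", {
  sim <- simulate_iaf(iaf_params(), tonic_input, n_samples = 40000,
                      seed = 3)
  est <- pe_td(sim$trace, tau_max = 200)
  expect_equal(est$seconds, iaf_isi_analytic(iaf_params(), 4),
               tolerance = 0.1)
})
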