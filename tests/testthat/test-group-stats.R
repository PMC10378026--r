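make_subject <- function(periods, n = 6000, fs = 250) {
  mat <- t(vapply(periods, function(P)
    sin(2 * pi * ((0:(n - 1)) %% P) / P), numeric(n)))
  multichannel(mat, fs, labels = paste0("ch", seq_along(periods)))
}

test_that("channel maps are per-channel estimates in seconds", {
  mc <- make_subject(rep(40, 4))
  mp <- channel_maps(mc, "PE-TD", tau_max = 60)
  expect_length(mp$values, 4L)
  expect_true(all(mp$values == mp$values[1]))  # identical channels
  expect_equal(unname(mp$values[1]), 40 / 250)
})

test_that("PE-TD and ACW-0 maps keep the period/quarter-period ratio", {
  mc <- make_subject(c(20, 40, 60, 80))
  mp <- channel_maps(mc, "PE-TD", tau_max = 100)
  ma <- channel_maps(mc, "ACW-0")
  expect_true(all(diff(mp$values) > 0))  # monotone in the injected gradient
  ratio <- mp$values / ma$values
  expect_true(all(ratio > 3.3 & ratio < 4.3))
})

test_that("channel_maps validates labels and sampling rates", {
  a <- make_subject(c(20, 40))
  b <- multichannel(a$values, a$fs, labels = c("x", "y"))
  expect_error(channel_maps(list(a, b)), "labels differ")
})

test_that("map_correlation handles monotone, inverted and degenerate maps", {
  set.seed(1)
  m <- rnorm(20)
  expect_equal(map_correlation(m, 2 * m)$r, 1)
  expect_equal(map_correlation(m, -m)$r, -1)
  expect_error(map_correlation(rep(1, 20), m), "constant")
  # spearman is invariant under strictly monotone per-map transforms
  m2 <- rnorm(20)
  expect_equal(map_correlation(m, m2)$r,
               map_correlation(exp(m), m2^3 + m2)$r)
})

test_that("independent maps show no spurious correlation", {
  set.seed(3)
  mc <- map_correlation(rnorm(200), rnorm(200))
  expect_lt(abs(mc$r), 0.2)
  expect_gt(mc$p, 0.01)
})

test_that("fisher_z_test matches its closed form and is antisymmetric", {
  eq <- fisher_z_test(0.4, 50, 0.4, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  fz <- fisher_z_test(0.90, 244, 0.55, 244)
  z_expected <- (atanh(0.90) - atanh(0.55)) / sqrt(2 / 241)
  expect_equal(fz$z, z_expected)
  expect_lt(fz$p, 1e-3)
  expect_equal(fisher_z_test(0.55, 244, 0.90, 244)$z, -z_expected)
  expect_error(fisher_z_test(1, 50, 0.5, 50), "strictly inside")
})

test_that("bootstrap difference test behaves on identical and separated groups", {
  set.seed(4)
  x1 <- rnorm(200); y1 <- 0.9 * x1 + 0.45 * rnorm(200)
  x2 <- rnorm(200); y2 <- rnorm(200)
  same <- bootstrap_corr_difference(x1, y1, x1, y1, n_boot = 500, seed = 2)
  expect_gt(same$p_boot, 0.8)
  sep <- bootstrap_corr_difference(x1, y1, x2, y2, n_boot = 2000, seed = 5)
  expect_lt(sep$p_boot, 0.01)
  expect_lt(sep$p_fisher, 0.01)
  rerun <- bootstrap_corr_difference(x1, y1, x2, y2, n_boot = 2000, seed = 5)
  expect_identical(sep$p_boot, rerun$p_boot)
})

test_that("bootstrap and Fisher-z p-values agree on Gaussian synthetics", {
  set.seed(4)
  x1 <- rnorm(200); y1 <- 0.4 * x1 + rnorm(200)
  x2 <- rnorm(200); y2 <- 0.15 * x2 + rnorm(200)
  bc <- bootstrap_corr_difference(x1, y1, x2, y2, n_boot = 2000, seed = 9)
  expect_lt(abs(bc$p_boot - bc$p_fisher), 0.05)
})

test_that("rank-sum comparison detects shifts and respects ranks", {
  set.seed(6)
  a <- rnorm(30)
  b <- rnorm(30) + 3
  expect_lt(ranksum_groups(a, b)$p, 1e-3)
  expect_gt(ranksum_groups(a, a)$p, 0.99)
  # rank-based: invariant to a monotone transform of the pooled values
  pooled_monotone <- function(v) exp(v / 2)
  expect_identical(ranksum_groups(a, b)$p,
                   ranksum_groups(pooled_monotone(a), pooled_monotone(b))$p)
  expect_warning(ranksum_groups(rep(1, 5), rep(1, 5)), "tied")
})

test_that("the synthetic generator produces the regime contrast", {
  con <- synth_multichannel(n_subjects = 3, n_channels = 16, duration = 40,
                            regime = "conscious-like", seed = 7)
  uws <- synth_multichannel(n_subjects = 3, n_channels = 16, duration = 40,
                            regime = "uws-like", seed = 7)
  mp_c <- channel_maps(con, "PE-TD")
  ma_c <- channel_maps(con, "ACW-0")
  r_con <- map_correlation(mp_c, ma_c)$r
  r_uws <- map_correlation(channel_maps(uws, "PE-TD"),
                           channel_maps(uws, "ACW-0"))$r
  expect_gt(r_con, 0.8)
  expect_lt(r_uws, r_con)
  # injected gradient recovered in rank order
  grad <- cor(mp_c$values, attr(con[[1]], "true_period"),
              method = "spearman")
  expect_gt(grad, 0.9)
  # reproducible
  con2 <- synth_multichannel(n_subjects = 3, n_channels = 16,
                             duration = 40, regime = "conscious-like",
                             seed = 7)
  expect_identical(con[[1]]$values, con2[[1]]$values)
})
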