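test_that("ordinal_pattern ranks ascending with stable tie-break", {
  expect_identical(ordinal_pattern(c(1.2, 3.4, 2.1)), c(0L, 2L, 1L))
  expect_identical(ordinal_pattern(c(5, 5, 5)), c(0L, 1L, 2L))
  expect_identical(ordinal_pattern(c(9, 4, 1)), c(2L, 1L, 0L))
  expect_error(ordinal_pattern(c(1, NA, 2)), "finite")
})

test_that("pattern_index is the lexicographic bijection", {
  D <- 4L
  idx <- vapply(0:(factorial(D) - 1L), function(i)
    pattern_index(index_to_pattern(i, D)), integer(1))
  expect_identical(idx, 0:(factorial(D) - 1L))
  expect_identical(pattern_index(c(0L, 1L, 2L)), 0L)   # identity first
  expect_identical(pattern_index(c(2L, 1L, 0L)), 5L)   # reversal last
})

test_that("symbolize yields N - (D-1)*tau indices in range", {
  expect_identical(symbolize(c(1, 2, 3, 4), D = 3, tau = 1), c(0L, 0L))
  expect_length(symbolize(1:6, D = 3, tau = 2), 2L)
  set.seed(1)
  s <- symbolize(rnorm(1000), D = 5, tau = 1)
  expect_length(s, 996L)
  expect_true(all(s >= 0L & s < 120L))
  expect_error(symbolize(1:5, D = 3, tau = 3), "N >= 7")
})

test_that("pattern_distribution covers all D! patterns and normalizes", {
  d <- pattern_distribution(rep(2L, 10), D = 3)
  expect_identical(d$counts, c(0L, 0L, 10L, 0L, 0L, 0L))
  expect_equal(d$probs[3], 1)
  d2 <- pattern_distribution(0:5, D = 3)
  expect_equal(d2$probs, rep(1 / 6, 6))
  d3 <- pattern_distribution(symbolize(c(1, 2, 3, 4), 3, 1), D = 3)
  expect_equal(d3$probs[1], 1)
  expect_equal(sum(d3$probs), 1, tolerance = 1e-12)
  expect_error(pattern_distribution(integer(0), 3), "empty")
})

test_that("permutation entropy of deterministic monotone inputs is zero", {
  expect_equal(permutation_entropy(rep(3.7, 50), D = 4, tau = 2), 0)
  expect_equal(permutation_entropy(seq_len(200), D = 5, tau = 3), 0)
})

test_that("iid noise attains the uniform-pattern entropy ln(D!)", {
  set.seed(8)
  pe <- permutation_entropy(rnorm(1e5), D = 3, tau = 1)
  expect_equal(pe, log(6), tolerance = 0.01)
})

test_that("PE is bounded by [0, ln D!] on random inputs", {
  set.seed(42)
  for (rep in 1:20) {
    D <- sample(2:5, 1)
    tau <- sample(1:3, 1)
    x <- rnorm(sample(50:200, 1))
    pe <- permutation_entropy(x, D, tau)
    expect_gte(pe, 0)
    expect_lte(pe, log(factorial(D)) + 1e-12)
  }
})

test_that("PE is exactly invariant under strictly increasing transforms", {
  set.seed(7)
  x <- rnorm(500)
  for (D in c(3, 5)) {
    base <- permutation_entropy(x, D, 2)
    expect_identical(permutation_entropy(exp(x), D, 2), base)
    expect_identical(permutation_entropy(3.5 * x + 11, D, 2), base)
  }
})

test_that("fast PE matches the naive dictionary-counting oracle bit-exactly", {
  set.seed(123)
  for (rep in 1:100) {
    D <- sample(2:5, 1)
    tau <- sample(1:3, 1)
    n <- sample(((D - 1) * tau + 5):200, 1)
    x <- rnorm(n)
    if (rep %% 3 == 0) x <- round(x, 1)  # force ties
    expect_identical(permutation_entropy(x, D, tau), naive_pe(x, D, tau))
  }
})

test_that("PE at D = 2 is invariant to time reversal when there are no ties", {
  set.seed(5)
  x <- rnorm(300)
  expect_equal(permutation_entropy(x, 2, 1),
               permutation_entropy(rev(x), 2, 1), tolerance = 1e-12)
})

test_that("pe_curve dips to zero at the period of an exactly periodic sine", {
  x <- exact_sine(5001, 20)
  pc <- pe_curve(x, D = 5, tau_max = 40)
  expect_equal(pc$pe[20], 0)
  expect_identical(pc$taus[which.min(pc$pe)], 20L)
  expect_true(all(pc$pe >= 0 & pc$pe <= log(120) + 1e-12))
})

test_that("pe_curve is flat at zero for constants and flat near ln(D!) for noise", {
  pc <- pe_curve(timeseries(rep(1, 500), 100), D = 3, tau_max = 20)
  expect_true(all(pc$pe == 0))
  set.seed(9)
  pcn <- pe_curve(rnorm(2e5), D = 3, tau_max = 40)
  expect_lt(max(pcn$pe) - min(pcn$pe), 0.01)
  expect_equal(mean(pcn$pe), log(6), tolerance = 0.01)
})

test_that("pe_curve refuses an infeasible tau_max and names the feasible one", {
  expect_error(pe_curve(rnorm(41), D = 5, tau_max = 50), "max feasible tau is 10")
})
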