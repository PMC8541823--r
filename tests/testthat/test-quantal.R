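test_that("histogram bins are half-open, anchored at 0, and conserve events", {
  h <- build_histogram(c(0.005, 0.015), bin_width = 0.01)
  expect_equal(h$counts, c(1, 1))
  expect_equal(h$bin_edges[1], 0)

  # value exactly on an edge goes to the right bin
  h2 <- build_histogram(c(0.01), bin_width = 0.01)
  expect_equal(h2$counts, c(0, 1))

  set.seed(11)
  amp <- stats::runif(1000, 0.05, 3)
  h3 <- build_histogram(amp)
  expect_equal(sum(h3$counts), 1000)
  expect_equal(h3$bin_width, 0.01)
  expect_equal(diff(h3$bin_edges), rep(0.01, length(h3$counts)))

  expect_error(build_histogram(numeric(0)), "no amplitudes")
  expect_error(build_histogram(c(0.1), bin_width = 0), "bin_width")
})

test_that("quantal content pmf matches a brute-force binomial oracle (n <= 12)", {
  # independent oracle: enumerate C(n,i) p^i (1-p)^(n-i) from factorials
  oracle <- function(n, p, i)
    factorial(n) / (factorial(i) * factorial(n - i)) * p^i * (1 - p)^(n - i)
  for (n in 1:12) {
    for (p in c(0.1, 0.3, 0.5, 0.85)) {
      m <- quantal_model(q = 0.6, sigma0 = 0.1, n = n, p = p)
      iv <- 0:n
      expect_equal(quantal_content_pmf(m, iv, truncate = FALSE),
                   oracle(n, p, iv), tolerance = 1e-12)
      # truncated: renormalized over i >= 1
      iv1 <- seq_len(n)
      expect_equal(quantal_content_pmf(m, iv1, truncate = TRUE),
                   oracle(n, p, iv1) / sum(oracle(n, p, iv1)),
                   tolerance = 1e-12)
      expect_equal(sum(quantal_content_pmf(m, iv, truncate = FALSE)), 1)
      expect_equal(sum(quantal_content_pmf(m, iv1, truncate = TRUE)), 1)
    }
  }
  m <- quantal_model(0.6, 0.1, 4, 0.5)
  expect_equal(quantal_content_pmf(m, 2, truncate = FALSE), 0.375)
  expect_error(quantal_content_pmf(m, 5), "must lie in")
  expect_error(quantal_content_pmf(m, 0, truncate = TRUE), "must lie in")
})

test_that("peak SD follows the configured exponent", {
  m05 <- quantal_model(0.6, 0.05, 5, 0.3, peak_sd_exponent = 0.5)
  m10 <- quantal_model(0.6, 0.05, 5, 0.3, peak_sd_exponent = 1.0)
  expect_equal(peak_sd(m05, 1), 0.05)
  expect_equal(peak_sd(m10, 1), 0.05)
  expect_equal(peak_sd(m05, 4), 0.10)
  expect_equal(peak_sd(m10, 4), 0.20)
  expect_error(peak_sd(m05, 0), "i must be")
})

test_that("peak density is a unit-mass Gaussian", {
  expect_equal(peak_density(0, 1, 0), 1 / sqrt(2 * pi), tolerance = 1e-6)
  a <- c(0.1, 0.5, 2)
  expect_equal(peak_density(1.3, 0.4, 1.3 + a), peak_density(1.3, 0.4, 1.3 - a))
  total <- stats::integrate(function(y) peak_density(1, 0.3, y),
                            1 - 8 * 0.3, 1 + 8 * 0.3)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_error(peak_density(0, 0, 0), "sigma")
})

test_that("theoretical distribution conserves events and degenerates correctly", {
  m <- quantal_model(0.6, 0.08, 5, 0.3)
  h <- amplitude_histogram(0.01, rep(0, 500))
  td <- theoretical_distribution(m, 1000, h)
  expect_equal(sum(td$expected_counts), 1000, tolerance = 1e-6)
  expect_null(td$warning)

  # sigma0 -> 0: all mass in the bins holding i*q, weighted by the pmf
  m0 <- quantal_model(0.6, 0, 5, 0.3)
  td0 <- theoretical_distribution(m0, 1, h)
  nonzero <- which(td0$expected_counts > 0)
  expect_equal(h$bin_edges[nonzero], (1:5) * 0.6)
  expect_equal(td0$expected_counts[nonzero],
               quantal_content_pmf(m0, 1:5), tolerance = 1e-12)

  # a range excluding model mass is flagged
  h_short <- amplitude_histogram(0.01, rep(0, 30))
  td_short <- theoretical_distribution(m, 100, h_short)
  expect_false(is.null(td_short$warning))
  expect_lt(td_short$coverage, 0.99)
})

test_that("theoretical distribution matches a large Monte-Carlo histogram", {
  m <- quantal_model(0.6, 0.1, 5, 0.3)
  n_mc <- 1e6
  ev <- simulate_mepsp_events(m, n_mc, seed = 101)
  h <- build_histogram(ev)
  td <- theoretical_distribution(m, n_mc, h)
  # per-bin agreement within 3-sigma Poisson bands (where expectation sizable)
  keep <- td$expected_counts >= 25
  dev <- abs(h$counts[keep] - td$expected_counts[keep]) /
    sqrt(td$expected_counts[keep])
  expect_lt(mean(dev > 3), 0.01)
  expect_lt(max(dev), 5)
})

test_that("fit recovers generating parameters from a noiseless histogram", {
  m <- quantal_model(0.6, 0.08, 5, 0.3)
  h0 <- amplitude_histogram(0.01, rep(0, 400))
  td <- theoretical_distribution(m, 1000, h0)
  h <- amplitude_histogram(0.01, td$expected_counts)
  f <- fit_quantal_model(h, seed = 42)
  expect_equal(f$status, "ok")
  expect_equal(f$quantal_size, 0.6, tolerance = 1e-3 / 0.6)
  expect_equal(f$model$n, 5L)
  expect_equal(f$model$p, 0.3, tolerance = 0.02)
  expect_equal(sum(f$expected_counts), f$n_events, tolerance = 1e-3)
})

test_that("fit is invariant to appended empty bins and monotone in true q", {
  make_hist <- function(q, pad = 0) {
    m <- quantal_model(q, 0.08, 4, 0.35)
    h0 <- amplitude_histogram(0.01, rep(0, 350 + pad))
    td <- theoretical_distribution(m, 800, h0)
    amplitude_histogram(0.01, td$expected_counts)
  }
  f1 <- fit_quantal_model(make_hist(0.6), seed = 5)
  f2 <- fit_quantal_model(make_hist(0.6, pad = 80), seed = 5)
  expect_equal(f1$quantal_size, f2$quantal_size, tolerance = 1e-6)

  qs <- c(0.4, 0.5, 0.6, 0.7)
  fitted <- vapply(qs, function(q)
    fit_quantal_model(make_hist(q), seed = 5)$quantal_size, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("single dominant peak pins the quantal size to within one bin", {
  m <- quantal_model(0.55, 0.001 * 0.55, 1, 0.5)
  ev <- simulate_mepsp_events(m, 300, seed = 3)
  f <- fit_quantal_model(build_histogram(ev), seed = 3)
  expect_equal(f$quantal_size, 0.55, tolerance = 0.01 / 0.55)
})

test_that("fit refuses under-filled histograms", {
  h <- build_histogram(stats::runif(10, 0.1, 1))
  expect_error(fit_quantal_model(h), "floor")
})

test_that("mEPSP frequency is count over duration", {
  ev <- event_series(rep(0.5, 120), duration = 60)
  expect_equal(mepsp_frequency(ev), 2)
  expect_equal(mepsp_frequency(event_series(numeric(0), duration = 30)), 0)
  # concatenating two identical recordings preserves the frequency
  ev2 <- event_series(rep(0.5, 240), duration = 120)
  expect_equal(mepsp_frequency(ev2), mepsp_frequency(ev))
  expect_error(mepsp_frequency(event_series(0.5)), "duration")
})

test_that("event series validation catches malformed inputs", {
  expect_error(event_series(c(0.5, -0.1)), "> 0")
  expect_error(event_series(c(0.5, 0.6), duration = 10, times = c(5)), "length")
  expect_error(event_series(c(0.5, 0.6), duration = 10, times = c(11, 12)),
               "within")
  expect_error(event_series(c(0.5, 0.6), duration = 10, times = c(8, 4)),
               "nondecreasing")
})
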