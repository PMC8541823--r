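test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  const <- rep(5, 100)
  expect_equal(smooth_area(const), const)
  ramp <- seq(0, 10, length.out = 100)
  expect_equal(smooth_area(ramp, window = 11, polyorder = 3), ramp,
               tolerance = 1e-9)
  expect_error(smooth_area(ramp, window = 10), "odd")
  expect_error(smooth_area(ramp, window = 3, polyorder = 3), "polyorder")
  expect_error(smooth_area(rep(1, 5), window = 11), "length")
})

test_that("smoothing reduces noise on a sinusoid by at least 2x", {
  set.seed(21)
  t <- seq(0, 120, by = 1 / 12.5)
  clean <- 6 + 0.8 * sin(2 * pi * t / 6)
  noisy <- clean + stats::rnorm(length(t), sd = 0.05 * 0.8)
  sm <- smooth_area(noisy)
  expect_lt(sd(sm - clean), sd(noisy - clean) / 2)
})

test_that("wave counting finds sinusoid cycles and ignores flat series", {
  t <- seq(0, 120, length.out = 1500)
  sine <- 6 + 0.8 * sin(2 * pi * 10 * t / 120 - pi / 2)
  expect_equal(count_peristaltic_waves(sine), 10)
  expect_equal(count_peristaltic_waves(rep(4, 100)), 0)
  expect_error(count_peristaltic_waves(c(1, 2)), "short")
})

test_that("wave count is invariant under positive scaling of the area", {
  tr <- simulate_crawl(15, noise = 0.08, seed = 4)
  sm <- smooth_area(tr)
  n0 <- count_peristaltic_waves(sm)
  for (c in c(0.2, 3.7, 40)) {
    expect_equal(count_peristaltic_waves(c * sm), n0)
  }
})

test_that("synthetic crawler wave counts are recovered within one wave", {
  for (nw in c(0, 10, 23)) {
    for (seed in 1:5) {
      tr <- simulate_crawl(nw, noise = 0.10, seed = seed)
      cnt <- count_peristaltic_waves(smooth_area(tr))
      expect_lte(abs(cnt - nw), 1)
    }
  }
})

test_that("traveled distance is a Euclidean path length", {
  tr <- larva_track(x = seq(0, 20, length.out = 50), y = rep(0, 50),
                    area = rep(6, 50))
  expect_equal(traveled_distance(tr), 20)
  still <- larva_track(rep(3, 10), rep(3, 10), rep(6, 10))
  expect_equal(traveled_distance(still), 0)
  # rigid rotation preserves path length
  set.seed(8)
  x <- cumsum(stats::rnorm(200)); y <- cumsum(stats::rnorm(200))
  th <- 0.7
  rx <- cos(th) * x - sin(th) * y; ry <- sin(th) * x + cos(th) * y
  a <- rep(6, 200)
  expect_equal(traveled_distance(larva_track(x, y, a)),
               traveled_distance(larva_track(rx, ry, a)))
  bad <- larva_track(c(1, 2, 3), c(1, NaN, 3), rep(6, 3))
  expect_error(traveled_distance(bad), "frames 2")
})

test_that("stride metrics satisfy their defining identities", {
  tr <- larva_track(x = seq(0, 20, length.out = 100), y = rep(0, 100),
                    area = rep(6, 100))
  m <- stride_metrics(tr, 10, recording_time = 120)
  expect_equal(m$stride_size, 2)
  expect_equal(m$stride_size * m$n_waves, m$distance, tolerance = 1e-12)
  expect_equal(m$stride_duration * m$n_waves, 120, tolerance = 1e-12)
  m60 <- stride_metrics(tr, 60, recording_time = 120)
  expect_equal(m60$stride_duration, 2)
  # zero waves: undefined, flagged, no exception
  m0 <- stride_metrics(tr, 0, recording_time = 120)
  expect_true(m0$undefined)
  expect_true(is.na(m0$stride_size))
})

test_that("generator stride is recovered through the full chain", {
  tr <- simulate_crawl(20, stride_mm = 1.5, noise = 0.05, seed = 9)
  nw <- count_peristaltic_waves(smooth_area(tr))
  m <- stride_metrics(tr, nw, recording_time = 120)
  expect_equal(m$stride_size, 1.5, tolerance = 0.05 / 1.5)
})

test_that("body dimensions are time averages, invariant to frame order", {
  tr <- larva_track(1:4, 1:4, rep(6, 4), spine_length = c(3, 5, 3, 5),
                    width = rep(0.8, 4))
  d <- body_dimensions(tr)
  expect_equal(d$mean_length, 4)
  expect_equal(d$mean_width, 0.8)
  tr2 <- larva_track(1:4, 1:4, rep(6, 4), spine_length = c(5, 3, 5, 3),
                     width = rep(0.8, 4))
  expect_equal(body_dimensions(tr2)$mean_length, d$mean_length)
})

test_that("QC flags escape and sustained area collapse", {
  bounds <- c(0, 100, 0, 100)
  ok <- simulate_crawl(10, seed = 2)
  expect_equal(unname(qc_exclude(ok, bounds)), c(FALSE, FALSE))

  esc <- larva_track(x = seq(50, 120, length.out = 100), y = rep(50, 100),
                     area = rep(6, 100))
  expect_true(qc_exclude(esc, bounds)[["escaped"]])

  # area at 10% of median for > 2 s flags burrowing
  a <- rep(6, 500); a[200:250] <- 0.6      # 51 frames = 4 s at 12.5 fps
  bur <- larva_track(rep(50, 500), rep(50, 500), a)
  expect_true(qc_exclude(bur, bounds)[["burrowed"]])
  # a brief dip does not
  a2 <- rep(6, 500); a2[200:210] <- 0.6    # 0.9 s
  expect_false(qc_exclude(larva_track(rep(50, 500), rep(50, 500), a2),
                          bounds)[["burrowed"]])
})
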