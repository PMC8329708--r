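test_that("binning uses half-open 100 ms bins and conserves counts", {
  rs <- bin_rates(c(0.05, 0.08, 0.25), 0, 0.3)
  expect_equal(rs$counts, c(2, 0, 1))
  expect_equal(rs$rates, c(20, 0, 10))

  expect_equal(bin_rates(numeric(0), 0, 1)$counts, rep(0, 10))

  # a spike exactly on a bin edge belongs to the right (later) bin
  rs2 <- bin_rates(c(0.1), 0, 0.3)
  expect_equal(rs2$counts, c(0, 1, 0))

  set.seed(20)
  s <- runif(500, 0, 60)
  expect_equal(sum(bin_rates(s, 0, 60)$counts), 500)
})

test_that("rolling-mean smoothing preserves constants and spreads impulses", {
  const <- bin_rates(numeric(0), 0, 10)
  const$rates <- rep(7, length(const$rates))
  sm <- smooth_rates(const)
  expect_equal(sm$rates, rep(7, 100))

  imp <- rep(0, 200)
  imp[100] <- 30
  sm2 <- smooth_rates(imp, window_s = 3, bin_width_s = 0.1)
  expect_equal(sum(sm2 > 0), 30)
  expect_equal(unique(round(sm2[sm2 > 0], 12)), 1)

  # interior mean preserved by the moving average
  set.seed(21)
  r <- rpois(300, 5)
  sm3 <- smooth_rates(r, window_s = 3, bin_width_s = 0.1)
  expect_equal(mean(sm3[30:270]),
               mean(vapply(30:270, function(i) mean(r[(i - 14):(i + 15)]),
                           numeric(1))),
               tolerance = 1e-12)
})

test_that("repetition segmentation recovers the generator's bounds", {
  fl <- small_flight(n_repetitions = 2)
  seg <- segment_repetitions(fl$telemetry, start_center = c(0, 0),
                             start_radius = 10)
  expect_equal(nrow(seg), nrow(fl$repetition_bounds))
  expect_true(all(abs(seg$start_s - fl$repetition_bounds[, 1]) <= 0.02))
  expect_true(all(abs(seg$end_s - fl$repetition_bounds[, 2]) <= 0.02))
})

test_that("a single repetition yields one interval; doubling doubles them", {
  fl1 <- small_flight(1)
  seg1 <- segment_repetitions(fl1$telemetry, c(0, 0), 10)
  expect_equal(nrow(seg1), 1)
  fl2 <- small_flight(2)
  seg2 <- segment_repetitions(fl2$telemetry, c(0, 0), 10)
  expect_equal(nrow(seg2), 2)
  expect_warning(segment_repetitions(fl1$telemetry, c(1000, 1000), 10),
                 "start region")
})

test_that("sliding autocorrelation is exact on periodic series", {
  set.seed(22)
  block <- rpois(40, 6)
  series <- rep(block, 4)
  rs <- structure(list(start_t_s = 0, bin_width_s = 0.1, counts = series,
                       rates = series / 0.1,
                       t_s = (seq_along(series) - 0.5) * 0.1),
                  class = "rate_series")
  ac <- sliding_autocorrelation(rs, c(0, 4))
  at <- function(off) ac$r[which.min(abs(ac$offset_s - off))]
  expect_equal(at(0), 1)
  expect_equal(at(4), 1)
  expect_equal(at(8), 1)
  expect_error(sliding_autocorrelation(block, c(1, 200)), "longer")
})

test_that("white-noise series show only weak spurious autocorrelation", {
  for (seed in 1:5) {
    set.seed(seed)
    r <- rnorm(1400)
    ac <- sliding_autocorrelation(r, c(1, 600))
    expect_lt(max(abs(ac$r[-1])), 0.3)
  }
})

test_that("lagged cross-correlation recovers a constructed shift", {
  fl <- small_flight()
  tel <- fl$telemetry
  t1 <- max(tel$t_s)
  yaw <- bin_yaw_rate(tel, 0, t1)
  k <- 5  # +0.5 s shift
  rate <- c(rep(0, k), yaw[1:(length(yaw) - k)])
  cc <- lagged_crosscorr(rate, yaw, max_lag_s = 2)
  expect_equal(cc$peak_lag_s, 0.5, tolerance = 1e-9)
  expect_gt(cc$peak_r, 0.95)

  cc0 <- lagged_crosscorr(yaw, yaw, max_lag_s = 1)
  expect_equal(cc0$peak_lag_s, 0)
  expect_equal(cc0$peak_r, 1)
})

test_that("independent series yield negligible peak correlation", {
  set.seed(23)
  a <- rnorm(6000)
  b <- rnorm(6000)
  cc <- lagged_crosscorr(a, b, max_lag_s = 2)
  expect_lt(abs(cc$peak_r), 0.2)
})

test_that("lags with insufficient overlap are omitted", {
  a <- rnorm(30)
  b <- rnorm(30)
  cc <- lagged_crosscorr(a, b, max_lag_s = 2.5, min_overlap = 10)
  expect_true(all(abs(cc$lags_s) <= 2.0 + 1e-9))
})
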