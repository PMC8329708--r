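test_that("trefoil telemetry flies at the commanded speed", {
  fl <- small_flight()
  tel <- fl$telemetry
  path_len <- sum(sqrt(diff(tel$x_m)^2 + diff(tel$y_m)^2))
  v <- path_len / (max(tel$t_s) - min(tel$t_s))
  expect_lt(abs(v - 5.5) / 5.5, 0.01)
  expect_true(all(tel$alt_m == 15))
})

test_that("one repetition yields one bound covering the flight", {
  fl <- gen_trefoil_telemetry(feeder_xy = c(0, 50), leg_beyond_m = 30,
                              turn_radius_m = 8, turnaround_behind_m = 25,
                              n_repetitions = 1)
  expect_equal(nrow(fl$repetition_bounds), 1)
  t_end <- max(fl$telemetry$t_s)
  # bound ends at the final return into the start region, just short of
  # the landing point
  expect_lt(t_end - fl$repetition_bounds[1, 2], 5)
  expect_lt(fl$repetition_bounds[1, 1], 10)
})

test_that("yaw rate is zero on straight legs and nonzero in turns", {
  fl <- small_flight()
  tel <- fl$telemetry
  # straight approach to the feeder early in the flight
  straight <- tel$t_s > 8 & tel$t_s < 12
  expect_true(all(abs(tel$yaw_rate_rad_s[straight]) < 1e-6))
  # somewhere the copter must turn at ~speed/radius
  expect_gt(max(abs(tel$yaw_rate_rad_s)), 0.5)
  expect_lt(max(abs(tel$yaw_rate_rad_s)), 5.5 / 8 + 0.01)
})

test_that("geometry parameters are validated", {
  expect_error(gen_trefoil_telemetry(speed_m_s = -1), "positive")
  expect_error(gen_trefoil_telemetry(n_repetitions = 0), "repetitions")
})

test_that("homogeneous spike counts match the Poisson expectation", {
  tel <- straight_track(100)
  gt <- gen_spike_trains(tel, n_units = 1, baseline_rate_hz = 10,
                         rate_gain = 0, refractory_s = 0,
                         relative_refractory_s = 0, seed = 7)
  n <- length(gt$unit_spike_times[[1]])
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
})

test_that("zero rates give zero spikes and lags are validated", {
  tel <- straight_track(50)
  gt <- gen_spike_trains(tel, n_units = 2, baseline_rate_hz = 0,
                         rate_gain = 0, seed = 1)
  expect_true(all(lengths(gt$unit_spike_times) == 0))
  short <- straight_track(0.5)
  expect_error(gen_spike_trains(short, lag_s = 0.7), "lag")
})

test_that("the refractory period is enforced exactly", {
  fl <- small_flight()
  gt <- gen_spike_trains(fl$telemetry, n_units = 3, refractory_s = 0.004,
                         seed = 3)
  for (st in gt$unit_spike_times) {
    expect_true(all(diff(st) >= 0.004 - 1e-12))
    expect_true(all(diff(st) > 0))
  }
})

test_that("spike trains are reproducible from the seed", {
  tel <- straight_track(30)
  a <- gen_spike_trains(tel, seed = 11)
  b <- gen_spike_trains(tel, seed = 11)
  expect_identical(a$unit_spike_times, b$unit_spike_times)
})

test_that("binned rates regressed on lagged yaw speed recover the gain", {
  fl <- memo("flight_long", {
    gen_trefoil_telemetry(feeder_xy = c(0, 60), leg_beyond_m = 40,
                          turn_radius_m = 8, turnaround_behind_m = 30,
                          n_repetitions = 6)  # ~10 min
  })
  tel <- fl$telemetry
  t0 <- tel$t_s[1]
  t1 <- tel$t_s[nrow(tel)]
  yaw <- bin_yaw_rate(tel, t0, t1)
  for (seed in 1:5) {
    gt <- gen_spike_trains(tel, n_units = 1, baseline_rate_hz = 10,
                           rate_gain = 25, lag_s = 0.7, refractory_s = 0,
                           relative_refractory_s = 0, seed = seed)
    r <- bin_rates(gt$unit_spike_times[[1]], t0, t1)
    k <- 7  # 0.7 s = 7 bins
    n <- length(r$rates)
    fit <- stats::coef(stats::lm(r$rates[(1 + k):n] ~ yaw[1:(n - k)]))
    expect_lt(abs(fit[2] - 25) / 25, 0.2)
  }
})

test_that("noise-free recordings reproduce templates up to quantization", {
  tpl <- default_templates()[[1]]
  quiet <- noise_model(common_mode_harmonics = cbind(freq_hz = numeric(0),
                                                     amplitude = numeric(0)),
                       common_broadband_sd = 0, impulse_rate_hz = 0,
                       independent_noise_sd = 0)
  spikes <- list(c(0.1, 0.25, 0.6))
  rec <- gen_recording(spikes, list(tpl), noise = quiet,
                       channel_gains = c(1, 1), duration_s = 1, seed = 1)
  g <- 1
  d <- rec$channel_a - g * rec$channel_b  # = template * counts_per_unit
  for (ts in spikes[[1]]) {
    i0 <- round(ts * 20000) + 1
    win <- d[(i0 - 14):(i0 + 14)]
    expect_lt(max(abs(win - tpl * 1000)), 1.01)  # half-count rounding x2
  }
})

test_that("without spikes the gain-matched residual is independent noise", {
  nm <- noise_model(impulse_rate_hz = 0)
  rec <- gen_recording(list(numeric(0)), default_templates()[1],
                       noise = nm, channel_gains = c(2, 1),
                       duration_s = 5, seed = 4)
  resid <- rec$channel_a - 2 * rec$channel_b
  # expected: ind_a - 2*ind_b, sd = sqrt(5) * 0.05 * 1000 (band-limited)
  expect_lt(abs(stats::sd(resid) - sqrt(5) * 50) / (sqrt(5) * 50), 0.1)
})

test_that("recordings are byte-identical across regeneration", {
  tel <- straight_track(3)
  gt <- gen_spike_trains(tel, n_units = 1, seed = 5)
  r1 <- gen_recording(gt, default_templates()[1], telemetry = tel, seed = 6)
  r2 <- gen_recording(gt, default_templates()[1], telemetry = tel, seed = 6)
  expect_identical(r1$channel_a, r2$channel_a)
  expect_identical(r1$channel_b, r2$channel_b)
  f1 <- tempfile(fileext = ".wav")
  f2 <- tempfile(fileext = ".wav")
  write_recording(r1, f1)
  write_recording(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("terrain generation honors flatness, mask and seed", {
  flat <- gen_terrain(extent_m = 40, cell_m = 2, relief_m = 0,
                      origin_xy_m = c(0, 0), seed = 1)
  expect_true(all(flat$heights == 0))
  poly <- cbind(c(10, 30, 30, 10), c(10, 10, 30, 30))
  terr <- gen_terrain(extent_m = 40, cell_m = 2, field_polygon = poly,
                      origin_xy_m = c(0, 0), seed = 2)
  px_in <- terrain_pixel(terr, 20, 20)
  px_out <- terrain_pixel(terr, 35, 35)
  expect_true(terr$field_mask[px_in$row, px_in$col])
  expect_false(terr$field_mask[px_out$row, px_out$col])
  t2 <- gen_terrain(extent_m = 40, cell_m = 2, field_polygon = poly,
                    origin_xy_m = c(0, 0), seed = 2)
  expect_identical(terr$heights, t2$heights)
  expect_error(gen_terrain(field_polygon = cbind(c(0, 1), c(0, 1))),
               "polygon")
})

test_that("generated common-mode noise is cancelled by the differential", {
  tel <- straight_track(10)
  gt <- gen_spike_trains(tel, n_units = 1, seed = 2)
  rec <- gen_recording(gt, default_templates()[1], telemetry = tel, seed = 3)
  na <- robust_normalize(rec$channel_a)
  nb <- robust_normalize(rec$channel_b)
  g <- estimate_subtraction_gain(na, nb)
  n_diff <- robust_noise(na - g * nb)
  expect_lt(n_diff, robust_noise(na))
  expect_lt(n_diff, robust_noise(nb))
})
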