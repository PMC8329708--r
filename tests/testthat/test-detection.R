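test_that("robust noise applies the 1.4826 Gaussian consistency factor", {
  # median 0 and median absolute value 1 by construction
  x <- c(-3, -1, -1, 0, 0, 0, 1, 1, 3)
  expect_equal(robust_noise(x), 1.4826)
  expect_equal(robust_noise(rep(0, 10)), 0)
})

test_that("robust noise converges to the true sd for Gaussian data", {
  set.seed(99)
  z <- rnorm(1e6)
  expect_lt(abs(robust_noise(z) - 1), 0.01)
})

test_that("sub-threshold signals yield no detections", {
  t <- seq(0, 1, by = 1 / 20000)
  x <- 3 * sin(2 * pi * 5 * t)
  x <- x / robust_noise(x)  # robust noise exactly 1, amplitude ~2.9
  expect_equal(nrow(detect_spikes(x)), 0)
})

test_that("a single planted trough is found at its sample", {
  set.seed(5)
  x <- runif(10000, -2, 2)  # robust noise ~1.48, threshold ~5.9, no tails
  x[5000] <- -10
  ev <- detect_spikes(x)
  expect_equal(ev$sample_index, 5000)
  expect_equal(ev$trough_amplitude, -10)
  expect_equal(ev$t_s, 4999 / 20000)
})

test_that("nearby troughs are suppressed to the deeper one; separated ones kept", {
  set.seed(5)
  x <- runif(20000, -2, 2)
  # 0.5 ms apart (10 samples): within one half-width -> deeper one kept
  x[8000] <- -10
  x[8010] <- -12
  # 0.8 ms apart (16 samples): beyond the half-width -> both kept
  x[12000] <- -10
  x[12016] <- -10
  ev <- detect_spikes(x)
  expect_true(8010 %in% ev$sample_index)
  expect_false(8000 %in% ev$sample_index)
  expect_true(all(c(12000, 12016) %in% ev$sample_index))
})

test_that("detection is invariant to global scaling", {
  set.seed(6)
  x <- rnorm(50000)
  x[seq(2000, 48000, by = 1500)] <- -8
  e1 <- detect_spikes(x)
  e2 <- detect_spikes(7.3 * x)
  expect_equal(e1$sample_index, e2$sample_index)
})

test_that("waveform windows are 29 samples, trough-centered, edge-dropped", {
  x <- rep(0, 300)
  x[100] <- -10
  x[5] <- -10
  ev <- data.frame(t_s = c(4, 99) / 20000, sample_index = c(5L, 100L),
                   trough_amplitude = c(-10, -10), origin = "threshold")
  ew <- extract_waveforms(x, ev, align = FALSE)
  expect_equal(ew$n_dropped, 1)
  expect_equal(nrow(ew$waveforms), 1)
  expect_equal(ncol(ew$waveforms), 29)
  expect_equal(ew$waveforms[1, 15], -10)  # trough at the window center
  expect_equal(ew$events$sample_index, 100L)
})

test_that("the median template is robust to a gross outlier", {
  tpl <- default_templates()[[2]]
  wf <- matrix(rep(tpl, 10), nrow = 10, byrow = TRUE)
  wf[10, ] <- wf[10, ] + 50  # one corrupted waveform
  med <- median_template(wf)
  expect_equal(med, tpl)
  # per-sample brute-force oracle on random waveforms
  set.seed(2)
  wf2 <- matrix(rnorm(9 * 29), nrow = 9)
  oracle <- vapply(1:29, function(j) sort(wf2[, j])[5], numeric(1))
  expect_equal(median_template(wf2), oracle)
})

test_that("sliding Pearson correlation is exact at a planted template", {
  tpl <- default_templates()[[1]]
  x <- rep(0, 2000)
  p <- 700
  x[(p - 14):(p + 14)] <- tpl
  cc <- sliding_pearson(x, tpl)
  expect_equal(cc[p], 1.0, tolerance = 1e-12)
  # flat windows are defined as zero correlation
  expect_equal(cc[100], 0)
})

test_that("template re-detection only adds events and dedups existing ones", {
  for (seed in 1:2) {
    ac <- attenuation_chain(seed)
    expect_gte(ac$n_thr + ac$n_extra, ac$n_thr)
    expect_gte(ac$matched_all, ac$matched_thr)
  }
  # dedup: events at existing positions are not re-reported
  tpl <- default_templates()[[1]]
  set.seed(8)
  x <- runif(20000, -0.2, 0.2)
  p <- c(5000, 9000)
  for (pp in p) x[(pp - 14):(pp + 14)] <- x[(pp - 14):(pp + 14)] + 8 * tpl
  ev <- detect_spikes(x)
  expect_true(all(p %in% ev$sample_index))
  extra <- template_matching_detect(x, tpl, existing_events = ev)
  expect_true(all(abs(outer(extra$sample_index, ev$sample_index, "-")) > 40))
})

test_that("template matching recovers attenuated spikes the threshold missed", {
  for (seed in 1:2) {
    ac <- attenuation_chain(seed)
    expect_gt(ac$recall_ep_all, ac$recall_ep_thr)
  }
})
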