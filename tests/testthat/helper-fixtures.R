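# Shared fixtures, computed lazily and cached for the whole test run.
# Study-scale fixtures use a compact trefoil (feeder 72 m from the start
# corner, 48 m legs beyond it, 8 m turn radius) giving a ~2 minute flight
# per repetition at the standard 5.5 m/s.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_flight <- function(n_repetitions = 1) {
  memo(paste0("flight", n_repetitions), {
    gen_trefoil_telemetry(feeder_xy = c(0, 60), leg_beyond_m = 40,
                          turn_radius_m = 8, turnaround_behind_m = 30,
                          n_repetitions = n_repetitions)
  })
}

study_flight <- function() {
  memo("study_flight", {
    gen_trefoil_telemetry(feeder_xy = c(0, 72), leg_beyond_m = 48,
                          turn_radius_m = 8, turnaround_behind_m = 30,
                          n_repetitions = 1)
  })
}

# a 100 Hz straight-line track, cheap stand-in where flight geometry is
# irrelevant
straight_track <- function(duration_s = 100, speed = 5.5) {
  t <- seq(0, duration_s, by = 0.01)
  telemetry_track(t, x_m = speed * t, y_m = rep(0, length(t)),
                  alt_m = rep(15, length(t)), yaw_rad = rep(0, length(t)),
                  yaw_rate_rad_s = rep(0, length(t)),
                  speed_m_s = rep(speed, length(t)))
}

# full chain on the ~2 min study flight: generate -> preprocess -> detect ->
# sort; returns per-seed summaries only (big arrays are discarded)
study_chain <- function(seed) {
  memo(paste0("chain", seed), {
    fl <- study_flight()
    tel <- fl$telemetry
    gt <- gen_spike_trains(tel, n_units = 3, seed = seed)
    rec <- gen_recording(gt, default_templates(), telemetry = tel,
                         seed = seed + 100)
    na <- robust_normalize(rec$channel_a)
    nb <- robust_normalize(rec$channel_b)
    g <- estimate_subtraction_gain(na, nb)
    x <- local_robust_normalize(differential(na, nb, g))
    events <- detect_spikes(x)
    truth_all <- sort(unlist(gt$unit_spike_times))
    f1_diff <- match_spike_times(events$t_s, truth_all)$f1

    f1_raw <- vapply(list(na, nb), function(ch) {
      xr <- local_robust_normalize(ch, 20000)
      evr <- tryCatch(detect_spikes(xr), error = function(e) NULL)
      if (is.null(evr)) return(0)
      match_spike_times(evr$t_s, truth_all)$f1
    }, numeric(1))

    ew <- extract_waveforms(x, events)
    red <- pca_reduce(haar_features(ew$waveforms))
    out <- flag_outliers(red$scores)
    labels <- cluster_spikes(red$scores[!out, , drop = FALSE],
                             min_cluster_size = 100)
    units <- build_units(ew$events[!out, , drop = FALSE], labels,
                         ew$waveforms[!out, , drop = FALSE])
    truth_labels <- match_events_to_units(ew$events$t_s[!out], gt)
    ok <- !is.na(truth_labels)
    ari <- mclust::adjustedRandIndex(labels[ok], truth_labels[ok])

    # one template-matching pass per unit against the same signal
    merged_n <- nrow(events)
    all_ev <- ew$events[!out, , drop = FALSE]
    for (u in units) {
      extra <- template_matching_detect(x, u$template,
                                        existing_events = all_ev)
      merged_n <- merged_n + nrow(extra)
      if (nrow(extra)) all_ev <- rbind(all_ev, extra)
    }

    list(f1_diff = f1_diff, f1_raw = f1_raw, ari = ari,
         n_units = length(units),
         cluster_sizes = as.integer(table(labels[labels > 0])),
         isi_fractions = vapply(units, `[[`, numeric(1),
                                "fraction_isi_below_4ms"),
         n_threshold = nrow(events), n_merged = merged_n,
         threshold_used = attr(events, "threshold"))
  })
}

# recording with attenuated-amplitude spike episodes (40% of the flight at
# a quarter amplitude) and its detection summaries
attenuation_chain <- function(seed) {
  memo(paste0("atten", seed), {
    fl <- small_flight()
    tel <- fl$telemetry
    t_end <- max(tel$t_s)
    ep <- data.frame(start_s = seq(10, t_end - 12, by = 25), factor = 0.25)
    ep$end_s <- ep$start_s + 10
    gt <- gen_spike_trains(tel, n_units = 1, seed = seed)
    rec <- gen_recording(gt, default_templates()[1], telemetry = tel,
                         seed = seed + 200, attenuation_episodes = ep)
    na <- robust_normalize(rec$channel_a)
    nb <- robust_normalize(rec$channel_b)
    g <- estimate_subtraction_gain(na, nb)
    x <- local_robust_normalize(differential(na, nb, g))
    ev <- detect_spikes(x)
    ew <- extract_waveforms(x, ev)
    tpl <- median_template(ew$waveforms)
    extra <- template_matching_detect(x, tpl, existing_events = ev)
    truth <- gt$unit_spike_times[[1]]
    in_ep <- vapply(truth, function(ts) {
      any(ts >= ep$start_s & ts < ep$end_s)
    }, logical(1))
    m_thr <- match_spike_times(ev$t_s, truth)
    m_all <- match_spike_times(sort(c(ev$t_s, extra$t_s)), truth)
    m_thr_ep <- match_spike_times(ev$t_s, truth[in_ep])
    m_all_ep <- match_spike_times(sort(c(ev$t_s, extra$t_s)), truth[in_ep])
    list(n_thr = nrow(ev), n_extra = nrow(extra),
         matched_thr = m_thr$n_matched, matched_all = m_all$n_matched,
         recall_ep_thr = m_thr_ep$recall, recall_ep_all = m_all_ep$recall)
  })
}
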