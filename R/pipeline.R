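#' Pipeline configuration
#'
#' Validated configuration for the full simulate-to-map pipeline. Defaults
#' are the field-analysis values: 20 kHz sampling, threshold 4 times the
#' robust noise, 1.44 ms waveform windows, 1 s local-normalization window,
#' 1% PCA variance floor, minimum cluster size 100, 100 ms rate bins, 3 s
#' smoothing, 0.7 s injected lag. Unknown keys are rejected.
#'
#' @param ... overrides of the default keys.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    # synthetic flight
    speed_m_s = 5.5, altitude_m = 15,
    start_xy = c(0, 0), feeder_xy = c(0, 150), leg_beyond_m = 80,
    n_repetitions = 3, turn_radius_m = 10, turnaround_behind_m = 40,
    start_region_radius_m = 10, telemetry_hz = 100,
    # synthetic units and recording
    n_units = 3, baseline_rate_hz = 10, rate_gain = 25, lag_s = 0.7,
    refractory_s = 0.004, channel_gains = c(2, 1), sample_rate_hz = 20000,
    counts_per_unit = 1000,
    # preprocessing
    local_window_s = 1.0, gain_grid_max = 4, gain_grid_step = 0.01,
    # detection
    threshold_multiplier = 4, window_s = 0.00144, dedup_s = 0.002,
    # sorting
    pca_min_explained = 0.01, min_cluster_size = 100, min_samples = NULL,
    lof_neighbors = 20, lof_threshold = 1.5,
    # rates and correlation
    bin_width_s = 0.1, smooth_window_s = 3.0, max_lag_s = 3.0,
    # mapping
    make_map = FALSE, n_ommatidia = 500, turn_exclusion_rad_s = 0.3,
    terrain_cell_m = 4
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  with(cfg, {
    if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
    if (sample_rate_hz <= 0 || telemetry_hz <= 0) stop("rates must be positive")
    if (bin_width_s <= 0) stop("bin_width_s must be positive")
    if (threshold_multiplier <= 0) stop("threshold_multiplier must be positive")
    if (n_units < 1) stop("need at least one unit")
  })
  structure(cfg, class = c("pipeline_config", "list"))
}

config_fingerprint <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 10)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2^31)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, preprocess, detect, sort, rates, correlate and
#' (optionally) map with one configuration and seed, returning all
#' intermediate products plus ground-truth metrics (detection F1, sorting
#' adjusted Rand index, recovered lag). When `out_dir` is given, every
#' stage's outputs and a `metrics.json` (tagged with the config fingerprint
#' and seed) are written there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `telemetry`, `repetition_bounds`, `ground_truth`,
#'   `recording`, `clean`, `events`, `units`, `rates` (per unit),
#'   `pooled_rates`, `crosscorr` (pooled), `crosscorr_per_unit`,
#'   `autocorrelation`, `metrics`, and `map` (when enabled); invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  ## simulate -----------------------------------------------------------
  flight <- gen_trefoil_telemetry(
    speed_m_s = cfg$speed_m_s, altitude_m = cfg$altitude_m,
    start_xy = cfg$start_xy, feeder_xy = cfg$feeder_xy,
    leg_beyond_m = cfg$leg_beyond_m, n_repetitions = cfg$n_repetitions,
    turn_radius_m = cfg$turn_radius_m,
    turnaround_behind_m = cfg$turnaround_behind_m,
    start_region_radius_m = cfg$start_region_radius_m,
    sample_hz = cfg$telemetry_hz
  )
  tel <- flight$telemetry
  gt <- gen_spike_trains(tel, n_units = cfg$n_units,
                         baseline_rate_hz = cfg$baseline_rate_hz,
                         rate_gain = cfg$rate_gain, lag_s = cfg$lag_s,
                         refractory_s = cfg$refractory_s, seed = cfg$seed)
  templates <- default_templates()[seq_len(cfg$n_units)]
  if (cfg$n_units > 3) {
    templates <- c(templates, lapply(4:cfg$n_units, function(u) {
      make_spike_template(trough_width_samples = 2 + u,
                          rebound_delay_samples = 4 + u)
    }))
  }
  rec <- gen_recording(gt, templates, channel_gains = cfg$channel_gains,
                       telemetry = tel, sample_hz = cfg$sample_rate_hz,
                       counts_per_unit = cfg$counts_per_unit,
                       seed = cfg$seed + 1000L)
  session <- align(rec, tel, clock_offset_s = 0)

  ## preprocess ---------------------------------------------------------
  na <- robust_normalize(rec$channel_a)
  nb <- robust_normalize(rec$channel_b)
  g <- estimate_subtraction_gain(
    na, nb, gain_grid = seq(0, cfg$gain_grid_max, by = cfg$gain_grid_step))
  clean <- differential(na, nb, g, sample_rate_hz = cfg$sample_rate_hz)
  x <- local_robust_normalize(clean, window_s = cfg$local_window_s)

  ## detect -------------------------------------------------------------
  events <- detect_spikes(x, sample_rate_hz = cfg$sample_rate_hz,
                          multiplier = cfg$threshold_multiplier,
                          window_s = cfg$window_s)
  ew <- extract_waveforms(x, events, sample_rate_hz = cfg$sample_rate_hz,
                          window_s = cfg$window_s)

  ## sort ---------------------------------------------------------------
  feats <- haar_features(ew$waveforms)
  red <- pca_reduce(feats, min_explained = cfg$pca_min_explained)
  out_mask <- flag_outliers(red$scores, n_neighbors = cfg$lof_neighbors,
                            threshold = cfg$lof_threshold)
  core_events <- ew$events[!out_mask, , drop = FALSE]
  core_wf <- ew$waveforms[!out_mask, , drop = FALSE]
  labels <- cluster_spikes(red$scores[!out_mask, , drop = FALSE],
                           min_cluster_size = cfg$min_cluster_size,
                           min_samples = cfg$min_samples)
  units <- build_units(core_events, labels, core_wf,
                       refractory_s = cfg$refractory_s)

  ## template re-detection per unit, pooled into the unit trains --------
  all_events <- core_events
  for (u in seq_along(units)) {
    extra <- template_matching_detect(
      x, units[[u]]$template, existing_events = all_events,
      sample_rate_hz = cfg$sample_rate_hz,
      multiplier = cfg$threshold_multiplier, dedup_s = cfg$dedup_s)
    if (nrow(extra)) {
      units[[u]]$spike_times_s <- sort(c(units[[u]]$spike_times_s,
                                         extra$t_s))
      units[[u]]$isi_s <- diff(units[[u]]$spike_times_s)
      units[[u]]$fraction_isi_below_4ms <-
        mean(units[[u]]$isi_s < cfg$refractory_s)
      all_events <- rbind(all_events, extra)
    }
  }

  ## rates and correlations ---------------------------------------------
  t0 <- tel$t_s[1]
  t1 <- tel$t_s[nrow(tel)]
  rates <- lapply(units, function(u) {
    bin_rates(u$spike_times_s, t0, t1, cfg$bin_width_s)
  })
  pooled_times <- sort(unlist(lapply(units, `[[`, "spike_times_s")))
  pooled <- bin_rates(pooled_times, t0, t1, cfg$bin_width_s)
  yaw <- bin_yaw_rate(tel, t0, t1, cfg$bin_width_s)
  cc_pooled <- lagged_crosscorr(pooled, yaw, max_lag_s = cfg$max_lag_s,
                                step_s = cfg$bin_width_s)
  cc_units <- lapply(rates, function(r) {
    lagged_crosscorr(r, yaw, max_lag_s = cfg$max_lag_s,
                     step_s = cfg$bin_width_s)
  })
  auto <- sliding_autocorrelation(pooled, flight$repetition_bounds[1, ])

  ## metrics vs ground truth --------------------------------------------
  truth_all <- sort(unlist(gt$unit_spike_times))
  det <- match_spike_times(events$t_s, truth_all)
  truth_labels <- match_events_to_units(core_events$t_s, gt)
  ok <- !is.na(truth_labels)
  ari <- if (any(ok)) {
    mclust::adjustedRandIndex(labels[ok], truth_labels[ok])
  } else NA_real_
  metrics <- list(
    detection_f1 = det$f1,
    detection_precision = det$precision,
    detection_recall = det$recall,
    sorting_ari = ari,
    n_units_found = length(units),
    peak_lag_s = cc_pooled$peak_lag_s,
    peak_r = cc_pooled$peak_r,
    injected_lag_s = cfg$lag_s,
    subtraction_gain = g,
    seed = cfg$seed,
    config = config_fingerprint(cfg)
  )

  result <- list(telemetry = tel,
                 repetition_bounds = flight$repetition_bounds,
                 ground_truth = gt, recording = rec, session = session,
                 clean = clean, gain = g, events = events,
                 units = units, labels = labels, rates = rates,
                 pooled_rates = pooled, crosscorr = cc_pooled,
                 crosscorr_per_unit = cc_units, autocorrelation = auto,
                 metrics = metrics)

  ## map (optional) ------------------------------------------------------
  if (isTRUE(cfg$make_map)) {
    span_x <- range(tel$x_m) + c(-40, 40)
    span_y <- range(tel$y_m) + c(-40, 40)
    terr <- gen_terrain(extent_m = c(diff(span_x), diff(span_y)),
                        cell_m = cfg$terrain_cell_m,
                        origin_xy_m = c(span_x[1], span_y[1]),
                        seed = cfg$seed)
    eye <- build_eye_model(n_ommatidia = cfg$n_ommatidia)
    result$map <- project_rates(session, pooled, eye, terr,
                                turn_exclusion_rad_s = cfg$turn_exclusion_rad_s)
    result$terrain <- terr
  }

  if (!is.null(out_dir)) write_pipeline_outputs(result, cfg, out_dir)
  invisible(result)
}

#' Assign ground-truth unit identities to detected spike times
#'
#' Each detected time is matched to the nearest ground-truth spike within
#' `tol_s`; the matching unit's id is returned, `NA` where no truth spike is
#' close enough.
#'
#' @param detected_t detected spike times, seconds.
#' @param ground_truth a `ground_truth` object.
#' @param tol_s matching tolerance (default 1 ms).
#' @return integer vector of unit ids (NA = unmatched).
#' @export
match_events_to_units <- function(detected_t, ground_truth, tol_s = 0.001) {
  truth <- unlist(ground_truth$unit_spike_times)
  unit_of <- rep(seq_along(ground_truth$unit_spike_times),
                 lengths(ground_truth$unit_spike_times))
  o <- order(truth)
  truth <- truth[o]
  unit_of <- unit_of[o]
  if (!length(truth)) return(rep(NA_integer_, length(detected_t)))
  pos <- findInterval(detected_t, truth)
  lo <- pmax(pos, 1)
  hi <- pmin(pos + 1, length(truth))
  d_lo <- abs(detected_t - truth[lo])
  d_hi <- abs(detected_t - truth[hi])
  best <- ifelse(d_lo <= d_hi, lo, hi)
  d <- pmin(d_lo, d_hi)
  out <- unit_of[best]
  out[d > tol_s] <- NA_integer_
  out
}

write_pipeline_outputs <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_telemetry(result$telemetry, file.path(out_dir, "telemetry.csv"))
  write_recording(result$recording, file.path(out_dir, "recording.wav"))
  utils::write.csv(result$events, file.path(out_dir, "spikes.csv"),
                   row.names = FALSE)
  units_df <- do.call(rbind, lapply(result$units, function(u) {
    data.frame(t_s = u$spike_times_s, unit_id = u$unit_id)
  }))
  utils::write.csv(units_df, file.path(out_dir, "units.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(result$units, function(u) {
      list(unit_id = u$unit_id, n_spikes = length(u$spike_times_s),
           template = u$template,
           fraction_isi_below_4ms = u$fraction_isi_below_4ms)
    }),
    file.path(out_dir, "units.json"), auto_unbox = TRUE, digits = NA)
  cc <- result$crosscorr
  utils::write.csv(data.frame(lag_s = cc$lags_s, r = cc$r_at_lag),
                   file.path(out_dir, "crosscorr.csv"), row.names = FALSE)
  utils::write.csv(result$autocorrelation,
                   file.path(out_dir, "autocorrelation.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
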