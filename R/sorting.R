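#' Orthonormal Haar wavelet coefficients of spike waveforms
#'
#' Each waveform is padded to the next power of two (29 to 32 samples at
#' 20 kHz) by replicating its last sample, then decomposed with the
#' full-depth orthonormal Haar transform. All coefficients are returned
#' (final approximation first, then details from coarsest to finest), so the
#' transform conserves energy (Parseval).
#'
#' Edge replication is used rather than zero padding because a zero pad
#' would introduce a spurious step at the window edge that the coarse
#' coefficients would pick up.
#'
#' @param waveforms matrix, one waveform per row.
#' @return coefficient matrix with `2^ceiling(log2(ncol))` columns.
#' @export
haar_features <- function(waveforms) {
  if (is.null(dim(waveforms))) waveforms <- matrix(waveforms, nrow = 1)
  w <- ncol(waveforms)
  target <- 2^ceiling(log2(w))
  if (target > w) {
    pad <- waveforms[, w, drop = FALSE][, rep(1, target - w), drop = FALSE]
    waveforms <- cbind(waveforms, pad)
  }
  t(apply(waveforms, 1, haar_transform))
}

# full-depth orthonormal Haar analysis of a power-of-two length vector
haar_transform <- function(x) {
  n <- length(x)
  details <- numeric(0)
  a <- x
  while (length(a) > 1) {
    ev <- a[seq(1, length(a), by = 2)]
    od <- a[seq(2, length(a), by = 2)]
    d <- (ev - od) / sqrt(2)
    a <- (ev + od) / sqrt(2)
    details <- c(d, details)  # coarsest ends up first
  }
  c(a, details)
}

#' PCA reduction keeping components that explain at least 1% of variance
#'
#' Principal components of the feature matrix are retained while each
#' explains at least `min_explained` of the total variance; at least one
#' component is always kept. Zero-variance features are dropped before the
#' decomposition.
#'
#' @param features numeric matrix, one observation per row.
#' @param min_explained minimum explained-variance ratio per retained
#'   component (default 0.01).
#' @return list with `scores` (reduced matrix), `loadings`,
#'   `explained_ratio` (all components), `n_components`.
#' @export
pca_reduce <- function(features, min_explained = 0.01) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 observations")
  v <- apply(features, 2, stats::var)
  keep_cols <- which(v > 0)
  if (!length(keep_cols)) stop("all features have zero variance")
  p <- stats::prcomp(features[, keep_cols, drop = FALSE], center = TRUE,
                     scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  k <- max(1L, sum(ratio >= min_explained))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained_ratio = ratio,
       n_components = k)
}

#' Cluster spike features into putative units
#'
#' Runs hierarchical density-based clustering ([hdbscan_cluster()]) with a
#' minimum cluster size of 100 (the shipped default for field recordings;
#' small fixtures may lower it). Unassigned spikes are labeled `-1` (noise).
#' Cluster labels are ordered by first spike occurrence for determinism.
#'
#' @param features numeric matrix of spike features, rows in spike-time
#'   order.
#' @param min_cluster_size minimum reported cluster size.
#' @param min_samples core-distance smoothing parameter; defaults to
#'   `min_cluster_size`.
#' @return integer label vector, `-1` = noise.
#' @export
cluster_spikes <- function(features, min_cluster_size = 100,
                           min_samples = NULL) {
  hdbscan_cluster(features, min_cluster_size = min_cluster_size,
                  min_samples = min_samples)
}

#' Build sorted units from labeled spike events
#'
#' Assembles one unit per non-noise cluster label: sorted spike times, the
#' median waveform template, interspike intervals, and the fraction of ISIs
#' below 4 ms (the physiological refractory bound; values near 0 indicate
#' clean single-unit isolation).
#'
#' @param events spike-event data.frame (rows aligned with `labels`).
#' @param labels integer cluster labels from [cluster_spikes()].
#' @param waveforms optional waveform matrix aligned with `events`, used for
#'   the unit template.
#' @param refractory_s ISI hygiene bound in seconds (default 0.004).
#' @return list of `spike_unit` objects, ordered by unit id.
#' @export
build_units <- function(events, labels, waveforms = NULL,
                        refractory_s = 0.004) {
  if (nrow(events) != length(labels)) {
    stop("labels must align with events")
  }
  ids <- sort(unique(labels[labels > 0]))
  lapply(ids, function(id) {
    sel <- labels == id
    times <- sort(events$t_s[sel])
    isi <- diff(times)
    template <- if (!is.null(waveforms)) {
      median_template(waveforms[sel, , drop = FALSE])
    } else NULL
    structure(
      list(unit_id = id,
           spike_times_s = times,
           template = template,
           isi_s = isi,
           fraction_isi_below_4ms = if (length(isi)) {
             mean(isi < refractory_s)
           } else 0),
      class = "spike_unit"
    )
  })
}

#' @export
print.spike_unit <- function(x, ...) {
  cat(sprintf("spike_unit %d: %d spikes, ISI<4ms fraction %.4f\n",
              x$unit_id, length(x$spike_times_s), x$fraction_isi_below_4ms))
  invisible(x)
}
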