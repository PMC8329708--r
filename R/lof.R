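#' Local Outlier Factor scores
#'
#' Density-ratio anomaly score of Breunig et al.: for each point, the ratio
#' of its neighbors' local reachability density to its own. Scores near 1
#' indicate inlier density; scores well above 1 indicate points sitting in a
#' sparser region than their neighbors.
#'
#' @param features numeric matrix, one observation per row.
#' @param n_neighbors neighborhood size `k` (default 20).
#' @param eps distance floor applied off-diagonal so duplicate points do not
#'   produce infinite densities.
#' @return numeric vector of LOF scores, length `nrow(features)`.
#' @export
lof_scores <- function(features, n_neighbors = 20, eps = 1e-10) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < n_neighbors + 1) stop("need at least n_neighbors + 1 points")
  d <- as.matrix(stats::dist(features))
  d[d < eps] <- eps
  diag(d) <- Inf

  k <- n_neighbors
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    kd <- sort.int(di, partial = k)[k]
    kdist[i] <- kd
    nbrs[[i]] <- which(di <= kd)  # includes distance ties
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    o <- nbrs[[i]]
    reach <- pmax(kdist[o], d[i, o])
    lrd[i] <- 1 / mean(reach)
  }
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], numeric(1))
}

#' Flag outlying spikes by Local Outlier Factor
#'
#' Computes [lof_scores()] on the feature matrix and flags points whose
#' score exceeds `threshold`. Flagged spikes are excluded from clustering
#' and all downstream rate analyses.
#'
#' @param features numeric matrix of spike features (PCA scores).
#' @param n_neighbors neighborhood size (default 20).
#' @param threshold decision threshold on the LOF score (default 1.5; LOF
#'   is ~1 for inliers regardless of cluster density).
#' @return logical vector, `TRUE` where the point is flagged as an outlier.
#' @export
flag_outliers <- function(features, n_neighbors = 20, threshold = 1.5) {
  lof_scores(features, n_neighbors = n_neighbors) > threshold
}
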