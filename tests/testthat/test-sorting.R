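test_that("Haar features are orthonormal on edge-replicated waveforms", {
  # constant waveform: all detail coefficients vanish
  h <- haar_features(matrix(5, 1, 29))
  expect_equal(h[1, 1], 5 * sqrt(32))
  expect_equal(h[1, -1], rep(0, 31))

  # Parseval: energy conserved relative to the padded waveform
  set.seed(10)
  wf <- matrix(rnorm(5 * 29), nrow = 5)
  padded <- cbind(wf, wf[, 29], wf[, 29], wf[, 29])
  h <- haar_features(wf)
  expect_equal(rowSums(h^2), rowSums(padded^2), tolerance = 1e-12)

  # step at the midpoint: a single coarsest-level detail coefficient
  step <- matrix(c(rep(1, 16), rep(3, 16)), nrow = 1)
  hs <- haar_features(step)
  expect_equal(hs[1, 2], (16 - 48) / sqrt(32))
  expect_equal(hs[1, -(1:2)], rep(0, 30))

  # full transform against a direct recursive oracle
  oracle <- function(x) {
    if (length(x) == 1) return(x)
    ev <- x[seq(1, length(x), 2)]
    od <- x[seq(2, length(x), 2)]
    c(oracle((ev + od) / sqrt(2)), (ev - od) / sqrt(2))
  }
  expect_equal(h[1, ], oracle(padded[1, ]), tolerance = 1e-12)
})

test_that("PCA keeps components explaining at least 1% of variance", {
  # exactly collinear data: one component
  set.seed(11)
  t <- rnorm(50)
  line <- outer(t, seq(1, 10)) # rank 1 in 10-D
  expect_equal(pca_reduce(line)$n_components, 1)

  # isotropic 10-D Gaussian: all ten components retained
  for (seed in 1:5) {
    set.seed(seed)
    iso <- matrix(rnorm(2000 * 10), ncol = 10)
    expect_equal(pca_reduce(iso)$n_components, 10)
  }

  # two-scale data: the second direction falls below the 1% floor
  set.seed(12)
  two <- cbind(rnorm(4000, sd = 10), rnorm(4000, sd = sqrt(0.5)),
               rnorm(4000, sd = 0.01))
  expect_equal(pca_reduce(two)$n_components, 1)
})

test_that("LOF flags a far outlier and spares a uniform grid", {
  set.seed(13)
  blob <- matrix(runif(500 * 3), ncol = 3)  # tight uniform-density blob
  pts <- rbind(blob, c(100, 100, 100))
  mask <- flag_outliers(pts)
  expect_length(mask, 501)
  expect_true(mask[501])
  expect_false(any(mask[1:500]))

  grid <- as.matrix(expand.grid(x = 1:15, y = 1:15))
  expect_false(any(flag_outliers(grid)))
})

test_that("LOF scores match a brute-force implementation", {
  set.seed(14)
  pts <- matrix(rnorm(40 * 2), ncol = 2)
  k <- 5
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  kdist <- apply(d, 1, function(r) sort(r)[k])
  nbrs <- lapply(1:40, function(i) which(d[i, ] <= kdist[i]))
  lrd <- sapply(1:40, function(i) {
    1 / mean(pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]]))
  })
  ref <- sapply(1:40, function(i) mean(lrd[nbrs[[i]]]) / lrd[i])
  expect_equal(lof_scores(pts, n_neighbors = 5), ref, tolerance = 1e-12)
})

test_that("density clustering separates well-spaced blobs", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(rnorm(300 * 2), ncol = 2)
    b <- matrix(rnorm(300 * 2), ncol = 2) + 20
    X <- rbind(a, b)
    truth <- rep(1:2, each = 300)
    lab <- cluster_spikes(X, min_cluster_size = 100)
    expect_gte(mclust::adjustedRandIndex(lab, truth), 0.99)
    expect_equal(length(unique(lab[lab > 0])), 2)
  }
})

test_that("small data sets and single blobs follow the min-size contract", {
  set.seed(15)
  tiny <- matrix(rnorm(50 * 2), ncol = 2)
  expect_true(all(cluster_spikes(tiny, min_cluster_size = 100) == -1))

  one <- matrix(rnorm(300 * 2), ncol = 2)
  lab <- cluster_spikes(one, min_cluster_size = 100)
  expect_equal(length(unique(lab[lab > 0])), 1)
})

test_that("reported clusters respect the minimum size", {
  set.seed(16)
  a <- matrix(rnorm(300 * 2), ncol = 2)
  b <- matrix(rnorm(60 * 2), ncol = 2) + 20   # below the minimum size
  lab <- cluster_spikes(rbind(a, b), min_cluster_size = 100)
  sizes <- table(lab[lab > 0])
  expect_true(all(sizes >= 100))
  expect_true(all(lab[301:360] == -1))
})

test_that("outlier screening does not fragment clusters", {
  set.seed(17)
  clean <- rbind(matrix(rnorm(300 * 2), ncol = 2),
                 matrix(rnorm(300 * 2), ncol = 2) + 15)
  k_clean <- length(unique(cluster_spikes(clean, 100)[
    cluster_spikes(clean, 100) > 0]))
  outliers <- matrix(runif(40, -40, 40), ncol = 2)
  dirty <- rbind(clean, outliers)
  keep <- !flag_outliers(dirty)
  lab <- cluster_spikes(dirty[keep, , drop = FALSE], 100)
  expect_lte(length(unique(lab[lab > 0])), k_clean)
})

test_that("units carry sorted times, ISIs and the refractory fraction", {
  ev <- data.frame(t_s = c(0.0, 0.021, 0.042), sample_index = 1:3,
                   trough_amplitude = -5, origin = "threshold")
  u <- build_units(ev, c(1L, 1L, 1L))[[1]]
  expect_equal(u$isi_s, c(0.021, 0.021))
  expect_equal(u$fraction_isi_below_4ms, 0)

  single <- build_units(ev[1, ], 1L)[[1]]
  expect_length(single$isi_s, 0)
  expect_equal(single$fraction_isi_below_4ms, 0)

  # labels order by first spike time
  ev2 <- data.frame(t_s = c(0.1, 0.2, 0.3, 0.4), sample_index = 1:4,
                    trough_amplitude = -5, origin = "threshold")
  units <- build_units(ev2, c(2L, 1L, 2L, 1L))
  expect_equal(units[[1]]$unit_id, 1)
  expect_equal(units[[1]]$spike_times_s, c(0.2, 0.4))
})
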