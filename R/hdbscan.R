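#' Hierarchical density-based clustering (HDBSCAN)
#'
#' Clusters points by the HDBSCAN procedure of Campello, Moulavi & Sander:
#' mutual-reachability distances (with a core-distance smoothing parameter)
#' feed a single-linkage hierarchy, which is condensed by discarding splits
#' that shed fewer than `min_cluster_size` points, and clusters are selected
#' by maximizing stability (excess of mass). Points not inside any selected
#' cluster are labeled noise (`-1`).
#'
#' With `allow_single_cluster = TRUE` (the default here) a data set whose
#' hierarchy never splits into two viable clusters is returned as one
#' cluster rather than all noise.
#'
#' @param features numeric matrix, one observation per row.
#' @param min_cluster_size smallest cluster size that is reported (100 in
#'   the flight pipeline).
#' @param min_samples core-distance neighborhood size; defaults to
#'   `min_cluster_size`, capped at `n - 1`.
#' @param allow_single_cluster permit the root cluster to be selected.
#' @return integer vector of cluster labels, `-1` for noise; clusters are
#'   numbered `1, 2, ...` in order of first appearance in the input.
#' @export
hdbscan_cluster <- function(features, min_cluster_size = 100,
                            min_samples = NULL,
                            allow_single_cluster = TRUE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (!all(is.finite(features))) stop("features must be finite")
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
  if (n < min_cluster_size) return(rep(-1L, n))
  if (is.null(min_samples)) min_samples <- min_cluster_size
  min_samples <- min(min_samples, n - 1L)

  d <- as.matrix(stats::dist(features))
  core <- apply(d, 1, function(row) sort.int(row, partial = min_samples + 1L)[min_samples + 1L])
  mr <- pmax(d, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  labels <- condensed_tree_labels(hc, n, min_cluster_size,
                                  allow_single_cluster)
  relabel_by_first(labels)
}

# Condense the single-linkage dendrogram and select stable clusters.
# Returns integer labels (-1 noise).
condensed_tree_labels <- function(hc, n, mcs, allow_single_cluster) {
  merge <- hc$merge
  height <- hc$height
  nm <- nrow(merge)
  # subtree sizes per merge node
  size <- integer(nm)
  for (k in seq_len(nm)) {
    s <- 0L
    for (c in merge[k, ]) s <- s + if (c < 0) 1L else size[c]
    size[k] <- s
  }
  node_size <- function(c) if (c < 0) 1L else size[c]
  lambda_of <- function(h) 1 / max(h, .Machine$double.xmin)

  # enumerate leaf points under a merge-tree child (iterative)
  leaves_under <- function(c) {
    if (c < 0) return(-c)
    out <- integer(node_size(c))
    m <- 0L
    stack <- c
    while (length(stack)) {
      top <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (ch in merge[top, ]) {
        if (ch < 0) {
          m <- m + 1L
          out[m] <- -ch
        } else {
          stack <- c(stack, ch)
        }
      }
    }
    out
  }

  # condensed-tree bookkeeping
  parent <- integer(0)        # parent condensed cluster (0 = none)
  birth <- numeric(0)         # lambda at which the cluster appears
  stability <- numeric(0)
  new_cluster <- function(par, lam) {
    parent <<- c(parent, par)
    birth <<- c(birth, lam)
    stability <<- c(stability, 0)
    length(parent)
  }
  fall_cluster <- integer(n)  # condensed cluster each point falls out of
  fall_lambda <- numeric(n)

  root_id <- new_cluster(0L, 0)
  # stack of (merge node, condensed cluster id)
  stack_node <- nm
  stack_cl <- root_id
  while (length(stack_node)) {
    k <- stack_node[length(stack_node)]
    cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    lam <- lambda_of(height[k])
    ch <- merge[k, ]
    s1 <- node_size(ch[1]); s2 <- node_size(ch[2])
    big <- c(s1 >= mcs, s2 >= mcs)
    if (all(big)) {
      # true split: remaining points leave cl here, two children born
      stability[cl] <- stability[cl] + (s1 + s2) * (lam - birth[cl])
      for (j in 1:2) {
        child_cl <- new_cluster(cl, lam)
        if (ch[j] < 0) {
          # single point can never be >= mcs (mcs >= 2); unreachable
          fall_cluster[-ch[j]] <- child_cl
          fall_lambda[-ch[j]] <- lam
        } else {
          stack_node <- c(stack_node, ch[j])
          stack_cl <- c(stack_cl, child_cl)
        }
      }
    } else if (any(big)) {
      # cluster continues through the big child; small side falls out
      small <- ch[if (big[1]) 2 else 1]
      pts <- leaves_under(small)
      fall_cluster[pts] <- cl
      fall_lambda[pts] <- lam
      stability[cl] <- stability[cl] + length(pts) * (lam - birth[cl])
      stack_node <- c(stack_node, ch[if (big[1]) 1 else 2])
      stack_cl <- c(stack_cl, cl)
    } else {
      # cluster dissolves: everything left falls out here
      pts <- c(leaves_under(ch[1]), leaves_under(ch[2]))
      fall_cluster[pts] <- cl
      fall_lambda[pts] <- lam
      stability[cl] <- stability[cl] + length(pts) * (lam - birth[cl])
    }
  }

  n_cl <- length(parent)
  children <- vector("list", n_cl)
  for (c in seq_len(n_cl)) {
    if (parent[c] > 0) children[[parent[c]]] <- c(children[[parent[c]]], c)
  }
  # excess-of-mass selection, bottom-up (clusters were created parent-first,
  # so reverse id order is a valid post-order)
  selected <- logical(n_cl)
  subtree_stab <- numeric(n_cl)
  for (c in rev(seq_len(n_cl))) {
    kids <- children[[c]]
    kid_stab <- if (length(kids)) sum(subtree_stab[kids]) else 0
    can_select <- (c != root_id) || allow_single_cluster
    wins <- length(kids) == 0 || stability[c] > kid_stab
    if (can_select && wins) {
      selected[c] <- TRUE
      subtree_stab[c] <- max(stability[c], kid_stab)
      # deselect all descendants
      st <- kids
      while (length(st)) {
        x <- st[length(st)]; st <- st[-length(st)]
        selected[x] <- FALSE
        st <- c(st, children[[x]])
      }
    } else {
      subtree_stab[c] <- kid_stab
    }
  }

  # nearest selected ancestor (inclusive) of each point's fallout cluster.
  # When the *root* is the selected cluster (single-cluster case), only the
  # maximal-density core is labeled — the points that persist to the
  # root's final dissolution — following the reference implementation;
  # loosely attached points (low fallout lambda) stay noise.
  root_lambda_floor <- if (selected[root_id]) {
    max(fall_lambda[fall_cluster == root_id]) * (1 - 1e-9)
  } else {
    Inf
  }
  labels <- rep(-1L, n)
  anc_cache <- rep(NA_integer_, n_cl)
  nearest_selected <- function(c) {
    if (!is.na(anc_cache[c])) return(anc_cache[c])
    cur <- c
    found <- -1L
    while (cur > 0) {
      if (selected[cur]) {
        found <- cur
        break
      }
      cur <- parent[cur]
    }
    anc_cache[c] <<- found
    found
  }
  for (p in seq_len(n)) {
    if (fall_cluster[p] > 0) {
      sel <- nearest_selected(fall_cluster[p])
      if (sel == root_id && fall_lambda[p] < root_lambda_floor) next
      labels[p] <- sel
    }
  }
  labels
}

relabel_by_first <- function(labels) {
  ids <- unique(labels[labels > 0])
  if (!length(ids)) return(labels)
  first_seen <- vapply(ids, function(i) which(labels == i)[1], numeric(1))
  ids <- ids[order(first_seen)]
  out <- labels
  for (j in seq_along(ids)) out[labels == ids[j]] <- j
  out
}
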