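#' Density-based clustering of opsin expression phenotypes
#'
#' Clusters cells in the `(s_intensity, m_intensity)` plane with a
#' hierarchical density-based method: k-nearest-neighbour core distances
#' define a mutual-reachability distance, its single-linkage tree is condensed
#' with a minimum cluster size, and clusters are selected by excess-of-mass
#' stability. Points in no selected cluster are labelled noise (`-1`).
#' Expression phenotypes form manifolds rather than compact blobs (the
#' S-only band vs the position-dependent CEC manifold), which is exactly what
#' connecting regions of high local density handles and centroid methods do
#' not.
#'
#' Tables larger than `max_points` are subsampled for the O(n^2) tree and the
#' remaining cells are labelled by their nearest subsampled neighbour.
#'
#' @param table A cell table (or any data frame with `s_intensity` and
#'   `m_intensity`).
#' @param min_cluster_size Smallest cluster to report; default 4% of cells
#'   (at least 20).
#' @param min_samples Neighbour count for core distances.
#' @param min_split_gap Mutual-reachability scale (intensity units) below
#'   which a split never creates clusters: density dips narrower than the
#'   intensity noise scale are not phenotype boundaries.
#' @param log_scale Cluster on `log1p` intensities instead of raw (default
#'   raw).
#' @param max_points Subsample cap for the exact tree.
#' @param seed Subsampling seed.
#' @return A `cluster_result`: list with `labels` (per cell; `-1` = noise),
#'   `n_clusters`, `min_cluster_size`.
#' @examples
#' tab <- generate_cell_table(generator_params(
#'   strip_length_um = 2000, strip_width_um = 150
#' ))
#' cluster_cells(tab)$n_clusters
#' @export
cluster_cells <- function(table, min_cluster_size = NULL, min_samples = 25,
                          min_split_gap = 15, log_scale = FALSE,
                          max_points = 4000, seed = 1L) {
  n <- nrow(table)
  min_cluster_size <- min_cluster_size %||% max(20L, round(0.04 * n))
  if (min_cluster_size < 2) abort("min_cluster_size must be >= 2")
  if (n < 2 * min_cluster_size) {
    abort("need at least 2 * min_cluster_size cells to cluster")
  }
  x <- cbind(table$s_intensity, table$m_intensity)
  if (log_scale) x <- log1p(x)

  if (n > max_points) {
    withr::local_seed(as.integer(seed))
    idx <- sort(sample.int(n, max_points))
    mcs_sub <- max(2L, round(min_cluster_size * max_points / n))
    sub_labels <- hdbscan_lite(
      x[idx, , drop = FALSE], mcs_sub, min_samples, min_split_gap
    )
    labels <- as.integer(class::knn1(
      train = x[idx, , drop = FALSE], test = x,
      cl = factor(sub_labels)
    ))
    labels <- as.integer(levels(factor(sub_labels)))[labels]
  } else {
    labels <- hdbscan_lite(x, min_cluster_size, min_samples, min_split_gap)
  }
  structure(
    list(
      labels = labels,
      n_clusters = length(setdiff(unique(labels), -1L)),
      min_cluster_size = min_cluster_size
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s), %d/%d points noise (min size %d)\n",
    x$n_clusters, sum(x$labels == -1L), length(x$labels), x$min_cluster_size
  ))
  invisible(x)
}

# Exact small-n implementation: mutual-reachability single linkage, condensed
# tree, excess-of-mass selection (single-cluster solution allowed).
hdbscan_lite <- function(x, min_cluster_size, min_samples = 25,
                         min_split_gap = 0) {
  n <- nrow(x)
  k <- min(min_samples, n - 1)
  d <- as.matrix(stats::dist(x))
  core <- apply(d, 1, function(r) sort(r, partial = k + 1)[k + 1])
  mreach <- pmax(d, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")

  m <- hc$merge
  h <- pmax(hc$height, 1e-12)
  n_int <- nrow(m)
  sz <- integer(n_int)
  for (i in seq_len(n_int)) {
    sz[i] <- sum(ifelse(m[i, ] < 0, 1L, sz[pmax(m[i, ], 1L)]))
  }
  lam <- 1 / h

  # condensed clusters
  birth <- 1 / h[n_int]
  cl_parent <- c(NA_integer_)
  cl_birth <- c(birth)
  cl_stab <- c(0)
  cl_split <- c(NA_real_)
  cl_children <- list(integer(0))
  cid <- integer(n_int) # condensed cluster of each dendrogram node
  cid[n_int] <- 1L
  pt_parent <- integer(n) # condensed cluster each point was shed from

  shed <- function(node, cluster, lambda) {
    # assign all leaves under `node` as shed from `cluster`
    stack <- node
    while (length(stack) > 0) {
      nd <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (nd < 0) {
        pt_parent[-nd] <<- cluster
      } else {
        stack <- c(stack, m[nd, 1], m[nd, 2])
      }
    }
  }

  for (i in rev(seq_len(n_int))) {
    cc <- cid[i]
    if (cc == 0L) next # unreachable (handled by shed())
    left <- m[i, 1]
    right <- m[i, 2]
    s_left <- if (left < 0) 1L else sz[left]
    s_right <- if (right < 0) 1L else sz[right]
    li <- lam[i]
    if (s_left >= min_cluster_size && s_right >= min_cluster_size &&
      h[i] >= min_split_gap) {
      # true split: parent ends here, two new clusters born
      cl_stab[cc] <- cl_stab[cc] + sz[i] * (li - cl_birth[cc])
      cl_split[cc] <- li
      for (child in c(left, right)) {
        cl_parent <- c(cl_parent, cc)
        cl_birth <- c(cl_birth, li)
        cl_stab <- c(cl_stab, 0)
        cl_split <- c(cl_split, NA_real_)
        newid <- length(cl_parent)
        cl_children[[cc]] <- c(cl_children[[cc]], newid)
        cl_children[[newid]] <- integer(0)
        cid[child] <- newid # child is internal here (size >= mcs >= 2)
      }
    } else {
      for (j in 1:2) {
        child <- m[i, j]
        s_child <- if (child < 0) 1L else sz[child]
        if (s_child >= min_cluster_size) {
          cid[child] <- cc # continuation (including sub-gap splits)
        } else {
          cl_stab[cc] <- cl_stab[cc] + s_child * (li - cl_birth[cc])
          shed(child, cc, li)
        }
      }
    }
  }

  # excess-of-mass selection, children before parents (ids increase downward)
  n_cl <- length(cl_parent)
  sel <- logical(n_cl)
  sel_stab <- cl_stab
  for (cc in rev(seq_len(n_cl))) {
    kids <- cl_children[[cc]]
    if (length(kids) == 0) {
      sel[cc] <- TRUE
      next
    }
    child_sum <- sum(sel_stab[kids])
    if (child_sum > cl_stab[cc]) {
      sel[cc] <- FALSE
      sel_stab[cc] <- child_sum
    } else {
      sel[cc] <- TRUE
    }
  }
  # finalize top-down: a selected cluster masks all its descendants
  final <- logical(n_cl)
  stack <- 1L
  while (length(stack) > 0) {
    cc <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (sel[cc]) {
      final[cc] <- TRUE
    } else {
      stack <- c(stack, cl_children[[cc]])
    }
  }

  # label points by their nearest finally-selected ancestor
  new_ids <- cumsum(final)
  labels <- integer(n)
  for (p in seq_len(n)) {
    cc <- pt_parent[p]
    lab <- -1L
    while (!is.na(cc) && cc != 0L) {
      if (final[cc]) {
        lab <- as.integer(new_ids[cc])
        break
      }
      cc <- cl_parent[cc]
    }
    labels[p] <- lab
  }
  labels
}
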