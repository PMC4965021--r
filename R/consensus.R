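#' Subsampled consensus clustering
#'
#' Repeatedly draws sub-cohorts (without replacement by default), reruns the
#' full clustering procedure on each with a per-iteration derived seed, and
#' counts, for every item pair, how often both were sampled and how often
#' they landed in the same cluster. The consensus is the element-wise ratio;
#' pairs never co-sampled are missing. Items a run leaves unassigned count
#' as sampled but co-clustered with no one.
#'
#' @param data Items x features matrix: the items are what gets clustered
#'   (measures for the feature map — pass the transposed Z-matrix —
#'   participants for the body map).
#' @param subsample_size Items drawn per iteration (<= number of items).
#' @param n_iter Number of iterations (>= 2; the reference analysis uses
#'   100).
#' @param clustering_procedure Function `(data_subset, seed) -> labels`
#'   returning an integer cluster label per row of `data_subset` (`NA`
#'   allowed for unassigned).
#' @param seed Integer seed; iteration i uses `seed + i`.
#' @param with_replacement Draw subsamples with replacement instead
#'   (classical bootstrap; duplicated draws of an item collapse to one).
#' @param resample `"items"` (default): subsample the rows being clustered —
#'   the participant-map case, where each run clusters a sub-cohort.
#'   `"features"`: subsample the feature columns and recluster all items
#'   every run — the feature-map case, where measures are clustered on
#'   resampled sub-cohorts of participants, so every measure pair is
#'   co-sampled in every iteration.
#' @return An object of class `consensus_matrix`: `consensus`,
#'   `co_cluster_counts`, `co_sample_counts` (item x item), and
#'   `per_iter_n_clusters`.
#' @export
subsampled_consensus <- function(data, subsample_size, n_iter = 100,
                                 clustering_procedure, seed = 1,
                                 with_replacement = FALSE,
                                 resample = c("items", "features")) {
  data <- as.matrix(data)
  resample <- match.arg(resample)
  n <- nrow(data)
  stop_if_not_count(subsample_size, "subsample_size")
  n_pool <- if (resample == "items") n else ncol(data)
  if (subsample_size > n_pool) {
    stop("`subsample_size` exceeds the number of ",
         if (resample == "items") "items" else "feature columns", call. = FALSE)
  }
  if (!is.numeric(n_iter) || n_iter < 2) {
    stop("`n_iter` must be at least 2", call. = FALSE)
  }
  co_clust <- matrix(0, n, n)
  co_samp <- matrix(0, n, n)
  n_clusters <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    it_seed <- as.integer(seed) + it
    draw <- with_seed(it_seed, sample.int(n_pool, subsample_size,
                                          replace = with_replacement))
    draw <- sort(unique(draw))
    if (resample == "items") {
      idx <- draw
      labels <- clustering_procedure(data[idx, , drop = FALSE], it_seed)
    } else {
      idx <- seq_len(n)
      labels <- clustering_procedure(data[, draw, drop = FALSE], it_seed)
    }
    if (length(labels) != length(idx)) {
      stop("clustering_procedure returned ", length(labels),
           " labels for ", length(idx), " items", call. = FALSE)
    }
    co_samp[idx, idx] <- co_samp[idx, idx] + 1
    assigned <- !is.na(labels)
    n_clusters[it] <- length(unique(labels[assigned]))
    if (any(assigned)) {
      la <- labels[assigned]
      same <- outer(la, la, "==") * 1    # 1 where pair shares a label
      ai <- idx[assigned]
      co_clust[ai, ai] <- co_clust[ai, ai] + same
    }
    # an item always co-clusters with itself while sampled, assigned or not
    diag_idx <- cbind(idx, idx)
    co_clust[diag_idx[!assigned, , drop = FALSE]] <-
      co_clust[diag_idx[!assigned, , drop = FALSE]] + 1
  }
  consensus <- co_clust / co_samp
  consensus[co_samp == 0] <- NA_real_
  structure(list(consensus = consensus, co_cluster_counts = co_clust,
                 co_sample_counts = co_samp,
                 per_iter_n_clusters = n_clusters,
                 n_iter = n_iter, subsample_size = subsample_size),
            class = "consensus_matrix")
}

#' Intra- and inter-cluster consensus statistics
#'
#' Given a reference partition (typically the clustering of the full
#' cohort), `m(k)` is the mean consensus over all observed within-cluster-k
#' item pairs, `inter(k, l)` the mean consensus over cross pairs, and
#' `mean_intra` the unweighted mean of `m(k)` over clusters. Pairs that were
#' never co-sampled are excluded from the averages; clusters with fewer than
#' two items have undefined `m(k)` (`NA`).
#'
#' @param cmat A `consensus_matrix`.
#' @param reference Reference labels: a `cluster_assignment`, a
#'   `body_type_assignment`, or an integer vector (`NA` = unassigned) over
#'   the same items.
#' @return An object of class `consensus_stats`: `intra` (per-cluster
#'   `m(k)`), `mean_intra`, `inter` (cluster x cluster matrix, diagonal =
#'   `m(k)`), `cluster_sizes`.
#' @export
consensus_stats <- function(cmat, reference) {
  stopifnot(inherits(cmat, "consensus_matrix"))
  labels <- reference_labels(reference)
  n <- nrow(cmat$consensus)
  if (length(labels) != n) {
    stop("reference covers ", length(labels), " items; consensus matrix has ",
         n, call. = FALSE)
  }
  ks <- sort(unique(labels[!is.na(labels)]))
  k <- length(ks)
  pair_mean <- function(ii, jj, exclude_diag) {
    block <- cmat$consensus[ii, jj, drop = FALSE]
    if (exclude_diag) {
      # within-cluster: upper-triangle pairs only
      block <- block[upper.tri(block)]
    }
    if (length(block) == 0L || all(is.na(block))) NA_real_
    else mean(block, na.rm = TRUE)
  }
  inter <- matrix(NA_real_, k, k, dimnames = list(ks, ks))
  for (a in seq_len(k)) {
    ia <- which(labels == ks[a])
    inter[a, a] <- if (length(ia) >= 2L) pair_mean(ia, ia, TRUE) else NA_real_
    for (b in seq_len(k)) {
      if (b > a) {
        ib <- which(labels == ks[b])
        inter[a, b] <- inter[b, a] <- pair_mean(ia, ib, FALSE)
      }
    }
  }
  intra <- diag(inter)
  structure(list(intra = intra, mean_intra = mean(intra, na.rm = TRUE),
                 inter = inter,
                 cluster_sizes = as.integer(table(factor(labels, levels = ks)))),
            class = "consensus_stats")
}

reference_labels <- function(reference) {
  if (inherits(reference, "cluster_assignment")) reference$item_labels
  else if (inherits(reference, "body_type_assignment")) reference$labels
  else as.integer(reference)
}

#' Consensus dendrogram of clusters
#'
#' Single-linkage agglomeration of the reference clusters using
#' dissimilarity `1 - inter(k, l)`: clusters that frequently exchange items
#' across resampled runs merge low, unrelated clusters merge at height 1.
#'
#' @param stats A `consensus_stats` with a complete `inter` matrix.
#' @param labels Optional cluster display labels (e.g. body-type names).
#' @return An object of class `hclust` (merge matrix + heights in [0, 1]).
#' @export
consensus_dendrogram <- function(stats, labels = NULL) {
  stopifnot(inherits(stats, "consensus_stats"))
  d <- 1 - stats$inter
  diag(d) <- 0
  if (anyNA(d)) stop("inter-cluster consensus matrix has missing entries",
                     call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  hc$labels <- labels %||% rownames(stats$inter)
  hc
}

#' Cluster count and stability versus cohort size
#'
#' For each sub-cohort size, runs [subsampled_consensus()] and records the
#' mean and SD of the per-iteration cluster counts plus the mean
#' intra-cluster consensus against the full-data reference clustering —
#' the stability analysis asking how many clusters a cohort of a given size
#' can resolve. Also reports, per size, the Pearson correlation between the
#' reference cluster sizes and their `m(k)` (larger clusters tend to be more
#' stable).
#'
#' @param data Items x features matrix.
#' @param sizes Increasing sub-cohort sizes (each <= number of items).
#' @param n_iter Iterations per size.
#' @param clustering_procedure As in [subsampled_consensus()].
#' @param seed Integer seed; size s uses a seed derived from `seed` and the
#'   size's position.
#' @param reference Optional reference labels; default is
#'   `clustering_procedure(data, seed)` on the full data.
#' @param resample Passed to [subsampled_consensus()]; `"features"` makes
#'   `sizes` sub-cohort sizes (feature columns) while all items are
#'   reclustered each run.
#' @return An object of class `stability_curve`: data frame with one row per
#'   size (`size`, `mean_n_clusters`, `sd_n_clusters`, `mean_intra`,
#'   `size_consensus_cor`, `n_iterations`).
#' @export
stability_vs_size <- function(data, sizes, n_iter = 100,
                              clustering_procedure, seed = 1,
                              reference = NULL,
                              resample = c("items", "features")) {
  data <- as.matrix(data)
  resample <- match.arg(resample)
  n_pool <- if (resample == "items") nrow(data) else ncol(data)
  stopifnot(!is.unsorted(sizes, strictly = TRUE), all(sizes <= n_pool))
  if (is.null(reference)) {
    reference <- clustering_procedure(data, as.integer(seed))
  } else {
    reference <- reference_labels(reference)
  }
  rows <- lapply(seq_along(sizes), function(i) {
    cmat <- subsampled_consensus(data, sizes[i], n_iter, clustering_procedure,
                                 seed = stage_seed(seed, paste0("size", sizes[i])),
                                 resample = resample)
    st <- consensus_stats(cmat, reference)
    r <- if (length(st$intra) >= 3L && stats::sd(st$cluster_sizes) > 0 &&
             stats::sd(st$intra, na.rm = TRUE) > 0) {
      stats::cor(st$cluster_sizes, st$intra, use = "complete.obs")
    } else NA_real_
    data.frame(size = sizes[i],
               mean_n_clusters = mean(cmat$per_iter_n_clusters),
               sd_n_clusters = stats::sd(cmat$per_iter_n_clusters),
               mean_intra = st$mean_intra,
               size_consensus_cor = r,
               n_iterations = n_iter)
  })
  structure(do.call(rbind, rows), class = c("stability_curve", "data.frame"))
}
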