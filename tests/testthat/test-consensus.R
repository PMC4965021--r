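# deterministic clustering by sign of the first feature
sign_procedure <- function(x, seed) as.integer(x[, 1] > 0) + 1L

test_that("a stable procedure on separated data gives a 0/1 consensus matrix", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, -5), 20, 2), matrix(rnorm(40, 5), 20, 2))
  cm <- subsampled_consensus(x, subsample_size = 30, n_iter = 10,
                             sign_procedure, seed = 3)
  vals <- cm$consensus[!is.na(cm$consensus)]
  expect_true(all(vals %in% c(0, 1)))
  within1 <- cm$consensus[1:20, 1:20]
  expect_true(all(within1[!is.na(within1)] == 1))
})

test_that("subsample_size = N with a deterministic procedure gives exact 0/1 and mean_intra 1", {
  set.seed(2)
  x <- rbind(matrix(rnorm(30, -4), 15, 2), matrix(rnorm(30, 4), 15, 2))
  cm <- subsampled_consensus(x, subsample_size = 30, n_iter = 5,
                             sign_procedure, seed = 1)
  expect_true(all(cm$co_sample_counts == 5))
  expect_true(all(cm$consensus %in% c(0, 1)))
  st <- consensus_stats(cm, sign_procedure(x, 0))
  expect_identical(st$mean_intra, 1)
  expect_true(all(st$inter[upper.tri(st$inter)] == 0))
})

test_that("consensus counts equal brute-force pair counting over recorded runs", {
  n <- 4
  base_seed <- 100
  # reconstruct the per-iteration samples the implementation will draw
  draws <- lapply(1:3, function(it) {
    s <- base_seed + it
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(s)
    idx <- sort(unique(sample.int(n, 3)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    idx
  })
  # hand-chosen labelings per iteration (keyed by derived seed), with one
  # unassigned item in run 2
  label_book <- list(`101` = c(1L, 1L, 2L), `102` = c(1L, NA, 1L),
                     `103` = c(2L, 1L, 1L))
  proc <- function(x, seed) label_book[[as.character(seed)]]
  data <- matrix(seq_len(n * 2), n, 2)
  cm <- subsampled_consensus(data, subsample_size = 3, n_iter = 3, proc,
                             seed = base_seed)
  # brute-force oracle
  co_s <- matrix(0, n, n); co_c <- matrix(0, n, n)
  for (it in 1:3) {
    idx <- draws[[it]]
    lab <- label_book[[as.character(base_seed + it)]]
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      co_s[idx[a], idx[b]] <- co_s[idx[a], idx[b]] + 1
      same <- if (a == b) TRUE else
        (!is.na(lab[a]) && !is.na(lab[b]) && lab[a] == lab[b])
      if (same) co_c[idx[a], idx[b]] <- co_c[idx[a], idx[b]] + 1
    }
  }
  expect_equal(cm$co_sample_counts, co_s)
  expect_equal(cm$co_cluster_counts, co_c)
  expect_equal(cm$consensus, ifelse(co_s == 0, NA, co_c / co_s))
})

test_that("consensus matrix invariants hold across random runs", {
  set.seed(9)
  x <- matrix(rnorm(25 * 3), 25, 3)
  noisy <- function(xx, seed) {
    set.seed(seed)
    sample(1:3, nrow(xx), replace = TRUE)
  }
  cm <- subsampled_consensus(x, 15, n_iter = 12, noisy, seed = 7)
  expect_equal(cm$consensus, t(cm$consensus))
  expect_true(all(cm$co_cluster_counts <= cm$co_sample_counts))
  sampled <- diag(cm$co_sample_counts) > 0
  expect_true(all(diag(cm$consensus)[sampled] == 1))
  v <- cm$consensus[!is.na(cm$consensus)]
  expect_true(all(v >= 0 & v <= 1))
  expect_error(subsampled_consensus(x, 15, n_iter = 1, noisy), "at least 2")
  expect_error(subsampled_consensus(x, 26, n_iter = 5, noisy), "exceeds")
})

test_that("feature-mode resampling keeps all items co-sampled every run", {
  set.seed(4)
  x <- matrix(rnorm(12 * 30), 12, 30)
  proc <- function(xx, seed) rep(1:2, each = 6)
  cm <- subsampled_consensus(x, subsample_size = 20, n_iter = 4, proc,
                             seed = 2, resample = "features")
  expect_true(all(cm$co_sample_counts == 4))
  expect_true(all(cm$consensus[1:6, 1:6] == 1))
  expect_true(all(cm$consensus[1:6, 7:12] == 0))
})

test_that("consensus statistics match hand-computed pair means", {
  cons <- matrix(c(
    1.0, 0.8, 0.6, 0.1, 0.2,
    0.8, 1.0, 0.4, 0.0, 0.3,
    0.6, 0.4, 1.0, 0.2, 0.1,
    0.1, 0.0, 0.2, 1.0, 0.9,
    0.2, 0.3, 0.1, 0.9, 1.0), 5, 5)
  cm <- structure(list(consensus = cons,
                       co_cluster_counts = cons * 10,
                       co_sample_counts = matrix(10, 5, 5),
                       per_iter_n_clusters = rep(2L, 10),
                       n_iter = 10, subsample_size = 5),
                  class = "consensus_matrix")
  ref <- c(1L, 1L, 1L, 2L, 2L)
  st <- consensus_stats(cm, ref)
  expect_equal(unname(st$intra), c(mean(c(0.8, 0.6, 0.4)), 0.9))
  expect_equal(unname(st$inter[1, 2]),
               mean(c(0.1, 0.2, 0.0, 0.3, 0.2, 0.1)))
  expect_equal(st$mean_intra, mean(c(0.6, 0.9)))
  expect_identical(st$cluster_sizes, c(3L, 2L))
  # single-item cluster has undefined m(k)
  st2 <- consensus_stats(cm, c(1L, 1L, 1L, 1L, 2L))
  expect_true(is.na(st2$intra[2]))
})

test_that("the consensus dendrogram agrees with hand single-linkage", {
  inter <- matrix(c(1.0, 0.8, 0.1,
                    0.8, 1.0, 0.2,
                    0.1, 0.2, 1.0), 3, 3,
                  dimnames = list(1:3, 1:3))
  st <- structure(list(intra = diag(inter), mean_intra = 1, inter = inter,
                       cluster_sizes = c(5L, 5L, 5L)),
                  class = "consensus_stats")
  hc <- consensus_dendrogram(st, labels = c("a", "b", "c"))
  # first merge: the 0.8 pair at height 1 - 0.8 = 0.2; then single linkage
  # attaches c at 1 - max(0.1, 0.2) = 0.8
  expect_equal(hc$height, c(0.2, 0.8))
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
  # 2-cluster input merges once at 1 - inter
  inter2 <- matrix(c(1, 0.35, 0.35, 1), 2, 2, dimnames = list(1:2, 1:2))
  st2 <- structure(list(intra = c(1, 1), mean_intra = 1, inter = inter2,
                        cluster_sizes = c(3L, 3L)),
                   class = "consensus_stats")
  expect_equal(consensus_dendrogram(st2)$height, 0.65)
  # all-zero inter: every merge at height 1
  inter3 <- diag(3); dimnames(inter3) <- list(1:3, 1:3)
  st3 <- structure(list(intra = c(1, 1, 1), mean_intra = 1, inter = inter3,
                        cluster_sizes = c(2L, 2L, 2L)),
                   class = "consensus_stats")
  expect_true(all(consensus_dendrogram(st3)$height == 1))
})

test_that("stability at full size with a deterministic procedure has zero spread", {
  set.seed(3)
  x <- rbind(matrix(rnorm(30, -4), 15, 2), matrix(rnorm(30, 4), 15, 2))
  curve <- stability_vs_size(x, sizes = 30, n_iter = 5, sign_procedure,
                             seed = 2)
  expect_equal(curve$sd_n_clusters, 0)
  expect_equal(curve$mean_n_clusters, 2)
  expect_equal(curve$mean_intra, 1)
})
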