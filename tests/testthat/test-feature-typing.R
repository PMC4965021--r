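test_that("a flat distance map yields a single cluster holding every item", {
  dmap <- fake_dmap(rep(0.3, 16), 4, 4)
  bmu <- c(1, 5, 9, 16, 7)
  asg <- detect_clusters(dmap, bmu)
  expect_identical(asg$n_clusters, 1L)
  expect_true(all(asg$item_labels == 1L))
})

test_that("two basins split by a ridge match the flood-fill oracle", {
  # 6x6 map: columns 0-2 low (0.1), column 3 high ridge (1.0), columns 4-5 low
  vals <- rep(0.1, 36)
  ridge_units <- which((seq_len(36) - 1) %% 6 == 3)
  vals[ridge_units] <- 1.0
  dmap <- fake_dmap(vals, 6, 6)
  # items on both sides of the ridge
  left_units <- c(1, 8, 14, 20)     # cols 0-2
  right_units <- c(5, 12, 18, 29)   # cols 4-5
  bmu <- c(left_units, right_units)
  asg <- detect_clusters(dmap, bmu, theta = 0.10)
  expect_identical(asg$n_clusters, 2L)
  # flood-fill oracle: connected components of sub-ridge units
  low <- which(vals < 0.5)
  comp <- rep(NA_integer_, 36)
  nextc <- 0
  for (s in low) {
    if (!is.na(comp[s])) next
    nextc <- nextc + 1
    queue <- s; comp[s] <- nextc
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1) %/% 6; c <- (cur - 1) %% 6
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 0 && rr < 6 && cc >= 0 && cc < 6) {
          u <- rr * 6 + cc + 1
          if (u %in% low && is.na(comp[u])) {
            comp[u] <- nextc; queue <- c(queue, u)
          }
        }
      }
    }
  }
  oracle <- comp[bmu]
  expect_identical(ari(asg$item_labels, oracle), 1)
})

test_that("singleton pruning dissolves small clusters and renumbers", {
  asg <- fake_assignment(item_labels = c(1, 1, 1, 2, 3, 3),
                         item_units = 1:6, width = 3, height = 2)
  out <- prune_singletons(asg, min_members = 2)
  expect_identical(out$n_clusters, 2L)
  expect_identical(out$cluster_sizes, c(3L, 2L))
  expect_identical(sum(is.na(out$item_labels)), 1L)
  # min_members = 1 is the identity
  out1 <- prune_singletons(asg, min_members = 1)
  expect_identical(out1$item_labels, asg$item_labels)
  expect_error(prune_singletons(asg, min_members = 10), "below")
})

test_that("meta-measure aggregation equals per-cluster means", {
  vals <- cbind(a = c(1, 3), b = c(3, 5), c = c(3, 5), d = c(10, 20))
  tab <- measure_table(vals, data.frame(height = c(170, 160)))
  # clusters {a,b} and {c,d}; units chosen so {a,b} sits top (A), {c,d} right (B)
  asg <- fake_assignment(item_labels = c(1L, 1L, 2L, 2L),
                         item_units = c(2, 2, 6, 6), width = 3, height = 3)
  meta <- aggregate_meta_measures(tab, asg)
  expect_identical(colnames(meta$values), c("A", "B"))
  expect_equal(unname(meta$values[, "A"]), c(2, 4))
  expect_equal(unname(meta$values[, "B"]), c(6.5, 12.5))
  expect_identical(meta$members$A, c("a", "b"))
  # duplicated measure aggregates to itself
  vals2 <- cbind(m1 = c(1, 2, 3), m1b = c(1, 2, 3))
  tab2 <- measure_table(vals2, data.frame(height = rep(170, 3)))
  asg2 <- fake_assignment(c(1L, 1L), c(1, 1), 2, 2)
  expect_equal(unname(aggregate_meta_measures(tab2, asg2)$values[, 1]),
               c(1, 2, 3))
})

test_that("aggregation matches a brute-force group-mean oracle and commutes with reordering", {
  set.seed(13)
  vals <- matrix(rnorm(8 * 10), 8, 10,
                 dimnames = list(NULL, paste0("m", 1:10)))
  tab <- measure_table(vals, data.frame(height = rep(170, 8)))
  labels <- c(1L, 2L, 1L, 3L, 2L, 3L, 1L, NA, 2L, 3L)
  units <- c(2, 6, 2, 8, 6, 8, 2, 5, 6, 8)
  asg <- fake_assignment(labels, units, 3, 3)
  meta <- aggregate_meta_measures(tab, asg)
  for (k in 1:3) {
    oracle <- rowMeans(vals[, which(labels == k), drop = FALSE])
    found <- vapply(seq_len(3), function(j) {
      all(abs(meta$values[, j] - oracle) < 1e-12)
    }, logical(1))
    expect_identical(sum(found), 1L)
  }
  expect_identical(meta$singletons_excluded, "m8")
  # conservation: members + singletons = all measures
  expect_identical(sort(c(unlist(meta$members, use.names = FALSE),
                          meta$singletons_excluded)),
                   sort(colnames(vals)))
  # participant reordering commutes
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  tabp <- measure_table(vals[perm, ], data.frame(height = rep(170, 8)))
  metap <- aggregate_meta_measures(tabp, asg)
  expect_equal(unname(metap$values), unname(meta$values[perm, ]))
})

test_that("meta-measure labels follow clockwise order from 12 o'clock", {
  # 5x5 map, center (2,2): clusters at top, right, bottom, left
  top <- 3      # (0, 2)
  right <- 15   # (2, 4)
  bottom <- 23  # (4, 2)
  left <- 11    # (2, 0)
  vals <- matrix(rnorm(4 * 8), 4, 8,
                 dimnames = list(NULL, paste0("m", 1:8)))
  tab <- measure_table(vals, data.frame(height = rep(170, 4)))
  asg <- fake_assignment(item_labels = rep(c(3L, 1L, 4L, 2L), each = 2),
                         item_units = rep(c(bottom, top, left, right), each = 2),
                         width = 5, height = 5)
  meta <- aggregate_meta_measures(tab, asg)
  # clockwise from the top: top (A), right (B), bottom (C), left (D)
  members_by_letter <- vapply(meta$members, function(m) m[1], character(1))
  expect_identical(unname(members_by_letter[c("A", "B", "C", "D")]),
                   c("m3", "m7", "m1", "m5"))
})

test_that("row Z-normalization centers and scales each participant profile", {
  meta <- fake_meta(rbind(c(1, 2, 3), c(10, 20, 30)))
  out <- z_normalize_rows(meta)
  expect_equal(unname(out$values[1, ]), c(-1, 0, 1))
  expect_true(all(abs(rowMeans(out$values)) < 1e-12))
  expect_true(all(abs(apply(out$values, 1, stats::sd) - 1) < 1e-12))
  set.seed(5)
  m2 <- fake_meta(matrix(rnorm(20, 3, 2), 4, 5))
  o2 <- z_normalize_rows(m2)
  oracle <- t(apply(m2$values, 1, function(r) (r - mean(r)) / stats::sd(r)))
  expect_equal(unname(o2$values), unname(oracle))
  # constant profile errors with the participant named
  m3 <- fake_meta(rbind(P1 = c(1, 2, 3), P2 = c(4, 4, 4)))
  rownames(m3$values) <- c("P1", "P2")
  expect_error(z_normalize_rows(m3), "P2")
})

test_that("feature typing recovers planted measure blocks", {
  p <- prep_cohort(seed = 31, n = 800, k = 4)
  det <- p$fm$assignment$item_labels
  truth <- p$truth_measure
  keep <- !is.na(truth) & !is.na(det)
  expect_gte(ari(truth[keep], det[keep]), 0.9)
  # member-count conservation through the whole feature stage
  expect_identical(length(unlist(p$fm$meta$members)) +
                     length(p$fm$meta$singletons_excluded),
                   ncol(p$norm$values))
})
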