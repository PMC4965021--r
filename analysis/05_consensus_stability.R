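#!/usr/bin/env Rscript
# Consensus clustering and stability: rerun the body typing on resampled
# sub-cohorts, compute intra-/inter-cluster consensus, build the
# single-linkage consensus dendrogram of body types, and trace cluster count
# and stability as a function of sub-cohort size.

library(bodysom)

seed <- 1
n_iter <- 20
norm <- read_measure_table("results/cohort_normalized.csv")
meta_df <- utils::read.csv("results/meta_measures.csv", check.names = FALSE)
rowz <- z_normalize_rows(as_meta_measure_table(meta_df[-1], norm$covariates))

typing <- assign_body_types(rowz, 60, 60, seed = stage_seed(seed, "body_som"))
typing <- label_by_gender(typing, norm$covariates$gender)

body_proc <- function(x, it_seed) {
  som <- som_train(x, 60, 60, som_schedule(final_radius = 10), seed = it_seed)
  asg <- detect_clusters(distance_map(som), best_matching_units(som, x),
                         theta = 0.1)
  asg <- tryCatch(prune_singletons(asg, max(2L, ceiling(0.01 * nrow(x)))),
                  error = function(e) NULL)
  if (is.null(asg)) rep(NA_integer_, nrow(x)) else asg$item_labels
}

cat(sprintf("consensus over %d sub-cohorts of 80%% of the cohort ...\n", n_iter))
cmat <- subsampled_consensus(rowz$values,
                             subsample_size = floor(0.8 * nrow(rowz$values)),
                             n_iter = n_iter, body_proc,
                             seed = stage_seed(seed, "consensus"))
st <- consensus_stats(cmat, typing)
cat(sprintf("mean intra-cluster consensus <m(k)> = %.3f\n", st$mean_intra))
utils::write.csv(
  data.frame(type = typing$type_names, n = st$cluster_sizes,
             m_k = round(st$intra, 4)),
  "results/consensus_intra.csv", row.names = FALSE)
utils::write.csv(round(st$inter, 4), "results/consensus_inter.csv")

hc <- consensus_dendrogram(st, labels = typing$type_names)
utils::write.csv(
  data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
             height = round(hc$height, 4)),
  "results/consensus_dendrogram.csv", row.names = FALSE)
cat("first dendrogram merge at height", round(hc$height[1], 3), "\n")

cat("stability versus sub-cohort size ...\n")
stab_proc <- function(x, it_seed) {
  som <- som_train(x, 40, 40, som_schedule(final_radius = 40 / 6),
                   seed = it_seed)
  asg <- detect_clusters(distance_map(som), best_matching_units(som, x),
                         theta = 0.1)
  asg <- tryCatch(prune_singletons(asg, max(2L, ceiling(0.01 * nrow(x)))),
                  error = function(e) NULL)
  if (is.null(asg)) rep(NA_integer_, nrow(x)) else asg$item_labels
}
curve <- stability_vs_size(rowz$values, c(400, 900, 1600), n_iter = 8,
                           stab_proc, seed = stage_seed(seed, "stability"),
                           reference = typing)
print(curve, digits = 3)
utils::write.csv(curve, "results/stability_curve.csv", row.names = FALSE)
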