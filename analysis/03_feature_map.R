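#!/usr/bin/env Rscript
# Feature map: train a SOM on the measures (items = measures, features =
# participants), detect U-matrix watershed clusters, exclude singleton
# measures and aggregate the survivors into per-participant meta-measures.
# Compares the detected measure clusters against the planted blocks.

library(bodysom)

seed <- 1
norm <- read_measure_table("results/cohort_normalized.csv")
fm <- feature_typing(norm, 30, 30, seed = stage_seed(seed, "feature_som"))
print(fm$assignment)
print(fm$meta)

truth <- utils::read.csv("results/truth_measures.csv")
det <- fm$assignment$item_labels
truth_block <- truth$true_block[match(colnames(norm$values), truth$measure)]
keep <- !is.na(truth_block) & !is.na(det)
cat(sprintf("\nadjusted Rand index vs planted blocks (assigned measures): %.3f\n",
            mclust::adjustedRandIndex(truth_block[keep], det[keep])))

utils::write.csv(
  data.frame(measure = unlist(fm$meta$members),
             meta_measure = rep(names(fm$meta$members),
                                lengths(fm$meta$members))),
  "results/measure_clusters.csv", row.names = FALSE)
utils::write.csv(
  data.frame(participant_id = norm$covariates$participant_id,
             fm$meta$values, check.names = FALSE),
  "results/meta_measures.csv", row.names = FALSE)
grid <- bodysom:::unit_grid(fm$dmap$width, fm$dmap$height)
utils::write.csv(
  data.frame(row = grid[, "row"], col = grid[, "col"],
             distance = fm$dmap$values),
  "results/feature_umatrix.csv", row.names = FALSE)
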