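#!/usr/bin/env Rscript
# Atlas outputs: mean bodygrams for the gender / age / weight strata and for
# each body type, body-map stainings by mean age and BMI, and tertile maps
# of every meta-measure.

library(bodysom)

seed <- 1
norm <- read_measure_table("results/cohort_normalized.csv")
meta_df <- utils::read.csv("results/meta_measures.csv", check.names = FALSE)
meta <- as_meta_measure_table(meta_df[-1], norm$covariates)
rowz <- z_normalize_rows(meta)
typing <- assign_body_types(rowz, 60, 60, seed = stage_seed(seed, "body_som"))
typing <- label_by_gender(typing, norm$covariates$gender)

cov <- norm$covariates
med_age <- stats::median(cov$age)
strata <- list(
  all = NULL,
  female = function(cv) cv$gender == "F",
  male = function(cv) cv$gender == "M",
  young_female = function(cv) cv$gender == "F" & cv$age < med_age,
  old_female = function(cv) cv$gender == "F" & cv$age >= med_age,
  young_male = function(cv) cv$gender == "M" & cv$age < med_age,
  old_male = function(cv) cv$gender == "M" & cv$age >= med_age,
  light_female = function(cv) cv$gender == "F" &
    cv$weight < stats::median(cv$weight[cv$gender == "F"]),
  heavy_female = function(cv) cv$gender == "F" &
    cv$weight >= stats::median(cv$weight[cv$gender == "F"]),
  light_male = function(cv) cv$gender == "M" &
    cv$weight < stats::median(cv$weight[cv$gender == "M"]),
  heavy_male = function(cv) cv$gender == "M" &
    cv$weight >= stats::median(cv$weight[cv$gender == "M"]))

bg_rows <- do.call(rbind, lapply(names(strata), function(s) {
  bg <- mean_bodygram(meta, strata[[s]], stratum = s)
  data.frame(stratum = s, axis = bg$axis_order,
             radius = round(bg$radii, 4), n = bg$n)
}))
# per-body-type mean bodygrams
bg_types <- do.call(rbind, lapply(seq_len(typing$n_types), function(t) {
  sel <- !is.na(typing$labels) & typing$labels == t
  bg <- mean_bodygram(meta, sel, stratum = typing$type_names[t])
  data.frame(stratum = bg$stratum, axis = bg$axis_order,
             radius = round(bg$radii, 4), n = bg$n)
}))
utils::write.csv(rbind(bg_rows, bg_types), "results/bodygrams.csv",
                 row.names = FALSE)
cat(sprintf("wrote %d bodygrams (%d strata + %d body types)\n",
            length(strata) + typing$n_types, length(strata), typing$n_types))

idx <- cohort_indices(norm)
grid <- expand.grid(col = 0:59, row = 0:59)[, 2:1]
overlays <- list(age = cov$age, bmi = idx$bmi, whtr = idx$whtr,
                 absi = idx$absi)
ov_rows <- do.call(rbind, lapply(names(overlays), function(nm) {
  ov <- stain_map(typing$bmu, overlays[[nm]], 60, 60)
  keep <- ov$n > 0
  data.frame(characteristic = nm, row = grid$row[keep], col = grid$col[keep],
             mean_value = round(ov$values[keep], 4), n = ov$n[keep])
}))
utils::write.csv(ov_rows, "results/map_overlays.csv", row.names = FALSE)

tert_rows <- do.call(rbind, lapply(colnames(meta$values), function(mm) {
  ov <- tertile_map(meta, mm, typing$bmu, 60, 60)
  keep <- ov$n > 0
  data.frame(meta_measure = mm, row = grid$row[keep], col = grid$col[keep],
             tertile = ov$values[keep], n = ov$n[keep])
}))
utils::write.csv(tert_rows, "results/tertile_maps.csv", row.names = FALSE)
cat(sprintf("wrote stainings for %d characteristics and %d tertile maps\n",
            length(overlays), ncol(meta$values)))
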