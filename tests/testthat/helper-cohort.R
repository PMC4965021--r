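# Shared builders for test cohorts and hand-made pipeline objects.

# Small gender-balanced cohort with k planted body-type components, run
# through preprocessing; returns the stages most tests need.
prep_cohort <- function(seed, n = 600, k = 4, separation = 5,
                        feature_grid = 20, affinity = rep(0.5, k), ...) {
  cfg <- cohort_config(n_participants = n, n_body_types = k,
                       body_type_gender_affinity = affinity,
                       component_separation = separation,
                       missing_rate_background = 0.001, seed = seed, ...)
  ch <- generate_cohort(cfg)
  filt <- filter_missing(ch$table)
  norm <- z_normalize_columns(height_normalize(filt$table))
  fm <- feature_typing(norm, feature_grid, feature_grid, seed = seed + 100)
  keep <- match(rownames(norm$values), ch$table$covariates$participant_id)
  list(cohort = ch, norm = norm, fm = fm,
       rowz = z_normalize_rows(fm$meta),
       truth_body = ch$truth_body_type[keep],
       truth_measure = ch$truth_block_of_measure[colnames(norm$values)])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Hand-made distance_map over a width x height lattice (row-major values).
fake_dmap <- function(values, width, height, neighborhood = 4L) {
  structure(list(values = values, width = width, height = height,
                 neighborhood = neighborhood), class = "distance_map")
}

# Hand-made cluster_assignment (for label/aggregation tests).
fake_assignment <- function(item_labels, item_units, width, height,
                            unit_labels = NULL) {
  item_labels <- as.integer(item_labels)
  k <- length(unique(item_labels[!is.na(item_labels)]))
  structure(list(unit_labels = unit_labels %||% integer(width * height),
                 item_labels = item_labels, item_units = item_units,
                 n_clusters = k,
                 cluster_sizes = tabulate(item_labels, nbins = k),
                 width = width, height = height),
            class = "cluster_assignment")
}

# Hand-made body_type_assignment over n participants.
fake_typing <- function(labels, n_types = length(unique(stats::na.omit(labels)))) {
  structure(list(labels = labels, bmu = NULL, assignment = NULL,
                 som = NULL, dmap = NULL, n_types = n_types,
                 type_sizes = tabulate(labels, nbins = n_types),
                 min_size_used = 1L, type_names = NULL),
            class = "body_type_assignment")
}

# Hand-made meta_measure_table.
fake_meta <- function(values, covariates = NULL) {
  if (is.null(colnames(values))) colnames(values) <- LETTERS[seq_len(ncol(values))]
  structure(list(values = values,
                 members = stats::setNames(as.list(colnames(values)), colnames(values)),
                 singletons_excluded = character(0),
                 covariates = covariates %||%
                   data.frame(height = rep(170, nrow(values))),
                 axis_order = colnames(values)),
            class = "meta_measure_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
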