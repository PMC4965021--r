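#' Aggregate measure clusters into meta-measures
#'
#' Each meta-measure is the per-participant arithmetic mean of its member
#' measures (taken on the Z-normalized scale, so the result is in cohort-SD
#' units). Meta-measures are labelled "A", "B", ... following clockwise
#' order in the feature map: clusters are sorted by the angle of their
#' member-BMU centroid around the map center, starting at 12 o'clock.
#'
#' @param z_table A column-Z-normalized [measure_table()].
#' @param assignment A `cluster_assignment` over the measures of `z_table`
#'   (items = measures, in column order).
#' @return An object of class `meta_measure_table`: `values` (participants x
#'   meta-measures, columns named "A", "B", ...), `members` (named list of
#'   constituent measure names per meta-measure), `singletons_excluded`
#'   (measure names left unassigned), `covariates`, and `axis_order`.
#' @export
aggregate_meta_measures <- function(z_table, assignment) {
  stopifnot(inherits(z_table, "measure_table"),
            inherits(assignment, "cluster_assignment"))
  p <- ncol(z_table$values)
  if (length(assignment$item_labels) != p) {
    stop("assignment covers ", length(assignment$item_labels),
         " items but the table has ", p, " measures", call. = FALSE)
  }
  k <- assignment$n_clusters
  if (k == 0L) stop("assignment contains no clusters", call. = FALSE)
  sizes <- tabulate(assignment$item_labels, nbins = k)
  if (any(sizes == 0L)) stop("empty cluster(s): ",
                             paste(which(sizes == 0L), collapse = ", "),
                             call. = FALSE)

  ord <- clockwise_order(assignment)
  letters_k <- make.unique(rep(LETTERS, length.out = k), sep = "")
  meta_names <- letters_k[seq_len(k)]

  vals <- matrix(NA_real_, nrow(z_table$values), k,
                 dimnames = list(rownames(z_table$values), meta_names))
  members <- vector("list", k)
  for (pos in seq_len(k)) {
    cl <- ord[pos]
    cols <- which(assignment$item_labels == cl)
    vals[, pos] <- rowMeans(z_table$values[, cols, drop = FALSE])
    members[[pos]] <- colnames(z_table$values)[cols]
  }
  names(members) <- meta_names
  structure(list(values = vals,
                 members = members,
                 singletons_excluded = colnames(z_table$values)[is.na(assignment$item_labels)],
                 covariates = z_table$covariates,
                 axis_order = meta_names),
            class = "meta_measure_table")
}

# Cluster order by clockwise angle (from 12 o'clock) of the member-item BMU
# centroid around the lattice center.
clockwise_order <- function(assignment) {
  grid <- unit_grid(assignment$width, assignment$height)
  cx <- (assignment$width - 1) / 2
  cy <- (assignment$height - 1) / 2
  ang <- vapply(seq_len(assignment$n_clusters), function(cl) {
    units <- assignment$item_units[which(assignment$item_labels == cl)]
    dr <- mean(grid[units, "row"]) - cy     # down is +row
    dc <- mean(grid[units, "col"]) - cx
    (atan2(dc, -dr)) %% (2 * pi)            # 0 at top, increasing clockwise
  }, numeric(1))
  order(ang)
}

#' Z-normalize each participant's meta-measure profile
#'
#' Centers and scales each participant's row of meta-measures to mean 0 and
#' sample SD 1 across the meta-measures, removing additive offsets so the
#' body map clusters on profile shape rather than overall size.
#'
#' @param meta A `meta_measure_table` with at least 2 meta-measures.
#' @return The row-Z-normalized `meta_measure_table`.
#' @export
z_normalize_rows <- function(meta) {
  stopifnot(inherits(meta, "meta_measure_table"))
  if (ncol(meta$values) < 2L) stop("need at least 2 meta-measures per participant",
                                   call. = FALSE)
  mu <- rowMeans(meta$values)
  sd <- apply(meta$values, 1, stats::sd)
  zero <- sd < .Machine$double.eps^0.5
  if (any(zero)) {
    stop("zero-variance meta-measure profiles for participant(s): ",
         paste(rownames(meta$values)[zero], collapse = ", "), call. = FALSE)
  }
  out <- meta
  out$values <- (meta$values - mu) / sd
  out
}

#' Feature-map stage: cluster measures into meta-measures
#'
#' Runs the full feature-typing stage on a preprocessed (height- and
#' column-Z-normalized) table: trains a SOM on the measures (items =
#' measures, features = participants), computes the U-matrix, detects
#' watershed clusters, drops clusters below `min_members` measures
#' (singletons by default), and aggregates the survivors into the
#' per-participant meta-measure table.
#'
#' @param z_table Column-Z-normalized [measure_table()].
#' @param width,height Feature-map lattice size (the reference analysis uses
#'   50 x 50; smaller maps suit smaller measure sets).
#' @param schedule A [som_schedule()].
#' @param seed Integer seed.
#' @param theta Watershed ridge-merge threshold (see [detect_clusters()]).
#' @param min_members Minimum measures per retained cluster (default 2).
#' @return A list of class `feature_map`: `som`, `dmap`, `assignment`
#'   (pruned), `meta` (a `meta_measure_table`).
#' @export
feature_typing <- function(z_table, width = 50, height = 50,
                           schedule = som_schedule(), seed = 1,
                           theta = 0.10, min_members = 2L) {
  stopifnot(inherits(z_table, "measure_table"))
  items <- t(z_table$values)          # measures as items
  som <- som_train(items, width, height, schedule, seed)
  dmap <- distance_map(som)
  bmu <- best_matching_units(som, items)
  asg <- detect_clusters(dmap, bmu, theta = theta,
                         item_names = colnames(z_table$values))
  asg <- prune_singletons(asg, min_members = min_members)
  meta <- aggregate_meta_measures(z_table, asg)
  structure(list(som = som, dmap = dmap, assignment = asg, meta = meta),
            class = "feature_map")
}

#' @export
print.meta_measure_table <- function(x, ...) {
  cat(sprintf("meta_measure_table: %d participants x %d meta-measures (%s); %d singleton measures excluded\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(x$members), lengths(x$members)),
                    collapse = " "),
              length(x$singletons_excluded)))
  invisible(x)
}

#' Assemble a meta-measure table from precomputed values
#'
#' Builds a `meta_measure_table` from an existing participants x
#' meta-measures matrix (e.g. re-read from a written artifact or a deposited
#' summary file), when the cluster membership bookkeeping is not needed.
#'
#' @param values Numeric matrix, participants x meta-measures, with column
#'   names.
#' @param covariates Per-participant covariate data frame.
#' @param members Optional named list of constituent measures per column.
#' @param singletons_excluded Optional character vector of excluded
#'   measures.
#' @return A `meta_measure_table`.
#' @export
as_meta_measure_table <- function(values, covariates, members = NULL,
                                  singletons_excluded = character(0)) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("`values` needs column names", call. = FALSE)
  structure(list(values = values,
                 members = members %||%
                   stats::setNames(as.list(colnames(values)), colnames(values)),
                 singletons_excluded = singletons_excluded,
                 covariates = covariates,
                 axis_order = colnames(values)),
            class = "meta_measure_table")
}
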