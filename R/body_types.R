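#' Body-map stage: cluster participants into body types
#'
#' Trains a participant SOM ("body map") on the row-Z-normalized
#' meta-measure profiles, detects watershed clusters on its U-matrix, and
#' dissolves clusters smaller than the minimum-size rule: a body type must
#' contain at least `ceil(min_fraction * N)` participants (1% of the cohort
#' by default), or `min_count` if that absolute floor is supplied and
#' larger. Participants of dissolved clusters — and of basins without a
#' surviving cluster — are unassigned.
#'
#' @param meta A row-Z-normalized `meta_measure_table` (see
#'   [z_normalize_rows()]).
#' @param width,height Body-map lattice size (the reference analysis uses
#'   130 x 130 for ~8,500 participants; scale down with the cohort).
#' @param schedule A [som_schedule()]; the default (`NULL`) uses a
#'   neighborhood radius decaying to `max(width, height) / 6` rather than to
#'   1. On high-dimensional profile data a tightly converged map folds into
#'   the within-cluster noise and the U-matrix loses its border ridges; the
#'   wide final neighborhood keeps the codebook sheet smooth inside
#'   participant clouds so that watershed basins follow the between-cloud
#'   structure.
#' @param seed Integer seed.
#' @param min_fraction Minimum cluster size as a fraction of the cohort
#'   (default 0.01).
#' @param min_count Optional absolute minimum participant count overriding
#'   the fraction when larger (the reference analysis used 85 at N = 8,499).
#' @param theta Watershed ridge-merge threshold.
#' @return An object of class `body_type_assignment`: `labels`
#'   (per-participant integer type id, `NA` = unassigned), `bmu` (data frame
#'   from [best_matching_units()]), `assignment` (unit-level
#'   `cluster_assignment`), `som`, `dmap`, `n_types`, `type_sizes`,
#'   `min_size_used`, and `type_names` (filled by [label_by_gender()]).
#' @export
assign_body_types <- function(meta, width = 130, height = 130,
                              schedule = NULL, seed = 1,
                              min_fraction = 0.01, min_count = NULL,
                              theta = 0.10) {
  stopifnot(inherits(meta, "meta_measure_table"))
  schedule <- schedule %||% som_schedule(final_radius = max(width, height) / 6)
  x <- meta$values
  if (anyNA(x)) stop("meta-measure table must be complete", call. = FALSE)
  n <- nrow(x)
  min_size <- as.integer(max(ceiling(min_fraction * n), min_count %||% 0L))

  som <- som_train(x, width, height, schedule, seed)
  dmap <- distance_map(som)
  bmu <- best_matching_units(som, x)
  asg <- detect_clusters(dmap, bmu, theta = theta, item_names = rownames(x))
  asg <- tryCatch(prune_singletons(asg, min_members = min_size),
                  error = function(e) stop("no body-type cluster reaches the minimum size of ",
                                           min_size, " participants", call. = FALSE))
  structure(list(labels = asg$item_labels, bmu = bmu, assignment = asg,
                 som = som, dmap = dmap,
                 n_types = asg$n_clusters, type_sizes = asg$cluster_sizes,
                 min_size_used = min_size, type_names = NULL),
            class = "body_type_assignment")
}

#' Label body types by gender composition
#'
#' A type is female-specific (`F*`) if its female fraction is at least
#' `majority_threshold`, male-specific (`M*`) if its male fraction is, and
#' mixed (`B*`) otherwise. Within each letter group, types are numbered by
#' descending size.
#'
#' @param typing A `body_type_assignment`.
#' @param gender Per-participant gender, `"F"`/`"M"` (length = cohort size).
#' @param majority_threshold Gender fraction required to call a type
#'   gender-specific (default 0.8).
#' @return The `body_type_assignment` with `type_names` (per-type labels
#'   like `"F1"`), `participant_type` (per-participant character label or
#'   `NA`), and `female_fraction` filled in.
#' @export
label_by_gender <- function(typing, gender, majority_threshold = 0.8) {
  stopifnot(inherits(typing, "body_type_assignment"))
  gender <- as.character(gender)
  if (length(gender) != length(typing$labels)) {
    stop("`gender` must have one entry per participant", call. = FALSE)
  }
  stop_if_not_proportion(majority_threshold, "majority_threshold")
  k <- typing$n_types
  frac_f <- vapply(seq_len(k), function(t) {
    g <- gender[which(typing$labels == t)]
    mean(g == "F")
  }, numeric(1))
  letter <- ifelse(frac_f >= majority_threshold, "F",
                   ifelse(1 - frac_f >= majority_threshold, "M", "B"))
  nm <- character(k)
  for (l in unique(letter)) {
    idx <- which(letter == l)
    idx <- idx[order(-typing$type_sizes[idx])]
    nm[idx] <- paste0(l, seq_along(idx))
  }
  typing$type_names <- nm
  typing$female_fraction <- frac_f
  typing$participant_type <- ifelse(is.na(typing$labels), NA_character_,
                                    nm[typing$labels])
  typing
}

#' Summarize body types
#'
#' Per-type cohort share, gender split, mean +/- SD of age and height, and
#' banded distributions of the classical indices: BMI classes (<18.5,
#' 18.5-25, 25-30, >30), WHtR classes (<0.4, 0.4-0.5, 0.5-0.6, >0.6), and
#' cohort-wide tertiles of WHR and ABSI.
#'
#' @param typing A `body_type_assignment` (after [label_by_gender()] if type
#'   names are wanted).
#' @param covariates Per-participant data frame with `gender`, `age`,
#'   `height`.
#' @param indices Per-participant data frame from [cohort_indices()].
#' @return A list with `summary` (one row per type) and `bands` (long data
#'   frame of per-type index-band counts).
#' @export
summarize_body_types <- function(typing, covariates, indices) {
  stopifnot(inherits(typing, "body_type_assignment"))
  n <- length(typing$labels)
  k <- typing$n_types
  nm <- typing$type_names %||% as.character(seq_len(k))
  whr_cuts <- stats::quantile(indices$whr, c(1, 2) / 3, type = 2)
  absi_cuts <- stats::quantile(indices$absi, c(1, 2) / 3, type = 2)

  rows <- lapply(seq_len(k), function(t) {
    sel <- which(typing$labels == t)
    data.frame(
      type = nm[t], n = length(sel),
      pct_of_cohort = 100 * length(sel) / n,
      n_female = sum(covariates$gender[sel] == "F"),
      n_male = sum(covariates$gender[sel] == "M"),
      mean_age = mean(covariates$age[sel]),
      sd_age = stats::sd(covariates$age[sel]),
      mean_height = mean(covariates$height[sel]),
      sd_height = stats::sd(covariates$height[sel]),
      mean_bmi = mean(indices$bmi[sel]),
      mean_whr = mean(indices$whr[sel]),
      mean_whtr = mean(indices$whtr[sel]),
      mean_absi = mean(indices$absi[sel]),
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)

  band_count <- function(t, what, breaks, labels) {
    sel <- which(typing$labels == t)
    cls <- cut(what[sel], breaks = breaks, labels = labels,
               include.lowest = TRUE, right = TRUE)
    as.data.frame(table(cls), stringsAsFactors = FALSE)
  }
  bands <- do.call(rbind, lapply(seq_len(k), function(t) {
    b1 <- band_count(t, indices$bmi, c(-Inf, 18.5, 25, 30, Inf),
                     c("<18.5", "18.5-25", "25-30", ">30"))
    b1$index <- "bmi"
    b2 <- band_count(t, indices$whtr, c(-Inf, 0.4, 0.5, 0.6, Inf),
                     c("<0.4", "0.4-0.5", "0.5-0.6", ">0.6"))
    b2$index <- "whtr"
    b3 <- band_count(t, indices$whr, c(-Inf, whr_cuts, Inf),
                     c("T1", "T2", "T3"))
    b3$index <- "whr"
    b4 <- band_count(t, indices$absi, c(-Inf, absi_cuts, Inf),
                     c("T1", "T2", "T3"))
    b4$index <- "absi"
    out <- rbind(b1, b2, b3, b4)
    out$type <- nm[t]
    out
  }))
  names(bands)[names(bands) == "cls"] <- "band"
  names(bands)[names(bands) == "Freq"] <- "count"
  list(summary = summary, bands = bands[c("type", "index", "band", "count")],
       n_unassigned = sum(is.na(typing$labels)))
}

#' @export
print.body_type_assignment <- function(x, ...) {
  nm <- x$type_names %||% as.character(seq_len(x$n_types))
  cat(sprintf("body_type_assignment: %d types on a %d x %d map (min size %d); %d of %d participants unassigned\n",
              x$n_types, x$assignment$width, x$assignment$height,
              x$min_size_used, sum(is.na(x$labels)), length(x$labels)))
  cat("  ", paste(sprintf("%s:%d", nm, x$type_sizes), collapse = " "), "\n")
  invisible(x)
}
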