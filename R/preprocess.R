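#' Three-stage missing-value filtering
#'
#' Applies, in this fixed order: (1) remove participants whose missing
#' fraction across measures exceeds `participant_threshold`; (2) remove
#' measures whose missing fraction — computed on the participants that
#' survived stage 1 — exceeds `measure_threshold`; (3) remove every remaining
#' participant that still has at least one missing value. The output table
#' has no missing cells. The stage order matters and is part of the
#' procedure's definition: measure missing-fractions are evaluated only
#' after grossly incomplete participants are gone.
#'
#' @param table A [measure_table()].
#' @param participant_threshold Stage-1 missing-fraction threshold (default
#'   0.5).
#' @param measure_threshold Stage-2 missing-fraction threshold (default
#'   0.05).
#' @return A list with `table` (filtered, complete) and `report` (class
#'   `preprocess_report`: per-stage removal counts, remaining dimensions,
#'   and the input's total missing cell count).
#' @export
filter_missing <- function(table, participant_threshold = 0.5,
                           measure_threshold = 0.05) {
  stopifnot(inherits(table, "measure_table"))
  stop_if_not_proportion(participant_threshold, "participant_threshold", open = TRUE)
  stop_if_not_proportion(measure_threshold, "measure_threshold", open = TRUE)
  m <- is.na(table$values)
  n0 <- nrow(m); p0 <- ncol(m)
  total_missing <- sum(m)

  keep1 <- rowMeans(m) <= participant_threshold
  if (!any(keep1)) stop("stage 1 (participant filter) removed all participants",
                        call. = FALSE)
  m1 <- m[keep1, , drop = FALSE]

  keep2 <- colMeans(m1) <= measure_threshold
  if (!any(keep2)) stop("stage 2 (measure filter) removed all measures",
                        call. = FALSE)
  m2 <- m1[, keep2, drop = FALSE]

  keep3 <- rowSums(m2) == 0
  if (!any(keep3)) stop("stage 3 (complete-case filter) removed all participants",
                        call. = FALSE)

  vals <- table$values[keep1, keep2, drop = FALSE][keep3, , drop = FALSE]
  cov <- table$covariates[keep1, , drop = FALSE][keep3, , drop = FALSE]
  rownames(cov) <- NULL
  out <- measure_table(vals, cov, measure_kind = table$measure_kind[keep2])
  report <- structure(list(
    n_participants_removed_stage1 = sum(!keep1),
    n_measures_removed_stage2 = sum(!keep2),
    n_participants_removed_stage3 = sum(!keep3),
    remaining_P = ncol(vals),
    remaining_N = nrow(vals),
    input_P = p0,
    input_N = n0,
    total_missing_cells = total_missing,
    removed_measures = colnames(table$values)[!keep2]
  ), class = "preprocess_report")
  list(table = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(paste0(
    "preprocess_report: %d missing cells in %d x %d input\n",
    "  stage 1 removed %d participants (>50%% missing by default)\n",
    "  stage 2 removed %d measures\n",
    "  stage 3 removed %d incomplete participants\n",
    "  remaining: %d participants x %d measures\n"),
    x$total_missing_cells, x$input_N, x$input_P,
    x$n_participants_removed_stage1, x$n_measures_removed_stage2,
    x$n_participants_removed_stage3, x$remaining_N, x$remaining_P))
  invisible(x)
}

#' Divide each participant's measures by their body height
#'
#' Adjusts for overall body size under the assumption that body shape scales
#' linearly with height; the result is dimensionless shape (height is taken
#' in the same unit as the measures, cm/cm). By default every measure is
#' divided, including angles and weight; `exempt_kinds` allows the physically
#' cleaner option of leaving e.g. angle measures untouched.
#'
#' @param table A complete [measure_table()] (no missing cells).
#' @param exempt_kinds Character vector of measure kinds to leave unscaled
#'   (default none).
#' @return The height-normalized `measure_table`; covariates unchanged.
#' @export
height_normalize <- function(table, exempt_kinds = character(0)) {
  stopifnot(inherits(table, "measure_table"))
  if (anyNA(table$values)) stop("height_normalize requires a complete table; run filter_missing first",
                                call. = FALSE)
  h <- table$covariates$height
  if (any(h <= 0)) stop("all heights must be positive", call. = FALSE)
  scale_col <- !(table$measure_kind %in% exempt_kinds)
  vals <- table$values
  vals[, scale_col] <- vals[, scale_col, drop = FALSE] / h
  measure_table(vals, table$covariates, measure_kind = table$measure_kind)
}

#' Z-normalize each measure across participants
#'
#' Centers every measure column to its cohort mean and scales to unit sample
#' standard deviation (denominator N - 1), putting all measures on a common
#' scale of cohort SD units.
#'
#' @param table A complete [measure_table()] with at least 2 participants.
#' @return The column-Z-normalized `measure_table`.
#' @export
z_normalize_columns <- function(table) {
  stopifnot(inherits(table, "measure_table"))
  if (anyNA(table$values)) stop("z_normalize_columns requires a complete table",
                                call. = FALSE)
  if (nrow(table$values) < 2L) stop("need at least 2 participants", call. = FALSE)
  mu <- colMeans(table$values)
  sd <- apply(table$values, 2, stats::sd)
  zero <- sd < .Machine$double.eps^0.5
  if (any(zero)) {
    stop("zero-variance measures cannot be Z-normalized: ",
         paste(colnames(table$values)[zero], collapse = ", "), call. = FALSE)
  }
  vals <- sweep(sweep(table$values, 2, mu), 2, sd, "/")
  measure_table(vals, table$covariates, measure_kind = table$measure_kind)
}

#' Classical body shape indices
#'
#' BMI = weight / height^2 (kg/m^2); WHR = waist / hip; WHtR = waist /
#' height; ABSI = waist / (BMI^(2/3) * height^(1/2)) with waist and height in
#' metres, the body shape index of Krakauer & Krakauer that normalizes waist
#' circumference for BMI and height.
#'
#' @param weight_kg Weight in kg.
#' @param height_m Height in metres.
#' @param waist_m Waist circumference in metres.
#' @param hip_m Hip circumference in metres.
#' @return A data frame with columns `bmi`, `whr`, `whtr`, `absi`
#'   (vectorized over the inputs).
#' @export
compute_indices <- function(weight_kg, height_m, waist_m, hip_m) {
  args <- list(weight_kg = weight_kg, height_m = height_m,
               waist_m = waist_m, hip_m = hip_m)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] <= 0)) {
      stop("`", nm, "` must be positive and finite", call. = FALSE)
    }
  }
  bmi <- weight_kg / height_m^2
  data.frame(
    bmi = bmi,
    whr = waist_m / hip_m,
    whtr = waist_m / height_m,
    absi = waist_m / (bmi^(2 / 3) * sqrt(height_m))
  )
}

#' Indices for every participant of a cohort table
#'
#' Convenience wrapper computing [compute_indices()] from the `weight`,
#' `height`, `waist` and `hip` covariates (cm converted to metres).
#'
#' @param table A [measure_table()] whose covariates include `weight` (kg),
#'   `height`, `waist`, `hip` (cm).
#' @return Data frame of per-participant `bmi`, `whr`, `whtr`, `absi`.
#' @export
cohort_indices <- function(table) {
  cov <- table$covariates
  need <- c("weight", "height", "waist", "hip")
  miss <- setdiff(need, names(cov))
  if (length(miss)) stop("covariates lack: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  compute_indices(cov$weight, cov$height / 100, cov$waist / 100, cov$hip / 100)
}
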