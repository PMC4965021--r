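#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a large adult population cohort measured by a 3D body
#' scanner: ~140 measures organised into 13 correlated blocks plus 11
#' uncorrelated singleton measures, participants drawn from a gender-linked
#' mixture of 15 body-shape components, gender-specific height and weight
#' marginals (men 176 +/- 7 cm, 86 +/- 14 kg; women 165 +/- 7 cm,
#' 71 +/- 14 kg), ages uniform over 40-79 years, and missing values planted
#' at participant-, measure- and background level so that all three
#' preprocessing filters have work to do.
#'
#' @param n_participants Cohort size.
#' @param n_blocks Number of planted correlated measure blocks (latent
#'   factors).
#' @param measures_per_block Integer vector of block sizes (length
#'   `n_blocks`); defaults to sizes between 2 and 27 summing to 129.
#' @param n_singleton_measures Number of unstructured noise measures (planted
#'   singletons), default 11.
#' @param n_body_types Number of mixture components ("true" body types).
#' @param gender_fraction_female Marginal probability of female gender.
#' @param body_type_gender_affinity Per-component probability that a member
#'   is female; length `n_body_types`. Default: components split into mostly
#'   female, mostly male and two mixed components, mirroring the F/M/B
#'   structure of real cohorts.
#' @param component_separation Distance between component centres in latent
#'   factor SD units (0 = indistinguishable components).
#' @param within_block_correlation Target correlation among measures of one
#'   block, in (0,1).
#' @param noise_sd SD of the measure-specific noise in latent units.
#' @param height_mean_by_gender,height_sd_by_gender Named numeric vectors
#'   (`F`, `M`), cm.
#' @param weight_mean_by_gender,weight_sd_by_gender Named numeric vectors
#'   (`F`, `M`), kg.
#' @param missing_rate_background Background MCAR cell missingness rate.
#' @param missing_rate_bad_participants Cell missingness rate within the
#'   planted bad participants (> 0.5 so the 50% participant filter can fire).
#' @param missing_rate_bad_measures Cell missingness rate within the planted
#'   bad measures (> 0.05 so the 5% measure filter can fire).
#' @param n_bad_participants,n_bad_measures How many rows / columns get
#'   elevated missingness.
#' @param age_range Two-element vector, uniform age range in years.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 5000,
                          n_blocks = 13,
                          measures_per_block = c(27, 18, 14, 12, 11, 10, 9, 8, 6, 5, 4, 3, 2),
                          n_singleton_measures = 11,
                          n_body_types = 15,
                          gender_fraction_female = 0.515,
                          body_type_gender_affinity = NULL,
                          component_separation = 5,
                          within_block_correlation = 0.8,
                          noise_sd = 1,
                          height_mean_by_gender = c(F = 165, M = 176),
                          height_sd_by_gender = c(F = 7, M = 7),
                          weight_mean_by_gender = c(F = 71, M = 86),
                          weight_sd_by_gender = c(F = 14, M = 14),
                          missing_rate_background = 0.005,
                          missing_rate_bad_participants = 0.6,
                          missing_rate_bad_measures = 0.08,
                          n_bad_participants = max(1L, round(0.005 * n_participants)),
                          n_bad_measures = 6,
                          age_range = c(40, 79),
                          seed = 1) {
  cfg <- mget(names(formals()))
  stop_if_not_count(n_participants, "n_participants")
  stop_if_not_count(n_blocks, "n_blocks")
  stop_if_not_count(measures_per_block, "measures_per_block", min = 2L)
  if (length(measures_per_block) != n_blocks) {
    stop("`measures_per_block` must have length `n_blocks`", call. = FALSE)
  }
  stop_if_not_count(n_singleton_measures, "n_singleton_measures", min = 0L)
  stop_if_not_count(n_body_types, "n_body_types")
  stop_if_not_proportion(gender_fraction_female, "gender_fraction_female")
  if (is.null(body_type_gender_affinity)) {
    body_type_gender_affinity <- default_gender_affinity(n_body_types)
  }
  stop_if_not_proportion(body_type_gender_affinity, "body_type_gender_affinity")
  if (length(body_type_gender_affinity) != n_body_types) {
    stop("`body_type_gender_affinity` must have length `n_body_types`", call. = FALSE)
  }
  if (!is.numeric(component_separation) || component_separation < 0) {
    stop("`component_separation` must be >= 0", call. = FALSE)
  }
  stop_if_not_proportion(within_block_correlation, "within_block_correlation",
                         open = TRUE)
  stopifnot(noise_sd > 0)
  for (nm in c("missing_rate_background", "missing_rate_bad_participants",
               "missing_rate_bad_measures")) {
    stop_if_not_proportion(get(nm), nm)
  }
  stop_if_not_count(n_bad_participants, "n_bad_participants", min = 0L)
  stop_if_not_count(n_bad_measures, "n_bad_measures", min = 0L)
  p_total <- sum(measures_per_block) + n_singleton_measures
  if (n_bad_measures > p_total) {
    stop("`n_bad_measures` exceeds the total number of measures", call. = FALSE)
  }
  if (n_bad_participants > n_participants) {
    stop("`n_bad_participants` exceeds `n_participants`", call. = FALSE)
  }
  cfg$body_type_gender_affinity <- body_type_gender_affinity
  cfg$p_total <- p_total
  structure(cfg, class = "cohort_config")
}

# Mostly-female, mostly-male and mixed components in rough proportion to a
# 6 F / 7 M / 2 B split, recycled to any component count.
default_gender_affinity <- function(k) {
  base <- c(rep(0.95, ceiling(k * 6 / 15)),
            rep(0.05, ceiling(k * 7 / 15)),
            rep(0.50, k))
  base[seq_len(k)]
}

#' Generate a synthetic anthropometric cohort
#'
#' Deterministic given the config seed. Generative model, per participant:
#' gender is drawn first; the body-type component is drawn conditional on
#' gender through the component gender affinities; a latent factor vector
#' (one factor per measure block) is the component centre plus unit-variance
#' Gaussian noise; each measure of block b mixes factor b with independent
#' noise so that the within-block correlation matches the configured target,
#' is mapped to a measure-specific location/scale in cm, and is finally
#' multiplied by the participant's height relative to the cohort mean height
#' (so the height normalization of the preprocessing stage is non-trivial).
#' Component centres sit at the vertices of a regular simplex scaled by
#' `component_separation`, so each component shifts its signature latent
#' factor by about `component_separation` SD units relative to the others
#' (all pairwise centre distances equal, `component_separation * sqrt(2)`);
#' when the component count exceeds `n_blocks + 1` (where no regular simplex
#' exists) centres fall back to seeded random unit directions at comparable
#' pairwise separation. Height and weight come from gender-specific normals; waist and
#' hip are affine transforms of the first two latent factors so that WHR and
#' WHtR vary with component. Missingness is MCAR: a background rate over all
#' cells plus elevated rates on planted bad rows and bad columns.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `table` (a
#'   [measure_table()] with planted `NA`s), `truth_block_of_measure` (named
#'   integer; `NA` for singleton measures), `truth_body_type` (integer per
#'   participant) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  c2 <- config
  with_seed(c2$seed, {
    n <- c2$n_participants
    b <- c2$n_blocks
    k <- c2$n_body_types

    gender <- ifelse(stats::runif(n) < c2$gender_fraction_female, "F", "M")
    aff <- c2$body_type_gender_affinity
    comp <- vapply(gender, function(g) {
      w <- if (g == "F") aff else 1 - aff
      if (sum(w) == 0) w <- rep(1, k)
      sample.int(k, 1L, prob = w)
    }, integer(1L), USE.NAMES = FALSE)

    centers <- component_centers(k, b, c2$component_separation)
    factors <- centers[comp, , drop = FALSE] +
      matrix(stats::rnorm(n * b), n, b)

    height <- stats::rnorm(n, c2$height_mean_by_gender[gender],
                           c2$height_sd_by_gender[gender])
    height <- pmax(height, 100)
    weight <- stats::rnorm(n, c2$weight_mean_by_gender[gender],
                           c2$weight_sd_by_gender[gender])
    weight <- pmax(weight, 30)
    age <- stats::runif(n, c2$age_range[1], c2$age_range[2])

    # waist/hip in cm from the first two latent factors; gender-specific
    # baselines track adult population means
    waist <- ifelse(gender == "F", 91, 101) + 8 * factors[, 1]
    hip <- ifelse(gender == "F", 108, 105) + 6 * factors[, min(2L, b)]
    waist <- pmax(waist, 50)
    hip <- pmax(hip, 60)

    p <- c2$p_total
    block_of <- c(rep(seq_len(b), times = c2$measures_per_block),
                  rep(NA_integer_, c2$n_singleton_measures))
    loc <- stats::runif(p, 40, 120)
    scl <- stats::runif(p, 3, 12)
    w <- c2$within_block_correlation
    vals <- matrix(NA_real_, n, p)
    for (j in seq_len(p)) {
      sig <- if (is.na(block_of[j])) stats::rnorm(n) else factors[, block_of[j]]
      std <- if (is.na(block_of[j])) sig
             else sqrt(w) * sig + sqrt(1 - w) * c2$noise_sd * stats::rnorm(n)
      vals[, j] <- loc[j] + scl[j] * std
    }
    vals <- vals * (height / mean(height))
    colnames(vals) <- c(
      sprintf("m_b%02d_%02d", rep(seq_len(b), times = c2$measures_per_block),
              unlist(lapply(c2$measures_per_block, seq_len))),
      if (c2$n_singleton_measures > 0)
        sprintf("m_single_%02d", seq_len(c2$n_singleton_measures))
    )

    miss <- matrix(stats::runif(n * p) < c2$missing_rate_background, n, p)
    bad_rows <- if (c2$n_bad_participants > 0)
      sample.int(n, c2$n_bad_participants) else integer(0)
    bad_cols <- if (c2$n_bad_measures > 0)
      sample.int(p, c2$n_bad_measures) else integer(0)
    if (length(bad_rows)) {
      miss[bad_rows, ] <- miss[bad_rows, , drop = FALSE] |
        matrix(stats::runif(length(bad_rows) * p) < c2$missing_rate_bad_participants,
               length(bad_rows), p)
    }
    if (length(bad_cols)) {
      miss[, bad_cols] <- miss[, bad_cols, drop = FALSE] |
        matrix(stats::runif(n * length(bad_cols)) < c2$missing_rate_bad_measures,
               n, length(bad_cols))
    }
    vals[miss] <- NA_real_

    cov <- data.frame(
      participant_id = sprintf("P%05d", seq_len(n)),
      gender = gender, age = age, height = height, weight = weight,
      waist = waist, hip = hip, stringsAsFactors = FALSE
    )
    tab <- measure_table(vals, cov)
    structure(
      list(table = tab,
           truth_block_of_measure = stats::setNames(block_of, colnames(vals)),
           truth_body_type = comp,
           planted_bad_participants = sort(bad_rows),
           planted_bad_measures = sort(bad_cols),
           config = c2),
      class = "synthetic_cohort"
    )
  })
}

# Component centres at regular-simplex vertices scaled by `sep`: component k
# raises its signature latent factor by ~sep SD units (pairwise centre
# distance sep * sqrt(2), identical for all pairs) when k <= b + 1; otherwise
# seeded random unit directions scaled to sep, whose pairwise distances
# concentrate near sep * sqrt(2) in moderate dimension.
component_centers <- function(k, b, sep) {
  if (k == 1L || sep == 0) return(matrix(0, k, b))
  if (k <= b + 1L) {
    v <- diag(k) - 1 / k                       # centered identity: pairwise dist sqrt(2)
    rot <- svd(v)$u[, seq_len(k - 1L), drop = FALSE]
    vert <- v %*% rot                          # k x (k-1), distances preserved
    out <- matrix(0, k, b)
    out[, seq_len(k - 1L)] <- vert
  } else {
    g <- matrix(stats::rnorm(k * b), k, b)
    out <- g / sqrt(rowSums(g^2))              # unit directions
  }
  out * sep
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d participants, %d measures (%d blocks + %d singletons), %d body-type components\n",
              x$config$n_participants, x$config$p_total, x$config$n_blocks,
              x$config$n_singleton_measures, x$config$n_body_types))
  print(x$table)
  invisible(x)
}

#' Hand-built fixture exercising the three preprocessing filters
#'
#' An 8-participant x 6-measure table with a fixed missingness pattern, meant
#' to be filtered with `participant_threshold = 0.5` and
#' `measure_threshold = 0.34` (at 7-8 participants the default 5% measure
#' threshold would sweep up every measure with any missing value, leaving no
#' work for the third filter stage; the fixture documents its own threshold
#' instead). Pattern (X = missing):
#'
#' ```
#'      M1 M2 M3 M4 M5 M6
#'  P1   .  .  .  .  X  .
#'  P2   .  .  .  .  X  .
#'  P3   .  .  .  .  X  X
#'  P4   .  .  .  .  .  X
#'  P5   .  .  .  .  .  .
#'  P6   .  .  .  .  .  .
#'  P7   .  .  .  .  .  .
#'  P8   X  X  X  X  .  X
#' ```
#'
#' Hand-derived filtering under those thresholds:
#' \itemize{
#'   \item Stage 1 (participants missing > 50% of 6 measures, i.e. >= 4
#'     cells): only P8 (5/6 missing) is removed.
#'   \item Stage 2 (measures missing in > 34% of the 7 remaining, i.e. >= 3):
#'     only M5 (missing for P1, P2, P3: 3/7 = 43%) is removed; M6 (P3, P4:
#'     2/7 = 29%) stays.
#'   \item Stage 3 (remaining participants with any missing value): P3 and P4
#'     (still missing M6) are removed.
#' }
#' Survivors: participants P1, P2, P5, P6, P7 and measures M1-M4, M6. The
#' stage order matters: filtering measures before participants (fractions
#' over all 8 rows) would also remove M6 (3/8 = 37.5%) and keep all of
#' P1-P7, a different survivor set — a regression guard for the prescribed
#' participants-first order.
#'
#' @return A `synthetic_cohort` whose `table` carries the pattern above;
#'   values are deterministic (no RNG). The recommended thresholds are
#'   attached as attributes `participant_threshold` and `measure_threshold`.
#' @export
toy_filter_fixture <- function() {
  vals <- matrix(as.numeric(outer(1:8, 1:6, function(i, j) 10 * i + j)),
                 8, 6, dimnames = list(sprintf("P%d", 1:8), sprintf("M%d", 1:6)))
  vals[1, 5] <- NA; vals[2, 5] <- NA; vals[3, 5] <- NA
  vals[3, 6] <- NA; vals[4, 6] <- NA
  vals[8, 1:4] <- NA; vals[8, 6] <- NA
  cov <- data.frame(participant_id = rownames(vals),
                    gender = rep(c("F", "M"), 4),
                    age = seq(41, 76, by = 5),
                    height = seq(160, 181, by = 3),
                    stringsAsFactors = FALSE)
  tab <- measure_table(vals, cov)
  out <- structure(list(table = tab,
                        truth_block_of_measure = stats::setNames(rep(NA_integer_, 6), colnames(vals)),
                        truth_body_type = rep(1L, 8),
                        config = NULL),
                   class = "synthetic_cohort")
  attr(out, "participant_threshold") <- 0.5
  attr(out, "measure_threshold") <- 0.34
  out
}
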