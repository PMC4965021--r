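make_table <- function(vals, heights = NULL) {
  if (is.null(colnames(vals))) colnames(vals) <- paste0("m", seq_len(ncol(vals)))
  measure_table(vals, data.frame(
    participant_id = sprintf("P%d", seq_len(nrow(vals))),
    gender = rep(c("F", "M"), length.out = nrow(vals)),
    age = 50, height = heights %||% rep(170, nrow(vals))))
}

test_that("a complete matrix passes the filters unchanged", {
  tab <- make_table(matrix(rnorm(40), 8, 5))
  out <- filter_missing(tab)
  expect_identical(out$table$values, tab$values)
  rep <- out$report
  expect_identical(rep$n_participants_removed_stage1, 0L)
  expect_identical(rep$n_measures_removed_stage2, 0L)
  expect_identical(rep$n_participants_removed_stage3, 0L)
  expect_identical(rep$total_missing_cells, 0L)
})

test_that("the fixture's three stages remove exactly the hand-derived sets", {
  fx <- toy_filter_fixture()
  out <- filter_missing(fx$table,
                        participant_threshold = attr(fx, "participant_threshold"),
                        measure_threshold = attr(fx, "measure_threshold"))
  expect_identical(rownames(out$table$values), c("P1", "P2", "P5", "P6", "P7"))
  expect_identical(colnames(out$table$values), c("M1", "M2", "M3", "M4", "M6"))
  rep <- out$report
  expect_identical(rep$n_participants_removed_stage1, 1L)
  expect_identical(rep$n_measures_removed_stage2, 1L)
  expect_identical(rep$removed_measures, "M5")
  expect_identical(rep$n_participants_removed_stage3, 2L)
  expect_false(anyNA(out$table$values))
})

test_that("permuting the filter stages changes the survivors", {
  fx <- toy_filter_fixture()
  pt <- attr(fx, "participant_threshold")
  mt <- attr(fx, "measure_threshold")
  # measures-first variant, brute force: measure fractions over all 8 rows
  m <- is.na(fx$table$values)
  keep_meas <- colMeans(m) <= mt
  permuted_measures <- colnames(fx$table$values)[keep_meas]
  canonical <- filter_missing(fx$table, pt, mt)
  # M6 is missing in 3/8 rows (> 34%) before the bad participant is removed,
  # but only 2/7 (< 34%) after — the prescribed order keeps it
  expect_false("M6" %in% permuted_measures)
  expect_true("M6" %in% colnames(canonical$table$values))
  expect_false(setequal(permuted_measures, colnames(canonical$table$values)))
})

test_that("filter report arithmetic holds on random missingness patterns", {
  for (seed in 1:8) {
    set.seed(seed)
    vals <- matrix(rnorm(30 * 12), 30, 12)
    vals[matrix(runif(360) < 0.12, 30, 12)] <- NA
    tab <- make_table(vals)
    out <- tryCatch(filter_missing(tab, 0.4, 0.2), error = function(e) NULL)
    if (is.null(out)) next
    rep <- out$report
    expect_identical(rep$remaining_N,
                     rep$input_N - rep$n_participants_removed_stage1 -
                       rep$n_participants_removed_stage3)
    expect_identical(rep$remaining_P, rep$input_P - rep$n_measures_removed_stage2)
    expect_false(anyNA(out$table$values))
    expect_identical(dim(out$table$values), c(rep$remaining_N, rep$remaining_P))
  }
})

test_that("emptying filters raise stage-specific errors", {
  vals <- matrix(NA_real_, 4, 3)
  vals[1, 1] <- 1
  expect_error(filter_missing(make_table(vals), 0.1, 0.5), "stage 1")
  vals2 <- matrix(rnorm(12), 4, 3)
  vals2[cbind(1:3, 1:3)] <- NA  # every measure missing in 25% of participants
  expect_error(filter_missing(make_table(vals2), 0.9, 0.1), "stage 2")
})

test_that("height normalization divides every measure by participant height", {
  vals <- matrix(runif(20, 50, 150), 5, 4)
  h <- c(160, 170, 180, 155, 175)
  tab <- make_table(vals, heights = h)
  out <- height_normalize(tab)
  expect_equal(out$values, sweep(vals, 1, h, "/"), ignore_attr = TRUE)
  # unit heights leave the table unchanged
  tab1 <- make_table(vals, heights = rep(1, 5))
  expect_equal(height_normalize(tab1)$values, tab1$values)
  # a 2.0 m participant with a 1.0 m measure yields 0.5
  tab2 <- make_table(matrix(1, 1, 1), heights = 2)
  expect_equal(unname(height_normalize(tab2)$values[1, 1]), 0.5)
})

test_that("angle measures can be exempted from height normalization", {
  vals <- matrix(runif(12, 10, 100), 4, 3,
                 dimnames = list(NULL, c("len", "ang", "gir")))
  tab <- measure_table(vals, data.frame(height = c(160, 170, 180, 190)),
                       measure_kind = c("length", "angle", "girth"))
  out <- height_normalize(tab, exempt_kinds = "angle")
  expect_equal(out$values[, "ang"], tab$values[, "ang"])
  expect_equal(out$values[, "len"], tab$values[, "len"] / tab$covariates$height)
})

test_that("column Z-normalization matches the two-pass oracle and is idempotent", {
  expect_equal(unname(z_normalize_columns(make_table(matrix(c(1, 2, 3), 3, 1)))$values[, 1]),
               c(-1, 0, 1))
  set.seed(11)
  vals <- matrix(rnorm(18, 5, 3), 6, 3)
  out <- z_normalize_columns(make_table(vals))
  oracle <- apply(vals, 2, function(col) (col - mean(col)) / stats::sd(col))
  expect_equal(unname(out$values), unname(oracle))
  expect_true(all(abs(colMeans(out$values)) < 1e-12))
  expect_true(all(abs(apply(out$values, 2, stats::sd) - 1) < 1e-12))
  twice <- z_normalize_columns(out)
  expect_equal(twice$values, out$values, tolerance = 1e-12)
})

test_that("zero-variance columns are reported by name", {
  vals <- cbind(a = rnorm(5), b = rep(2, 5), c = rnorm(5))
  expect_error(z_normalize_columns(make_table(vals)), "b")
})

test_that("classical indices match their definitions and printed cohort values", {
  expect_equal(compute_indices(1, 1, 1, 1)$bmi, 1)
  # male cohort means: 86 kg, 1.76 m, waist 1.01 m
  male <- compute_indices(86, 1.76, 1.01, 1.05)
  expect_equal(round(male$bmi), 28)
  expect_equal(round(male$whtr, 2), 0.57)
  # female cohort means: 71 kg, 1.65 m, waist 0.91 m
  female <- compute_indices(71, 1.65, 0.91, 1.08)
  expect_equal(round(female$bmi), 26)
  expect_equal(round(female$whtr, 2), 0.55)
  # ABSI against a direct evaluation of its formula
  absi_oracle <- 1.01 / ((86 / 1.76^2)^(2 / 3) * sqrt(1.76))
  expect_equal(male$absi, absi_oracle)
  expect_equal(male$whr, 1.01 / 1.05)
  expect_error(compute_indices(-1, 1.7, 0.9, 1), "weight")
  expect_error(compute_indices(70, 1.7, 0.9, 0), "hip")
})
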