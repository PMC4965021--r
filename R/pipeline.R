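#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default. A
#' single global `seed` fans out into stage-specific seeds via
#' [stage_seed()], so any stage can be rerun in isolation.
#'
#' @param out_dir Output directory for all artifacts.
#' @param cohort A [cohort_config()] (a synthetic cohort is generated) or
#'   `NULL` with `input_path` pointing to an existing delimited cohort file.
#' @param input_path Optional path to a cohort table read with
#'   [read_measure_table()]; overrides `cohort`.
#' @param participant_threshold,measure_threshold Preprocessing filter
#'   thresholds.
#' @param exempt_kinds Measure kinds exempt from height normalization.
#' @param feature_grid,body_grid Two-element integer vectors (width,
#'   height) for the two SOMs.
#' @param schedule A [som_schedule()] for the feature SOM.
#' @param body_schedule A [som_schedule()] for the body SOM; `NULL` uses the
#'   wide-final-radius default of [assign_body_types()].
#' @param theta Watershed ridge-merge threshold.
#' @param min_members Minimum measures per meta-measure cluster.
#' @param min_fraction Minimum body-type size as a cohort fraction.
#' @param gender_threshold Gender-majority threshold for F/M/B labels.
#' @param consensus_iters Consensus iterations (0 skips the consensus
#'   stage).
#' @param consensus_subsample Sub-cohort fraction for participant consensus.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "bodysom_out",
                            cohort = cohort_config(),
                            input_path = NULL,
                            participant_threshold = 0.5,
                            measure_threshold = 0.05,
                            exempt_kinds = character(0),
                            feature_grid = c(30, 30),
                            body_grid = c(60, 60),
                            schedule = som_schedule(),
                            body_schedule = NULL,
                            theta = 0.10,
                            min_members = 2L,
                            min_fraction = 0.01,
                            gender_threshold = 0.8,
                            consensus_iters = 0L,
                            consensus_subsample = 0.8,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest -> preprocessing filters -> height and column-Z
#' normalization -> feature SOM and meta-measure detection -> row-Z
#' normalization -> body SOM and body typing -> gender labelling and
#' summaries -> (optional) participant consensus -> bodygrams and map
#' overlays, writing every artifact as delimited text or JSON under
#' `config$out_dir` together with a manifest (inputs, seeds, per-stage
#' record counts, file checksums) that makes a rerun bit-checkable.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `report`, `feature`, `typing`, `summary`, `consensus_stats`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  manifest <- list(seed = config$seed, stages = list(), files = character(0))

  # -- ingest / simulate ------------------------------------------------
  if (!is.null(config$input_path)) {
    tab <- read_measure_table(config$input_path)
    truth <- NULL
  } else {
    cfg <- config$cohort
    cfg$seed <- stage_seed(config$seed, "simulate")
    cohort <- generate_cohort(do.call(cohort_config, cfg[setdiff(names(cfg), "p_total")]))
    tab <- cohort$table
    truth <- data.frame(participant_id = tab$covariates$participant_id,
                        true_body_type = cohort$truth_body_type)
    write_measure_table(tab, pth("cohort.csv"))
    utils::write.csv(truth, pth("truth_participants.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(measure = names(cohort$truth_block_of_measure),
                 true_block = unname(cohort$truth_block_of_measure)),
      pth("truth_measures.csv"), row.names = FALSE)
  }
  manifest$stages$ingest <- list(n_participants = nrow(tab$values),
                                 n_measures = ncol(tab$values))

  # -- preprocess -------------------------------------------------------
  filt <- filter_missing(tab, config$participant_threshold,
                         config$measure_threshold)
  clean <- filt$table
  jsonlite::write_json(unclass(filt$report), pth("preprocess_report.json"),
                       auto_unbox = TRUE)
  norm <- z_normalize_columns(height_normalize(clean, config$exempt_kinds))
  write_measure_table(norm, pth("clean_normalized.csv"))
  manifest$stages$preprocess <- unclass(filt$report)[1:5]

  # -- feature map ------------------------------------------------------
  fm <- feature_typing(norm, config$feature_grid[1], config$feature_grid[2],
                       schedule = config$schedule,
                       seed = stage_seed(config$seed, "feature_som"),
                       theta = config$theta, min_members = config$min_members)
  utils::write.csv(
    data.frame(measure = unlist(fm$meta$members),
               meta_measure = rep(names(fm$meta$members), lengths(fm$meta$members))),
    pth("measure_clusters.csv"), row.names = FALSE)
  meta_out <- data.frame(participant_id = norm$covariates$participant_id,
                         fm$meta$values, check.names = FALSE)
  utils::write.csv(meta_out, pth("meta_measures.csv"), row.names = FALSE)
  manifest$stages$feature_map <- list(
    grid = config$feature_grid, n_meta_measures = ncol(fm$meta$values),
    n_singletons_excluded = length(fm$meta$singletons_excluded))

  # -- body map ---------------------------------------------------------
  rowz <- z_normalize_rows(fm$meta)
  typing <- assign_body_types(rowz, config$body_grid[1], config$body_grid[2],
                              schedule = config$body_schedule,
                              seed = stage_seed(config$seed, "body_som"),
                              min_fraction = config$min_fraction,
                              theta = config$theta)
  typing <- label_by_gender(typing, norm$covariates$gender,
                            config$gender_threshold)
  idx <- cohort_indices(norm)
  summ <- summarize_body_types(typing, norm$covariates, idx)
  utils::write.csv(
    data.frame(participant_id = norm$covariates$participant_id,
               bmu_row = typing$bmu$row, bmu_col = typing$bmu$col,
               body_type = typing$participant_type),
    pth("body_type_assignments.csv"), row.names = FALSE)
  utils::write.csv(summ$summary, pth("body_type_summary.csv"), row.names = FALSE)
  utils::write.csv(summ$bands, pth("body_type_bands.csv"), row.names = FALSE)
  manifest$stages$body_map <- list(
    grid = config$body_grid, n_body_types = typing$n_types,
    n_unassigned = sum(is.na(typing$labels)),
    min_size_used = typing$min_size_used)

  # -- consensus (optional) --------------------------------------------
  cons <- NULL
  if (config$consensus_iters >= 2L) {
    proc <- body_typing_procedure(config)
    cmat <- subsampled_consensus(
      rowz$values,
      subsample_size = max(2L, round(config$consensus_subsample * nrow(rowz$values))),
      n_iter = config$consensus_iters, clustering_procedure = proc,
      seed = stage_seed(config$seed, "consensus"))
    cons <- consensus_stats(cmat, typing)
    utils::write.csv(
      data.frame(type = typing$type_names, m_k = cons$intra,
                 n = cons$cluster_sizes),
      pth("consensus_intra.csv"), row.names = FALSE)
    manifest$stages$consensus <- list(n_iter = config$consensus_iters,
                                      mean_intra = cons$mean_intra)
  }

  # -- atlas ------------------------------------------------------------
  strata <- list(all = NULL,
                 female = function(cv) cv$gender == "F",
                 male = function(cv) cv$gender == "M")
  bg_rows <- do.call(rbind, lapply(names(strata), function(s) {
    bg <- mean_bodygram(fm$meta, strata[[s]], stratum = s)
    data.frame(stratum = s, axis = bg$axis_order, radius = bg$radii, n = bg$n)
  }))
  utils::write.csv(bg_rows, pth("bodygrams.csv"), row.names = FALSE)
  ov <- stain_map(typing$bmu, idx$bmi, config$body_grid[1], config$body_grid[2])
  grid <- unit_grid(config$body_grid[1], config$body_grid[2])
  utils::write.csv(
    data.frame(row = grid[, "row"], col = grid[, "col"],
               mean_bmi = ov$values, n = ov$n)[ov$n > 0, ],
    pth("overlay_bmi.csv"), row.names = FALSE)

  # -- manifest ---------------------------------------------------------
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest$files <- as.list(stats::setNames(unname(tools::md5sum(files)),
                                            basename(files)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(cohort = tab, report = filt$report, feature = fm,
                 typing = typing, summary = summ, consensus_stats = cons,
                 manifest = manifest))
}

# Full body-typing clustering procedure as a consensus-compatible closure:
# retrains the SOM and reruns cluster detection on each subsample.
body_typing_procedure <- function(config) {
  body_schedule <- config$body_schedule %||%
    som_schedule(final_radius = max(config$body_grid) / 6)
  function(x, seed) {
    som <- som_train(x, config$body_grid[1], config$body_grid[2],
                     schedule = body_schedule, seed = seed)
    dmap <- distance_map(som)
    bmu <- best_matching_units(som, x)
    asg <- detect_clusters(dmap, bmu, theta = config$theta)
    min_size <- ceiling(config$min_fraction * nrow(x))
    asg <- tryCatch(prune_singletons(asg, min_members = max(2L, min_size)),
                    error = function(e) NULL)
    if (is.null(asg)) rep(NA_integer_, nrow(x)) else asg$item_labels
  }
}

#' Read a processed per-participant summary table
#'
#' Ingests a delimited-text export of a deposited per-participant summary
#' (columns: participant id, age, gender, BMI, body type, then one column
#' per meta-measure) into a `meta_measure_table` plus covariates — the
#' format in which processed cohort results are shared when raw scans are
#' access-restricted.
#'
#' @param path Delimited text file (separator autodetected).
#' @param meta_prefix Regular expression or prefix identifying meta-measure
#'   columns; by default every column not among the known covariate columns
#'   is treated as a meta-measure.
#' @return A list: `meta` (a `meta_measure_table`), `body_type` (character
#'   per participant), `covariates`.
#' @export
read_s2_table <- function(path, meta_prefix = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           na.strings = c("", "NA"), quote = "\"")
  known <- c("participant_id", "id", "age", "gender", "sex", "bmi",
             "body_type", "bodytype")
  is_meta <- if (is.null(meta_prefix)) {
    !(tolower(names(raw)) %in% known)
  } else grepl(meta_prefix, names(raw))
  if (!any(is_meta)) stop("no meta-measure columns found in ", path, call. = FALSE)
  vals <- as.matrix(raw[is_meta])
  storage.mode(vals) <- "double"
  cov <- raw[!is_meta]
  names(cov) <- tolower(names(cov))
  if (is.null(cov$height)) cov$height <- NA_real_
  bt_col <- intersect(c("body_type", "bodytype"), names(cov))
  meta <- structure(list(values = vals,
                         members = stats::setNames(as.list(colnames(vals)), colnames(vals)),
                         singletons_excluded = character(0),
                         covariates = cov,
                         axis_order = colnames(vals)),
                    class = "meta_measure_table")
  list(meta = meta,
       body_type = if (length(bt_col)) as.character(cov[[bt_col[1]]]) else NULL,
       covariates = cov)
}
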