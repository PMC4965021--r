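#' Construct a measure table
#'
#' The central container of the pipeline: a participants x measures numeric
#' matrix (missing values as `NA`), per-measure metadata and per-participant
#' covariates. Measures are columns; the transpose is used when measures are
#' the items being clustered (feature map).
#'
#' @param values Numeric matrix, participants in rows, measures in columns,
#'   with column names. `NA` marks a missing cell.
#' @param covariates Data frame with one row per participant; must contain a
#'   `height` column (cm, positive) and typically `gender` (factor/character
#'   with levels "F"/"M"), `age` (years), `weight` (kg), `waist` and `hip`
#'   (cm).
#' @param measure_kind Character vector tagging each measure as one of
#'   `"length"`, `"girth"`, `"angle"`, `"weight"`, `"index"`. Defaults to
#'   `"length"` for all.
#' @return An object of class `measure_table`.
#' @export
measure_table <- function(values, covariates,
                          measure_kind = rep("length", ncol(values))) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(values))) stop("`values` must have column names", call. = FALSE)
  if (anyDuplicated(colnames(values))) {
    stop("duplicate measure names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.data.frame(covariates) || nrow(covariates) != nrow(values)) {
    stop("`covariates` must be a data frame with one row per participant",
         call. = FALSE)
  }
  if (is.null(covariates$height)) stop("covariates must contain `height`", call. = FALSE)
  if (any(!is.finite(covariates$height)) || any(covariates$height <= 0)) {
    stop("all participant heights must be positive and finite", call. = FALSE)
  }
  kinds <- c("length", "girth", "angle", "weight", "index")
  measure_kind <- rep_len(as.character(measure_kind), ncol(values))
  if (!all(measure_kind %in% kinds)) {
    stop("`measure_kind` entries must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- covariates$participant_id %||% sprintf("P%04d", seq_len(nrow(values)))
  }
  structure(
    list(values = values, covariates = covariates, measure_kind = measure_kind),
    class = "measure_table"
  )
}

#' Missingness mask of a measure table
#'
#' @param table A `measure_table`.
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(table) {
  stopifnot(inherits(table, "measure_table"))
  is.na(table$values)
}

#' @export
print.measure_table <- function(x, ...) {
  cat(sprintf("measure_table: %d participants x %d measures (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat("kinds:", paste(sprintf("%s=%d", names(table(x$measure_kind)),
                              table(x$measure_kind)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.measure_table <- function(x) dim(x$values)

#' Read a measure table from delimited text
#'
#' Parses a participants-per-row delimited file (comma or tab autodetected
#' unless `sep` is given). Empty fields become missing values. Columns whose
#' names start with `cov_` are covariates (prefix stripped); everything else
#' is a numeric measure. A `cov_height` column is required. Malformed numeric
#' cells raise an error naming the row and column.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) autodetects `","` vs `"\t"`
#'   from the header line.
#' @param measure_kind Optional per-measure kind vector (recycled).
#' @return A [measure_table()].
#' @export
read_measure_table <- function(path, sep = NULL, measure_kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", na.strings = c("", "NA"),
                           quote = "\"", comment.char = "")
  if (anyDuplicated(names(raw))) {
    stop("duplicate column names in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  is_cov <- startsWith(names(raw), "cov_")
  id_col <- names(raw) == "participant_id"
  if (!any(is_cov & names(raw) == "cov_height")) {
    stop("missing required column `cov_height` in ", path, call. = FALSE)
  }
  meas_cols <- which(!is_cov & !id_col)
  if (length(meas_cols) == 0L) stop("no measure columns found in ", path, call. = FALSE)
  vals <- matrix(NA_real_, nrow(raw), length(meas_cols),
                 dimnames = list(NULL, names(raw)[meas_cols]))
  for (j in seq_along(meas_cols)) {
    col <- raw[[meas_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value %s at row %d, column \"%s\" of %s",
                   dQuote(col[bad[1L]]), bad[1L], names(raw)[meas_cols[j]], path),
           call. = FALSE)
    }
    vals[, j] <- num
  }
  cov <- raw[is_cov | id_col]
  names(cov) <- sub("^cov_", "", names(cov))
  for (nm in setdiff(names(cov), c("gender", "participant_id"))) {
    cov[[nm]] <- suppressWarnings(as.numeric(cov[[nm]]))
  }
  if (!is.null(cov$participant_id)) rownames(vals) <- cov$participant_id
  measure_table(vals, cov,
                measure_kind = measure_kind %||% rep("length", ncol(vals)))
}

#' Write a measure table to delimited text
#'
#' Inverse of [read_measure_table()]: covariates get the `cov_` prefix,
#' missing cells are written as empty fields.
#'
#' @param table A `measure_table`.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_measure_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "measure_table"))
  cov <- table$covariates
  keep <- names(cov) != "participant_id"
  out <- cbind(
    data.frame(participant_id = cov$participant_id %||% rownames(table$values)),
    stats::setNames(cov[keep], paste0("cov_", names(cov)[keep])),
    as.data.frame(table$values)
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}
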