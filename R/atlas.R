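#' Bodygram of a single meta-measure profile
#'
#' A bodygram is a polar profile of the meta-measures in Z-units: one axis
#' per meta-measure, ordered as in the feature map, with axis i at angle
#' `2*pi*i/K` clockwise from 12 o'clock. The polygon at Z = 0 is the cohort
#' reference (the average body).
#'
#' @param meta_row Numeric vector of meta-measure values (Z-units) in axis
#'   order, or a single row name / index into a `meta_measure_table` given
#'   as `axis_order`'s source.
#' @param axis_order Character vector of axis (meta-measure) labels; length
#'   must match `meta_row`.
#' @param stratum Free-text descriptor of what the profile is (participant
#'   id or stratum definition).
#' @param n Number of participants averaged into the profile (1 for a
#'   single participant).
#' @return An object of class `bodygram`: `axis_order`, `radii`, `stratum`,
#'   `n`.
#' @export
bodygram <- function(meta_row, axis_order, stratum = "participant", n = 1L) {
  meta_row <- as.numeric(meta_row)
  if (length(meta_row) != length(axis_order)) {
    stop("profile has ", length(meta_row), " values but ",
         length(axis_order), " axes", call. = FALSE)
  }
  if (anyNA(meta_row)) stop("bodygram profile contains missing values", call. = FALSE)
  structure(list(axis_order = as.character(axis_order), radii = meta_row,
                 stratum = stratum, n = as.integer(n)),
            class = "bodygram")
}

#' Polygon vertices of a bodygram
#'
#' Converts the Z-radii to Cartesian vertex coordinates for plotting: axis i
#' (1-based) sits at angle `2*pi*(i-1)/K` clockwise from 12 o'clock, and the
#' plotted radius is `offset + Z` so that the Z = 0 reference is a regular
#' polygon of radius `offset`.
#'
#' @param bg A `bodygram`.
#' @param offset Radial offset of the Z = 0 reference (default 3, i.e.
#'   profiles down to Z = -3 stay inside the plot).
#' @return Data frame with `axis`, `angle` (radians clockwise from 12
#'   o'clock), `radius` (Z), `x`, `y`.
#' @export
bodygram_vertices <- function(bg, offset = 3) {
  stopifnot(inherits(bg, "bodygram"))
  k <- length(bg$radii)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  r <- offset + bg$radii
  data.frame(axis = bg$axis_order, angle = ang, radius = bg$radii,
             x = r * sin(ang), y = r * cos(ang))
}

#' Mean bodygram over a participant stratum
#'
#' Per-axis arithmetic mean of the meta-measure profiles of all
#' participants matching a covariate predicate (e.g. all women, all
#' participants above the median weight).
#'
#' @param meta A `meta_measure_table`.
#' @param stratum_filter Predicate: a function taking the covariate data
#'   frame and returning a logical vector, or a logical vector directly.
#' @param stratum Descriptor string for the stratum.
#' @return A `bodygram` with `n` = number of matching participants.
#' @export
mean_bodygram <- function(meta, stratum_filter = NULL, stratum = "all") {
  stopifnot(inherits(meta, "meta_measure_table"))
  sel <- if (is.null(stratum_filter)) rep(TRUE, nrow(meta$values))
         else if (is.function(stratum_filter)) stratum_filter(meta$covariates)
         else as.logical(stratum_filter)
  if (length(sel) != nrow(meta$values)) {
    stop("stratum filter length mismatch", call. = FALSE)
  }
  if (!any(sel, na.rm = TRUE)) {
    stop("stratum \"", stratum, "\" matches no participants", call. = FALSE)
  }
  sel[is.na(sel)] <- FALSE
  bodygram(colMeans(meta$values[sel, , drop = FALSE]),
           axis_order = colnames(meta$values), stratum = stratum,
           n = sum(sel))
}

#' Stain the body map with a participant characteristic
#'
#' Aggregates a per-participant characteristic (age, gender, BMI, a
#' meta-measure, ...) over the participants mapped to each body-map unit:
#' the per-unit mean, the modal value, or the modal cohort tertile class.
#' Units without participants carry `NA`.
#'
#' @param bmu Per-participant BMU assignment ([best_matching_units()] data
#'   frame or integer unit vector).
#' @param characteristic Numeric vector, one value per participant.
#' @param width,height Body-map lattice size.
#' @param statistic `"mean"`, `"mode"`, or `"tertile_class"` (classes from
#'   cohort-wide tertiles of the characteristic, then per-unit modal class).
#' @return An object of class `map_overlay`: `values` (per-unit, row-major;
#'   `NA` = empty unit), `n` (participants per unit), `width`, `height`,
#'   `statistic`.
#' @export
stain_map <- function(bmu, characteristic, width, height,
                      statistic = c("mean", "mode", "tertile_class")) {
  statistic <- match.arg(statistic)
  if (is.data.frame(bmu)) bmu <- bmu$unit
  bmu <- as.integer(bmu)
  u <- width * height
  if (length(characteristic) != length(bmu)) {
    stop("`characteristic` must have one value per participant", call. = FALSE)
  }
  if (anyNA(characteristic)) stop("`characteristic` contains missing values",
                                  call. = FALSE)
  vals <- if (statistic == "tertile_class") {
    tertile_classes(characteristic)
  } else characteristic
  out <- rep(NA_real_, u)
  counts <- tabulate(bmu, nbins = u)
  for (uix in unique(bmu)) {
    v <- vals[bmu == uix]
    out[uix] <- if (statistic == "mean") mean(v) else modal_value(v)
  }
  structure(list(values = out, n = counts, width = width, height = height,
                 statistic = statistic),
            class = "map_overlay")
}

# most frequent value; ties go to the lowest value
modal_value <- function(v) {
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

# cohort-wide tertile classes: boundaries at the 1/3 and 2/3 empirical
# quantiles (midpoint interpolation, quantile type 2); ties at a boundary
# fall to the lower class
tertile_classes <- function(x) {
  q <- stats::quantile(x, c(1, 2) / 3, type = 2, names = FALSE)
  1L + (x > q[1]) + (x > q[2])
}

#' Tertile map of a meta-measure
#'
#' Classes every participant into cohort-wide tertiles of one meta-measure
#' and stains the body map with the per-unit modal class — a discretized
#' view of how that shape dimension distributes over the body types.
#'
#' @param meta A `meta_measure_table`.
#' @param meta_index Column index or name of the meta-measure.
#' @param bmu Per-participant BMU assignment on the body map.
#' @param width,height Body-map lattice size.
#' @return A `map_overlay` with values in {1, 2, 3}.
#' @export
tertile_map <- function(meta, meta_index, bmu, width, height) {
  stopifnot(inherits(meta, "meta_measure_table"))
  x <- meta$values[, meta_index]
  stain_map(bmu, x, width, height, statistic = "tertile_class")
}

#' @export
print.map_overlay <- function(x, ...) {
  cat(sprintf("map_overlay (%s): %d x %d units, %d occupied\n",
              x$statistic, x$width, x$height, sum(!is.na(x$values))))
  invisible(x)
}

#' @export
print.bodygram <- function(x, ...) {
  cat(sprintf("bodygram [%s] (n = %d): %s\n", x$stratum, x$n,
              paste(sprintf("%s=%.2f", x$axis_order, x$radii), collapse = " ")))
  invisible(x)
}

#' Plot a bodygram
#'
#' Base-graphics polar rendering: the solid polygon is the profile, the bold
#' reference polygon is Z = 0, dotted rings mark +/- 1, 2, ... SD.
#'
#' @param x A `bodygram`.
#' @param offset Radial offset of the Z = 0 reference.
#' @param col Polygon border color.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the vertex data frame.
#' @export
plot.bodygram <- function(x, offset = 3, col = "steelblue", ...) {
  v <- bodygram_vertices(x, offset)
  lim <- max(offset + 2, max(abs(c(v$x, v$y)))) * 1.15
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s (n = %d)", x$stratum, x$n), ...)
  k <- length(x$radii)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  for (ring in seq(1, offset + 1)) {
    graphics::polygon(ring * sin(ang), ring * cos(ang),
                      border = "grey80", lty = 3)
  }
  graphics::polygon(offset * sin(ang), offset * cos(ang), border = "black", lwd = 2)
  graphics::polygon(v$x, v$y, border = col, lwd = 2)
  graphics::text(1.08 * lim * sin(ang) / 1.15, 1.08 * lim * cos(ang) / 1.15,
                 x$axis_order, cex = 0.8)
  invisible(v)
}

#' Plot a map overlay
#'
#' @param x A `map_overlay`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.map_overlay <- function(x, ...) {
  m <- matrix(x$values, nrow = x$height, ncol = x$width, byrow = TRUE)
  graphics::image(t(m)[, rev(seq_len(x$height))], axes = FALSE, ...)
  invisible(x)
}
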