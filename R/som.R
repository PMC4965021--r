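#' Training schedule for a self-organizing map
#'
#' The default is a batch SOM with a Gaussian neighborhood whose radius
#' decays linearly from half the larger map side to 1 over 100 epochs — a
#' conventional coarse-to-fine schedule; every field is overridable. Online
#' (stochastic) training with a decaying learning rate is available for
#' small problems.
#'
#' @param n_epochs Number of passes over the data.
#' @param initial_radius,final_radius Neighborhood radius in lattice units;
#'   `initial_radius = NULL` means `max(width, height) / 2`.
#' @param initial_alpha,final_alpha Learning rates (online mode only).
#' @param neighborhood_kernel `"gaussian"` (radius = kernel SD) or
#'   `"bubble"` (hard cutoff at the radius).
#' @param mode `"batch"` or `"online"`.
#' @return A list of class `som_schedule`.
#' @export
som_schedule <- function(n_epochs = 100, initial_radius = NULL,
                         final_radius = 1, initial_alpha = 0.05,
                         final_alpha = 0.01,
                         neighborhood_kernel = c("gaussian", "bubble"),
                         mode = c("batch", "online")) {
  stop_if_not_count(n_epochs, "n_epochs")
  neighborhood_kernel <- match.arg(neighborhood_kernel)
  mode <- match.arg(mode)
  if (!is.null(initial_radius) && initial_radius < final_radius) {
    stop("`initial_radius` must be >= `final_radius`", call. = FALSE)
  }
  if (initial_alpha < final_alpha || initial_alpha > 1 || final_alpha <= 0) {
    stop("alphas must satisfy 0 < final_alpha <= initial_alpha <= 1", call. = FALSE)
  }
  structure(list(n_epochs = n_epochs, initial_radius = initial_radius,
                 final_radius = final_radius, initial_alpha = initial_alpha,
                 final_alpha = final_alpha,
                 neighborhood_kernel = neighborhood_kernel, mode = mode),
            class = "som_schedule")
}

# Unit coordinates of a width x height lattice in row-major linear order:
# unit index u (1-based) sits at 0-based (row, col) with u = row*width + col + 1.
unit_grid <- function(width, height) {
  cbind(row = rep(0:(height - 1), each = width),
        col = rep(0:(width - 1), times = height))
}

#' Train a self-organizing map on a rectangular lattice
#'
#' Items are rows of `data`; the codebook holds one vector per lattice unit,
#' stored in row-major order. Initialization spans the plane of the first
#' two principal axes of the data (deterministic given the data), which
#' anchors the map orientation and avoids run-to-run topology flips; if the
#' data are too degenerate for two principal axes, a seeded random sample of
#' items is used instead. Batch training assigns all items to their
#' best-matching units, then replaces each codebook vector by the
#' neighborhood-weighted mean of the assigned items (the Gaussian smoothing
#' is separable over rows and columns of the lattice, which keeps the update
#' linear in map side length). The quantization error (mean Euclidean
#' distance of items to their BMU) is logged per epoch.
#'
#' @param data Numeric matrix, items x features; no missing values.
#' @param width,height Lattice dimensions (>= 2 each).
#' @param schedule A [som_schedule()].
#' @param seed Integer seed (used by the sample initialization and online
#'   item order).
#' @param init `"pca"` (deterministic PCA-plane interpolation, default) or
#'   `"sample"` (seeded random draw of items). PCA init anchors orientation
#'   but can start two clusters on top of each other when the between-cluster
#'   structure needs more than two axes; sample init avoids that at the cost
#'   of run-to-run layout variation.
#' @return An object of class `som_grid`: `codebook` (units x features,
#'   row-major unit order), `width`, `height`, `seed`, `schedule`,
#'   `training_log` (quantization error per epoch).
#' @export
som_train <- function(data, width, height, schedule = som_schedule(), seed = 1,
                      init = c("pca", "sample")) {
  init <- match.arg(init)
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop("`data` must be a finite numeric matrix", call. = FALSE)
  }
  stop_if_not_count(width, "width", min = 2L)
  stop_if_not_count(height, "height", min = 2L)
  stopifnot(inherits(schedule, "som_schedule"))
  n <- nrow(data); d <- ncol(data); u <- width * height
  r0 <- schedule$initial_radius %||% (max(width, height) / 2)
  r1 <- schedule$final_radius
  ep <- schedule$n_epochs

  codebook <- init_codebook(data, width, height, seed, init)
  radii <- if (ep == 1L) r1 else r0 + (r1 - r0) * (seq_len(ep) - 1) / (ep - 1)
  qe <- numeric(ep)

  if (schedule$mode == "batch") {
    for (e in seq_len(ep)) {
      bmu <- nearest_unit(data, codebook)
      qe[e] <- mean(sqrt(rowSums((data - codebook[bmu, , drop = FALSE])^2)))
      sums <- matrix(0, u, d)
      agg <- rowsum(data, group = bmu, reorder = TRUE)
      sums[as.integer(rownames(agg)), ] <- agg
      counts <- tabulate(bmu, nbins = u)
      num <- lattice_smooth(sums, width, height, radii[e], schedule$neighborhood_kernel)
      den <- lattice_smooth(matrix(counts, ncol = 1), width, height, radii[e],
                            schedule$neighborhood_kernel)[, 1]
      upd <- den > .Machine$double.eps
      codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    }
  } else {
    grid <- unit_grid(width, height)
    alphas <- seq(schedule$initial_alpha, schedule$final_alpha, length.out = ep)
    ord_all <- with_seed(seed, replicate(ep, sample.int(n), simplify = FALSE))
    for (e in seq_len(ep)) {
      for (i in ord_all[[e]]) {
        x <- data[i, ]
        b <- which.min(colSums((t(codebook) - x)^2))
        d2 <- (grid[, 1] - grid[b, 1])^2 + (grid[, 2] - grid[b, 2])^2
        hgt <- if (schedule$neighborhood_kernel == "gaussian") {
          exp(-d2 / (2 * radii[e]^2))
        } else as.numeric(sqrt(d2) <= radii[e])
        codebook <- codebook + alphas[e] * hgt * (matrix(x, u, d, byrow = TRUE) - codebook)
      }
      bmu <- nearest_unit(data, codebook)
      qe[e] <- mean(sqrt(rowSums((data - codebook[bmu, , drop = FALSE])^2)))
    }
  }

  structure(list(codebook = codebook, width = width, height = height,
                 seed = seed, schedule = schedule, training_log = qe),
            class = "som_grid")
}

# PCA-plane initialization: codebook vectors interpolate linearly over the
# first two principal axes, lattice columns along PC1 and rows along PC2,
# each spanning +/- 2 SD of the respective scores.
init_codebook <- function(data, width, height, seed, init = "pca") {
  n <- nrow(data); d <- ncol(data)
  u <- width * height
  grid <- unit_grid(width, height)
  mu <- colMeans(data)
  ok <- FALSE
  if (init == "pca" && n >= 3L && d >= 2L) {
    pc <- tryCatch(stats::prcomp(data, center = TRUE, scale. = FALSE),
                   error = function(e) NULL)
    if (!is.null(pc) && ncol(pc$rotation) >= 2L &&
        all(pc$sdev[1:2] > .Machine$double.eps^0.5)) {
      s1 <- if (width > 1) 2 * pc$sdev[1] * (2 * grid[, "col"] / (width - 1) - 1) else rep(0, u)
      s2 <- if (height > 1) 2 * pc$sdev[2] * (2 * grid[, "row"] / (height - 1) - 1) else rep(0, u)
      cb <- matrix(mu, u, d, byrow = TRUE) +
        outer(s1, pc$rotation[, 1]) + outer(s2, pc$rotation[, 2])
      ok <- TRUE
    }
  }
  if (!ok) {
    idx <- with_seed(seed, sample.int(n, u, replace = TRUE))
    cb <- data[idx, , drop = FALSE] +
      with_seed(seed + 1, matrix(stats::rnorm(u * d, sd = 1e-4), u, d))
  }
  dimnames(cb) <- NULL
  cb
}

# Squared-distance BMU search; the item's own squared norm is constant per
# row and dropped from the argmin. Ties resolve to the lowest row-major unit
# index (max.col with ties.method = "first").
nearest_unit <- function(data, codebook) {
  # argmax_u of 2<x,w_u> - |w_u|^2, folded into one crossproduct by
  # augmenting x with a constant 1 coordinate
  s <- tcrossprod(cbind(data, 1),
                  cbind(2 * codebook, -rowSums(codebook^2)))
  max.col(s, ties.method = "first")
}

# Separable neighborhood smoothing of per-unit quantities living on the
# lattice: values (units x k, row-major) are convolved with the kernel along
# lattice rows and columns independently.
lattice_smooth <- function(values, width, height, radius, kernel) {
  k1 <- function(m) {
    dd <- outer(0:(m - 1), 0:(m - 1), "-")
    if (kernel == "gaussian") exp(-dd^2 / (2 * radius^2))
    else (abs(dd) <= radius) * 1
  }
  kr <- k1(height); kc <- k1(width)
  out <- values
  for (j in seq_len(ncol(values))) {
    v <- matrix(values[, j], nrow = height, ncol = width, byrow = TRUE)
    out[, j] <- as.vector(t(kr %*% v %*% kc))
  }
  out
}

#' Best-matching units of items on a trained map
#'
#' Each item is assigned to the lattice unit whose codebook vector is
#' nearest in Euclidean distance; exact ties go to the lowest row-major unit
#' index.
#'
#' @param som A `som_grid`.
#' @param data Items x features matrix with the codebook's feature
#'   dimension.
#' @return A data frame with one row per item: `unit` (1-based row-major
#'   linear index), `row`, `col` (0-based lattice coordinates).
#' @export
best_matching_units <- function(som, data) {
  stopifnot(inherits(som, "som_grid"))
  data <- as.matrix(data)
  if (ncol(data) != ncol(som$codebook)) {
    stop(sprintf("feature dimension mismatch: data has %d, codebook has %d",
                 ncol(data), ncol(som$codebook)), call. = FALSE)
  }
  u <- nearest_unit(data, som$codebook)
  grid <- unit_grid(som$width, som$height)
  data.frame(unit = u, row = grid[u, "row"], col = grid[u, "col"])
}

# 1-based linear indices of lattice neighbors for every unit.
lattice_neighbors <- function(width, height, neighborhood = 4L) {
  grid <- unit_grid(width, height)
  offs <- if (neighborhood == 4L) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  }
  offs <- as.matrix(offs)
  lapply(seq_len(width * height), function(uix) {
    r <- grid[uix, 1] + offs[, 1]; c <- grid[uix, 2] + offs[, 2]
    ok <- r >= 0 & r < height & c >= 0 & c < width
    as.integer(r[ok] * width + c[ok] + 1)
  })
}

#' U-matrix (distance map) of a trained SOM
#'
#' For every lattice unit, the mean Euclidean distance between its codebook
#' vector and those of its adjacent lattice neighbors (4-neighborhood by
#' default, 8 configurable); border units average over their existing
#' neighbors only. Ridges of large values mark cluster borders.
#'
#' @param som A `som_grid`.
#' @param neighborhood 4 (von Neumann, default) or 8 (Moore).
#' @return An object of class `distance_map`: `values` (per-unit, row-major
#'   vector), `width`, `height`, `neighborhood`.
#' @export
distance_map <- function(som, neighborhood = 4L) {
  stopifnot(inherits(som, "som_grid"), neighborhood %in% c(4L, 8L))
  nb <- lattice_neighbors(som$width, som$height, neighborhood)
  cb <- som$codebook
  vals <- vapply(seq_along(nb), function(uix) {
    diff <- cb[nb[[uix]], , drop = FALSE] -
      matrix(cb[uix, ], length(nb[[uix]]), ncol(cb), byrow = TRUE)
    mean(sqrt(rowSums(diff^2)))
  }, numeric(1))
  structure(list(values = vals, width = som$width, height = som$height,
                 neighborhood = neighborhood),
            class = "distance_map")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d units, %d features, %s training (%d epochs), final QE %.4g\n",
              x$width, x$height, ncol(x$codebook), x$schedule$mode,
              x$schedule$n_epochs, utils::tail(x$training_log, 1)))
  invisible(x)
}

#' Choose a map size by downstream cluster-count plateau
#'
#' Trains maps of increasing size, counts the downstream clusters each
#' yields, and returns the smallest size after which the count stops
#' increasing for `patience` consecutive larger sizes. If the curve never
#' plateaus the largest candidate is returned with `plateau_found = FALSE`.
#'
#' @param data Items x features matrix.
#' @param candidate_sizes Increasing integer vector of (square) map side
#'   lengths.
#' @param cluster_counter Function `(data, size, seed) -> count` running the
#'   full downstream clustering at the given size.
#' @param seed Integer seed passed through to every run.
#' @param patience Number of consecutive non-increasing larger sizes
#'   required (default 2; capped by the candidates remaining).
#' @return A list: `size` (chosen), `curve` (data frame size/n_clusters),
#'   `plateau_found`.
#' @export
select_map_size <- function(data, candidate_sizes, cluster_counter, seed = 1,
                            patience = 2L) {
  stopifnot(is.numeric(candidate_sizes), length(candidate_sizes) >= 1L,
            !is.unsorted(candidate_sizes, strictly = TRUE))
  counts <- vapply(candidate_sizes, function(s) as.numeric(cluster_counter(data, s, seed)),
                   numeric(1))
  curve <- data.frame(size = candidate_sizes, n_clusters = counts)
  m <- length(counts)
  for (i in seq_len(max(0L, m - patience))) {
    if (all(counts[(i + 1L):(i + patience)] <= counts[i])) {
      return(list(size = candidate_sizes[i], curve = curve, plateau_found = TRUE))
    }
  }
  list(size = candidate_sizes[m], curve = curve, plateau_found = FALSE)
}
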