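#' Detect clusters on a distance map by watershed descent
#'
#' Clusters are basins of the U-matrix: regions of low codebook distance
#' surrounded by ridges of (locally) maximal distance. The procedure is
#' (1) every unit follows its lowest-valued lattice neighbor downhill until
#' it reaches a local minimum, which seeds a basin (ties go to the lowest
#' row-major index; a unit not above any neighbor is itself a seed);
#' (2) adjacent basins whose separating ridge is shallow — saddle height
#' minus the deeper of the two basin minima at most `theta` times the
#' dynamic range of the map — are merged iteratively, shallowest ridge
#' first; (3) items inherit the basin of their best-matching unit, and
#' basins holding no items are background.
#'
#' @param dmap A [distance_map()].
#' @param bmu Per-item BMU assignment as returned by
#'   [best_matching_units()] (or an integer vector of 1-based row-major unit
#'   indices).
#' @param theta Ridge-prominence merge threshold as a fraction of the
#'   distance map's dynamic range (default 0.10). A flat map merges into a
#'   single basin.
#' @param item_names Optional item labels.
#' @return An object of class `cluster_assignment`: `unit_labels` (per-unit
#'   cluster id, 0 = background), `item_labels` (per-item id, `NA` =
#'   unassigned), `item_units`, `n_clusters`, `cluster_sizes` (items per
#'   cluster), `width`, `height`.
#' @export
detect_clusters <- function(dmap, bmu, theta = 0.10, item_names = NULL) {
  stopifnot(inherits(dmap, "distance_map"))
  if (is.data.frame(bmu)) bmu <- bmu$unit
  bmu <- as.integer(bmu)
  u <- dmap$width * dmap$height
  if (any(bmu < 1L | bmu > u)) stop("BMU indices out of lattice range", call. = FALSE)
  d <- dmap$values
  nb <- lattice_neighbors(dmap$width, dmap$height, dmap$neighborhood)

  # steepest-descent pointers
  ptr <- vapply(seq_len(u), function(i) {
    cand <- c(i, nb[[i]])
    cand[which.min(d[cand])]      # which.min takes the first (lowest index) on ties
  }, integer(1))
  # pointer chasing with path compression
  root <- seq_len(u)
  repeat {
    nxt <- ptr[root]
    if (all(nxt == root)) break
    root <- nxt
  }

  basin <- match(root, sort(unique(root)))
  n_basin <- max(basin)
  basin_min <- vapply(seq_len(n_basin), function(b) min(d[basin == b]), numeric(1))
  rng <- max(d) - min(d)

  # saddle heights between adjacent basins: min over boundary unit pairs of
  # the higher endpoint
  merged <- merge_shallow_basins(basin, basin_min, d, nb, theta * rng)
  basin <- merged

  # items -> basins; empty basins become background
  item_basin <- basin[bmu]
  occupied <- sort(unique(item_basin))
  unit_labels <- ifelse(basin %in% occupied, match(basin, occupied), 0L)
  item_labels <- match(item_basin, occupied)
  if (!is.null(item_names)) names(item_labels) <- item_names
  sizes <- tabulate(item_labels, nbins = length(occupied))
  structure(list(unit_labels = unit_labels, item_labels = item_labels,
                 item_units = bmu, n_clusters = length(occupied),
                 cluster_sizes = sizes,
                 width = dmap$width, height = dmap$height),
            class = "cluster_assignment")
}

# Iteratively merge basin pairs whose ridge prominence (saddle height minus
# the higher of the two basin minima) is <= tol, shallowest first.
merge_shallow_basins <- function(basin, basin_min, d, nb, tol) {
  u <- length(basin)
  # undirected lattice edge list (i < j), built once
  ei <- rep(seq_len(u), lengths(nb))
  ej <- unlist(nb)
  keep <- ej > ei
  ei <- ei[keep]; ej <- ej[keep]
  edge_h <- pmax(d[ei], d[ej])
  repeat {
    a <- basin[ei]; b <- basin[ej]
    cross <- a != b
    if (!any(cross)) break
    lo <- pmin(a[cross], b[cross]); hi <- pmax(a[cross], b[cross])
    key <- paste(lo, hi)
    saddle <- tapply(edge_h[cross], key, min)
    bmin <- tapply(d, basin, min)
    ab <- do.call(rbind, strsplit(names(saddle), " "))
    prom <- as.numeric(saddle) -
      pmax(bmin[ab[, 1]], bmin[ab[, 2]])
    if (all(prom > tol)) break
    best <- which.min(prom)
    basin[basin == as.integer(ab[best, 2])] <- as.integer(ab[best, 1])
  }
  basin
}

#' Dissolve clusters below a minimum size
#'
#' Clusters with fewer than `min_members` items are dissolved: their items
#' become unassigned (`NA`) and their units background. Remaining clusters
#' are renumbered contiguously (in their previous order).
#'
#' @param assignment A `cluster_assignment`.
#' @param min_members Minimum item count to keep a cluster (default 2, i.e.
#'   singleton clusters are dropped).
#' @return The pruned `cluster_assignment`.
#' @export
prune_singletons <- function(assignment, min_members = 2L) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  stop_if_not_count(min_members, "min_members")
  keep <- which(assignment$cluster_sizes >= min_members)
  if (length(keep) == 0L) stop("all clusters fall below `min_members`", call. = FALSE)
  new_item <- match(assignment$item_labels, keep)
  new_unit <- match(assignment$unit_labels, keep)
  new_unit[is.na(new_unit)] <- 0L
  out <- assignment
  out$item_labels <- new_item
  out$unit_labels <- new_unit
  out$n_clusters <- length(keep)
  out$cluster_sizes <- assignment$cluster_sizes[keep]
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d clusters on a %d x %d map; sizes: %s; %d unassigned item(s)\n",
              x$n_clusters, x$width, x$height,
              paste(x$cluster_sizes, collapse = ", "),
              sum(is.na(x$item_labels))))
  invisible(x)
}
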