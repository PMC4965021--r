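test_that("training is deterministic given data and seed", {
  set.seed(1)
  x <- matrix(rnorm(60 * 5), 60, 5)
  a <- som_train(x, 6, 6, som_schedule(n_epochs = 20), seed = 4)
  b <- som_train(x, 6, 6, som_schedule(n_epochs = 20), seed = 4)
  expect_identical(a$codebook, b$codebook)
  expect_identical(a$training_log, b$training_log)
})

test_that("identical items collapse the codebook onto that item", {
  x <- matrix(rep(c(2, -1, 0.5), each = 40), 40, 3)
  s <- som_train(x, 4, 4, som_schedule(n_epochs = 30), seed = 2)
  expect_lt(max(abs(sweep(s$codebook, 2, x[1, ]))), 1e-6)
  expect_lt(tail(s$training_log, 1), 1e-6)
})

test_that("two well-separated blobs occupy disjoint contiguous map regions", {
  set.seed(3)
  blob1 <- matrix(rnorm(100 * 4, 0, 1), 100, 4)
  blob2 <- matrix(rnorm(100 * 4, 10, 1), 100, 4)
  x <- rbind(blob1, blob2)
  s <- som_train(x, 8, 8, seed = 5)
  bmu <- best_matching_units(s, x)
  u1 <- unique(bmu$unit[1:100]); u2 <- unique(bmu$unit[101:200])
  expect_length(intersect(u1, u2), 0)
  # contiguity: occupied units of each blob form one 8-connected component
  n_components <- function(units, width, height) {
    grid <- cbind(row = (units - 1) %/% width, col = (units - 1) %% width)
    seen <- rep(FALSE, length(units))
    comps <- 0
    for (i in seq_along(units)) {
      if (seen[i]) next
      comps <- comps + 1
      queue <- i
      seen[i] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        nb <- which(!seen & abs(grid[, 1] - grid[cur, 1]) <= 1 &
                      abs(grid[, 2] - grid[cur, 2]) <= 1)
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps
  }
  expect_identical(n_components(u1, 8, 8), 1)
  expect_identical(n_components(u2, 8, 8), 1)
})

test_that("best_matching_units equals exhaustive nearest-codebook search", {
  set.seed(7)
  x <- matrix(rnorm(10 * 3), 10, 3)
  s <- som_train(matrix(rnorm(30 * 3), 30, 3), 3, 3,
                 som_schedule(n_epochs = 10), seed = 1)
  bmu <- best_matching_units(s, x)
  brute <- apply(x, 1, function(v) {
    which.min(colSums((t(s$codebook) - v)^2))
  })
  expect_identical(bmu$unit, as.integer(brute))
  # coordinates agree with row-major indexing
  expect_identical(bmu$unit, as.integer(bmu$row * s$width + bmu$col + 1))
})

test_that("an item equal to a codebook vector maps to that unit; ties break row-major", {
  s <- som_train(matrix(rnorm(20 * 2), 20, 2), 3, 2,
                 som_schedule(n_epochs = 5), seed = 1)
  for (u in c(1L, 4L, 6L)) {
    expect_identical(best_matching_units(s, s$codebook[u, , drop = FALSE])$unit, u)
  }
  # exact tie between two units: force duplicate codebooks
  s$codebook[5, ] <- s$codebook[2, ]
  hit <- best_matching_units(s, s$codebook[2, , drop = FALSE])$unit
  expect_identical(hit, 2L)
  expect_error(best_matching_units(s, matrix(0, 1, 5)), "dimension mismatch")
})

test_that("distance map matches hand oracles and scales linearly", {
  # constant codebook: all zero
  s <- som_train(matrix(rep(1, 30), 30, 1) + 0, 3, 3,
                 som_schedule(n_epochs = 10), seed = 1)
  expect_true(all(distance_map(s)$values < 1e-8))
  # hand-set 2x2 codebooks (0), (1), (2), (3): each corner unit has two
  # 4-neighbors, mean distances (1+2)/2 = 1.5 everywhere
  s2 <- structure(list(codebook = matrix(c(0, 1, 2, 3), 4, 1),
                       width = 2L, height = 2L, seed = 1,
                       schedule = som_schedule(), training_log = 0),
                  class = "som_grid")
  expect_equal(distance_map(s2)$values, rep(1.5, 4))
  # scaling all codebooks by c > 0 scales the map by c
  s3 <- som_train(matrix(rnorm(40 * 3), 40, 3), 4, 4,
                  som_schedule(n_epochs = 10), seed = 2)
  d1 <- distance_map(s3)$values
  s3$codebook <- s3$codebook * 2.5
  expect_equal(distance_map(s3)$values, 2.5 * d1)
})

test_that("8-neighborhood distance map uses diagonal neighbors", {
  s2 <- structure(list(codebook = matrix(c(0, 1, 2, 3), 4, 1),
                       width = 2L, height = 2L, seed = 1,
                       schedule = som_schedule(), training_log = 0),
                  class = "som_grid")
  d8 <- distance_map(s2, neighborhood = 8L)
  # unit 1 (value 0): neighbors 1, 2, 3 -> mean 2
  expect_equal(d8$values[1], 2)
})

test_that("batch quantization error is non-increasing at a fixed small radius", {
  set.seed(9)
  x <- matrix(rnorm(150 * 4), 150, 4)
  s <- som_train(x, 5, 5, som_schedule(n_epochs = 25, initial_radius = 0.01,
                                       final_radius = 0.01), seed = 3)
  expect_true(all(diff(s$training_log) <= 1e-9))
})

test_that("a 1-D manifold maps monotonically along the lattice", {
  set.seed(4)
  t <- seq(0, 1, length.out = 120)
  x <- outer(t, c(3, -2, 5, 1)) + matrix(rnorm(480, sd = 0.02), 120, 4)
  s <- som_train(x, 30, 2, seed = 6)
  col <- best_matching_units(s, x)$col
  steps <- diff(col)
  frac_consistent <- max(mean(steps >= 0), mean(steps <= 0))
  expect_gte(frac_consistent, 0.95)
})

test_that("online mode trains and is deterministic", {
  set.seed(2)
  x <- matrix(rnorm(30 * 3), 30, 3)
  sch <- som_schedule(n_epochs = 5, mode = "online")
  a <- som_train(x, 4, 4, sch, seed = 8)
  b <- som_train(x, 4, 4, sch, seed = 8)
  expect_identical(a$codebook, b$codebook)
  expect_true(all(is.finite(a$training_log)))
  # codebook tracks the data range
  expect_lt(max(abs(a$codebook)), max(abs(x)) + 1)
})

test_that("map size selection finds the plateau of a counter curve", {
  counts <- c(`20` = 3, `30` = 5, `40` = 5, `50` = 5)
  counter <- function(data, size, seed) counts[[as.character(size)]]
  out <- select_map_size(NULL, c(20, 30, 40, 50), counter)
  expect_identical(out$size, 30)
  expect_true(out$plateau_found)
  expect_identical(out$curve$n_clusters, unname(counts))
  # strictly increasing curve: largest size, no plateau
  counter2 <- function(data, size, seed) size
  out2 <- select_map_size(NULL, c(10, 20, 30), counter2)
  expect_identical(out2$size, 30)
  expect_false(out2$plateau_found)
})

test_that("map size selection recovers the planted body-type count", {
  p <- prep_cohort(seed = 3, n = 1000, k = 4)
  counter <- function(data, size, seed) {
    typing <- tryCatch(
      assign_body_types(p$rowz, size, size, seed = seed),
      error = function(e) NULL)
    if (is.null(typing)) 0L else typing$n_types
  }
  out <- select_map_size(p$rowz$values, c(20, 30, 45), counter, seed = 203)
  expect_true(out$plateau_found)
  expect_identical(counter(NULL, out$size, 203), 4L)
})

test_that("non-finite input is rejected", {
  x <- matrix(rnorm(20), 10, 2)
  x[3, 1] <- NA
  expect_error(som_train(x, 3, 3), "finite")
})
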