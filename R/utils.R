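#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package take explicit seeds and route
# through this helper, so no function clobbers the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds so that any stage can be
#' rerun in isolation and reproduce its in-pipeline result. The derivation
#' hashes the stage name onto the seed and stays inside 32-bit integer range.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"feature_som"`).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stop_if_not_proportion <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) stop(sprintf("`%s` must be a proportion in %s", name,
                        if (open) "(0,1)" else "[0,1]"), call. = FALSE)
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x == round(x)) && all(x >= min)
  if (!ok) stop(sprintf("`%s` must be integer >= %d", name, min), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
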