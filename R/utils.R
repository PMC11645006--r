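# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package internals do not
#' perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Drop dimnames and coerce to plain numeric matrix.
as_plain_matrix <- function(x) {
  x <- as.matrix(x)
  dimnames(x) <- NULL
  storage.mode(x) <- "double"
  x
}

# Nearest evaluated grid index for border/stride fill-in.
# positions: integer pixel coords (1-based); grid: evaluated coords (sorted).
nearest_grid_index <- function(positions, grid) {
  idx <- findInterval(positions, grid, all.inside = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > length(grid)] <- length(grid)
  lower_ok <- idx >= 1L & idx < length(grid)
  # snap to whichever of grid[idx], grid[idx+1] is closer
  up <- which(lower_ok &
                abs(positions - grid[pmin(idx + 1L, length(grid))]) <
                abs(positions - grid[pmax(idx, 1L)]))
  idx[up] <- idx[up] + 1L
  idx
}
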