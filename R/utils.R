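#' @keywords internal
"_PACKAGE"

# Internal argument checks used across the package.  All stop() with the
# caller-facing argument name so error messages are actionable.

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

.assert_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  invisible(x)
}

.assert_square_symmetric <- function(x, name, tol = 1e-8) {
  .assert_matrix(x, name)
  if (nrow(x) != ncol(x))
    stop(sprintf("'%s' must be square", name), call. = FALSE)
  d <- abs(x - t(x))
  if (any(!is.na(d) & d > tol))
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  invisible(x)
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' One global seed governs all random draws in a pipeline run; per-stage
#' sub-seeds are derived deterministically so that re-running a single
#' stage reproduces exactly the draws it saw inside the full run.  The
#' result is kept below 2^31 so it is always a valid R integer seed.
#'
#' @param seed global integer seed.
#' @param stage character stage tag (e.g. `"invivo"`, `"invitro"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  .assert_scalar_number(seed, "seed", integer = TRUE)
  if (!is.character(stage) || length(stage) != 1L)
    stop("'stage' must be a single character string", call. = FALSE)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% .Machine$integer.max)
}

# row-wise variance without apply() overhead
.row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  (rowSums(x * x) - n * mu * mu) / (n - 1)
}
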