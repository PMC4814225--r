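# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-run seed derived from (seed, subject, condition, run) so a
# run can be regenerated independently of generation order.  Plain integer
# mixing; kept below 2^31.
derive_seed <- function(seed, subject_index, condition_index, run_index) {
  h <- (as.double(seed) %% 2147483647)
  for (x in c(subject_index, condition_index, run_index)) {
    h <- (h * 48271 + as.double(x) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "fcrel_config_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x),
          class = "fcrel_config_error")
  }
  invisible(x)
}

# Number of unique unordered pairs among k items.
#' Number of unique connections among K regions
#'
#' The handshake count `K * (K - 1) / 2`: how many unordered region pairs a
#' parcellation with `K` centers produces.  A 6923-region gray-matter
#' parcellation, for example, yields 23,960,503 connections.
#'
#' @param k Number of regions (non-negative integer, vectorised).
#' @return Number of unique `i < j` pairs, as a double to avoid integer
#'   overflow for whole-brain parcellations.
#' @examples
#' n_connections(6923)
#' @export
n_connections <- function(k) {
  if (any(k < 0) || any(k != floor(k))) {
    abort("`k` must contain non-negative integers.")
  }
  as.double(k) * (as.double(k) - 1) / 2
}

# Upper-triangle (i < j) index pairs for an n x n matrix, in the column-major
# order of `x[upper.tri(x)]` so extracted values can be cbound directly.
pair_index <- function(n, labels = NULL) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- tibble(
    roi_i = as.integer(ut[, 1L]),
    roi_j = as.integer(ut[, 2L])
  )
  if (!is.null(labels)) {
    out$roi_i <- labels[out$roi_i]
    out$roi_j <- labels[out$roi_j]
  }
  out
}
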