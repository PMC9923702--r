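# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`,
#' evaluates `expr`, and restores the previous state so that package
#' functions never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Pairwise Euclidean distance matrix for a D x N coordinate matrix.
pairwise_distances <- function(coords) {
  as.matrix(stats::dist(t(coords)))
}

# Ordering of `n` candidates by (distance, index): deterministic kNN ties.
order_by_distance <- function(d) {
  order(d, seq_along(d))
}

# Validate a D x N coordinate matrix.
check_coords <- function(coords) {
  if (!is.matrix(coords) || !is.numeric(coords)) {
    stop("`coords` must be a numeric matrix (dimensions x cells)", call. = FALSE)
  }
  if (any(!is.finite(coords))) {
    stop("`coords` contains non-finite values", call. = FALSE)
  }
  invisible(coords)
}

# Validate a genes x cells expression matrix with unique dimnames.
check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix (genes x cells)", call. = FALSE)
  }
  if (anyNA(expr)) stop("`expr` contains NA values", call. = FALSE)
  if (nrow(expr) < 1L || ncol(expr) < 2L) {
    stop("`expr` needs at least 1 gene and 2 cells", call. = FALSE)
  }
  if (!is.null(rownames(expr)) && anyDuplicated(rownames(expr))) {
    stop("duplicated gene identifiers in `expr`", call. = FALSE)
  }
  if (!is.null(colnames(expr)) && anyDuplicated(colnames(expr))) {
    stop("duplicated cell identifiers in `expr`", call. = FALSE)
  }
  invisible(expr)
}
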