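# Step 1: per-cell local tangent spaces and the classification of cells
# into tip / branching / intermediate from neighborhood geometry.

#' k-nearest-neighbor index sets
#'
#' For each cell, the indices of its `k` nearest cells by Euclidean
#' distance, self included, ordered by increasing distance with ties broken
#' by ascending cell index.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param k neighborhood size (2 <= k <= N).
#' @return list of integer vectors of length `k`; element `i` starts with `i`.
#' @export
knn_neighborhoods <- function(coords, k) {
  check_coords(coords)
  n <- ncol(coords)
  if (k < 2L || k > n) stop("`k` must be between 2 and the number of cells", call. = FALSE)
  dmat <- pairwise_distances(coords)
  lapply(seq_len(n), function(i) {
    d <- dmat[i, ]
    d[i] <- -1 # self always first
    order_by_distance(d)[seq_len(k)]
  })
}

#' Fit the local tangent space of a neighborhood
#'
#' Centers the neighborhood coordinates and takes the rank-`d` SVD
#' truncation: the left singular vectors span the best-fit d-dimensional
#' affine subspace (the local tangent space), and the first `d` rows of
#' `diag(sigma) %*% t(V)` are the local coordinates of the neighbors.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param ni integer vector of neighborhood member indices.
#' @param d tangent-space dimension (default 1).
#' @param cell_index index of the cell owning the neighborhood (optional,
#'   stored in the model).
#' @return object of class `local_tangent`: a list with `cell_index`,
#'   `neighbor_indices`, `mean` (D-vector), `basis` (D x d, orthonormal),
#'   `local_coords` (d x k, zero row sums), `singular_values`
#'   (nonincreasing), and `degenerate` (all points coincident).
#' @export
fit_local_tangent <- function(coords, ni, d = 1L, cell_index = ni[[1L]]) {
  k <- length(ni)
  if (k < d + 1L) stop("neighborhood smaller than d + 1", call. = FALSE)
  Xi <- coords[, ni, drop = FALSE]
  ctr <- rowMeans(Xi)
  Xc <- Xi - ctr
  sv <- svd(Xc)
  D <- nrow(coords)
  degenerate <- sv$d[1L] < .Machine$double.eps * k
  if (degenerate) {
    basis <- diag(nrow = D)[, seq_len(d), drop = FALSE] # arbitrary fixed basis
    theta <- matrix(0, d, k)
    sing <- rep(0, min(D, k))
  } else {
    basis <- sv$u[, seq_len(d), drop = FALSE]
    theta <- (sv$d[seq_len(d)] * t(sv$v[, seq_len(d), drop = FALSE]))
    theta <- matrix(theta, nrow = d)
    sing <- sv$d
  }
  structure(
    list(cell_index = cell_index, neighbor_indices = ni, mean = ctr,
         basis = basis, local_coords = theta, singular_values = sing,
         degenerate = degenerate),
    class = "local_tangent"
  )
}

#' Nonlinearity of a local neighborhood
#'
#' The ratio `sigma_{d+1}^2 / (sigma_1^2 + ... + sigma_d^2)` of the
#' neighborhood's singular values: close to 0 when the neighborhood is well
#' fit by a d-dimensional subspace (tip or intermediate cell), large near a
#' trajectory junction (branching cell). For d = 1 in a 2-D embedding the
#' score lies in [0, 1].
#'
#' @param model a `local_tangent` model.
#' @param d fitted dimension (default 1).
#' @return nonnegative scalar; 0 for a degenerate (coincident) neighborhood.
#' @export
nonlinearity_score <- function(model, d = 1L) {
  s <- model$singular_values
  if (length(s) < d + 1L) stop("model has fewer than d + 1 singular values", call. = FALSE)
  denom <- sum(s[seq_len(d)]^2)
  if (denom == 0) return(0)
  s[d + 1L]^2 / denom
}

#' Flag branching cells from nonlinearity scores
#'
#' The threshold delta_b is the `percentile`-th percentile
#' (linear-interpolation definition) of all scores; cells strictly above
#' it are flagged as branching, so at the default about 20% of cells —
#' those whose neighborhoods are least well fit by a one-dimensional
#' subspace — are flagged and later reassigned to branches by the
#' iterative tangent-distance assignment.
#'
#' @param scores numeric vector of per-cell nonlinearity scores.
#' @param percentile percentile level for the threshold (default 0.80).
#' @return list with `mask` (logical vector) and `threshold` (realized
#'   delta_b).
#' @export
identify_branching_cells <- function(scores, percentile = 0.80) {
  if (length(scores) < 2L) stop("need at least two cells", call. = FALSE)
  delta_b <- stats::quantile(scores, probs = percentile, names = FALSE, type = 7L)
  list(mask = scores > delta_b, threshold = delta_b)
}

#' Direction consistency of a cell's neighborhood
#'
#' Over all unordered pairs of neighbors p, q (the cell itself excluded),
#' counts the pairs lying on the same side of the cell, i.e. with
#' `(x_p - x_i)' (x_q - x_i) >= 0`, and scales the count by `2 / (k (k-1))`
#' where `k` is the neighborhood size including the cell. A tip cell, whose
#' neighbors all lie on one side, attains the maximum `(k-2)/k`; an
#' interior cell of a symmetric segment scores about half that.
#'
#' With `norm = "pairs"` the count is instead divided by the actual number
#' of pairs `(k-1)(k-2)/2`, so a perfect tip scores exactly 1.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param i cell index.
#' @param ni neighborhood index vector, must contain `i`.
#' @param norm normalization: `"count"` (scale by `2/(k(k-1))`, default) or
#'   `"pairs"` (divide by the true pair count).
#' @return scalar in `[0, (k-2)/k]` (or `[0, 1]` for `norm = "pairs"`).
#' @export
consistency_score <- function(coords, i, ni, norm = c("count", "pairs")) {
  norm <- match.arg(norm)
  if (!(i %in% ni)) stop("cell ", i, " is not in its own neighborhood", call. = FALSE)
  k <- length(ni)
  if (k < 3L) stop("neighborhood must have at least 3 members", call. = FALSE)
  others <- setdiff(ni, i)
  V <- coords[, others, drop = FALSE] - coords[, i]
  G <- crossprod(V) # inner products (x_p - x_i)' (x_q - x_i)
  same <- sum(G[upper.tri(G)] >= 0) # sgn(0) = 1 by convention
  if (norm == "count") {
    2 * same / (k * (k - 1))
  } else {
    npairs <- (k - 1) * (k - 2) / 2
    same / npairs
  }
}

#' Flag tip cells from consistency scores
#'
#' Cells whose consistency strictly exceeds `delta_t` are tips: their
#' neighbors lie on one side of them, which only happens at a trajectory
#' endpoint, so a tip lies on a one-dimensional stretch by construction
#' and is never treated as branching (when `branching_mask` is supplied it
#' is overridden for tips by the caller). Errors when the maximum
#' attainable score `(k-2)/k` does not exceed `delta_t`, since no cell
#' could ever qualify.
#'
#' @param consistencies per-cell consistency scores.
#' @param branching_mask optional logical vector; when supplied, cells
#'   flagged there are excluded from the tip set.
#' @param delta_t threshold (default 0.9).
#' @param k the neighborhood size the scores were computed with; used for
#'   the attainability check (skipped when `NULL`).
#' @return logical vector: `TRUE` for tip cells.
#' @export
identify_tip_cells <- function(consistencies, branching_mask = NULL,
                               delta_t = 0.9, k = NULL) {
  if (!is.null(k) && (k - 2) / k <= delta_t) {
    stop("with k = ", k, " the maximum consistency (k-2)/k = ",
         signif((k - 2) / k, 3), " cannot exceed delta_t = ", delta_t,
         "; increase k or lower delta_t", call. = FALSE)
  }
  tips <- consistencies > delta_t
  if (!is.null(branching_mask)) tips <- tips & !branching_mask
  tips
}

#' Select the root cell among the tips
#'
#' With experimental time labels, the tip with the earliest label wins
#' (ties broken by lowest cell index); without labels, a tip is drawn
#' uniformly using `seed`.
#'
#' @param tips logical tip mask.
#' @param time_labels optional per-cell ordinal or numeric labels.
#' @param seed integer seed for the unlabeled case.
#' @return root cell index.
#' @export
select_root <- function(tips, time_labels = NULL, seed = 1L) {
  idx <- which(tips)
  if (length(idx) == 0L) {
    stop("no tip cells found; lower `delta_t`, increase `k`, or supply an explicit root",
         call. = FALSE)
  }
  if (!is.null(time_labels)) {
    lab <- time_labels[idx]
    if (is.character(lab)) lab <- factor(lab) # ordinal by sorted level
    idx[order(as.numeric(lab), idx)][1L]
  } else if (length(idx) == 1L) {
    idx
  } else {
    with_seed(seed, sample(idx, 1L))
  }
}

#' Count tip groups (trajectory endpoints)
#'
#' Several adjacent cells at one trajectory endpoint typically all pass the
#' consistency threshold; for purposes such as bounding the number of
#' branches they represent a single endpoint. Two tip cells belong to the
#' same group when either lies in the other's neighborhood; groups are the
#' connected components of that relation.
#'
#' @param tip_idx indices of tip cells.
#' @param neighborhoods per-cell kNN index sets.
#' @return number of tip groups.
#' @export
count_tip_groups <- function(tip_idx, neighborhoods) {
  nt <- length(tip_idx)
  if (nt == 0L) return(0L)
  # union-find over tip cells
  parent <- seq_len(nt)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (a in seq_len(nt)) {
    for (b in seq_len(nt)) {
      if (a < b && (tip_idx[b] %in% neighborhoods[[tip_idx[a]]] ||
                    tip_idx[a] %in% neighborhoods[[tip_idx[b]]])) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  length(unique(vapply(seq_len(nt), find, integer(1L))))
}

#' Annotate every cell from its local neighborhood geometry
#'
#' Runs the full first stage: kNN neighborhoods, local tangent fits,
#' nonlinearity and consistency scores, branching/tip classification, and
#' root selection.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param k neighborhood size (default 50).
#' @param d tangent dimension (default 1).
#' @param delta_b_percentile upper-percentile level for the branching
#'   threshold (default 0.80).
#' @param delta_t tip threshold on consistency (default 0.9).
#' @param time_labels optional per-cell experimental time for root choice.
#' @param root optional explicit root cell index; overrides selection.
#' @param seed seed for the unlabeled root draw.
#' @param consistency_norm passed to [consistency_score()].
#' @return list with `annotation` (data.frame: cell, nonlinearity,
#'   consistency, category, is_root), `models` (per-cell `local_tangent`),
#'   `neighborhoods`, `root`, `delta_b`.
#' @export
annotate_cells <- function(coords, k = 50L, d = 1L, delta_b_percentile = 0.80,
                           delta_t = 0.9, time_labels = NULL, root = NULL,
                           seed = 1L, consistency_norm = "count") {
  check_coords(coords)
  n <- ncol(coords)
  nbhd <- knn_neighborhoods(coords, k)
  models <- lapply(seq_len(n), function(i) fit_local_tangent(coords, nbhd[[i]], d = d, cell_index = i))
  nonlin <- vapply(models, nonlinearity_score, numeric(1L), d = d)
  br <- identify_branching_cells(nonlin, percentile = delta_b_percentile)
  branching <- br$mask
  # degenerate (all-coincident) neighborhoods stay intermediate
  branching[vapply(models, `[[`, logical(1L), "degenerate")] <- FALSE
  cons <- vapply(seq_len(n), function(i) consistency_score(coords, i, nbhd[[i]], norm = consistency_norm),
                 numeric(1L))
  tips <- identify_tip_cells(cons, delta_t = delta_t,
                             k = if (consistency_norm == "count") k else NULL)
  # tips lie on a 1-D stretch by definition; they are never branching
  branching <- branching & !tips
  if (is.null(root)) {
    root <- select_root(tips, time_labels = time_labels, seed = seed)
  } else if (!tips[root]) {
    warning("explicit root ", root, " is not a tip cell; proceeding with it anyway")
  }
  category <- ifelse(branching, "branching", ifelse(tips, "tip", "intermediate"))
  ids <- colnames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  annotation <- data.frame(
    cell = ids, nonlinearity = nonlin, consistency = cons,
    category = category, is_root = seq_len(n) == root,
    stringsAsFactors = FALSE
  )
  list(annotation = annotation, models = models, neighborhoods = nbhd,
       root = root, delta_b = br$threshold)
}
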