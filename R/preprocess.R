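# Preprocessing: gene filtering, size-factor normalization, density filter,
# and the diffusion-map embedding the trajectory inference operates on.

#' Remove genes with zero expression in every cell
#'
#' @param expr numeric matrix, genes x cells.
#' @return the matrix restricted to genes with at least one nonzero entry,
#'   gene order preserved.
#' @examples
#' m <- rbind(g1 = c(1, 0), g2 = c(0, 0), g3 = c(2, 3))
#' colnames(m) <- c("c1", "c2")
#' filter_zero_genes(m)
#' @export
filter_zero_genes <- function(expr) {
  check_expression(expr)
  keep <- rowSums(expr != 0) > 0L
  if (!any(keep)) stop("all genes have zero expression in every cell", call. = FALSE)
  expr[keep, , drop = FALSE]
}

#' Size-factor normalization for read depth
#'
#' Scales each cell's column by its size factor, the ratio of that cell's
#' total expression to the median total over all cells, so that every
#' normalized cell has the same total (the median of the input totals).
#'
#' @param expr nonnegative numeric matrix, genes x cells.
#' @return matrix of the same shape with equal column totals.
#' @export
size_factor_normalize <- function(expr) {
  check_expression(expr)
  if (any(expr < 0)) stop("size-factor normalization expects nonnegative expression", call. = FALSE)
  totals <- colSums(expr)
  if (any(totals == 0)) {
    bad <- colnames(expr)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("cell(s) with zero total expression: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  target <- stats::median(totals)
  sweep(expr, 2L, totals / target, "/")
}

#' Remove low-density cells from an embedding
#'
#' Pools, over all cells, the distances to each of the `n_probe` nearest
#' neighbors; takes the `quantile` quantile of that pool as a radius
#' threshold; and removes cells with fewer than `min_neighbors` other cells
#' within the threshold.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param n_probe number of nearest neighbors probed per cell (default 100).
#' @param quantile quantile of the pooled neighbor distances (default 0.90).
#' @param min_neighbors minimum neighbor count within the radius (default 40).
#' @return list with `coords` (the filtered embedding) and `kept` (the
#'   surviving column indices of the input).
#' @export
density_filter_cells <- function(coords, n_probe = 100L, quantile = 0.90,
                                 min_neighbors = 40L) {
  check_coords(coords)
  n <- ncol(coords)
  if (n <= n_probe) {
    stop("need more cells than `n_probe` (", n_probe, ") to estimate density", call. = FALSE)
  }
  dmat <- pairwise_distances(coords)
  # distances to the n_probe nearest other cells, per cell
  knn_d <- vapply(seq_len(n), function(i) {
    sort(dmat[i, -i])[seq_len(n_probe)]
  }, numeric(n_probe))
  threshold <- stats::quantile(as.numeric(knn_d), probs = quantile, names = FALSE)
  counts <- vapply(seq_len(n), function(i) sum(dmat[i, -i] <= threshold), integer(1L))
  kept <- which(counts >= min_neighbors)
  list(coords = coords[, kept, drop = FALSE], kept = kept)
}

#' Diffusion-map embedding
#'
#' Builds a Gaussian kernel on pairwise Euclidean distances, applies
#' density normalization (anisotropic, alpha = 1), row-normalizes to a
#' Markov transition operator, and returns the `target_D` leading
#' non-trivial eigenvector coordinates (eigenvectors 2..target_D+1, each
#' scaled by its eigenvalue). The trivial constant eigenvector (eigenvalue
#' 1) is excluded.
#'
#' @param x numeric matrix, features x cells.
#' @param target_D number of diffusion coordinates to return.
#' @param sigma Gaussian kernel bandwidth; default is the median of all
#'   pairwise distances.
#' @return numeric matrix, `target_D` x cells, columns aligned with the
#'   input; column names carried over.
#' @export
diffusion_map <- function(x, target_D = 2L, sigma = NULL) {
  check_coords(x)
  n <- ncol(x)
  if (n < target_D + 2L) stop("need at least target_D + 2 cells", call. = FALSE)
  dmat <- pairwise_distances(x)
  if (is.null(sigma)) {
    sigma <- stats::median(dmat[upper.tri(dmat)])
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("kernel bandwidth is not positive: are all points coincident?", call. = FALSE)
  }
  K <- exp(-dmat^2 / (2 * sigma^2))
  # alpha = 1 density normalization removes the sampling-density bias
  q <- rowSums(K)
  K <- K / tcrossprod(q)
  d <- rowSums(K)
  if (any(d <= 0) || any(!is.finite(d))) {
    stop("degenerate kernel (rank-deficient or non-finite); check for duplicate-only input", call. = FALSE)
  }
  # symmetric conjugate of the transition operator: same eigenvalues,
  # right eigenvectors recovered as D^{-1/2} u
  dh <- 1 / sqrt(d)
  A <- K * tcrossprod(dh)
  es <- eigen(A, symmetric = TRUE)
  idx <- seq_len(target_D) + 1L
  psi <- dh * es$vectors[, idx, drop = FALSE]        # right eigenvectors of P
  lam <- es$values[idx]
  emb <- t(psi) * lam
  # deterministic sign: largest-magnitude entry of each coordinate positive
  for (j in seq_len(nrow(emb))) {
    pivot <- which.max(abs(emb[j, ]))
    if (emb[j, pivot] < 0) emb[j, ] <- -emb[j, ]
  }
  rownames(emb) <- paste0("DC", seq_len(target_D))
  colnames(emb) <- colnames(x)
  emb
}

#' Reduce an expression matrix to a low-dimensional embedding
#'
#' Optionally projects cells onto `pca_predim` principal components
#' (centered, unscaled) and then applies [diffusion_map()].
#'
#' @param expr numeric matrix, genes x cells (already filtered/normalized).
#' @param target_D embedding dimension (default 2).
#' @param pca_predim optional number of principal components to reduce to
#'   before the diffusion map (used for very high-dimensional data).
#' @param log1p if `TRUE`, apply `log1p` before reduction.
#' @param sigma optional diffusion kernel bandwidth, see [diffusion_map()].
#' @return numeric matrix, `target_D` x cells.
#' @export
reduce_dimensions <- function(expr, target_D = 2L, pca_predim = NULL,
                              log1p = FALSE, sigma = NULL) {
  check_expression(expr)
  n <- ncol(expr)
  if (target_D >= n) stop("`target_D` must be smaller than the number of cells", call. = FALSE)
  if (n < target_D + 2L) stop("need at least target_D + 2 cells", call. = FALSE)
  x <- if (log1p) log1p(expr) else expr
  if (!is.null(pca_predim)) {
    npc <- min(pca_predim, nrow(x), n - 1L)
    pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE, rank. = npc)
    x <- t(pc$x)
    colnames(x) <- colnames(expr)
  }
  diffusion_map(x, target_D = target_D, sigma = sigma)
}
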