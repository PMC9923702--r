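# Step 2: cluster non-branching cells into branches and absorb branching
# cells into their nearest branch, updating neighborhoods and tangent
# spaces as the branches grow.

#' Gaussian affinity matrix with median-distance bandwidth
#'
#' `A[p, q] = exp(-||x_p - x_q||^2 / (2 sigma^2))` with `sigma` equal to
#' `scale` times the median of the off-diagonal pairwise distances among
#' the selected cells; the diagonal is set to 0. At `scale = 1` the
#' bandwidth is the plain median pairwise distance; branch clustering uses
#' a down-scaled bandwidth (see [cluster_nonbranching()]) because the
#' median over all pairs is of the order of the trajectory diameter and is
#' blind to the much smaller gaps between branches.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param indices cells to include (default: all).
#' @param scale multiplier on the median-distance bandwidth (default 1).
#' @return symmetric affinity matrix with zero diagonal, entries in (0, 1].
#' @export
gaussian_affinity <- function(coords, indices = seq_len(ncol(coords)), scale = 1) {
  check_coords(coords)
  if (length(indices) < 2L) stop("need at least two cells", call. = FALSE)
  dmat <- pairwise_distances(coords[, indices, drop = FALSE])
  sigma <- scale * stats::median(dmat[upper.tri(dmat)])
  if (sigma <= 0) stop("all selected cells are coincident; affinity bandwidth is zero", call. = FALSE)
  A <- exp(-dmat^2 / (2 * sigma^2))
  diag(A) <- 0
  A
}

#' Graph (geodesic) distances along a kNN graph
#'
#' Builds a symmetric `knn`-nearest-neighbor graph with Euclidean edge
#' weights, bridges disconnected components through their closest point
#' pair, and returns all-pairs shortest-path distances. Along an elongated
#' trajectory this metric measures distance along the manifold rather than
#' through the ambient space, so cells on different branches that happen
#' to be spatially close remain far apart.
#'
#' @param X numeric matrix, cells x dimensions.
#' @param knn neighbors per cell in the graph (default 5).
#' @return dense symmetric matrix of graph distances.
#' @export
graph_distances <- function(X, knn = 5L) {
  n <- nrow(X)
  if (n < 2L) stop("need at least two points", call. = FALSE)
  knn <- min(knn, n - 1L)
  dmat <- as.matrix(stats::dist(X))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ], seq_len(n))[2:(knn + 1L)]
    adj[i, nb] <- dmat[i, nb]
    adj[nb, i] <- dmat[nb, i]
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    # bridge the two closest components through their closest point pair
    best <- c(Inf, NA, NA)
    for (ca in seq_len(comp$no - 1L)) {
      for (cb in (ca + 1L):comp$no) {
        ia <- which(comp$membership == ca)
        ib <- which(comp$membership == cb)
        sub <- dmat[ia, ib, drop = FALSE]
        m <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
        if (sub[m[1L], m[2L]] < best[1L]) best <- c(sub[m[1L], m[2L]], ia[m[1L]], ib[m[2L]])
      }
    }
    g <- igraph::add_edges(g, c(best[2L], best[3L]), weight = best[1L])
    comp <- igraph::components(g)
  }
  igraph::distances(g)
}

#' Cluster non-branching cells into branches
#'
#' Normalized spectral clustering (symmetric normalized Laplacian,
#' Gaussian affinity) of the non-branching cells, with the branch count
#' selected by the mean silhouette width over the candidate counts.
#'
#' Two choices depart from the textbook recipe, both because trajectory
#' branches are elongated, not blob-shaped. First, the affinity bandwidth
#' is `affinity_scale` times the median pairwise distance (default a
#' tenth): the plain median is of the order of the trajectory diameter and
#' washes out the gaps between branches entirely. Second, the silhouette
#' is computed by default in the graph metric of [graph_distances()]
#' (`sil_metric = "graph"`): under the Euclidean metric the mean
#' silhouette of elongated clusters systematically favors merging
#' adjacent branches, while under the manifold metric a merged pair of
#' branches is correctly penalized by the long within-cluster path
#' through their junction. For each candidate count several k-means
#' restart batches are scored and the partition with the best silhouette
#' is kept.
#'
#' @param coords numeric matrix, dimensions x cells (all cells).
#' @param nonbranching indices of the non-branching cells to cluster.
#' @param candidate_L integer vector of branch counts to try (default 2:8).
#' @param seed seed for the k-means restarts.
#' @param affinity_scale multiplier on the median-distance bandwidth
#'   (default 0.1).
#' @param sil_metric `"graph"` (default) or `"euclidean"` silhouette
#'   distance.
#' @param geo_knn neighbors for the graph metric (default 5).
#' @param restarts k-means restart batches scored per candidate (default 10).
#' @return list with `n_branches`, `labels` (integer vector over all cells,
#'   `NA` for cells not in `nonbranching`), and `silhouette` (named best
#'   widths per candidate).
#' @export
cluster_nonbranching <- function(coords, nonbranching, candidate_L = 2:8,
                                 seed = 1L, affinity_scale = 0.1,
                                 sil_metric = c("graph", "euclidean"),
                                 geo_knn = 5L, restarts = 10L) {
  check_coords(coords)
  sil_metric <- match.arg(sil_metric)
  candidate_L <- sort(unique(as.integer(candidate_L)))
  if (length(nonbranching) <= max(candidate_L)) {
    stop("need more non-branching cells than the largest candidate branch count", call. = FALSE)
  }
  A <- gaussian_affinity(coords, nonbranching, scale = affinity_scale)
  sub <- t(coords[, nonbranching, drop = FALSE])
  dsil <- if (sil_metric == "graph") {
    stats::as.dist(graph_distances(sub, knn = geo_knn))
  } else {
    stats::dist(sub)
  }
  # spectral embedding is shared across restarts; compute once
  d <- rowSums(A)
  d[d <= 0] <- .Machine$double.eps
  dh <- 1 / sqrt(d)
  M <- A * tcrossprod(dh)
  es <- eigen(M, symmetric = TRUE)
  sil <- stats::setNames(rep(-Inf, length(candidate_L)), candidate_L)
  labs <- vector("list", length(candidate_L))
  for (j in seq_along(candidate_L)) {
    L <- candidate_L[j]
    U <- es$vectors[, seq_len(L), drop = FALSE]
    rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
    U <- U / rn
    for (r in seq_len(restarts)) {
      cl <- with_seed(seed + 7919 * r, {
        stats::kmeans(U, centers = L, nstart = 3L, iter.max = 100L)$cluster
      })
      s <- mean(cluster::silhouette(cl, dsil)[, "sil_width"])
      if (s > sil[j]) {
        sil[j] <- s
        labs[[j]] <- cl
      }
    }
  }
  best <- which.max(sil)
  labels <- rep(NA_integer_, ncol(coords))
  labels[nonbranching] <- labs[[best]]
  list(n_branches = candidate_L[best], labels = labels, silhouette = sil)
}

#' Distance from a branching cell to a branch
#'
#' Uses the `n_anchor` branch cells closest to the cell as anchors. The
#' tangent distance is the mean norm of the residual of `x_i - x_j` after
#' projecting out anchor `j`'s tangent space; the Euclidean distance is the
#' mean of `||x_i - x_j||`. Returns their average.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param models per-cell list of `local_tangent` models (anchors must be
#'   fitted).
#' @param i branching cell index.
#' @param branch_cells indices of the branch members.
#' @param n_anchor number of anchor cells (all if the branch is smaller).
#' @return scalar distance `(d_t + d_e) / 2`.
#' @export
branch_distance <- function(coords, models, i, branch_cells, n_anchor = 50L) {
  if (length(branch_cells) == 0L) stop("branch is empty", call. = FALSE)
  d <- sqrt(colSums((coords[, branch_cells, drop = FALSE] - coords[, i])^2))
  anchors <- branch_cells[order_by_distance(d)][seq_len(min(n_anchor, length(branch_cells)))]
  xi <- coords[, i]
  dt <- vapply(anchors, function(j) {
    v <- xi - coords[, j]
    U <- models[[j]]$basis
    sqrt(sum((v - U %*% crossprod(U, v))^2))
  }, numeric(1L))
  de <- sqrt(colSums((coords[, anchors, drop = FALSE] - xi)^2))
  (mean(dt) + mean(de)) / 2
}

#' Iteratively assign branching cells to branches
#'
#' Globally greedy absorption: at each step the unassigned branching cell
#' with the smallest [branch_distance()] to any branch is assigned to that
#' branch (ties broken by lower branch index, then lower cell index), its
#' neighborhood is restricted to the original neighbors that lie in the
#' winning branch (plus itself), and its tangent model is refit on that
#' restricted neighborhood so it can serve as an anchor for later cells.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param models per-cell `local_tangent` models (updated in the result).
#' @param labels integer branch labels, `NA` for branching cells.
#' @param branching indices of the unassigned branching cells.
#' @param neighborhoods per-cell original kNN index sets.
#' @param n_anchor anchors per branch-distance evaluation (default 50).
#' @param d tangent dimension (default 1).
#' @return list with completed `labels`, updated `models` and
#'   `neighborhoods`, and `assignment_order` (data.frame cell/branch in
#'   assignment sequence).
#' @export
assign_branching_cells <- function(coords, models, labels, branching,
                                   neighborhoods, n_anchor = 50L, d = 1L) {
  if (any(is.na(labels[-branching])) && length(branching) > 0L) {
    stop("every non-branching cell must be labeled before assignment", call. = FALSE)
  }
  pending <- as.integer(branching)
  if (length(pending) == 0L) {
    return(list(labels = labels, models = models, neighborhoods = neighborhoods,
                assignment_order = data.frame(cell = integer(0), branch = integer(0))))
  }
  branch_ids <- sort(unique(labels[!is.na(labels)]))
  members <- lapply(branch_ids, function(b) which(labels == b))
  dall <- pairwise_distances(coords)
  # for d = 1 keep the per-cell tangent directions in a matrix so the
  # tangent residual sqrt(de^2 - ((x_i - x_j)' u_j)^2) vectorizes over anchors
  Umat <- if (d == 1L) {
    vapply(models, function(m) m$basis[, 1L], numeric(nrow(coords)))
  } else NULL
  bd <- function(i, mem) {
    de_all <- dall[i, mem]
    anchors <- mem[order_by_distance(de_all)][seq_len(min(n_anchor, length(mem)))]
    de <- dall[i, anchors]
    if (d == 1L) {
      V <- coords[, i] - coords[, anchors, drop = FALSE]
      dots <- colSums(V * Umat[, anchors, drop = FALSE])
      dt <- sqrt(pmax(de^2 - dots^2, 0))
    } else {
      dt <- vapply(seq_along(anchors), function(a) {
        j <- anchors[a]
        v <- coords[, i] - coords[, j]
        U <- models[[j]]$basis
        sqrt(max(sum(v^2) - sum(crossprod(U, v)^2), 0))
      }, numeric(1L))
    }
    (mean(dt) + mean(de)) / 2
  }
  L <- length(branch_ids)
  dmat <- matrix(Inf, length(pending), L)
  for (bj in seq_len(L)) {
    dmat[, bj] <- vapply(pending, bd, numeric(1L), mem = members[[bj]])
  }
  order_cells <- integer(0)
  order_branch <- integer(0)
  while (length(pending) > 0L) {
    pick <- which(dmat == min(dmat), arr.ind = TRUE)
    # ties: lower branch index, then lower cell index
    pick <- pick[order(pick[, 2L], pending[pick[, 1L]]), , drop = FALSE][1L, ]
    i <- pending[pick[1L]]
    bj <- pick[2L]
    b <- branch_ids[bj]
    labels[i] <- b
    members[[bj]] <- c(members[[bj]], i)
    new_ni <- intersect(neighborhoods[[i]], members[[bj]])
    if (length(new_ni) < d + 1L) {
      # too few same-branch neighbors: fall back to nearest branch members
      take <- members[[bj]][order_by_distance(dall[i, members[[bj]]])]
      new_ni <- unique(c(i, take[seq_len(min(n_anchor, length(take)))]))
    }
    neighborhoods[[i]] <- new_ni
    models[[i]] <- fit_local_tangent(coords, new_ni, d = d, cell_index = i)
    if (d == 1L) Umat[, i] <- models[[i]]$basis[, 1L]
    order_cells <- c(order_cells, i)
    order_branch <- c(order_branch, b)
    keep <- pending != i
    pending <- pending[keep]
    dmat <- dmat[keep, , drop = FALSE]
    if (length(pending) > 0L) {
      # anchors of the grown branch may have changed; refresh its column
      dmat[, bj] <- vapply(pending, bd, numeric(1L), mem = members[[bj]])
    }
  }
  list(labels = labels, models = models, neighborhoods = neighborhoods,
       assignment_order = data.frame(cell = order_cells, branch = order_branch))
}

#' Redistribute neighborhoods within branch and root branch
#'
#' After branch assignment each cell's neighborhood is rebuilt from the
#' cells eligible for it — those sharing its branch plus the root branch —
#' with an adaptive size chosen in `[kmin, kmax]` by
#' [adaptive_neighborhood_size()].
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param labels complete integer branch labels.
#' @param root_branch label of the branch containing the root cell.
#' @param kmin,kmax neighborhood size range (defaults 40, 100).
#' @param d tangent dimension (default 1).
#' @return list with `neighborhoods` (per-cell index sets, self included)
#'   and `chosen_k` (per-cell sizes).
#' @export
redistribute_neighborhoods <- function(coords, labels, root_branch,
                                       kmin = 40L, kmax = 100L, d = 1L) {
  if (anyNA(labels)) stop("labels must be complete", call. = FALSE)
  n <- ncol(coords)
  nbhd <- vector("list", n)
  chosen <- integer(n)
  for (i in seq_len(n)) {
    eligible <- which(labels == labels[i] | labels == root_branch)
    res <- adaptive_neighborhood_size(coords, eligible, i, kmin = kmin,
                                      kmax = kmax, d = d)
    nbhd[[i]] <- res$neighborhood
    chosen[i] <- res$k
  }
  list(neighborhoods = nbhd, chosen_k = chosen)
}
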