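# Step 3: adaptive neighborhood sizing, per-neighborhood alignment
# matrices, and the global eigenproblem whose second-smallest eigenvector
# is the pseudotime.

#' Choose a neighborhood size adaptively
#'
#' For each candidate size `k` in `[kmin, kmax]`, takes the `k` nearest
#' eligible cells and evaluates the d-dimensional fit ratio
#' `r(k) = sigma_{d+1} / sqrt(sigma_1^2 + ... + sigma_d^2)` of the centered
#' neighborhood; returns the `k` minimizing `r(k)` (ties to the smallest
#' `k`), so the neighborhood stays within the locally linear stretch of the
#' branch.
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param eligible candidate neighbor indices (must contain `i`).
#' @param i cell index.
#' @param kmin,kmax size range; if the eligible pool is smaller than
#'   `kmin` the whole pool is used.
#' @param d tangent dimension (default 1).
#' @return list with `k` (chosen size), `neighborhood` (the `k` nearest
#'   eligible cells, self first), and `ratios` (the r(k) profile).
#' @export
adaptive_neighborhood_size <- function(coords, eligible, i, kmin = 40L,
                                       kmax = 100L, d = 1L) {
  if (kmin > kmax) stop("kmin must not exceed kmax", call. = FALSE)
  if (kmin < d + 2L) stop("kmin must be at least d + 2", call. = FALSE)
  if (!(i %in% eligible)) eligible <- c(i, eligible)
  dd <- sqrt(colSums((coords[, eligible, drop = FALSE] - coords[, i])^2))
  dd[eligible == i] <- -1 # self first
  ord <- eligible[order_by_distance(dd)]
  pool <- length(ord)
  if (pool < kmin) {
    return(list(k = pool, neighborhood = ord, ratios = NULL))
  }
  kmax_eff <- min(kmax, pool)
  X <- coords[, ord[seq_len(kmax_eff)], drop = FALSE]
  ks <- kmin:kmax_eff
  if (nrow(coords) == 2L && d == 1L) {
    # closed form via cumulative first/second moments of the ordered pool
    c1 <- apply(X, 1L, cumsum)                      # k x 2
    s11 <- cumsum(X[1L, ]^2); s22 <- cumsum(X[2L, ]^2); s12 <- cumsum(X[1L, ] * X[2L, ])
    a <- s11[ks] - c1[ks, 1L]^2 / ks
    cc <- s22[ks] - c1[ks, 2L]^2 / ks
    b <- s12[ks] - c1[ks, 1L] * c1[ks, 2L] / ks
    disc <- sqrt(pmax((a - cc)^2 + 4 * b^2, 0))
    l1 <- pmax((a + cc + disc) / 2, 0)
    l2 <- pmax((a + cc - disc) / 2, 0)
    ratios <- ifelse(l1 == 0, 0, sqrt(l2 / l1))
  } else {
    ratios <- vapply(ks, function(k) {
      s <- svd(X[, seq_len(k), drop = FALSE] - rowMeans(X[, seq_len(k), drop = FALSE]),
               nu = 0L, nv = 0L)$d
      denom <- sqrt(sum(s[seq_len(d)]^2))
      if (denom == 0) 0 else s[d + 1L] / denom
    }, numeric(1L))
  }
  k <- ks[which.min(ratios)]
  list(k = k, neighborhood = ord[seq_len(k)], ratios = stats::setNames(ratios, ks))
}

#' Local alignment matrix of a neighborhood
#'
#' `W_i = (I - e e'/k)(I - pinv(Theta_i) Theta_i)`: the orthogonal
#' projector onto the complement of the span of the constant vector and the
#' rows of the local coordinates. Its quadratic form penalizes global
#' coordinates that are not an affine image of the local ones; by
#' construction `e' W_i = 0` and `Theta_i W_i = 0`.
#'
#' @param theta local coordinate matrix, d x k.
#' @param k neighborhood size (defaults to `ncol(theta)`).
#' @return k x k matrix.
#' @export
local_alignment_matrix <- function(theta, k = ncol(theta)) {
  theta <- matrix(theta, ncol = k)
  sv <- svd(theta)
  tol <- 1e-12 * max(sv$d, 0)
  pos <- sv$d > tol
  # pinv(theta) %*% theta = V_r V_r' for the positive singular directions
  P <- if (any(pos)) tcrossprod(sv$v[, pos, drop = FALSE]) else matrix(0, k, k)
  C <- diag(k) - matrix(1 / k, k, k)
  C %*% (diag(k) - P)
}

#' Assemble the global alignment matrix
#'
#' Scatter-adds each neighborhood's `W_i W_i'` into an N x N matrix
#' `B = sum_i S_i W_i W_i' S_i'` with `S_i` the 0-1 neighborhood selection
#' matrix. `B` is symmetric positive semidefinite and annihilates the
#' constant vector.
#'
#' @param neighborhoods per-cell index sets.
#' @param W_list per-cell alignment matrices, dimensions matching the
#'   neighborhood sizes.
#' @param n total number of cells.
#' @return dense symmetric N x N matrix.
#' @export
assemble_global_matrix <- function(neighborhoods, W_list, n) {
  covered <- logical(n)
  B <- matrix(0, n, n)
  for (i in seq_along(neighborhoods)) {
    ni <- neighborhoods[[i]]
    covered[ni] <- TRUE
    B[ni, ni] <- B[ni, ni] + tcrossprod(W_list[[i]])
  }
  if (!all(covered)) {
    stop("cell(s) not covered by any neighborhood: ",
         paste(which(!covered)[seq_len(min(5L, sum(!covered)))], collapse = ", "),
         call. = FALSE)
  }
  (B + t(B)) / 2
}

#' Solve the global alignment eigenproblem for pseudotime
#'
#' The constant vector is always a zero-eigenvector of `B` and carries no
#' ordering information, so it is deflated by default and the eigenvector
#' of the smallest remaining eigenvalue is taken (`deflate = FALSE`
#' reproduces the literal smallest-eigenvalue reading for comparison). The
#' sign is chosen so the root cell sits at the low end, and the vector is
#' affinely rescaled to [0, 1].
#'
#' @param B symmetric positive semidefinite alignment matrix.
#' @param root root cell index (pseudotime origin).
#' @param deflate drop the trivial constant direction first (default TRUE).
#' @return list with `tau` (per-cell pseudotime in [0, 1]), `root`,
#'   `eigenvalues` (the smallest few of `B`, constant direction included).
#' @export
solve_pseudotime <- function(B, root, deflate = TRUE) {
  n <- nrow(B)
  if (max(abs(B)) == 0) stop("alignment matrix is zero: no geometry to align", call. = FALSE)
  es <- eigen(B, symmetric = TRUE) # ascending after reversal
  vals <- rev(es$values)
  vecs <- es$vectors[, rev(seq_len(n)), drop = FALSE]
  if (deflate) {
    # shift the constant direction out of the bottom of the spectrum
    shift <- sum(abs(vals)) + 1
    es2 <- eigen(B + shift * matrix(1 / n, n, n), symmetric = TRUE)
    v <- es2$vectors[, n]
    lam2 <- es2$values[n]
    if (n >= 2L && abs(es2$values[n - 1L] - lam2) < 1e-10 * max(1, abs(lam2))) {
      warning("near-degenerate smallest eigenvalue; pseudotime direction may be unstable")
    }
  } else {
    v <- vecs[, 1L]
  }
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps * n) {
    stop("alignment eigenvector is constant: no geometry to align", call. = FALSE)
  }
  tau_fwd <- (v - rng[1L]) / diff(rng)
  tau_rev <- 1 - tau_fwd
  tau <- if (tau_fwd[root] <= tau_rev[root]) tau_fwd else tau_rev
  list(tau = tau, root = root, eigenvalues = vals[seq_len(min(6L, n))])
}
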