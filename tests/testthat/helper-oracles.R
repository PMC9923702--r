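# Shared helpers: small geometric fixtures and brute-force oracles used to
# cross-check the package's vectorized implementations.

# random D x N embedding
random_embedding <- function(n, D = 2L, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(D * n), D, n)
}

# brute-force k-nearest neighbors from a full distance matrix sort,
# self included, ties by ascending index
brute_knn <- function(coords, k) {
  dmat <- as.matrix(dist(t(coords)))
  lapply(seq_len(ncol(coords)), function(i) {
    d <- dmat[i, ]
    d[i] <- -1
    order(d, seq_along(d))[seq_len(k)]
  })
}

# brute-force windowed mean with edge truncation (rank window in tau order)
brute_smooth <- function(values, tau, half_window) {
  n <- length(values)
  ord <- order(tau, seq_len(n))
  v <- values[ord]
  sm <- sapply(seq_len(n), function(j) {
    mean(v[max(1, j - half_window):min(n, j + half_window)])
  })
  out <- numeric(n)
  out[ord] <- sm
  out
}

# a noiseless Y-shaped trajectory: three straight arms of `m` points each
# meeting at the origin, separated by 120 degrees
y_toy <- function(m = 60L, arm_len = 1) {
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 - 2 * pi / 3)
  pts <- do.call(cbind, lapply(ang, function(a) {
    t <- seq(arm_len / m, arm_len, length.out = m)
    rbind(t * cos(a), t * sin(a))
  }))
  colnames(pts) <- paste0("c", seq_len(ncol(pts)))
  arm <- rep(1:3, each = m)
  list(coords = pts, arm = arm, arc = rep(seq_len(m), 3))
}

# explicit selection-matrix assembly of B = sum_i S_i W_i W_i' S_i'
brute_assemble <- function(neighborhoods, W_list, n) {
  B <- matrix(0, n, n)
  for (i in seq_along(neighborhoods)) {
    ni <- neighborhoods[[i]]
    S <- matrix(0, n, length(ni))
    S[cbind(ni, seq_along(ni))] <- 1
    B <- B + S %*% tcrossprod(W_list[[i]]) %*% t(S)
  }
  B
}
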