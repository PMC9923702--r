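test_that("filter_zero_genes keeps exactly the genes with nonzero expression", {
  m <- rbind(g1 = c(1, 0), g2 = c(0, 0), g3 = c(2, 3))
  colnames(m) <- c("c1", "c2")
  out <- filter_zero_genes(m)
  expect_identical(rownames(out), c("g1", "g3"))
  expect_identical(out["g3", ], m["g3", ])

  # matrix without zero rows is returned unchanged
  full <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
  expect_identical(filter_zero_genes(full), full)

  # large random case against a per-row brute-force scan
  set.seed(42)
  big <- matrix(rpois(1000 * 50, 1), 1000, 50,
                dimnames = list(paste0("g", 1:1000), paste0("c", 1:50)))
  zero_rows <- sample(1000, 200)
  big[zero_rows, ] <- 0
  out <- filter_zero_genes(big)
  keep <- apply(big, 1, function(r) any(r != 0))
  expect_equal(nrow(out), sum(keep))
  expect_identical(rownames(out), rownames(big)[keep])

  # idempotent
  expect_identical(filter_zero_genes(out), out)
  expect_error(filter_zero_genes(big * 0), "zero expression")
})

test_that("size-factor normalization equalizes totals at the median library size", {
  m <- matrix(c(4, 6, 8, 12), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  out <- size_factor_normalize(m) # totals 10 and 20, median 15
  expect_equal(unname(colSums(out)), c(15, 15))

  # equal totals: unchanged
  eq <- matrix(c(1, 3, 2, 2), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_equal(size_factor_normalize(eq), eq)

  # doubling one cell's reads leaves its normalized column unchanged
  # (three cells so the median library size is unaffected)
  m3 <- matrix(c(4, 6, 8, 12, 10, 20), 2, 3,
               dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  m3b <- m3
  m3b[, 3] <- 2 * m3b[, 3]
  expect_equal(size_factor_normalize(m3b)[, 3], size_factor_normalize(m3)[, 3])

  # all column totals equal after normalization (random case)
  set.seed(7)
  r <- matrix(rpois(200, 5) + 1, 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  tot <- colSums(size_factor_normalize(r))
  expect_lt(diff(range(tot)) / mean(tot), 1e-10)

  bad <- m
  bad[, 1] <- 0
  expect_error(size_factor_normalize(bad), "zero total")
})

test_that("density filter removes isolated cells, matching a brute-force radius count", {
  set.seed(3)
  dense <- matrix(runif(2 * 200, -0.5, 0.5), 2, 200)
  outliers <- matrix(c(50, 50, -50, 40, 60, -60, -70, -10, 80, 0), 2, 5)
  coords <- cbind(dense, outliers)
  colnames(coords) <- paste0("c", 1:205)
  res <- density_filter_cells(coords, n_probe = 100, quantile = 0.90, min_neighbors = 40)
  removed <- setdiff(1:205, res$kept)
  expect_true(all(201:205 %in% removed)) # every isolated outlier goes
  expect_lte(length(setdiff(removed, 201:205)), 2) # at most a couple of edge cells

  # brute-force check of the removal set
  dmat <- as.matrix(dist(t(coords)))
  knn_d <- sapply(1:205, function(i) sort(dmat[i, -i])[1:100])
  thr <- quantile(as.numeric(knn_d), 0.90, names = FALSE)
  counts <- sapply(1:205, function(i) sum(dmat[i, -i] <= thr))
  expect_setequal(res$kept, which(counts >= 40))

  # degenerate geometry: all identical points are all kept
  same <- matrix(1, 2, 120)
  expect_length(density_filter_cells(same, n_probe = 50)$kept, 120)

  # min_neighbors = 0 is a vacuous filter
  expect_length(density_filter_cells(coords, n_probe = 100, min_neighbors = 0)$kept, 205)

  expect_error(density_filter_cells(coords[, 1:50], n_probe = 100), "n_probe")
})

test_that("diffusion map preserves angular order on a circle and excludes the trivial eigenvector", {
  n <- 60
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  circ <- rbind(cos(theta), sin(theta))
  colnames(circ) <- paste0("c", 1:n)
  emb <- diffusion_map(circ, 2)
  # the two leading coordinates trace the loop: angular order preserved
  ang <- atan2(emb[2, ], emb[1, ])
  ang <- (ang - ang[1]) %% (2 * pi)
  sp <- cor(ang, theta, method = "spearman")
  expect_equal(abs(sp), 1, tolerance = 1e-8)
  # no coordinate is the constant trivial eigenvector
  expect_gt(sd(emb[1, ]), 1e-8)
  expect_gt(sd(emb[2, ]), 1e-8)
})

test_that("diffusion map is invariant under rigid motion and cell permutation", {
  x <- random_embedding(80, D = 3, seed = 11)
  emb <- diffusion_map(x, 2)
  # rigid motion: kernel depends only on distances
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  emb_rot <- diffusion_map(qr_q %*% x + c(5, -2, 1), 2)
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(emb[j, ], emb_rot[j, ], tolerance = 1e-6)) ||
                isTRUE(all.equal(emb[j, ], -emb_rot[j, ], tolerance = 1e-6)))
  }
  # permutation of cells then inverse permutation of output columns
  set.seed(2)
  perm <- sample(80)
  emb_p <- diffusion_map(x[, perm], 2)[, order(perm)]
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(unname(emb[j, ]), unname(emb_p[j, ]), tolerance = 1e-6)) ||
                isTRUE(all.equal(unname(emb[j, ]), -unname(emb_p[j, ]), tolerance = 1e-6)))
  }
  expect_error(diffusion_map(matrix(1, 2, 30), 2), "coincident|degenerate")
})

test_that("reduce_dimensions recovers the ordering of a noiseless 1-D curve", {
  n <- 300
  t <- seq(0, 1, length.out = n)
  set.seed(5)
  basis <- matrix(rnorm(50 * 3), 50, 3)
  curve <- basis %*% rbind(t, t^2, sqrt(t)) # smooth 1-D curve in 50 dims
  curve <- curve - min(curve)
  dimnames(curve) <- list(paste0("g", 1:50), paste0("c", 1:n))
  emb <- reduce_dimensions(curve, target_D = 2)
  expect_equal(abs(cor(emb[1, ], t, method = "spearman")), 1, tolerance = 1e-6)

  # PCA pre-reduction to full rank is a rotation: diffusion map unchanged up to sign
  emb_pca <- reduce_dimensions(curve, target_D = 2, pca_predim = 50)
  for (j in 1:2) {
    expect_true(isTRUE(all.equal(unname(emb[j, ]), unname(emb_pca[j, ]), tolerance = 1e-4)) ||
                isTRUE(all.equal(unname(emb[j, ]), -unname(emb_pca[j, ]), tolerance = 1e-4)))
  }
  expect_error(reduce_dimensions(curve[, 1:3], target_D = 4), "target_D")
})
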