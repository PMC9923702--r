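# End-to-end orchestration: configuration, the three-step pipeline, and a
# result container.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the method's standard settings: neighborhood size `k = 50` for cell
#' classification, adaptive alignment neighborhoods in `[40, 100]`,
#' embedding dimension `D = 2`, branching threshold at the 80th percentile
#' of nonlinearity, tip threshold `delta_t = 0.9`.
#'
#' @param k neighborhood size for tip/branching identification.
#' @param delta_b_percentile upper-percentile level of the nonlinearity
#'   threshold.
#' @param delta_t consistency threshold for tip cells.
#' @param kmin,kmax adaptive neighborhood range for alignment.
#' @param D embedding dimension.
#' @param d local tangent dimension (1 for pseudotime).
#' @param root optional explicit root cell (index or cell id).
#' @param seed integer seed for every stochastic step.
#' @param normalize apply size-factor normalization (disable for inputs
#'   that are coordinates rather than expression counts).
#' @param log1p log-transform before dimension reduction.
#' @param pca_predim optional PCA pre-reduction dimension.
#' @param reduce apply the diffusion map; `FALSE` uses the input rows
#'   directly as the embedding (requires `D` rows).
#' @param sigma optional diffusion kernel bandwidth.
#' @param candidate_branches integer vector of branch counts for the
#'   silhouette search; `NULL` derives `max(2, T-1) .. T+1` from the
#'   number of detected tip groups `T` (falling back to 2..8).
#' @param n_anchor anchors per branch-distance evaluation; `NULL` uses `k`.
#' @param consistency_norm `"count"` or `"pairs"`, see
#'   [consistency_score()].
#' @param affinity_scale bandwidth scale of the clustering affinity, see
#'   [cluster_nonbranching()].
#' @param sil_metric silhouette metric for branch-count selection,
#'   `"graph"` (default) or `"euclidean"`.
#' @return list of class `bltsa_config`.
#' @export
bltsa_config <- function(k = 50L, delta_b_percentile = 0.80, delta_t = 0.9,
                         kmin = 40L, kmax = 100L, D = 2L, d = 1L,
                         root = NULL, seed = 1L, normalize = TRUE,
                         log1p = FALSE, pca_predim = NULL, reduce = TRUE,
                         sigma = NULL, candidate_branches = NULL,
                         n_anchor = NULL, consistency_norm = "count",
                         affinity_scale = 0.1, sil_metric = "graph") {
  if (kmin > kmax) stop("kmin must not exceed kmax", call. = FALSE)
  if (delta_b_percentile <= 0 || delta_b_percentile >= 1) {
    stop("delta_b_percentile must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), delta_b_percentile = delta_b_percentile,
         delta_t = delta_t, kmin = as.integer(kmin), kmax = as.integer(kmax),
         D = as.integer(D), d = as.integer(d), root = root,
         seed = as.integer(seed), normalize = normalize, log1p = log1p,
         pca_predim = pca_predim, reduce = reduce, sigma = sigma,
         candidate_branches = candidate_branches, n_anchor = n_anchor,
         consistency_norm = consistency_norm,
         affinity_scale = affinity_scale, sil_metric = sil_metric),
    class = "bltsa_config"
  )
}

#' Run the full branched local tangent space alignment pipeline
#'
#' Executes preprocessing (gene filter, size-factor normalization,
#' diffusion-map embedding), cell classification (tip / branching /
#' intermediate), branch clustering and branching-cell assignment, and the
#' global tangent-space alignment that yields per-cell pseudotime in
#' [0, 1].
#'
#' @param expr numeric matrix: genes x cells expression, or (with
#'   `config$reduce = FALSE` and `D` rows) an embedding used directly.
#' @param config a [bltsa_config()].
#' @param time_labels optional per-cell experimental time used for root
#'   selection.
#' @param embedding optional precomputed `D` x cells embedding; skips
#'   preprocessing entirely.
#' @return object of class `bltsa_result`: list with `tau`, `branch`,
#'   `annotation` (per-cell data.frame), `root`, `root_branch`,
#'   `n_branches`, `embedding`, `chosen_k`, `eigenvalues`, `silhouette`,
#'   `delta_b`, `assignment_order`, `config`, `log`.
#' @examples
#' sim <- simulate_geometric_trifurcation(seed = 7)
#' cfg <- bltsa_config(normalize = FALSE, seed = 7)
#' res <- run_bltsa(sim$matrix, cfg, time_labels = sim$true_tau)
#' correlation_metrics(res$tau, sim$true_tau)
#' @export
run_bltsa <- function(expr, config = bltsa_config(), time_labels = NULL,
                      embedding = NULL) {
  stopifnot(inherits(config, "bltsa_config"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  # ---- preprocessing -------------------------------------------------
  if (is.null(embedding)) {
    check_expression(expr)
    x <- expr
    if (config$normalize) {
      x <- filter_zero_genes(x)
      x <- size_factor_normalize(x)
      note("normalized: ", nrow(x), " genes kept of ", nrow(expr))
    }
    if (config$reduce) {
      embedding <- reduce_dimensions(x, target_D = config$D,
                                     pca_predim = config$pca_predim,
                                     log1p = config$log1p,
                                     sigma = config$sigma)
      note("diffusion map to D = ", config$D)
    } else {
      if (nrow(x) != config$D) {
        stop("with reduce = FALSE the input must have exactly D = ",
             config$D, " rows", call. = FALSE)
      }
      embedding <- if (config$log1p) log1p(x) else x
      note("using input rows directly as the embedding")
    }
  } else {
    check_coords(embedding)
    note("using precomputed embedding")
  }
  n <- ncol(embedding)
  if (n <= config$kmax) {
    warning("fewer cells (", n, ") than kmax (", config$kmax,
            "); adaptive neighborhoods will saturate")
  }
  ids <- colnames(embedding)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  root_idx <- config$root
  if (is.character(root_idx)) {
    root_idx <- match(root_idx, ids)
    if (is.na(root_idx)) stop("root cell id not found", call. = FALSE)
  }

  # ---- step 1: classify cells ---------------------------------------
  ann <- annotate_cells(embedding, k = config$k, d = config$d,
                        delta_b_percentile = config$delta_b_percentile,
                        delta_t = config$delta_t, time_labels = time_labels,
                        root = root_idx, seed = config$seed,
                        consistency_norm = config$consistency_norm)
  note("delta_b = ", signif(ann$delta_b, 4), "; ",
       sum(ann$annotation$category == "branching"), " branching, ",
       sum(ann$annotation$category == "tip"), " tip cells; root = ",
       ids[ann$root])

  # ---- step 2: branches ---------------------------------------------
  branching <- which(ann$annotation$category == "branching")
  nonbranching <- setdiff(seq_len(n), branching)
  cand <- config$candidate_branches
  if (is.null(cand)) {
    # adjacent tip cells at one trajectory endpoint count as one tip group
    tip_idx <- which(ann$annotation$category == "tip")
    Tn <- count_tip_groups(tip_idx, ann$neighborhoods)
    cand <- if (Tn >= 2L) max(2L, Tn - 1L):(Tn + 1L) else 2:8
    note("tip groups: ", Tn, "; candidate branch counts ",
         min(cand), "..", max(cand))
  }
  cand <- cand[cand < length(nonbranching)]
  clus <- cluster_nonbranching(embedding, nonbranching, candidate_L = cand,
                               seed = config$seed,
                               affinity_scale = config$affinity_scale,
                               sil_metric = config$sil_metric)
  note("silhouette-selected L = ", clus$n_branches, " from {",
       paste(names(clus$silhouette), collapse = ","), "}")
  n_anchor <- if (is.null(config$n_anchor)) config$k else config$n_anchor
  asg <- assign_branching_cells(embedding, ann$models, clus$labels, branching,
                                ann$neighborhoods, n_anchor = n_anchor,
                                d = config$d)
  labels <- asg$labels
  root_branch <- labels[ann$root]

  # ---- step 3: alignment --------------------------------------------
  red <- redistribute_neighborhoods(embedding, labels, root_branch,
                                    kmin = config$kmin, kmax = config$kmax,
                                    d = config$d)
  W_list <- vector("list", n)
  for (i in seq_len(n)) {
    m <- fit_local_tangent(embedding, red$neighborhoods[[i]], d = config$d,
                           cell_index = i)
    W_list[[i]] <- local_alignment_matrix(m$local_coords,
                                          length(red$neighborhoods[[i]]))
  }
  B <- assemble_global_matrix(red$neighborhoods, W_list, n)
  sol <- solve_pseudotime(B, ann$root)
  note("pseudotime solved; smallest eigenvalues: ",
       paste(signif(sol$eigenvalues[1:3], 3), collapse = ", "))

  structure(
    list(tau = stats::setNames(sol$tau, ids),
         branch = stats::setNames(labels, ids),
         annotation = ann$annotation, root = ann$root,
         root_branch = root_branch, n_branches = clus$n_branches,
         embedding = embedding, chosen_k = red$chosen_k,
         eigenvalues = sol$eigenvalues, silhouette = clus$silhouette,
         delta_b = ann$delta_b, assignment_order = asg$assignment_order,
         config = config, log = log_lines),
    class = "bltsa_result"
  )
}

#' @export
print.bltsa_result <- function(x, ...) {
  cat("BLTSA pseudotime result\n")
  cat("  cells:", length(x$tau), " branches:", x$n_branches,
      " root:", names(x$tau)[x$root], "\n")
  cat("  tau range: [", signif(min(x$tau), 3), ", ", signif(max(x$tau), 3),
      "]\n", sep = "")
  cat("  tips:", sum(x$annotation$category == "tip"),
      " branching:", sum(x$annotation$category == "branching"), "\n")
  invisible(x)
}
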