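# Reading and writing expression matrices (dense TSV/CSV, MatrixMarket
# MTX with gene/barcode sidecars) and pipeline result tables.

#' Read an expression matrix
#'
#' Dense `.tsv`/`.csv` files are read as genes x cells with the first
#' column holding gene identifiers and the header holding cell
#' identifiers. `.mtx` files are read as MatrixMarket triplets with
#' `genes.tsv` and `barcodes.tsv` sidecars (one identifier per line) in
#' the same directory, unless explicit sidecar paths are given.
#'
#' @param path file path; format inferred from the extension.
#' @param genes,barcodes optional sidecar paths for MTX input.
#' @return numeric matrix, genes x cells, with dimnames.
#' @export
read_expression_matrix <- function(path, genes = NULL, barcodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "csv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            row.names = 1L, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    check_expression(m)
    m
  } else if (ext == "mtx") {
    if (is.null(genes)) genes <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dirname(path), "barcodes.tsv")
    for (f in c(genes, barcodes)) {
      if (!file.exists(f)) stop("sidecar not found: ", f, call. = FALSE)
    }
    sm <- Matrix::readMM(path)
    g <- readLines(genes)
    b <- readLines(barcodes)
    if (nrow(sm) != length(g) || ncol(sm) != length(b)) {
      stop("dimension mismatch between ", path, " (", nrow(sm), " x ", ncol(sm),
           ") and sidecars ", genes, " (", length(g), "), ", barcodes,
           " (", length(b), ")", call. = FALSE)
    }
    m <- as.matrix(sm)
    dimnames(m) <- list(g, b)
    check_expression(m)
    m
  } else {
    stop("unsupported extension: .", ext, " (use .tsv, .csv or .mtx)", call. = FALSE)
  }
}

#' Write an expression matrix
#'
#' @param expr numeric matrix, genes x cells.
#' @param path output path; `.tsv`/`.csv` writes dense with a gene-id
#'   column, `.mtx` writes MatrixMarket triplets plus `genes.tsv` /
#'   `barcodes.tsv` sidecars next to it.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  check_expression(expr)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "csv")) {
    sep <- if (ext == "csv") "," else "\t"
    df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), path)
    writeLines(rownames(expr), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(expr), file.path(dirname(path), "barcodes.tsv"))
  } else {
    stop("unsupported extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Write the pipeline result tables
#'
#' Writes `pseudotime.tsv` (cell_id, tau, branch, is_root, chosen_k),
#' `branches.tsv` (cell_id, branch, is_root_branch, assignment_rank) and
#' `cells.tsv` (the per-cell annotation) into a directory.
#'
#' @param result a `bltsa_result`.
#' @param dir output directory, created if missing.
#' @return the directory, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "bltsa_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(result$tau)
  n <- length(ids)
  pt <- data.frame(cell_id = ids, tau = result$tau, branch = result$branch,
                   is_root = seq_len(n) == result$root,
                   chosen_k = result$chosen_k)
  utils::write.table(pt, file.path(dir, "pseudotime.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rank <- rep(NA_integer_, n)
  if (nrow(result$assignment_order) > 0L) {
    rank[result$assignment_order$cell] <- seq_len(nrow(result$assignment_order))
  }
  br <- data.frame(cell_id = ids, branch = result$branch,
                   is_root_branch = result$branch == result$root_branch,
                   assignment_rank = rank)
  utils::write.table(br, file.path(dir, "branches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$annotation, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Write an embedding as TSV
#'
#' @param coords numeric matrix, dimensions x cells.
#' @param path output TSV path (columns: cell_id, dim1..dimD).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(coords, path) {
  check_coords(coords)
  ids <- colnames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(coords)))
  df <- data.frame(cell_id = ids, t(coords), check.names = FALSE)
  names(df)[-1L] <- paste0("dim", seq_len(nrow(coords)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
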