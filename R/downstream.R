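# exact k-nearest-neighbour indices of each query row among the reference
# rows (Euclidean); dense distance computation, adequate at single-cell
# embedding sizes used here
knn_indices <- function(query, ref, k) {
  q2 <- rowSums(query^2)
  r2 <- rowSums(ref^2)
  d2 <- outer(q2, r2, "+") - 2 * tcrossprod(query, ref)
  idx <- apply(d2, 1, function(row) order(row)[seq_len(k)])
  # apply() returns a k x n matrix (or a bare vector when k = 1)
  matrix(idx, nrow = nrow(query), ncol = k, byrow = TRUE)
}

#' Predict cell-type labels for the unlabelled modality
#'
#' Same classifier contract as [label_transfer_f1()] — a linear SVM fit on
#' the source modality's full-dimensional joint coordinates — but returns
#' the predictions themselves rather than scores, for use when only one
#' modality carries annotations.
#'
#' @param emb An embedding tibble whose `source` modality is labelled.
#' @param source `"rna"` or `"atac"`: the modality providing labels.
#' @param cost,kernel SVM options (see [label_transfer_f1()]).
#' @return A tibble with `cell_id` and `predicted_label` for every cell of
#'   the other modality.
#' @export
predict_labels <- function(emb, source = c("rna", "atac"), cost = 1,
                           kernel = "linear") {
  source <- match.arg(source)
  mods <- modality_split(emb$modality)
  is_src <- mods == source
  y <- emb$label[is_src]
  if (length(unique(y)) == 1) {
    # degenerate but well-defined: a single-class source predicts itself
    return(tibble::tibble(cell_id = emb$cell_id[!is_src],
                          predicted_label = rep(unique(y), sum(!is_src))))
  }
  pred <- svm_transfer(emb, source, cost, kernel)
  tibble::tibble(cell_id = pred$test_cells,
                 predicted_label = pred$predicted)
}

#' Predict gene expression for activity-profiled cells
#'
#' For each ATAC cell, the predicted expression profile is the unweighted
#' mean of the expression profiles of its `k` nearest RNA cells by
#' Euclidean distance in the joint latent space — the minimal prediction
#' mechanism the joint representation affords.
#'
#' @param emb An embedding tibble containing both modalities.
#' @param rna_expr An [expr_matrix()] whose rows align (by cell id) with
#'   the RNA-tagged embedding rows.
#' @param k Number of neighbours (default 30; clamped to the number of
#'   RNA cells with a warning).
#' @return A matrix of predicted expression, one row per ATAC cell, with
#'   the gene columns of `rna_expr`.
#' @export
predict_expression <- function(emb, rna_expr, k = 30) {
  mods <- modality_split(emb$modality)
  X <- embedding_dims(emb)
  rna_idx <- which(mods == "rna")
  atac_idx <- which(mods == "atac")
  if (!length(rna_idx) || !length(atac_idx)) {
    stop("embedding must contain both modalities", call. = FALSE)
  }
  ids <- emb$cell_id[rna_idx]
  if (!setequal(ids, cell_ids(rna_expr))) {
    stop("rna_expr cell ids do not match the rna-tagged embedding rows",
         call. = FALSE)
  }
  E <- unclass(rna_expr)[ids, , drop = FALSE]
  if (k > length(rna_idx)) {
    warning(sprintf("k = %d exceeds the %d rna cells; clamped", k,
                    length(rna_idx)))
    k <- length(rna_idx)
  }
  nn <- knn_indices(X[atac_idx, , drop = FALSE],
                    X[rna_idx, , drop = FALSE], k)
  pred <- matrix(0, length(atac_idx), ncol(E),
                 dimnames = list(emb$cell_id[atac_idx], colnames(E)))
  for (i in seq_len(nrow(nn))) {
    pred[i, ] <- colMeans(E[nn[i, ], , drop = FALSE])
  }
  pred
}

#' Assemble layers for activity-expression velocity
#'
#' Velocity analysis of chromatin-priming dynamics replaces the spliced
#' layer with the gene activity matrix and the unspliced layer with the
#' (true or predicted) gene expression matrix, and takes neighbourhood
#' moments in the joint latent space rather than in PCA space. This
#' function builds that input container: the two layers reindexed to a
#' common cell order, the joint coordinates, and the k-nearest-neighbour
#' graph (row degree exactly `k`) an external velocity solver needs for
#' moment estimation.
#'
#' @param activity An [expr_matrix()] of gene activity (spliced slot).
#' @param expression A matrix of expression values with matching cell and
#'   gene ids (unspliced slot; typically [predict_expression()] output).
#' @param emb An embedding tibble covering the same cells.
#' @param k Neighbours in the joint-space graph.
#' @return A list of class `velocity_layers`: `spliced`, `unspliced`
#'   (cells x genes matrices), `joint_coords` (cells x d), `neighbors`
#'   (sparse cells x cells adjacency, row degree `k`), `neighbor_k`.
#' @export
assemble_velocity_layers <- function(activity, expression, emb, k = 30) {
  expression <- as.matrix(expression)
  cells <- rownames(expression)
  genes <- colnames(expression)
  missing_cells <- setdiff(cells, cell_ids(activity))
  missing_genes <- setdiff(genes, gene_ids(activity))
  if (length(missing_cells) || length(missing_genes)) {
    stop("activity matrix lacks cell(s)/gene(s): ",
         paste(utils::head(c(missing_cells, missing_genes), 5),
               collapse = ", "), call. = FALSE)
  }
  if (!all(cells %in% emb$cell_id)) {
    stop("embedding lacks cell(s): ",
         paste(utils::head(setdiff(cells, emb$cell_id), 5),
               collapse = ", "), call. = FALSE)
  }
  X <- embedding_dims(emb)[cells, , drop = FALSE]
  if (k >= length(cells)) {
    stop("k must be smaller than the number of cells", call. = FALSE)
  }
  # self is each row's nearest point; ask for k+1 and drop it
  nn <- knn_indices(X, X, k + 1)
  adj_i <- integer(0)
  adj_j <- integer(0)
  for (i in seq_len(nrow(nn))) {
    nb <- setdiff(nn[i, ], i)[seq_len(k)]
    adj_i <- c(adj_i, rep(i, k))
    adj_j <- c(adj_j, nb)
  }
  neighbors <- Matrix::sparseMatrix(i = adj_i, j = adj_j, x = 1,
                                    dims = c(length(cells), length(cells)),
                                    dimnames = list(cells, cells))
  structure(
    list(spliced = unclass(activity)[cells, genes, drop = FALSE],
         unspliced = expression,
         joint_coords = X,
         neighbors = neighbors,
         neighbor_k = as.integer(k)),
    class = "velocity_layers")
}

#' @export
print.velocity_layers <- function(x, ...) {
  cat(sprintf(
    "<velocity_layers> %d cells x %d genes | joint space %d-d | k = %d\n",
    nrow(x$spliced), ncol(x$spliced), ncol(x$joint_coords), x$neighbor_k))
  invisible(x)
}

#' Write / read velocity layers as a plain-text directory
#'
#' Layout: `spliced.mtx` / `unspliced.mtx` (MatrixMarket),
#' `neighbors.mtx`, `cells.tsv`, `genes.tsv`, `joint_coords.tsv` and a
#' `manifest.json` echoing `neighbor_k`.
#'
#' @param x A `velocity_layers` object.
#' @param dir Directory path.
#' @return `write_velocity_layers()` returns `dir` invisibly;
#'   `read_velocity_layers()` returns the object.
#' @export
write_velocity_layers <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(x$spliced, sparse = TRUE),
                  file.path(dir, "spliced.mtx"))
  Matrix::writeMM(Matrix::Matrix(x$unspliced, sparse = TRUE),
                  file.path(dir, "unspliced.mtx"))
  Matrix::writeMM(x$neighbors, file.path(dir, "neighbors.mtx"))
  writeLines(rownames(x$spliced), file.path(dir, "cells.tsv"))
  writeLines(colnames(x$spliced), file.path(dir, "genes.tsv"))
  utils::write.table(x$joint_coords, file.path(dir, "joint_coords.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  jsonlite::write_json(list(neighbor_k = x$neighbor_k),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_velocity_layers
#' @export
read_velocity_layers <- function(dir) {
  cells <- readLines(file.path(dir, "cells.tsv"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  rd <- function(f) {
    m <- as.matrix(Matrix::readMM(file.path(dir, f)))
    dimnames(m) <- list(cells, genes)
    m
  }
  coords <- as.matrix(utils::read.table(file.path(dir, "joint_coords.tsv"),
                                        sep = "\t", row.names = 1))
  colnames(coords) <- sprintf("dim_%d", seq_len(ncol(coords)))
  nb <- methods::as(Matrix::readMM(file.path(dir, "neighbors.mtx")),
                    "CsparseMatrix")
  nb <- nb * 1  # pattern/logical sparse formats read back as numeric
  dimnames(nb) <- list(cells, cells)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(
    list(spliced = rd("spliced.mtx"), unspliced = rd("unspliced.mtx"),
         joint_coords = coords, neighbors = nb,
         neighbor_k = as.integer(manifest$neighbor_k)),
    class = "velocity_layers")
}
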