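#' Embedding tibbles
#'
#' Joint-representation coordinates are carried as an ordinary tibble with
#' one row per cell: `cell_id`, `modality`, `label` (may be `NA`), and
#' coordinate columns `dim_1 ... dim_d`. This matches the on-disk TSV
#' exchange format and pipes cleanly through dplyr; [embedding_dims()]
#' recovers the numeric matrix when linear algebra is needed.
#'
#' @param coords Numeric matrix, cells in rows.
#' @param modality Character vector of per-cell modality tags.
#' @param label Optional character vector of per-cell type labels.
#' @param cell_id Optional character vector of cell identifiers.
#' @return A tibble of class `modalign_embedding`.
#' @export
as_embedding <- function(coords, modality, label = NULL, cell_id = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (length(modality) == 1) modality <- rep(modality, n)
  if (length(modality) != n) {
    stop("modality must have one entry per cell", call. = FALSE)
  }
  if (is.null(label)) label <- rep(NA_character_, n)
  if (length(label) != n) stop("label must have one entry per cell",
                               call. = FALSE)
  if (is.null(cell_id)) cell_id <- sprintf("cell%d", seq_len(n))
  colnames(coords) <- sprintf("dim_%d", seq_len(ncol(coords)))
  out <- tibble::tibble(cell_id = as.character(cell_id),
                        modality = as.character(modality),
                        label = as.character(label))
  out <- dplyr::bind_cols(out, tibble::as_tibble(coords))
  class(out) <- c("modalign_embedding", class(out))
  out
}

#' @rdname as_embedding
#' @param emb An embedding tibble.
#' @return For `embedding_dims()`, the cells-by-d coordinate matrix.
#' @export
embedding_dims <- function(emb) {
  cols <- grep("^dim_", names(emb), value = TRUE)
  if (!length(cols)) stop("no dim_* coordinate columns found", call. = FALSE)
  m <- as.matrix(emb[, cols])
  rownames(m) <- emb$cell_id
  m
}

#' Read / write embeddings as TSV
#'
#' Columns: `cell_id`, `modality`, `label`, `dim_1 ... dim_d`.
#'
#' @param emb An embedding tibble.
#' @param path TSV file path.
#' @return `write_embedding()` returns `path` invisibly; `read_embedding()`
#'   returns the embedding tibble.
#' @export
write_embedding <- function(emb, path) {
  utils::write.table(as.data.frame(emb), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_embedding(as.matrix(tab[, grep("^dim_", names(tab)), drop = FALSE]),
               modality = tab$modality,
               label = if ("label" %in% names(tab)) tab$label,
               cell_id = tab$cell_id)
}
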