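#' Construct an expression or gene-activity matrix
#'
#' The basic container of the package: a dense cells-by-genes nonnegative
#' matrix with unique cell and gene identifiers, a modality tag and a flag
#' recording whether log1p normalisation has been applied. scRNA-seq counts
#' and scATAC-seq-derived gene-activity values share this container so both
#' can feed one encoder.
#'
#' @param values Numeric matrix, cells in rows, genes in columns. All entries
#'   must be nonnegative and finite.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column.
#' @param modality Either `"rna"` (gene expression) or `"atac_activity"`
#'   (gene-activity derived from accessibility peaks).
#' @param normalized Logical; has [lognorm()] already been applied?
#'
#' @return An object of class `expr_matrix`: the value matrix with row and
#'   column names set and `modality` / `normalized` attributes.
#' @export
#' @examples
#' m <- expr_matrix(matrix(0:5, 3, 2), paste0("c", 1:3), c("g1", "g2"), "rna")
#' dim(m)
expr_matrix <- function(values, cell_ids, gene_ids,
                        modality = c("rna", "atac_activity"),
                        normalized = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(cell_ids) != nrow(values)) {
    stop("length(cell_ids) must equal the number of rows", call. = FALSE)
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) must equal the number of columns", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("matrix entries must be finite and nonnegative", call. = FALSE)
  }
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  structure(values,
            modality = modality,
            normalized = isTRUE(normalized),
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes | modality: %s | %s\n",
              nrow(x), ncol(x), attr(x, "modality"),
              if (attr(x, "normalized")) "log1p-normalized" else "raw"))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
cell_ids <- function(x) rownames(x)

#' @rdname expr_matrix
#' @export
gene_ids <- function(x) colnames(x)

#' @rdname expr_matrix
#' @export
modality <- function(x) attr(x, "modality")

#' @rdname expr_matrix
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

# keep class + attributes through column subsetting used internally
subset_genes <- function(x, genes) {
  expr_matrix(unclass(x)[, genes, drop = FALSE],
              rownames(x), genes,
              modality = attr(x, "modality"),
              normalized = attr(x, "normalized"))
}

stopifnot_expr_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "expr_matrix")) {
    stop(sprintf("`%s` must be an expr_matrix (see ?expr_matrix)", arg),
         call. = FALSE)
  }
  invisible(x)
}
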