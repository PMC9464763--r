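#' Read an expression or gene-activity matrix from disk
#'
#' Supports the two plain-text layouts commonly produced by single-cell
#' pipelines:
#' \describe{
#'   \item{`mtx_dir`}{a directory holding a MatrixMarket triplet:
#'     `matrix.mtx`, `features.tsv` (gene ids) and `barcodes.tsv` (cell
#'     ids). Both orientations are accepted; the genes-by-cells dialect
#'     written by many tools is detected by matching matrix dimensions
#'     against the companion-file lengths and transposed so that cells are
#'     always rows.}
#'   \item{`dense_delim`}{a dense TSV/CSV with a header row of gene ids and
#'     a first column of cell ids.}
#' }
#'
#' @param path Path to the directory (`mtx_dir`) or file (`dense_delim`).
#' @param fmt Input format, `"mtx_dir"` or `"dense_delim"`.
#' @param modality Modality tag to attach, `"rna"` or `"atac_activity"`.
#'
#' @return An [expr_matrix()] with `normalized = FALSE`.
#' @export
read_matrix <- function(path, fmt = c("mtx_dir", "dense_delim"),
                        modality = c("rna", "atac_activity")) {
  fmt <- match.arg(fmt)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)

  if (fmt == "mtx_dir") {
    files <- file.path(path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      stop("mtx_dir is missing companion file(s): ",
           paste(basename(missing), collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(files[1]))
    genes <- readLines(files[2])
    cells <- readLines(files[3])
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      # already cells x genes
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)
    } else {
      stop(sprintf(
        "matrix dimensions %d x %d match neither %d barcodes x %d features nor its transpose",
        nrow(m), ncol(m), length(cells), length(genes)), call. = FALSE)
    }
    if (any(m < 0)) stop("negative entries in matrix.mtx", call. = FALSE)
    return(expr_matrix(m, cells, genes, modality = modality))
  }

  # dense_delim
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (any(m < 0)) stop("negative entries in ", path, call. = FALSE)
  expr_matrix(m, rownames(tab), colnames(tab), modality = modality)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix()] for the same two layouts.
#'
#' @param x An [expr_matrix()].
#' @param path Output directory (`mtx_dir`) or file (`dense_delim`).
#' @inheritParams read_matrix
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, fmt = c("mtx_dir", "dense_delim")) {
  fmt <- match.arg(fmt)
  stopifnot_expr_matrix(x)
  if (fmt == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(gene_ids(x), file.path(path, "features.tsv"))
    writeLines(cell_ids(x), file.path(path, "barcodes.tsv"))
  } else {
    tab <- data.frame(cell_id = cell_ids(x), unclass(x),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(tab) <- c("cell_id", gene_ids(x))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Log1p-normalise a raw matrix
#'
#' Applies `y = log(1 + x)` entrywise, the standard variance-stabilising
#' transform for both count and gene-activity data; the pseudocount of 1
#' keeps zeros at zero. Refuses to run twice on the same matrix.
#'
#' @param x A raw (`normalized = FALSE`) [expr_matrix()].
#' @return The transformed `expr_matrix` with `normalized = TRUE`.
#' @export
lognorm <- function(x) {
  stopifnot_expr_matrix(x)
  if (is_normalized(x)) {
    stop("matrix is already log1p-normalized; refusing to transform twice",
         call. = FALSE)
  }
  expr_matrix(log1p(unclass(x)), cell_ids(x), gene_ids(x),
              modality = attr(x, "modality"), normalized = TRUE)
}

#' Select highly variable genes by binned normalised dispersion
#'
#' Classic mean-binned dispersion selection: per gene, mean and dispersion
#' (variance over mean) are computed on the expm1 scale (i.e. undoing the
#' log1p), genes are cut into 20 equal-frequency mean bins, dispersions are
#' z-scored within each bin, and the `n_target` genes with the largest
#' normalised dispersion are flagged. The procedure is deterministic; rank
#' ties are broken lexicographically by gene id. Genes with zero mean or
#' zero variance cannot be ranked and are never selected.
#'
#' @param x A normalised [expr_matrix()] with at least 2 cells.
#' @param n_target Number of genes to select (default 3000); clamped to the
#'   number of qualifying genes.
#' @param n_bins Number of equal-frequency mean bins (default 20).
#' @return A tibble of class `hvg_result` with one row per gene: `gene_id`,
#'   `mean`, `dispersion`, `dispersion_norm` and `selected`.
#' @export
select_hvg <- function(x, n_target = 3000, n_bins = 20) {
  stopifnot_expr_matrix(x)
  if (!is_normalized(x)) stop("select_hvg expects a log1p-normalized matrix",
                              call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 cells", call. = FALSE)
  if (!is.numeric(n_target) || length(n_target) != 1 || n_target <= 0) {
    stop("n_target must be a positive integer", call. = FALSE)
  }

  v <- expm1(unclass(x))
  mu <- colMeans(v)
  vr <- colSums((v - rep(mu, each = nrow(v)))^2) / (nrow(v) - 1)
  disp <- ifelse(mu > 0, vr / mu, NA_real_)
  qualifying <- is.finite(disp) & disp > 0

  disp_norm <- rep(-Inf, ncol(x))
  if (any(qualifying)) {
    qmu <- mu[qualifying]
    # equal-frequency bins on the qualifying genes' means
    nb <- max(1L, min(n_bins, length(unique(qmu))))
    breaks <- unique(stats::quantile(qmu, probs = seq(0, 1, length.out = nb + 1)))
    bins <- cut(qmu, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    z <- disp[qualifying]
    for (b in unique(bins)) {
      idx <- bins == b
      m <- mean(z[idx])
      s <- stats::sd(z[idx])
      z[idx] <- if (is.na(s) || s == 0) 0 else (z[idx] - m) / s
    }
    disp_norm[qualifying] <- z
  }

  ids <- gene_ids(x)
  ord <- order(-disp_norm, ids)
  n_sel <- min(n_target, sum(qualifying))
  selected <- rep(FALSE, ncol(x))
  if (n_sel > 0) selected[ord[seq_len(n_sel)]] <- TRUE

  out <- tibble::tibble(
    gene_id = ids,
    mean = mu,
    dispersion = ifelse(is.na(disp), NA_real_, disp),
    dispersion_norm = disp_norm,
    selected = selected
  )
  class(out) <- c("hvg_result", class(out))
  attr(out, "n_target") <- n_target
  out
}

#' Harmonise two modalities to one shared feature space
#'
#' Builds the integration feature list as the union of the two per-modality
#' highly variable gene sets, intersected with the genes present in both
#' matrices, sorted lexicographically; both matrices are subset and
#' reordered to that list so each column index refers to the same gene in
#' both modalities.
#'
#' @param rna,atac Normalised [expr_matrix()] objects.
#' @param hvg_rna,hvg_atac [select_hvg()] results for `rna` and `atac`.
#' @return A list of class `paired_input` with elements `rna`, `atac`
#'   (column-harmonised `expr_matrix` objects) and `features` (the shared
#'   ordered gene list).
#' @export
harmonize_features <- function(rna, atac, hvg_rna, hvg_atac) {
  stopifnot_expr_matrix(rna)
  stopifnot_expr_matrix(atac)
  if (!is_normalized(rna) || !is_normalized(atac)) {
    stop("both matrices must be log1p-normalized before harmonization",
         call. = FALSE)
  }
  hvg_union <- union(hvg_rna$gene_id[hvg_rna$selected],
                     hvg_atac$gene_id[hvg_atac$selected])
  shared <- intersect(gene_ids(rna), gene_ids(atac))
  features <- sort(intersect(hvg_union, shared))
  if (length(features) == 0) {
    stop(sprintf(
      paste0("integration impossible: no highly variable gene is shared ",
             "(HVG union %d, shared genes %d)"),
      length(hvg_union), length(shared)), call. = FALSE)
  }
  structure(
    list(rna = subset_genes(rna, features),
         atac = subset_genes(atac, features),
         features = features),
    class = "paired_input")
}

#' @export
print.paired_input <- function(x, ...) {
  cat(sprintf("<paired_input> %d shared features | rna: %d cells | atac: %d cells\n",
              length(x$features), nrow(x$rna), nrow(x$atac)))
  invisible(x)
}

#' One-call preprocessing: normalise, select HVG, harmonise
#'
#' Convenience wrapper running [lognorm()] (skipped for matrices already
#' normalised), [select_hvg()] per modality and [harmonize_features()].
#'
#' @inheritParams harmonize_features
#' @inheritParams select_hvg
#' @return A `paired_input` (see [harmonize_features()]).
#' @export
preprocess_pair <- function(rna, atac, n_target = 3000) {
  if (!is_normalized(rna)) rna <- lognorm(rna)
  if (!is_normalized(atac)) atac <- lognorm(atac)
  harmonize_features(rna, atac,
                     select_hvg(rna, n_target),
                     select_hvg(atac, n_target))
}
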