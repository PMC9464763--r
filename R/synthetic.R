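#' Specification of a synthetic dual-modality dataset
#'
#' Collects every knob of the generator in one validated list. The default
#' values define the package's "easy" study condition: 4 balanced cell
#' types, 500 cells per modality, 300 genes and a strong type signal, a
#' regime where integration should clearly succeed within minutes of CPU
#' training.
#'
#' @param n_cells_rna,n_cells_atac Cells per modality.
#' @param n_types Number of cell types shared by the modalities.
#' @param type_proportions Simplex vector of length `n_types` (defaults to
#'   balanced types).
#' @param n_genes Number of shared gene features.
#' @param n_programs Latent dimension of the cell-type signal.
#' @param signal_strength Standard deviation of the per-type program
#'   centers; 0 removes all type structure.
#' @param modality_shift Additive offset (log1p scale) applied to the
#'   activity modality; a removable, purely technical modality effect.
#' @param dropout_atac Probability of zeroing an activity entry, emulating
#'   the extreme sparsity of gene-activity matrices.
#' @param nb_dispersion Negative-binomial size parameter of the RNA counts
#'   (smaller = noisier).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param paired If `TRUE`, both modalities must have the same number of
#'   cells and atac cell `i` is generated from the same type as rna cell
#'   `i`, giving a known ground-truth pairing.
#'
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells_rna = 500, n_cells_atac = 500,
                           n_types = 4, type_proportions = NULL,
                           n_genes = 300, n_programs = 10,
                           signal_strength = 3, modality_shift = 1,
                           dropout_atac = 0.7, nb_dispersion = 2,
                           seed = 1, paired = FALSE) {
  counts <- c(n_cells_rna, n_cells_atac, n_types, n_genes, n_programs)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("cell/type/gene/program counts must be positive integers",
         call. = FALSE)
  }
  if (is.null(type_proportions)) {
    type_proportions <- rep(1 / n_types, n_types)
  }
  if (length(type_proportions) != n_types) {
    stop("type_proportions must have length n_types", call. = FALSE)
  }
  if (abs(sum(type_proportions) - 1) > 1e-9 || any(type_proportions < 0)) {
    stop("type_proportions must be nonnegative and sum to 1", call. = FALSE)
  }
  if (n_types > min(n_cells_rna, n_cells_atac)) {
    stop("n_types cannot exceed the number of cells in either modality",
         call. = FALSE)
  }
  if (signal_strength < 0 || modality_shift < 0) {
    stop("signal_strength and modality_shift must be >= 0", call. = FALSE)
  }
  if (dropout_atac < 0 || dropout_atac > 1) {
    stop("dropout_atac must be a probability", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (paired && n_cells_rna != n_cells_atac) {
    stop("paired data requires equal cell counts", call. = FALSE)
  }
  structure(
    list(n_cells_rna = as.integer(n_cells_rna),
         n_cells_atac = as.integer(n_cells_atac),
         n_types = as.integer(n_types),
         type_proportions = type_proportions,
         n_genes = as.integer(n_genes),
         n_programs = as.integer(n_programs),
         signal_strength = signal_strength,
         modality_shift = modality_shift,
         dropout_atac = dropout_atac,
         nb_dispersion = nb_dispersion,
         seed = as.integer(seed),
         paired = isTRUE(paired)),
    class = "synthetic_spec")
}

#' Simulate a paired-modality single-cell dataset
#'
#' Shared cell-type structure is encoded by per-type program centers
#' `mu_t ~ Normal(0, signal_strength^2)` in `n_programs` dimensions, mapped
#' to gene space through one random loading matrix common to both
#' modalities; per-gene means are `softplus(loading %*% mu_t)`. RNA counts
#' are negative-binomial draws around those means. Activity values are
#' Poisson draws around the means thinned by 0.5, with Bernoulli dropout
#' zero-masking, and finally carry a global additive offset of
#' `modality_shift` on the log1p scale (implemented exactly as
#' `x' = (1+x) * exp(shift) - 1` on the detected values, so `log1p(x') =
#' log1p(x) + shift` while zeros — the sparsity hallmark of gene-activity
#' data — stay zero, as a library-size-like technical offset would). The
#' two modalities therefore share biology but
#' differ in noise family, sparsity and a technical global shift — the
#' distortion an integrator must remove.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with elements `rna` and
#'   `atac` ([expr_matrix()] objects, raw scale), `labels_rna`,
#'   `labels_atac` (character vectors of cell types), and `pairing` (a
#'   tibble `rna_cell` / `atac_cell`, or `NULL` when unpaired).
#' @export
simulate_multiome <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("spec must come from synthetic_spec()", call. = FALSE)
  }
  set.seed(spec$seed)
  K <- spec$n_types
  P <- spec$n_programs
  G <- spec$n_genes

  centers <- matrix(stats::rnorm(K * P, sd = spec$signal_strength), K, P)
  loading <- matrix(stats::rnorm(P * G, sd = 1 / sqrt(P)), P, G)
  softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  type_means <- softplus(centers %*% loading)  # K x G

  draw_types <- function(n) {
    sample.int(K, n, replace = TRUE, prob = spec$type_proportions)
  }
  types_rna <- draw_types(spec$n_cells_rna)
  types_atac <- if (spec$paired) types_rna else draw_types(spec$n_cells_atac)

  mu_rna <- type_means[types_rna, , drop = FALSE]
  rna <- matrix(stats::rnbinom(length(mu_rna), mu = as.vector(mu_rna),
                               size = spec$nb_dispersion),
                nrow = spec$n_cells_rna)

  mu_atac <- 0.5 * type_means[types_atac, , drop = FALSE]
  atac <- matrix(stats::rpois(length(mu_atac), lambda = as.vector(mu_atac)),
                 nrow = spec$n_cells_atac)
  if (spec$dropout_atac > 0) {
    keep <- matrix(stats::runif(length(atac)) >= spec$dropout_atac,
                   nrow = nrow(atac))
    atac <- atac * keep
  }
  if (spec$modality_shift > 0) {
    # library-size-like technical offset: log1p(x') = log1p(x) + shift on
    # detected entries; zeros stay zero so the activity sparsity pattern
    # (the hallmark of gene-activity data) is preserved
    nz <- atac > 0
    atac[nz] <- (1 + atac[nz]) * exp(spec$modality_shift) - 1
  }

  genes <- sprintf("gene%03d", seq_len(G))
  rna_cells <- sprintf("rna_cell%04d", seq_len(spec$n_cells_rna))
  atac_cells <- sprintf("atac_cell%04d", seq_len(spec$n_cells_atac))
  type_names <- sprintf("type%d", seq_len(K))

  structure(
    list(rna = expr_matrix(rna, rna_cells, genes, modality = "rna"),
         atac = expr_matrix(atac, atac_cells, genes,
                            modality = "atac_activity"),
         labels_rna = type_names[types_rna],
         labels_atac = type_names[types_atac],
         pairing = if (spec$paired) {
           tibble::tibble(rna_cell = rna_cells, atac_cell = atac_cells)
         },
         spec = spec),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> rna %d x %d | atac %d x %d | %d types%s\n",
    nrow(x$rna), ncol(x$rna), nrow(x$atac), ncol(x$atac),
    x$spec$n_types, if (!is.null(x$pairing)) " | paired" else ""))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Serialises both modalities with [write_matrix()] plus two-column label
#' TSVs (`cell_id`, `label`) and, when present, the pairing table.
#'
#' @param data A [simulate_multiome()] result.
#' @param dir Output directory (created if needed).
#' @param fmt Matrix layout passed to [write_matrix()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, fmt = c("mtx_dir", "dense_delim")) {
  fmt <- match.arg(fmt)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (fmt == "mtx_dir") {
    write_matrix(data$rna, file.path(dir, "rna"), "mtx_dir")
    write_matrix(data$atac, file.path(dir, "atac"), "mtx_dir")
  } else {
    write_matrix(data$rna, file.path(dir, "rna.tsv"), "dense_delim")
    write_matrix(data$atac, file.path(dir, "atac.tsv"), "dense_delim")
  }
  utils::write.table(
    data.frame(cell_id = cell_ids(data$rna), label = data$labels_rna),
    file.path(dir, "labels_rna.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = cell_ids(data$atac), label = data$labels_atac),
    file.path(dir, "labels_atac.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(data$pairing)) {
    utils::write.table(data$pairing, file.path(dir, "pairing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Hand-constructed 2-D embeddings for exact metric tests
#'
#' Three tiny fixtures with known metric values:
#' \describe{
#'   \item{`coincident_types`}{50 points at (0,0) labelled `A` and 50 at
#'     (10,0) labelled `B`, modality alternating; within-type distances are
#'     all zero so the mean silhouette is exactly 1.}
#'   \item{`mixed_modalities`}{one seeded Gaussian cloud with random
#'     modality labels; modalities are perfectly mixed.}
#'   \item{`random_cloud`}{200 points uniform on a square with random
#'     labels; no structure at all.}
#' }
#'
#' @param case_id One of `"coincident_types"`, `"mixed_modalities"`,
#'   `"random_cloud"`.
#' @return An embedding tibble (see [as_embedding()]) with 2 coordinate
#'   columns.
#' @export
make_worked_embedding <- function(case_id = c("coincident_types",
                                              "mixed_modalities",
                                              "random_cloud")) {
  case_id <- match.arg(case_id)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(42)
  if (case_id == "coincident_types") {
    coords <- rbind(matrix(0, 50, 2),
                    cbind(rep(10, 50), rep(0, 50)))
    label <- rep(c("A", "B"), each = 50)
    mod <- rep(c("rna", "atac_activity"), 50)
  } else if (case_id == "mixed_modalities") {
    coords <- matrix(stats::rnorm(400), 200, 2)
    label <- rep(NA_character_, 200)
    mod <- sample(c("rna", "atac_activity"), 200, replace = TRUE)
  } else {
    coords <- matrix(stats::runif(400), 200, 2)
    label <- sample(c("A", "B"), 200, replace = TRUE)
    mod <- sample(c("rna", "atac_activity"), 200, replace = TRUE)
  }
  as_embedding(coords, modality = mod, label = label,
               cell_id = sprintf("cell%03d", seq_len(nrow(coords))))
}

# save/restore the global RNG state so fixture construction does not
# disturb a caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
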