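#' Reduce an embedding to 2-D with UMAP
#'
#' The integrated representations of different methods have different
#' dimensionalities, so silhouette-based comparison is done on a common
#' 2-D UMAP computed with identical parameters regardless of the input
#' dimension.
#'
#' @param emb An embedding tibble ([as_embedding()]) or a numeric matrix.
#' @param n_neighbors,min_dist UMAP parameters (15 / 0.1).
#' @param seed Seed making the layout reproducible (single-threaded).
#' @return A cells-by-2 coordinate matrix.
#' @export
umap2d <- function(emb, n_neighbors = 15, min_dist = 0.1, seed = 0) {
  X <- if (is.matrix(emb)) emb else embedding_dims(emb)
  if (nrow(X) < n_neighbors + 1) {
    stop(sprintf("need at least n_neighbors + 1 = %d cells, got %d",
                 n_neighbors + 1, nrow(X)), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  coords <- uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                       n_threads = 1, n_sgd_threads = 0, batch = TRUE)
  dimnames(coords) <- list(rownames(X), c("dim_1", "dim_2"))
  coords
}

#' Mean silhouette score
#'
#' Mean over cells of `s(i) = (b - a) / max(a, b)` with Euclidean
#' distances, where `a` is the mean distance of cell i to the other
#' members of its own class and `b` the smallest mean distance to any
#' other class; cells whose class has a single member get `s(i) = 0`. To
#' match benchmarking practice on large populations, a seeded random
#' subsample (20% by default) is scored; `subsample_frac = 1` disables
#' subsampling.
#'
#' @param coords Numeric matrix of coordinates (typically 2-D UMAP).
#' @param labels Class label per row (modality tags or cell types).
#' @param subsample_frac Fraction of cells scored (default 0.2).
#' @param seed Seed of the subsample draw.
#' @return Scalar mean silhouette in \[-1, 1\].
#' @export
silhouette_mean <- function(coords, labels, subsample_frac = 0.2,
                            seed = 0) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  if (length(labels) != nrow(coords)) {
    stop("labels must have one entry per row of coords", call. = FALSE)
  }
  if (subsample_frac <= 0 || subsample_frac > 1) {
    stop("subsample_frac must be in (0, 1]", call. = FALSE)
  }
  if (subsample_frac < 1) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    keep <- sort(sample.int(nrow(coords),
                            max(2, round(subsample_frac * nrow(coords)))))
    coords <- coords[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) {
    stop("need at least 2 distinct labels in the (sub)sample",
         call. = FALSE)
  }
  cl <- as.integer(factor(labels))
  sil <- cluster::silhouette(cl, stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Silhouette transforms for integration benchmarking
#'
#' With `S` the mean silhouette under modality labels, modality silhouette
#' is `1 - abs(S)`: perfectly mixed modalities give `S ~ 0` and a score of
#' 1 regardless of sign. With `S` computed under cell-type labels,
#' cell-type silhouette is `(1 + S) / 2`, rescaling \[-1, 1\] to \[0, 1\]
#' so that 1 means ideally preserved type structure.
#'
#' @param S Mean silhouette in \[-1, 1\].
#' @return A scalar in \[0, 1\].
#' @export
modality_silhouette <- function(S) {
  check_unit_interval(S, -1, 1, "S")
  1 - abs(S)
}

#' @rdname modality_silhouette
#' @export
celltype_silhouette <- function(S) {
  check_unit_interval(S, -1, 1, "S")
  (1 + S) / 2
}

check_unit_interval <- function(x, lo, hi, name) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("%s must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}

#' Cross-modality label transfer with a linear SVM
#'
#' Fits a linear support vector machine (cost 1) on the full-dimensional
#' integration coordinates of one modality and scores its predictions on
#' the other, reporting per-type F1 and macro F1 (the unweighted mean over
#' types present in the test modality — this keeps rare types as visible
#' as common ones). A test type the classifier can never predict (absent
#' from training) contributes an F1 of 0.
#'
#' @param emb An embedding tibble with labels for both modalities.
#' @param train_modality `"rna"` (transfer RNA -> ATAC) or `"atac"`.
#' @param cost SVM regularisation constant.
#' @param kernel SVM kernel.
#' @return A list with `per_type` (named vector of F1 scores) and `macro`.
#' @export
label_transfer_f1 <- function(emb, train_modality = c("rna", "atac"),
                              cost = 1, kernel = "linear") {
  train_modality <- match.arg(train_modality)
  pred <- svm_transfer(emb, train_modality, cost, kernel)
  f1_scores(truth = pred$truth, predicted = pred$predicted)
}

# shared SVM fit/predict used by label_transfer_f1 and predict_labels
svm_transfer <- function(emb, train_modality, cost = 1,
                         kernel = "linear") {
  mods <- modality_split(emb$modality)
  is_train <- mods == train_modality
  if (!any(is_train) || all(is_train)) {
    stop("embedding must contain both modalities", call. = FALSE)
  }
  X <- embedding_dims(emb)
  y_train <- emb$label[is_train]
  if (any(is.na(y_train))) {
    stop("training modality has missing labels", call. = FALSE)
  }
  if (length(unique(y_train)) < 2) {
    stop("training modality holds a single cell type; cannot fit a classifier",
         call. = FALSE)
  }
  fit <- e1071::svm(X[is_train, , drop = FALSE], factor(y_train),
                    kernel = kernel, cost = cost, scale = FALSE)
  predicted <- as.character(stats::predict(fit,
                                           X[!is_train, , drop = FALSE]))
  list(predicted = predicted,
       truth = emb$label[!is_train],
       test_cells = emb$cell_id[!is_train])
}

modality_split <- function(modality) {
  ifelse(modality %in% c("rna", "RNA"), "rna", "atac")
}

# per-type and macro F1 from truth/prediction vectors; macro averages over
# the types present in the truth
f1_scores <- function(truth, predicted) {
  types <- sort(unique(truth))
  per_type <- vapply(types, function(t) {
    tp <- sum(truth == t & predicted == t)
    fp <- sum(truth != t & predicted == t)
    fn <- sum(truth == t & predicted != t)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(per_type = per_type, macro = mean(per_type))
}

#' Aggregate component scores into the overall metrics
#'
#' `S_overall = 0.7 * S_celltype + 0.3 * S_modality` (biology preservation
#' weighted above modality mixing), `F1_overall = 0.5 * (F1_RtoA +
#' F1_AtoR)` (mutual transfer in both directions), and `R_overall = 0.5 *
#' S_overall + 0.5 * F1_overall`.
#'
#' @param S_celltype,S_modality,f1_rna_to_atac,f1_atac_to_rna Component
#'   scores in \[0, 1\].
#' @param method Optional method name recorded in the report.
#' @return A one-row tibble of class `metrics_report` with the four
#'   components and the three aggregates.
#' @export
aggregate_metrics <- function(S_celltype, S_modality, f1_rna_to_atac,
                              f1_atac_to_rna, method = "modalign") {
  for (v in list(S_celltype, S_modality, f1_rna_to_atac, f1_atac_to_rna)) {
    check_unit_interval(v, 0, 1, "component scores")
  }
  out <- tibble::tibble(
    method = method,
    S_celltype = S_celltype,
    S_modality = S_modality,
    f1_rna_to_atac = f1_rna_to_atac,
    f1_atac_to_rna = f1_atac_to_rna,
    S_overall = 0.7 * S_celltype + 0.3 * S_modality,
    F1_overall = 0.5 * (f1_rna_to_atac + f1_atac_to_rna),
    R_overall = NA_real_)
  out$R_overall <- 0.5 * out$S_overall + 0.5 * out$F1_overall
  class(out) <- c("metrics_report", class(out))
  out
}

#' Full integration evaluation of one embedding
#'
#' Runs the complete benchmark battery on one labelled two-modality
#' embedding: 2-D UMAP, modality silhouette (modality labels) and
#' cell-type silhouette (type labels) on the 2-D coordinates, linear-SVM
#' label transfer in both directions on the full-dimensional coordinates,
#' and the weighted aggregation.
#'
#' @param emb A labelled embedding tibble.
#' @param subsample_frac Silhouette subsample fraction (see
#'   [silhouette_mean()]).
#' @param seed Seed for UMAP and the silhouette subsample.
#' @param method Method name recorded in the report.
#' @param coords2 Optional precomputed 2-D coordinates (skips the UMAP).
#' @return A `metrics_report` tibble (see [aggregate_metrics()]) with the
#'   per-type F1 vectors attached as the `per_type` attribute.
#' @export
evaluate_integration <- function(emb, subsample_frac = 0.2, seed = 0,
                                 method = "modalign", coords2 = NULL) {
  if (is.null(coords2)) coords2 <- umap2d(emb, seed = seed)
  s_mod <- silhouette_mean(coords2, modality_split(emb$modality),
                           subsample_frac = subsample_frac, seed = seed)
  have_labels <- !any(is.na(emb$label))
  if (!have_labels) {
    warning("no cell-type labels; only modality silhouette computed")
    out <- tibble::tibble(method = method,
                          S_modality = modality_silhouette(s_mod))
    return(out)
  }
  s_ct <- silhouette_mean(coords2, emb$label,
                          subsample_frac = subsample_frac, seed = seed)
  f1_ra <- label_transfer_f1(emb, "rna")
  f1_ar <- label_transfer_f1(emb, "atac")
  rep <- aggregate_metrics(S_celltype = celltype_silhouette(s_ct),
                           S_modality = modality_silhouette(s_mod),
                           f1_rna_to_atac = f1_ra$macro,
                           f1_atac_to_rna = f1_ar$macro,
                           method = method)
  attr(rep, "per_type") <- list(rna_to_atac = f1_ra$per_type,
                                atac_to_rna = f1_ar$per_type)
  rep
}

#' Rank methods and compare per-replicate scores
#'
#' Methods are ranked per metric and by `R_overall` (best = rank 1; ties
#' share the better rank). When per-replicate score vectors are provided
#' (e.g. one score per 20% subsample draw), every pair of methods is
#' compared per metric with a two-sided Wilcoxon rank-sum test; a p-value
#' below 0.01 is the conventional significance call, reported but not
#' enforced.
#'
#' @param reports A `metrics_report` tibble with one row per method (bind
#'   several [evaluate_integration()] results with `dplyr::bind_rows()`).
#' @param scores Optional long tibble of per-replicate scores with columns
#'   `method`, `metric`, `replicate`, `value`.
#' @return A list with `ranking` (tibble of per-metric ranks) and
#'   `pairwise` (tibble of Wilcoxon p-values, or `NULL`).
#' @export
compare_and_rank <- function(reports, scores = NULL) {
  if (nrow(reports) < 1) stop("no reports given", call. = FALSE)
  metrics <- intersect(c("S_celltype", "S_modality", "f1_rna_to_atac",
                         "f1_atac_to_rna", "S_overall", "F1_overall",
                         "R_overall"), names(reports))
  ranking <- reports[, c("method", metrics)]
  for (m in metrics) {
    ranking[[paste0("rank_", m)]] <-
      rank(-ranking[[m]], ties.method = "min")
  }
  pairwise <- NULL
  if (!is.null(scores)) {
    need <- c("method", "metric", "replicate", "value")
    if (!all(need %in% names(scores))) {
      stop("scores needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    combos <- utils::combn(unique(scores$method), 2, simplify = FALSE)
    rows <- list()
    for (m in unique(scores$metric)) {
      sm <- scores[scores$metric == m, ]
      for (cp in combos) {
        a <- sm$value[sm$method == cp[1]][order(sm$replicate[sm$method == cp[1]])]
        b <- sm$value[sm$method == cp[2]][order(sm$replicate[sm$method == cp[2]])]
        if (length(a) != length(b)) {
          stop("score vectors differ in length for methods ",
               cp[1], " vs ", cp[2], call. = FALSE)
        }
        p <- suppressWarnings(
          stats::wilcox.test(a, b, alternative = "two.sided",
                             exact = length(a) <= 25)$p.value)
        rows[[length(rows) + 1]] <- tibble::tibble(
          metric = m, method_a = cp[1], method_b = cp[2], p_value = p,
          significant = p < 0.01)
      }
    }
    pairwise <- dplyr::bind_rows(rows)
  }
  list(ranking = tibble::as_tibble(ranking), pairwise = pairwise)
}

#' Per-replicate silhouette scores over repeated subsamples
#'
#' Draws `n_replicates` seeded 20% subsamples and records modality and
#' cell-type silhouette for each — the score vectors consumed by
#' [compare_and_rank()].
#'
#' @param emb A labelled embedding tibble.
#' @param coords2 Optional precomputed 2-D coordinates.
#' @param n_replicates Number of subsample draws (default 20).
#' @param subsample_frac Fraction per draw (default 0.2).
#' @param seed Base seed; draw i uses `seed + i`.
#' @param method Method name recorded in the result.
#' @return A long tibble with columns `method`, `metric`, `replicate`,
#'   `value`.
#' @export
replicate_silhouettes <- function(emb, coords2 = NULL, n_replicates = 20,
                                  subsample_frac = 0.2, seed = 0,
                                  method = "modalign") {
  if (is.null(coords2)) coords2 <- umap2d(emb, seed = seed)
  rows <- lapply(seq_len(n_replicates), function(i) {
    s_mod <- silhouette_mean(coords2, modality_split(emb$modality),
                             subsample_frac = subsample_frac,
                             seed = seed + i)
    out <- tibble::tibble(method = method, metric = "S_modality",
                          replicate = i,
                          value = modality_silhouette(s_mod))
    if (!any(is.na(emb$label))) {
      s_ct <- silhouette_mean(coords2, emb$label,
                              subsample_frac = subsample_frac,
                              seed = seed + i)
      out <- dplyr::bind_rows(out, tibble::tibble(
        method = method, metric = "S_celltype", replicate = i,
        value = celltype_silhouette(s_ct)))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Write a metrics report to TSV and JSON
#'
#' @param report A `metrics_report` tibble (one or more rows).
#' @param path_tsv,path_json Output paths; either may be `NULL` to skip.
#' @return The report, invisibly.
#' @export
write_metrics_report <- function(report, path_tsv = NULL,
                                 path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(as.data.frame(report), path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(as.data.frame(report), path_json,
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
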