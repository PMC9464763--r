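test_that("umap2d is shaped, seeded and separates well-separated types", {
  emb <- separable_embedding(n_per = 60)
  co <- umap2d(emb, seed = 1)
  expect_equal(dim(co), c(120L, 2L))
  expect_identical(co, umap2d(emb, seed = 1))
  s <- silhouette_mean(co, emb$label, subsample_frac = 1)
  expect_gt(s, 0)
  expect_error(umap2d(emb[1:10, ], n_neighbors = 15), "n_neighbors")
})

test_that("coincident clusters give a mean silhouette of exactly 1", {
  ce <- make_worked_embedding("coincident_types")
  S <- silhouette_mean(embedding_dims(ce), ce$label, subsample_frac = 1)
  expect_identical(S, 1)  # a = 0, b = 10 for every point
  expect_identical(celltype_silhouette(S), 1)
})

test_that("random labels on an unstructured cloud give near-zero silhouette", {
  set.seed(14)
  X <- matrix(rnorm(800), 400, 2)
  labs <- sample(c("A", "B"), 400, replace = TRUE)
  expect_lt(abs(silhouette_mean(X, labs, subsample_frac = 1)), 0.1)
})

test_that("silhouette_mean equals the brute-force double loop to 1e-9", {
  set.seed(15)
  for (rep in 1:8) {
    n <- sample(30:120, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * 2, sd = sample(1:3, 1)), n, 2)
    labs <- sample(letters[1:k], n, replace = TRUE)
    labs[1:k] <- letters[1:k]  # every class inhabited
    expect_equal(silhouette_mean(X, labs, subsample_frac = 1),
                 sil_brute(X, labs), tolerance = 1e-9)
  }
  # singleton class convention: that cell scores 0
  X <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  labs <- c("a", "a", "b")
  expect_equal(silhouette_mean(X, labs, subsample_frac = 1),
               sil_brute(X, labs), tolerance = 1e-12)
})

test_that("subsampling is seeded and scores the stated fraction", {
  set.seed(16)
  X <- matrix(rnorm(600), 300, 2)
  labs <- rep(c("A", "B"), 150)
  s1 <- silhouette_mean(X, labs, subsample_frac = 0.2, seed = 3)
  s2 <- silhouette_mean(X, labs, subsample_frac = 0.2, seed = 3)
  expect_identical(s1, s2)
  s3 <- silhouette_mean(X, labs, subsample_frac = 0.2, seed = 4)
  expect_false(identical(s1, s3))
  expect_error(silhouette_mean(X, rep("A", 300), subsample_frac = 1),
               "distinct")
})

test_that("silhouette transforms follow the printed formulas and symmetry", {
  expect_equal(modality_silhouette(0), 1)
  expect_equal(celltype_silhouette(1), 1)
  expect_equal(celltype_silhouette(-1), 0)
  expect_equal(modality_silhouette(-0.4), 0.6)
  expect_equal(celltype_silhouette(-0.4), 0.3)
  ss <- seq(-1, 1, by = 0.05)
  expect_true(all(modality_silhouette(ss) >= 0 &
                    modality_silhouette(ss) <= 1))
  expect_true(all(celltype_silhouette(ss) >= 0 &
                    celltype_silhouette(ss) <= 1))
  expect_equal(modality_silhouette(ss), modality_silhouette(-ss))
  expect_error(modality_silhouette(1.2), "lie in")
})

test_that("label transfer is perfect on a separable embedding and null on shuffled labels", {
  emb <- separable_embedding(n_per = 60, gap = 25)
  res <- label_transfer_f1(emb, "rna")
  expect_equal(res$macro, 1)
  expect_equal(unname(res$per_type), c(1, 1))
  res_b <- label_transfer_f1(emb, "atac")
  expect_equal(res_b$macro, 1)

  set.seed(17)
  shuffled <- emb
  test_rows <- shuffled$modality != "rna"
  shuffled$label[test_rows] <- sample(shuffled$label[test_rows])
  res_s <- label_transfer_f1(shuffled, "rna")
  expect_lt(abs(res_s$macro - 0.5), 0.2)  # ~1/n_types for 2 types
})

test_that("macro F1 equals the confusion-matrix oracle and ignores label naming", {
  set.seed(18)
  emb <- separable_embedding(n_per = 50, gap = 3)  # imperfect separation
  res <- label_transfer_f1(emb, "rna")
  pred <- predict_labels(emb, "rna")
  truth <- emb$label[emb$modality != "rna"]
  oracle <- f1_from_confusion(truth, pred$predicted_label)
  expect_equal(unname(res$per_type), unname(oracle), tolerance = 1e-12)
  expect_equal(res$macro, mean(oracle), tolerance = 1e-12)

  renamed <- emb
  renamed$label <- paste0("cell_", renamed$label)
  expect_equal(label_transfer_f1(renamed, "rna")$macro, res$macro)
})

test_that("aggregation reproduces the printed weights and is linear", {
  r <- aggregate_metrics(1, 1, 1, 1)
  expect_equal(r$R_overall, 1)
  expect_equal(aggregate_metrics(0.8, 0.5, 0, 0)$S_overall, 0.71)
  expect_equal(aggregate_metrics(0, 0, 0.6, 0.8)$F1_overall, 0.7)

  set.seed(19)
  for (rep in 1:5) {
    v <- runif(4)
    a <- runif(1)
    r1 <- aggregate_metrics(v[1], v[2], v[3], v[4])
    r2 <- aggregate_metrics(a * v[1], a * v[2], a * v[3], a * v[4])
    expect_equal(r2$S_overall, a * r1$S_overall, tolerance = 1e-12)
    expect_equal(r2$F1_overall, a * r1$F1_overall, tolerance = 1e-12)
    expect_equal(r2$R_overall, a * r1$R_overall, tolerance = 1e-12)
  }
  expect_error(aggregate_metrics(1.3, 0, 0, 0), "lie in")
})

test_that("ranking shares tied ranks and Wilcoxon separates dominating scores", {
  reports <- dplyr::bind_rows(
    aggregate_metrics(0.9, 0.9, 0.9, 0.9, method = "m1"),
    aggregate_metrics(0.5, 0.5, 0.5, 0.5, method = "m2"),
    aggregate_metrics(0.7, 0.7, 0.7, 0.7, method = "m3"))
  rk <- compare_and_rank(reports)$ranking
  expect_equal(rk$rank_R_overall, c(1L, 3L, 2L))

  tied <- dplyr::bind_rows(
    aggregate_metrics(0.7, 0.7, 0.7, 0.7, method = "a"),
    aggregate_metrics(0.7, 0.7, 0.7, 0.7, method = "b"))
  expect_equal(compare_and_rank(tied)$ranking$rank_R_overall, c(1L, 1L))

  scores <- dplyr::bind_rows(
    tibble::tibble(method = "a", metric = "S_celltype",
                   replicate = 1:20, value = seq(0.8, 0.99, length.out = 20)),
    tibble::tibble(method = "b", metric = "S_celltype",
                   replicate = 1:20, value = seq(0.1, 0.29, length.out = 20)))
  cw <- compare_and_rank(tied, scores)$pairwise
  expect_lt(cw$p_value, 0.01)
  expect_true(cw$significant)

  same <- scores
  same$value[same$method == "b"] <- same$value[same$method == "a"]
  cw2 <- compare_and_rank(tied, same)$pairwise
  expect_equal(cw2$p_value, 1)

  bad <- scores[-1, ]
  expect_error(compare_and_rank(tied, bad), "length")
})

test_that("evaluate_integration satisfies the report invariants end to end", {
  emb <- separable_embedding(n_per = 60)
  rep <- evaluate_integration(emb, subsample_frac = 1, seed = 2)
  expect_equal(rep$S_overall,
               0.7 * rep$S_celltype + 0.3 * rep$S_modality,
               tolerance = 1e-9)
  expect_equal(rep$F1_overall,
               0.5 * (rep$f1_rna_to_atac + rep$f1_atac_to_rna),
               tolerance = 1e-9)
  expect_equal(rep$R_overall, 0.5 * rep$S_overall + 0.5 * rep$F1_overall,
               tolerance = 1e-9)
  # replicate scores feed the ranking machinery
  sc <- replicate_silhouettes(emb, n_replicates = 4, seed = 5)
  expect_equal(nrow(sc), 8)
  expect_true(all(sc$value >= 0 & sc$value <= 1))
})
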