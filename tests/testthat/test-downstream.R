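test_that("predict_labels recovers truth on separable data and handles one-class sources", {
  emb <- separable_embedding(n_per = 50, gap = 25)
  pred <- predict_labels(emb, "rna")
  truth <- emb$label[emb$modality != "rna"]
  expect_identical(pred$predicted_label, truth)

  one <- emb
  one$label[one$modality == "rna"] <- "only"
  p1 <- predict_labels(one, "rna")
  expect_true(all(p1$predicted_label == "only"))
})

test_that("k = 1 prediction at a coincident embedding point copies that cell's profile", {
  set.seed(21)
  coords <- rbind(matrix(rnorm(5 * 3), 5), matrix(rnorm(2 * 3, 6), 2))
  coords[6, ] <- coords[2, ]  # atac cell 1 sits exactly on rna cell 2
  emb <- as_embedding(coords,
                      modality = c(rep("rna", 5), rep("atac_activity", 2)),
                      cell_id = c(paste0("r", 1:5), paste0("a", 1:2)))
  expr <- expr_matrix(matrix(abs(rnorm(5 * 4)), 5), paste0("r", 1:5),
                      paste0("g", 1:4), "rna", normalized = TRUE)
  pred <- predict_expression(emb, expr, k = 1)
  expect_equal(pred["a1", ], unclass(expr)["r2", ])

  # constant field: identical profiles predict themselves for any k
  const <- expr_matrix(matrix(2, 5, 4), paste0("r", 1:5), paste0("g", 1:4),
                       "rna", normalized = TRUE)
  for (k in c(1, 3, 5)) {
    p <- predict_expression(emb, const, k = k)
    expect_true(all(p == 2))
  }
  expect_warning(predict_expression(emb, expr, k = 10), "clamped")
})

test_that("predictions are convex combinations and rotation-equivariant", {
  set.seed(22)
  n_r <- 30
  coords <- matrix(rnorm((n_r + 10) * 4), n_r + 10)
  emb <- as_embedding(coords,
                      modality = rep(c("rna", "atac_activity"),
                                     c(n_r, 10)),
                      cell_id = c(paste0("r", 1:n_r), paste0("a", 1:10)))
  expr <- expr_matrix(matrix(abs(rnorm(n_r * 6)), n_r), paste0("r", 1:n_r),
                      paste0("g", 1:6), "rna", normalized = TRUE)
  pred <- predict_expression(emb, expr, k = 5)
  expect_true(all(pred >= min(expr) & pred <= max(expr)))

  Q <- qr.Q(qr(matrix(rnorm(16), 4)))  # random rigid rotation
  emb_rot <- as_embedding(coords %*% Q, modality = emb$modality,
                          cell_id = emb$cell_id)
  expect_equal(predict_expression(emb_rot, expr, k = 5), pred,
               tolerance = 1e-9)
})

test_that("velocity layers carry aligned layers and an exact k-NN graph", {
  set.seed(23)
  n <- 50
  coords <- matrix(rnorm(n * 5), n)
  cells <- sprintf("cell%02d", 1:n)
  emb <- as_embedding(coords, modality = "atac_activity", cell_id = cells)
  act <- expr_matrix(matrix(rpois(n * 8, 3), n), cells,
                     paste0("g", 1:8), "atac_activity")
  expr <- matrix(abs(rnorm(n * 8)), n, dimnames = list(cells,
                                                       paste0("g", 1:8)))
  vl <- assemble_velocity_layers(act, expr, emb, k = 6)
  expect_equal(unname(Matrix::rowSums(vl$neighbors)), rep(6, n))
  expect_equal(vl$spliced, unclass(act), ignore_attr = TRUE)

  # brute-force all-pairs neighbour oracle
  D <- as.matrix(dist(coords))
  for (i in c(1, 17, 50)) {
    expected <- setdiff(order(D[i, ]), i)[1:6]
    expect_setequal(which(vl$neighbors[i, ] == 1), expected)
  }

  dir <- withr::local_tempdir()
  write_velocity_layers(vl, dir)
  back <- read_velocity_layers(dir)
  expect_equal(back$spliced, vl$spliced)
  expect_equal(back$unspliced, vl$unspliced)
  expect_equal(as.matrix(back$neighbors), as.matrix(vl$neighbors))
  expect_equal(back$neighbor_k, 6L)

  bad <- expr
  rownames(bad)[1] <- "missing_cell"
  expect_error(assemble_velocity_layers(act, bad, emb, k = 6),
               "missing_cell")
})

test_that("joint-space neighbours beat a shuffled embedding at predicting expression", {
  # paired data: the atac coordinates of each cell sit near its rna twin,
  # so true pairing information flows through the joint space
  wins <- logical(3)
  for (s in 1:3) {
    set.seed(100 + s)
    d <- simulate_multiome(synthetic_spec(
      n_cells_rna = 150, n_cells_atac = 150, n_types = 3, n_genes = 60,
      seed = 300 + s, paired = TRUE))
    rna_ln <- lognorm(d$rna)
    # stand-in joint embedding built from the shared type structure: PCA
    # of the rna cells, atac cells placed at their paired twin + noise
    pcs <- prcomp(unclass(rna_ln), rank. = 8)$x
    coords <- rbind(pcs, pcs + matrix(rnorm(length(pcs), sd = 0.3),
                                      nrow(pcs)))
    emb <- as_embedding(coords,
                        modality = rep(c("rna", "atac_activity"), each = 150),
                        cell_id = c(cell_ids(d$rna), cell_ids(d$atac)))
    pred <- predict_expression(emb, rna_ln, k = 10)
    shuf <- emb
    set.seed(s)
    atac_rows <- which(shuf$modality == "atac_activity")
    dimcols <- grep("^dim_", names(shuf))
    shuf[atac_rows, dimcols] <- shuf[sample(atac_rows), dimcols]
    pred_shuf <- predict_expression(shuf, rna_ln, k = 10)

    truth <- unclass(rna_ln)  # paired: atac cell i twins rna cell i
    gene_cor <- function(p) {
      cs <- sapply(seq_len(ncol(truth)), function(j) {
        if (sd(p[, j]) == 0 || sd(truth[, j]) == 0) return(NA_real_)
        cor(p[, j], truth[, j])
      })
      mean(cs, na.rm = TRUE)
    }
    wins[s] <- gene_cor(pred) > gene_cor(pred_shuf)
  }
  expect_true(all(wins))
})
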