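# Small in-code fixtures shared across test files.

tiny_matrix <- function(modality = "rna") {
  expr_matrix(matrix(c(1, 2, 0, 0, 3, 4), nrow = 3),
              paste0("c", 1:3), c("gA", "gB"), modality = modality)
}

# a small but non-trivial dataset + harmonized pair
tiny_dataset <- function(seed = 11, n = 80, genes = 40, types = 3) {
  simulate_multiome(synthetic_spec(
    n_cells_rna = n, n_cells_atac = n, n_types = types, n_genes = genes,
    seed = seed))
}

tiny_pair <- function(data, n_target = 30) {
  preprocess_pair(data$rna, data$atac, n_target = n_target)
}

# a micro network spec sized for fast test training
micro_spec <- function(input_dim, seed = 1) {
  network_spec(input_dim = input_dim, latent_dim = 16, encoder_hidden = 32,
               head_linear_dim = 8, head_softmax_dim = 6,
               disc_hidden = c(16, 16), gen_hidden = 16, init_seed = seed)
}

micro_cfg <- function(epochs = 2, seed = 3) {
  train_config(epochs = epochs, batch_size = 16, seed = seed)
}

# a cleanly separable labelled two-modality embedding
separable_embedding <- function(n_per = 40, gap = 20, seed = 5) {
  set.seed(seed)
  coords <- rbind(matrix(rnorm(n_per * 4 * 2, sd = 0.3), ncol = 4))
  types <- rep(c("A", "B"), each = n_per)
  coords[types == "B", 1] <- coords[types == "B", 1] + gap
  as_embedding(coords,
               modality = rep(c("rna", "atac_activity"), n_per),
               label = types)
}
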