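#' Architecture specification
#'
#' Dimensions of the five parameterised maps: encoder `E` (one fully
#' connected block with batch normalisation and ReLU, then a linear map to
#' the 128-dimensional latent space), the two contrastive heads (a 32-d
#' linear head and a 25-d softmax head), the two discriminators (three-layer
#' MLPs ending in a sigmoid scalar; `D_rna` reads latent codes, `D_atac`
#' reads data-space vectors), and the generator `G` (two-layer MLP mapping
#' latent codes back to the input dimension, ReLU output so generated
#' activity is nonnegative).
#'
#' @param input_dim Number of input features (shared by both modalities).
#' @param latent_dim Latent dimensionality (128 by default).
#' @param encoder_hidden Width of the encoder's hidden block.
#' @param head_linear_dim Output width of the linear contrastive head.
#' @param head_softmax_dim Output width of the softmax contrastive head.
#' @param disc_hidden Two hidden widths shared by both discriminators.
#' @param gen_hidden Hidden width of the generator.
#' @param init_seed Seed controlling parameter initialisation.
#' @return A validated list of class `network_spec`.
#' @export
network_spec <- function(input_dim, latent_dim = 128, encoder_hidden = 1024,
                         head_linear_dim = 32, head_softmax_dim = 25,
                         disc_hidden = c(512, 512), gen_hidden = 512,
                         init_seed = 0) {
  dims <- c(input_dim, latent_dim, encoder_hidden, head_linear_dim,
            head_softmax_dim, disc_hidden, gen_hidden)
  if (any(dims <= 0) || any(dims != round(dims))) {
    stop("all dimensions must be positive integers", call. = FALSE)
  }
  if (length(disc_hidden) != 2) {
    stop("disc_hidden must give exactly two hidden widths", call. = FALSE)
  }
  structure(
    list(input_dim = as.integer(input_dim),
         latent_dim = as.integer(latent_dim),
         encoder_hidden = as.integer(encoder_hidden),
         head_linear_dim = as.integer(head_linear_dim),
         head_softmax_dim = as.integer(head_softmax_dim),
         disc_hidden = as.integer(disc_hidden),
         gen_hidden = as.integer(gen_hidden),
         init_seed = as.integer(init_seed)),
    class = "network_spec")
}

#' Initialise all model parameters
#'
#' Every weight is drawn from the fan-in-scaled uniform distribution
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; batch-norm scale/shift start at
#' 1/0 and the running statistics at 0/1. Initialisation is fully
#' determined by `spec$init_seed`.
#'
#' @param spec A [network_spec()].
#' @return A list of class `modalign_model` holding the parameters of `E`,
#'   the two heads, `D_rna`, `D_atac` and `G`, the encoder's batch-norm
#'   running statistics, and the spec itself.
#' @export
init_model <- function(spec) {
  if (!inherits(spec, "network_spec")) {
    stop("spec must come from network_spec()", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$init_seed)
  model <- list(
    spec = spec,
    E = list(fc1 = lin_init(spec$input_dim, spec$encoder_hidden),
             bn = bn_init(spec$encoder_hidden),
             fc2 = lin_init(spec$encoder_hidden, spec$latent_dim)),
    head_linear = lin_init(spec$latent_dim, spec$head_linear_dim),
    head_softmax = lin_init(spec$latent_dim, spec$head_softmax_dim),
    d_rna = mlp_init(c(spec$latent_dim, spec$disc_hidden, 1)),
    d_atac = mlp_init(c(spec$input_dim, spec$disc_hidden, 1)),
    G = mlp_init(c(spec$latent_dim, spec$gen_hidden, spec$input_dim),
                 final_relu = TRUE),
    bn_state = bn_state_init(spec$encoder_hidden))
  class(model) <- "modalign_model"
  model
}

#' @export
print.modalign_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    paste0("<modalign_model> E: %d-%d-BN-ReLU-%d | heads: %d linear, ",
           "%d softmax | D: [%s] | G: %d-%d-%d\n"),
    s$input_dim, s$encoder_hidden, s$latent_dim, s$head_linear_dim,
    s$head_softmax_dim, paste(s$disc_hidden, collapse = ","),
    s$latent_dim, s$gen_hidden, s$input_dim))
  invisible(x)
}

# encoder forward with explicit cache; `update_running` threads new
# batch-norm running statistics back to the caller (training loop only)
enc_fwd <- function(model, X, training) {
  l1 <- lin_fwd(model$E$fc1, X)
  bn <- bn_fwd(model$E$bn, model$bn_state, l1$out, training = training)
  r <- relu_fwd(bn$out)
  l2 <- lin_fwd(model$E$fc2, r$out)
  list(z = l2$out,
       cache = list(l1 = l1, bn = bn$cache, relu = r, l2 = l2,
                    training = training),
       bn_state = bn$state)
}

# backward through the encoder; training-mode caches only
enc_bwd <- function(model, cache, dZ) {
  lb2 <- lin_bwd(model$E$fc2, cache$l2, dZ)
  dr <- relu_bwd(cache$relu, lb2$dX)
  bb <- bn_bwd(model$E$bn, cache$bn, dr)
  lb1 <- lin_bwd(model$E$fc1, cache$l1, bb$dX)
  list(dX = lb1$dX,
       grads = list(fc1 = lb1$grad, bn = bb$grad, fc2 = lb2$grad))
}

#' Encode cells into the joint latent space
#'
#' @param model A [init_model()] result (trained or fresh).
#' @param X Numeric matrix, cells by `input_dim` features (log1p scale).
#' @param mode `"eval"` standardises with the stored running batch-norm
#'   statistics (deterministic, row-wise); `"train"` uses the batch's own
#'   statistics as during optimisation.
#' @return A cells-by-`latent_dim` matrix.
#' @export
encode <- function(model, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X <- as.matrix(unclass(X))
  if (ncol(X) != model$spec$input_dim) {
    stop(sprintf("X has %d columns; model expects %d", ncol(X),
                 model$spec$input_dim), call. = FALSE)
  }
  z <- enc_fwd(model, X, training = (mode == "train"))$z
  rownames(z) <- rownames(X)
  z
}

#' Project latent codes through the two contrastive heads
#'
#' @param model A `modalign_model`.
#' @param Z Cells-by-`latent_dim` latent matrix.
#' @return A list with `h32` (linear head output) and `p25` (softmax head
#'   output; every row is a probability vector).
#' @export
project <- function(model, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != model$spec$latent_dim) {
    stop(sprintf("Z has %d columns; model latent dim is %d", ncol(Z),
                 model$spec$latent_dim), call. = FALSE)
  }
  list(h32 = lin_fwd(model$head_linear, Z)$out,
       p25 = softmax_rows(lin_fwd(model$head_softmax, Z)$out))
}

#' Discriminator forward pass
#'
#' `which = "rna_latent"` applies `D_rna` to latent codes (does this code
#' come from RNA?); `which = "atac_data"` applies `D_atac` to data-space
#' vectors (is this real activity data, rather than generated?).
#'
#' @param model A `modalign_model`.
#' @param which `"rna_latent"` or `"atac_data"`.
#' @param input Matrix with `latent_dim` (rna_latent) or `input_dim`
#'   (atac_data) columns.
#' @return A vector of probabilities strictly inside (0, 1).
#' @export
discriminate <- function(model, which = c("rna_latent", "atac_data"), input) {
  which <- match.arg(which)
  input <- as.matrix(unclass(input))
  p <- if (which == "rna_latent") model$d_rna else model$d_atac
  expect <- if (which == "rna_latent") model$spec$latent_dim else model$spec$input_dim
  if (ncol(input) != expect) {
    stop(sprintf("input has %d columns; %s expects %d", ncol(input), which,
                 expect), call. = FALSE)
  }
  stats::plogis(as.vector(mlp_fwd(p, input)$out))
}

#' Generate activity-like data from latent codes
#'
#' @param model A `modalign_model`.
#' @param Z Cells-by-`latent_dim` latent matrix.
#' @return A nonnegative cells-by-`input_dim` matrix (ReLU output).
#' @export
generate <- function(model, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != model$spec$latent_dim) {
    stop(sprintf("Z has %d columns; model latent dim is %d", ncol(Z),
                 model$spec$latent_dim), call. = FALSE)
  }
  mlp_fwd(model$G, Z)$out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding every named parameter
#' array, the batch-norm running statistics and the `network_spec`.
#'
#' @param model A `modalign_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  class(model$spec) <- "network_spec"
  class(model) <- "modalign_model"
  attr(model$d_rna, "final_relu") <- FALSE
  attr(model$d_atac, "final_relu") <- FALSE
  attr(model$G, "final_relu") <- TRUE
  model
}

# checksum used in determinism tests
param_checksum <- function(model) {
  leaves <- unlist(model[c("E", "head_linear", "head_softmax",
                           "d_rna", "d_atac", "G")], use.names = FALSE)
  sum(leaves * seq_along(leaves) %% 97)
}
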