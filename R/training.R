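#' Training configuration
#'
#' Published protocol: 100 epochs of stochastic gradient descent, learning
#' rate 0.005, weight decay 0.0005, contrastive temperatures 0.15 (linear
#' head) and 0.5 (softmax head). Momentum (0.9) and batch size (256) are
#' conventional values exposed here. One discriminator update is taken per
#' encoder/generator update.
#'
#' @param epochs Number of passes over the RNA modality.
#' @param lr Learning rate (constant; set `cosine_decay = TRUE` for a
#'   cosine schedule down to 0).
#' @param weight_decay L2 weight decay coupled into the SGD update.
#' @param momentum SGD momentum.
#' @param batch_size Cells per modality per step; the smaller modality is
#'   resampled with replacement to match.
#' @param weights A [loss_weights()].
#' @param augment An [augment_config()] (its `rng_seed` is ignored during
#'   training; the training `seed` governs all randomness).
#' @param tau_linear,tau_softmax Contrastive temperatures of the two heads.
#' @param seed Integer seed for all training randomness (batching,
#'   augmentation).
#' @param deterministic Reproducibility contract flag: the implementation
#'   is single-threaded and seeded, so two runs with the same seed always
#'   produce identical histories; the flag is recorded in the config echo.
#' @param cosine_decay Use a cosine learning-rate schedule?
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100, lr = 0.005, weight_decay = 0.0005,
                         momentum = 0.9, batch_size = 256,
                         weights = loss_weights(),
                         augment = augment_config(),
                         tau_linear = 0.15, tau_softmax = 0.5,
                         seed = 0, deterministic = TRUE,
                         cosine_decay = FALSE) {
  if (epochs < 0 || epochs != round(epochs)) {
    stop("epochs must be a nonnegative integer", call. = FALSE)
  }
  if (batch_size < 4) stop("batch_size must be at least 4", call. = FALSE)
  if (lr <= 0) stop("lr must be positive", call. = FALSE)
  structure(
    list(epochs = as.integer(epochs), lr = lr,
         weight_decay = weight_decay, momentum = momentum,
         batch_size = as.integer(batch_size), weights = weights,
         augment = augment, tau_linear = tau_linear,
         tau_softmax = tau_softmax, seed = as.integer(seed),
         deterministic = isTRUE(deterministic),
         cosine_decay = isTRUE(cosine_decay)),
    class = "train_config")
}

# corruptions drawn from the ambient (seeded) training RNG
augment_pair_inline <- function(X, cfg) {
  augment_views(X, augment_config(cfg$noise_sigma, cfg$mask_prob,
                                  rng_seed = NULL,
                                  .allow_degenerate = TRUE))
}

# contrastive branch over both modalities: the two interleaved view
# batches are encoded in one joint forward (consistent batch-norm
# statistics across everything the encoder sees in a step), the NCE terms
# are computed per modality on the head outputs, and the weighted
# encoder/head gradients are returned
contrastive_branch <- function(model, V_rna, V_atac, cfg, w_nce) {
  n_r <- nrow(V_rna)
  f_enc <- enc_fwd(model, rbind(V_rna, V_atac), training = TRUE)
  f_hl <- lin_fwd(model$head_linear, f_enc$z)
  f_hs <- lin_fwd(model$head_softmax, f_enc$z)
  P <- softmax_rows(f_hs$out)

  idx_r <- seq_len(n_r)
  idx_a <- n_r + seq_len(nrow(V_atac))
  dH <- matrix(0, nrow(f_enc$z), ncol(f_hl$out))
  dP <- matrix(0, nrow(f_enc$z), ncol(P))
  losses <- numeric(2)
  for (m in 1:2) {
    idx <- if (m == 1) idx_r else idx_a
    n32 <- nce_fwd(f_hl$out[idx, , drop = FALSE], cfg$tau_linear)
    n25 <- nce_fwd(P[idx, , drop = FALSE], cfg$tau_softmax)
    losses[m] <- n32$loss + n25$loss
    dH[idx, ] <- nce_bwd(n32) * w_nce
    dP[idx, ] <- nce_bwd(n25) * w_nce
  }
  bl <- lin_bwd(model$head_linear, f_hl, dH)
  # softmax backward, rowwise: dlogit = P * (dP - rowSums(dP * P))
  dlogit <- P * (dP - rowSums(dP * P))
  bs <- lin_bwd(model$head_softmax, f_hs, dlogit)
  be <- enc_bwd(model, f_enc$cache, bl$dX + bs$dX)
  list(loss_rna = losses[1], loss_atac = losses[2],
       g_E = be$grads, g_hl = bl$grad, g_hs = bs$grad,
       bn_state = f_enc$bn_state)
}

# logistic-loss gradient wrt logits for targets y in {0,1}; loss is the
# mean BCE over the batch
bce_logits <- function(o, y) {
  p <- stats::plogis(o)
  list(loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
       dlogit = (p - y) / length(o))
}

#' Train the integration model
#'
#' Alternating optimisation over paired mini-batches. Each step (1) updates
#' the two discriminators on their binary cross-entropy losses — `D_rna`
#' separating RNA from activity latent codes, `D_atac` separating real
#' from generated activity data — with the encoder and generator held
#' fixed; then (2) updates the encoder, both contrastive heads and the
#' generator on the weighted total of the two per-modality NCE losses, the
#' encoder-side domain-adversarial term, the generator-side adversarial
#' term and the latent cycle-consistency loss, with the discriminators
#' held fixed. The RNA modality defines the epoch; the activity batch is
#' drawn per step (with replacement when that modality is smaller). All
#' randomness flows from `cfg$seed`, so runs are exactly reproducible.
#'
#' @param pair A [harmonize_features()] / [preprocess_pair()] result.
#' @param net_spec A [network_spec()]; its `input_dim` must match
#'   `length(pair$features)`.
#' @param cfg A [train_config()].
#' @return An object of class `modalign_fit`: list with `model` (trained
#'   parameters), `history` (per-epoch tibble of mean loss terms and
#'   wall-clock seconds) and `config`.
#' @export
train <- function(pair, net_spec, cfg = train_config()) {
  if (!inherits(pair, "paired_input")) {
    stop("pair must come from harmonize_features()/preprocess_pair()",
         call. = FALSE)
  }
  if (net_spec$input_dim != length(pair$features)) {
    stop(sprintf("net_spec$input_dim (%d) != number of features (%d)",
                 net_spec$input_dim, length(pair$features)), call. = FALSE)
  }
  X_rna <- unclass(pair$rna)
  X_atac <- unclass(pair$atac)
  if (nrow(X_rna) == 0 || nrow(X_atac) == 0) {
    stop("both modalities must contain cells", call. = FALSE)
  }

  model <- init_model(net_spec)
  history <- empty_history()
  if (cfg$epochs == 0) {
    return(new_fit(model, history, cfg, pair))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  vel <- list(main = pl_zeros(model[c("E", "head_linear", "head_softmax",
                                      "G")]),
              d_rna = pl_zeros(model$d_rna),
              d_atac = pl_zeros(model$d_atac))

  bsz <- min(cfg$batch_size, nrow(X_rna))
  steps <- max(1L, nrow(X_rna) %/% bsz)
  term_names <- c("nce_rna", "nce_atac", "d_rna", "e_adv", "d_atac",
                  "g_adv", "cycle", "total")
  epoch_rows <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- if (cfg$cosine_decay) {
      cfg$lr * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$epochs))
    } else {
      cfg$lr
    }
    rna_order <- sample.int(nrow(X_rna))
    acc <- stats::setNames(numeric(length(term_names)), term_names)

    for (s in seq_len(steps)) {
      idx_r <- rna_order[((s - 1) * bsz + 1):(s * bsz)]
      idx_a <- sample.int(nrow(X_atac), bsz,
                          replace = nrow(X_atac) < bsz)
      step <- train_step(model, X_rna[idx_r, , drop = FALSE],
                         X_atac[idx_a, , drop = FALSE], cfg, vel, lr)
      model <- step$model
      vel <- step$vel
      bad <- !is.finite(unlist(step$terms))
      if (any(bad)) {
        stop("non-finite loss term(s): ",
             paste(names(step$terms)[bad], collapse = ", "), call. = FALSE)
      }
      acc <- acc + unlist(step$terms)[term_names]
    }
    epoch_rows[[epoch]] <- tibble::as_tibble(
      c(list(epoch = epoch), as.list(acc / steps),
        list(seconds = proc.time()[["elapsed"]] - t0)))
  }
  history <- dplyr::bind_rows(epoch_rows)
  model <- recalibrate_bn(model, rbind(X_rna, X_atac))
  new_fit(model, history, cfg, pair)
}

# replace the EMA batch-norm running statistics with the exact mean and
# variance of the pre-BN activations over the full dataset (both
# modalities); eval-mode encodings then standardise with the statistics
# of the data actually being embedded
recalibrate_bn <- function(model, X) {
  h <- lin_fwd(model$E$fc1, X)$out
  mu <- colMeans(h)
  v <- colSums(.addrow(h, -mu)^2) / max(1, nrow(h) - 1)
  model$bn_state <- list(rmean = mu, rvar = v)
  model
}

empty_history <- function() {
  tibble::tibble(epoch = integer(),
                 nce_rna = numeric(), nce_atac = numeric(),
                 d_rna = numeric(), e_adv = numeric(),
                 d_atac = numeric(), g_adv = numeric(),
                 cycle = numeric(), total = numeric(),
                 seconds = numeric())
}

new_fit <- function(model, history, config, pair) {
  structure(list(model = model,
                 history = tibble::as_tibble(history),
                 config = config,
                 features = pair$features,
                 n_rna = nrow(pair$rna),
                 n_atac = nrow(pair$atac)),
            class = "modalign_fit")
}

#' @export
print.modalign_fit <- function(x, ...) {
  cat(sprintf(
    "<modalign_fit> %d features | %d rna + %d atac cells | %d epochs\n",
    length(x$features), x$n_rna, x$n_atac, nrow(x$history)))
  if (nrow(x$history)) {
    cat(sprintf("  final total loss: %.4f\n",
                x$history$total[nrow(x$history)]))
  }
  invisible(x)
}

# one alternating optimisation step; returns updated model, velocity and
# the step's loss terms. do_disc / do_main gate the two update phases so
# the update-isolation property (each phase touches only its own
# parameters) can be asserted directly.
train_step <- function(model, x_r, x_a, cfg, vel, lr,
                       do_disc = TRUE, do_main = TRUE) {
  w <- cfg$weights

  n_b <- nrow(x_r)

  # one joint forward over both modality batches: batch normalisation then
  # standardises with shared statistics, so the modality offset stays
  # visible to D_rna and must be removed by the encoder weights themselves
  # (separate per-modality forwards would let BN center it away during
  # training while eval-mode running statistics re-expose it)
  f_z <- enc_fwd(model, rbind(x_r, x_a), training = TRUE)
  model$bn_state <- f_z$bn_state
  z_r <- f_z$z[seq_len(n_b), , drop = FALSE]
  z_a <- f_z$z[n_b + seq_len(n_b), , drop = FALSE]
  f_G <- mlp_fwd(model$G, z_r)
  x_fake <- f_G$out

  ## --- phase 1: discriminators (encoder and generator fixed) -----------
  f_dr <- mlp_fwd(model$d_rna, rbind(z_r, z_a))
  bl_dr <- bce_logits(as.vector(f_dr$out), c(rep(1, n_b), rep(0, n_b)))
  f_da <- mlp_fwd(model$d_atac, rbind(x_a, x_fake))
  bl_da <- bce_logits(as.vector(f_da$out), c(rep(1, n_b), rep(0, n_b)))
  if (do_disc) {
    g_dr <- mlp_bwd(model$d_rna, f_dr, matrix(bl_dr$dlogit, ncol = 1))$grads
    up <- sgd_step(model$d_rna, g_dr, vel$d_rna, lr, cfg$momentum,
                   cfg$weight_decay)
    attr(up$p, "final_relu") <- FALSE
    model$d_rna <- up$p
    vel$d_rna <- up$v

    g_da <- mlp_bwd(model$d_atac, f_da, matrix(bl_da$dlogit, ncol = 1))$grads
    up <- sgd_step(model$d_atac, g_da, vel$d_atac, lr, cfg$momentum,
                   cfg$weight_decay)
    attr(up$p, "final_relu") <- FALSE
    model$d_atac <- up$p
    vel$d_atac <- up$v
  }

  ## --- phase 2: encoder / heads / generator (discriminators fixed) -----
  grads <- list(E = NULL, head_linear = NULL, head_softmax = NULL, G = NULL)

  # contrastive branch (fresh augmented views per modality, one joint
  # encoder forward)
  vr <- augment_pair_inline(x_r, cfg$augment)
  va <- augment_pair_inline(x_a, cfg$augment)
  cb <- contrastive_branch(model, interleave_views(vr$x1, vr$x2),
                           interleave_views(va$x1, va$x2), cfg, w$w_nce)
  model$bn_state <- cb$bn_state
  grads$E <- cb$g_E
  grads$head_linear <- cb$g_hl
  grads$head_softmax <- cb$g_hs

  # encoder-side domain-adversarial term (updated D_rna, params frozen)
  f_adv <- mlp_fwd(model$d_rna, z_a)
  bl_adv <- bce_logits(as.vector(f_adv$out), rep(1, n_b))
  d_za <- mlp_bwd(model$d_rna, f_adv,
                  matrix(bl_adv$dlogit * w$w_domain, ncol = 1))$dX

  # generator-side adversarial term (updated D_atac, params frozen)
  f_gadv <- mlp_fwd(model$d_atac, x_fake)
  bl_gadv <- bce_logits(as.vector(f_gadv$out), rep(1, n_b))
  d_xfake <- mlp_bwd(model$d_atac, f_gadv,
                     matrix(bl_gadv$dlogit * w$w_atac_gan, ncol = 1))$dX

  # cycle consistency: E(G(z_rna)) must return to z_rna
  f_z2 <- enc_fwd(model, x_fake, training = TRUE)
  model$bn_state <- f_z2$bn_state
  diff <- f_z2$z - z_r
  cycle_val <- mean(diff^2)
  d_z2 <- (2 * diff / length(diff)) * w$w_cycle
  be_cyc <- enc_bwd(model, f_z2$cache, d_z2)
  grads$E <- pl_add(grads$E, be_cyc$grads)
  d_xfake <- d_xfake + be_cyc$dX

  bg <- mlp_bwd(model$G, f_G, d_xfake)
  grads$G <- bg$grads
  d_zr <- bg$dX - d_z2  # target branch of the cycle loss
  be_joint <- enc_bwd(model, f_z$cache, rbind(d_zr, d_za))
  grads$E <- pl_add(grads$E, be_joint$grads)

  if (do_main) {
    main_params <- model[c("E", "head_linear", "head_softmax", "G")]
    up <- sgd_step(main_params,
                   grads[c("E", "head_linear", "head_softmax", "G")],
                   vel$main, lr, cfg$momentum, cfg$weight_decay)
    attr(up$p$G, "final_relu") <- TRUE
    model[c("E", "head_linear", "head_softmax", "G")] <- up$p
    vel$main <- up$v
  }

  terms <- list(nce_rna = cb$loss_rna, nce_atac = cb$loss_atac,
                d_rna = bl_dr$loss, e_adv = bl_adv$loss,
                d_atac = bl_da$loss, g_adv = bl_gadv$loss,
                cycle = cycle_val)
  terms$total <- total_loss(list(nce_rna = terms$nce_rna,
                                 nce_atac = terms$nce_atac,
                                 e_adv = terms$e_adv,
                                 g_adv = terms$g_adv,
                                 cycle = terms$cycle), w)
  list(model = model, vel = vel, terms = terms)
}

#' Embed every cell of both modalities
#'
#' Eval-mode encoding of the full dataset; rows carry the modality tag and
#' any provided per-cell labels.
#'
#' @param model A `modalign_model` or `modalign_fit`.
#' @param pair The `paired_input` the model was trained on.
#' @param labels_rna,labels_atac Optional per-cell type labels.
#' @return An embedding tibble (see [as_embedding()]).
#' @export
embed_all <- function(model, pair, labels_rna = NULL, labels_atac = NULL) {
  if (inherits(model, "modalign_fit")) model <- model$model
  z_r <- encode(model, pair$rna, mode = "eval")
  z_a <- encode(model, pair$atac, mode = "eval")
  as_embedding(
    rbind(z_r, z_a),
    modality = c(rep("rna", nrow(z_r)), rep("atac_activity", nrow(z_a))),
    label = c(if (is.null(labels_rna)) rep(NA_character_, nrow(z_r))
              else labels_rna,
              if (is.null(labels_atac)) rep(NA_character_, nrow(z_a))
              else labels_atac),
    cell_id = c(cell_ids(pair$rna), cell_ids(pair$atac)))
}

#' Tidy the training history of a fit
#'
#' @param x A `modalign_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `epoch`, `term`, `value`.
#' @export
tidy.modalign_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, cols = -c("epoch", "seconds"),
                      names_to = "term", values_to = "value")
}

#' One-row summary of a fit
#'
#' @param x A `modalign_fit`.
#' @param ... Unused.
#' @return A one-row tibble: feature/cell counts, epochs, final and mean
#'   total loss, total wall-clock seconds.
#' @export
glance.modalign_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_features = length(x$features),
    n_rna = x$n_rna,
    n_atac = x$n_atac,
    epochs = nrow(h),
    final_total = if (nrow(h)) h$total[nrow(h)] else NA_real_,
    mean_total = if (nrow(h)) mean(h$total) else NA_real_,
    seconds = sum(h$seconds))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
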