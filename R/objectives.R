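#' Augmentation configuration
#'
#' Stochastic corruption applied to each mini-batch to make the two
#' contrastive views: additive Gaussian noise (`noise_sigma`), then random
#' feature zeroing (`mask_prob`), then clipping at 0 so values stay on the
#' nonnegative log1p scale. At least one of the two corruption strengths
#' must be positive, otherwise the two views collapse to the input and the
#' contrastive task is vacuous (`.allow_degenerate` bypasses the check for
#' tests).
#'
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param mask_prob Probability of zeroing each entry.
#' @param rng_seed Optional integer; when set, [augment_views()] is
#'   reproducible and leaves the caller's RNG stream untouched.
#' @param .allow_degenerate Skip the "at least one corruption" invariant.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(noise_sigma = 0.2, mask_prob = 0.1,
                           rng_seed = NULL, .allow_degenerate = FALSE) {
  if (noise_sigma < 0 || mask_prob < 0 || mask_prob > 1) {
    stop("noise_sigma must be >= 0 and mask_prob a probability",
         call. = FALSE)
  }
  if (!.allow_degenerate && noise_sigma == 0 && mask_prob == 0) {
    stop("at least one of noise_sigma, mask_prob must be positive",
         call. = FALSE)
  }
  structure(list(noise_sigma = noise_sigma, mask_prob = mask_prob,
                 rng_seed = rng_seed),
            class = "augment_config")
}

#' Loss weights
#'
#' Weights of the four loss groups entering the encoder/generator
#' objective; the discriminator losses are optimised separately and never
#' weighted into the total. All default to 1.
#'
#' @param w_nce Weight of the two per-modality contrastive (NCE) sums.
#' @param w_domain Weight of the encoder-side domain-adversarial term.
#' @param w_atac_gan Weight of the generator-side adversarial term.
#' @param w_cycle Weight of the latent cycle-consistency term.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(w_nce = 1, w_domain = 1, w_atac_gan = 1,
                         w_cycle = 1) {
  w <- c(w_nce, w_domain, w_atac_gan, w_cycle)
  if (any(w < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  structure(list(w_nce = w_nce, w_domain = w_domain,
                 w_atac_gan = w_atac_gan, w_cycle = w_cycle),
            class = "loss_weights")
}

#' Make two augmented views of a batch
#'
#' @param X Numeric matrix (cells by features, log1p scale).
#' @param cfg An [augment_config()].
#' @return A list with matrices `x1` and `x2`, two independent corruptions
#'   of `X`.
#' @export
augment_views <- function(X, cfg) {
  X <- as.matrix(unclass(X))
  if (!is.null(cfg$rng_seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(cfg$rng_seed)
  }
  corrupt <- function() {
    y <- X
    if (cfg$noise_sigma > 0) {
      y <- y + matrix(stats::rnorm(length(X), sd = cfg$noise_sigma),
                      nrow(X), ncol(X))
    }
    if (cfg$mask_prob > 0) {
      y <- y * (matrix(stats::runif(length(X)), nrow(X), ncol(X)) >=
                  cfg$mask_prob)
    }
    pmax(y, 0)
  }
  list(x1 = corrupt(), x2 = corrupt())
}

# interleave two view matrices so that rows 2i-1 and 2i are the two views
# of cell i — the pairing convention nce_loss expects
interleave_views <- function(x1, x2) {
  out <- matrix(0, 2 * nrow(x1), ncol(x1))
  out[seq(1, nrow(out), by = 2), ] <- x1
  out[seq(2, nrow(out), by = 2), ] <- x2
  out
}

# row-L2 normalisation with an epsilon guard; returns the norms for the
# backward pass
l2norm_rows <- function(V, eps = 1e-12) {
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm < eps)) {
    warning("zero-norm row(s) in contrastive input; epsilon-guarded")
  }
  nrm <- pmax(nrm, eps)
  list(U = V / nrm, norm = nrm)
}

#' Noise-contrastive estimation loss over paired views
#'
#' For a batch of N cells turned into 2N augmented views (rows `2i-1` and
#' `2i` are the two views of cell i), each view is an anchor whose partner
#' must be recognised among the in-batch negatives: the loss is the mean
#' over anchors of
#' `-log( exp(cos(z_i, z_j)/tau) / sum_k exp(cos(z_i, z_k)/tau) )`,
#' with `j` the partner of `i`, cosine similarity on L2-normalised rows and
#' temperature `tau`. By default the anchor itself is excluded from the
#' denominator sum (the standard contrastive convention); set
#' `include_self = TRUE` for the variant whose sum runs over all 2N views,
#' which only adds a constant-direction `exp(1/tau)` term.
#'
#' @param V Numeric matrix of 2N view representations (N >= 2).
#' @param tau Positive temperature.
#' @param include_self Include the anchor in the denominator sum?
#' @return The scalar loss.
#' @export
nce_loss <- function(V, tau, include_self = FALSE) {
  nce_fwd(as.matrix(V), tau, include_self)$loss
}

nce_fwd <- function(V, tau, include_self = FALSE) {
  n2 <- nrow(V)
  if (n2 < 4 || n2 %% 2 != 0) {
    stop("V must hold 2N rows of paired views with N >= 2", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  nr <- l2norm_rows(V)
  S <- tcrossprod(nr$U) / tau
  partner <- seq_len(n2) + c(1, -1)  # 2i-1 <-> 2i
  Sm <- S
  if (!include_self) diag(Sm) <- -Inf
  m <- apply(Sm, 1, max)
  E <- exp(Sm - m)
  denom <- rowSums(E)
  pos <- S[cbind(seq_len(n2), partner)]
  loss <- mean(-(pos - (log(denom) + m)))
  list(loss = loss, U = nr$U, norm = nr$norm, P = E / denom,
       partner = partner, tau = tau)
}

# gradient of nce_fwd w.r.t. V
nce_bwd <- function(fwd) {
  n2 <- nrow(fwd$U)
  dS <- fwd$P
  dS[cbind(seq_len(n2), fwd$partner)] <-
    dS[cbind(seq_len(n2), fwd$partner)] - 1
  dS <- dS / n2
  dU <- (dS %*% fwd$U + crossprod(dS, fwd$U)) / fwd$tau
  # through row normalisation: dV_i = (dU_i - U_i (dU_i . U_i)) / norm_i
  proj <- rowSums(dU * fwd$U)
  (dU - fwd$U * proj) / fwd$norm
}

# binary cross-entropy from probabilities; targets in {0,1}
bce <- function(p, y) {
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Per-modality contrastive totals
#'
#' Encodes each modality's interleaved view batch, projects through both
#' heads and sums the NCE terms: `nce(H32, tau = 0.15) + nce(P25,
#' tau = 0.5)`. The two modalities are scored independently.
#'
#' @param model A `modalign_model`.
#' @param rna_views,atac_views Lists `x1`/`x2` from [augment_views()].
#' @param tau_linear,tau_softmax Temperatures of the two heads.
#' @param mode Encoder mode (see [encode()]).
#' @return A list with scalars `nce_rna` and `nce_atac`.
#' @export
contrastive_total <- function(model, rna_views, atac_views,
                              tau_linear = 0.15, tau_softmax = 0.5,
                              mode = "eval") {
  one <- function(views) {
    V <- interleave_views(views$x1, views$x2)
    Z <- encode(model, V, mode = mode)
    pr <- project(model, Z)
    nce_loss(pr$h32, tau_linear) + nce_loss(pr$p25, tau_softmax)
  }
  list(nce_rna = one(rna_views), nce_atac = one(atac_views))
}

#' Domain-adversarial losses on the latent space
#'
#' `D_rna` is trained to output 1 on RNA-derived latent codes and 0 on
#' activity-derived ones (`d_rna_loss`, mean binary cross-entropy over the
#' combined batch, encoder treated as fixed); the encoder's adversarial
#' term `e_adv_loss` is the non-saturating objective pushing
#' `D_rna(z_atac)` towards 1 (discriminator treated as fixed).
#'
#' @param model A `modalign_model`.
#' @param z_rna,z_atac Latent batches of the two modalities.
#' @return A list with scalars `d_rna_loss` and `e_adv_loss`.
#' @export
domain_adversarial_losses <- function(model, z_rna, z_atac) {
  p_rna <- discriminate(model, "rna_latent", z_rna)
  p_atac <- discriminate(model, "rna_latent", z_atac)
  list(
    d_rna_loss = bce(c(p_rna, p_atac),
                     c(rep(1, length(p_rna)), rep(0, length(p_atac)))),
    e_adv_loss = bce(p_atac, rep(1, length(p_atac))))
}

#' Cycle-consistent adversarial losses
#'
#' The generator maps RNA latent codes to activity-like data
#' `x_fake = G(z_rna)`. `D_atac` is trained to tell real activity batches
#' (target 1) from generated ones (target 0) — `d_atac_loss`; the
#' generator's non-saturating adversarial term `g_adv_loss` pushes
#' `D_atac(x_fake)` towards 1; and the cycle-consistency loss is the mean
#' squared error between the re-encoded fake data `E(G(z_rna))` and the
#' original `z_rna` — consistency is enforced at the level of the latent
#' space, not the data space.
#'
#' @param model A `modalign_model`.
#' @param z_rna Latent batch of real RNA cells.
#' @param x_atac_real Real activity batch (data space, log1p scale).
#' @return A list with scalars `d_atac_loss`, `g_adv_loss`, `cycle_loss`.
#' @export
cycle_losses <- function(model, z_rna, x_atac_real) {
  z_rna <- as.matrix(z_rna)
  x_fake <- generate(model, z_rna)
  p_real <- discriminate(model, "atac_data", x_atac_real)
  p_fake <- discriminate(model, "atac_data", x_fake)
  z_back <- encode(model, x_fake, mode = "eval")
  list(
    d_atac_loss = bce(c(p_real, p_fake),
                      c(rep(1, length(p_real)), rep(0, length(p_fake)))),
    g_adv_loss = bce(p_fake, rep(1, length(p_fake))),
    cycle_loss = mean((z_back - z_rna)^2))
}

#' Weighted total loss of the encoder/generator step
#'
#' `total = w_nce * (nce_rna + nce_atac) + w_domain * e_adv +
#' w_atac_gan * g_adv + w_cycle * cycle`. The discriminator losses are
#' optimised by their own step and never enter this sum.
#'
#' @param terms A list holding at least `nce_rna`, `nce_atac`, `e_adv`,
#'   `g_adv` and `cycle` scalars.
#' @param w A [loss_weights()].
#' @return The scalar total.
#' @export
total_loss <- function(terms, w = loss_weights()) {
  vals <- c(terms$nce_rna, terms$nce_atac, terms$e_adv, terms$g_adv,
            terms$cycle)
  if (any(!is.finite(vals))) stop("loss terms must be finite", call. = FALSE)
  w$w_nce * (terms$nce_rna + terms$nce_atac) +
    w$w_domain * terms$e_adv +
    w$w_atac_gan * terms$g_adv +
    w$w_cycle * terms$cycle
}
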