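# Independent brute-force oracles. These deliberately mirror the printed
# definitions with scalar loops and share no code with the package
# implementations they check.

# mean silhouette via the textbook double loop: a(i) mean distance to own
# class, b(i) smallest mean distance to another class, singleton classes
# score 0
sil_brute <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, own])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == l]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# contrastive loss by scalar double loop over all anchors and negatives;
# rows 2i-1 and 2i are partners
nce_brute <- function(V, tau) {
  n <- nrow(V)
  U <- V / pmax(sqrt(rowSums(V^2)), 1e-12)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i %% 2 == 1) i + 1 else i - 1
    den <- 0
    for (k in seq_len(n)) {
      if (k != i) den <- den + exp(sum(U[i, ] * U[k, ]) / tau)
    }
    total <- total - log(exp(sum(U[i, ] * U[j, ]) / tau) / den)
  }
  total / n
}

# per-type F1 from an explicit confusion matrix
f1_from_confusion <- function(truth, predicted) {
  types <- sort(unique(truth))
  sapply(types, function(t) {
    tp <- sum(truth == t & predicted == t)
    fp <- sum(truth != t & predicted == t)
    fn <- sum(truth == t & predicted != t)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  })
}
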