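# Minimal dense-layer machinery: forward passes carry explicit caches and
# each primitive has a matching backward returning input and parameter
# gradients. Everything is plain base R on BLAS-backed matrices; batches
# are rows.

# broadcast a length-d vector across the rows of an n x d matrix
.addrow <- function(X, v) X + rep(v, each = nrow(X))
.mulrow <- function(X, v) X * rep(v, each = nrow(X))

lin_init <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = stats::runif(n_out, -bound, bound))
}

lin_fwd <- function(p, X) {
  list(out = .addrow(X %*% p$W, p$b), X = X)
}

lin_bwd <- function(p, cache, dY) {
  list(dX = dY %*% t(p$W),
       grad = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

relu_bwd <- function(cache, dY) dY * cache$mask

bn_init <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d))
}

bn_state_init <- function(d) {
  list(rmean = rep(0, d), rvar = rep(1, d))
}

# training mode standardises with batch statistics; eval mode with the
# running statistics accumulated during training (momentum 0.1, as is
# conventional). Returns updated running stats so the caller can thread
# state (params are immutable values in R).
bn_fwd <- function(p, state, X, training, eps = 1e-5, momentum = 0.1) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- .addrow(X, -mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- .mulrow(xc, inv)
    unbiased <- if (n > 1) v * n / (n - 1) else v
    new_state <- list(
      rmean = (1 - momentum) * state$rmean + momentum * mu,
      rvar = (1 - momentum) * state$rvar + momentum * unbiased)
    list(out = .addrow(.mulrow(xhat, p$gamma), p$beta),
         cache = list(xhat = xhat, xc = xc, inv = inv, n = n),
         state = new_state)
  } else {
    inv <- 1 / sqrt(state$rvar + eps)
    xhat <- .mulrow(.addrow(X, -state$rmean), inv)
    list(out = .addrow(.mulrow(xhat, p$gamma), p$beta),
         cache = list(xhat = xhat, inv = inv, n = n),
         state = state)
  }
}

# standard batch-norm backward (training mode)
bn_bwd <- function(p, cache, dY) {
  n <- cache$n
  dxhat <- .mulrow(dY, p$gamma)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  # dX = inv/n * (n*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- .mulrow(n * dxhat - rep(s1, each = n) - .mulrow(cache$xhat, s2),
                cache$inv / n)
  list(dX = dX, grad = list(gamma = dgamma, beta = dbeta))
}

softmax_rows <- function(X) {
  m <- apply(X, 1, max)
  e <- exp(X - m)
  e / rowSums(e)
}

# plain MLP: linear layers with ReLU between them; optional ReLU after the
# last layer (used by the generator whose outputs must be nonnegative).
mlp_init <- function(dims, final_relu = FALSE) {
  layers <- vector("list", length(dims) - 1)
  for (i in seq_along(layers)) layers[[i]] <- lin_init(dims[i], dims[i + 1])
  structure(layers, final_relu = final_relu)
}

mlp_fwd <- function(p, X) {
  n_layers <- length(p)
  caches <- vector("list", n_layers)
  out <- X
  for (i in seq_len(n_layers)) {
    lc <- lin_fwd(p[[i]], out)
    out <- lc$out
    rc <- NULL
    if (i < n_layers || isTRUE(attr(p, "final_relu"))) {
      rc <- relu_fwd(out)
      out <- rc$out
    }
    caches[[i]] <- list(lin = lc, relu = rc)
  }
  list(out = out, caches = caches)
}

mlp_bwd <- function(p, fwd, dOut) {
  n_layers <- length(p)
  grads <- vector("list", n_layers)
  d <- dOut
  for (i in rev(seq_len(n_layers))) {
    if (!is.null(fwd$caches[[i]]$relu)) {
      d <- relu_bwd(fwd$caches[[i]]$relu, d)
    }
    lb <- lin_bwd(p[[i]], fwd$caches[[i]]$lin, d)
    grads[[i]] <- lb$grad
    d <- lb$dX
  }
  list(dX = d, grads = grads)
}

# ---- parameter-tree utilities -------------------------------------------

# elementwise combination over parallel nested lists of numerics
pl_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- pl_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

pl_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  pl_map2(a, b, `+`)
}

pl_zeros <- function(p) {
  if (is.list(p)) {
    out <- p
    for (i in seq_along(p)) out[[i]] <- pl_zeros(p[[i]])
    out
  } else {
    p * 0
  }
}

# SGD with momentum and (decoupled-from-nothing, classic) weight decay:
# v <- momentum * v + grad + wd * p ; p <- p - lr * v
sgd_step <- function(params, grads, velocity, lr, momentum, wd) {
  step_one <- function(p, g, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- step_one(p[[i]], g[[i]], v[[i]])
        p[[i]] <- r$p
        v[[i]] <- r$v
      }
      return(list(p = p, v = v))
    }
    v <- momentum * v + g + wd * p
    list(p = p - lr * v, v = v)
  }
  step_one(params, grads, velocity)
}

# largest absolute difference between two parallel parameter trees; used
# by the update-isolation checks
pl_max_abs_diff <- function(a, b) {
  if (is.list(a)) {
    max(vapply(seq_along(a),
               function(i) pl_max_abs_diff(a[[i]], b[[i]]), numeric(1)))
  } else {
    if (length(a) == 0) 0 else max(abs(a - b))
  }
}
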