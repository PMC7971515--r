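# Minimal feed-forward building blocks with explicit reverse-mode gradients.
# All "networks" in the model (g_node, g_edge, g_graph) are 2-layer
# perceptrons; parameters live in plain nested lists so they can be flattened
# for the optimizer and inspected by coef().

lin_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

add_rows <- function(Z, v) Z + rep(v, each = nrow(Z))

lin_fwd <- function(p, X) {
  list(out = add_rows(X %*% p$W, p$b), X = X)
}

lin_bwd <- function(p, cache, dY) {
  list(grads = list(W = crossprod(cache$X, dY), b = colSums(dY)),
       dX = tcrossprod(dY, p$W))
}

bn_init <- function(n) list(gamma = rep(1, n), beta = numeric(n))

# feature normalization over the rows of Z; `stats` = NULL uses the batch's
# own statistics (training; minibatches are single-individual by
# construction), otherwise fixed per-individual statistics from an
# evaluation pre-pass.
bn_fwd <- function(p, Z, stats = NULL) {
  n <- nrow(Z)
  batch_stats <- is.null(stats)
  if (batch_stats) {
    mu <- colMeans(Z)
    va <- pmax(colMeans(Z * Z) - mu * mu, 0)
  } else {
    mu <- stats$mu
    va <- stats$va
  }
  s <- sqrt(va + 1e-5)
  Zh <- (Z - rep(mu, each = n)) / rep(s, each = n)
  out <- add_rows(Zh * rep(p$gamma, each = n), p$beta)
  list(out = out, Zh = Zh, s = s, batch_stats = batch_stats, n = n)
}

bn_bwd <- function(p, cache, dY) {
  n <- cache$n
  Zh <- cache$Zh
  dgamma <- colSums(dY * Zh)
  dbeta <- colSums(dY)
  dZh <- dY * rep(p$gamma, each = n)
  if (cache$batch_stats) {
    m1 <- colMeans(dZh)
    m2 <- colMeans(dZh * Zh)
    dZ <- (dZh - rep(m1, each = n) - Zh * rep(m2, each = n)) /
      rep(cache$s, each = n)
  } else {
    dZ <- dZh / rep(cache$s, each = n)
  }
  list(grads = list(gamma = dgamma, beta = dbeta), dX = dZ)
}

# 2-layer perceptron: linear -> [feature norm] -> ReLU -> linear
mlp_init <- function(n_in, n_hidden, n_out, bn = TRUE) {
  p <- list(l1 = lin_init(n_in, n_hidden), l2 = lin_init(n_hidden, n_out))
  if (bn) p$bn <- bn_init(n_hidden)
  p
}

mlp_fwd <- function(p, X, stats = NULL) {
  c1 <- lin_fwd(p$l1, X)
  Z <- c1$out
  cb <- NULL
  if (!is.null(p$bn)) {
    cb <- bn_fwd(p$bn, Z, stats)
    Z <- cb$out
  }
  mask <- Z > 0
  A <- Z * mask
  c2 <- lin_fwd(p$l2, A)
  list(out = c2$out, c1 = c1, cb = cb, mask = mask, c2 = c2)
}

mlp_bwd <- function(p, cache, dY) {
  b2 <- lin_bwd(p$l2, cache$c2, dY)
  dA <- b2$dX * cache$mask
  gbn <- NULL
  if (!is.null(p$bn)) {
    bb <- bn_bwd(p$bn, cache$cb, dA)
    gbn <- bb$grads
    dA <- bb$dX
  }
  b1 <- lin_bwd(p$l1, cache$c1, dA)
  g <- list(l1 = b1$grads, l2 = b2$grads)
  if (!is.null(gbn)) g$bn <- gbn
  list(grads = g, dX = b1$dX)
}

# first-layer pre-activation (for evaluation-time normalization statistics)
mlp_preact <- function(p, X) add_rows(X %*% p$l1$W, p$l1$b)

# --- parameter trees ------------------------------------------------------

tree_zero <- function(p) rapply(p, function(x) x * 0, how = "replace")

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

tree_scale <- function(a, s) rapply(a, function(x) x * s, how = "replace")

flatten_tree <- function(p) unlist(p, use.names = FALSE)

unflatten_tree <- function(v, skeleton) {
  pos <- 0L
  fill <- function(p) {
    if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- fill(p[[nm]])
      p
    } else {
      n <- length(p)
      out <- v[(pos + 1L):(pos + n)]
      pos <<- pos + n
      attributes(out) <- attributes(p)
      out
    }
  }
  fill(skeleton)
}

# --- Adam on flattened parameter vectors ----------------------------------

adam_init <- function(params) {
  n <- length(flatten_tree(params))
  list(m = numeric(n), v = numeric(n), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  g <- flatten_tree(grads)
  if (any(!is.finite(g))) stop("non-finite gradient: optimization diverged")
  p <- flatten_tree(params)
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * g
  state$v <- state$beta2 * state$v + (1 - state$beta2) * g * g
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + state$eps)
  list(params = unflatten_tree(p, params), state = state)
}
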