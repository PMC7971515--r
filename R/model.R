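#' Model and training configuration
#'
#' Collects the architecture and optimization hyperparameters that the
#' framework leaves open. Defaults: 2-layer perceptrons with 64 hidden units
#' and ReLU for `g_node`, `g_edge` and `g_graph`; node embeddings of
#' dimension 16; concatenation aggregation; a single message-passing step;
#' Adam with learning rate 1e-3; per-individual feature normalization after
#' the first linear layer of `g_node` and `g_graph`.
#'
#' @param model `"gnn"` (edge-inferring graph network) or `"mlp"`
#'   (structure-agnostic baseline).
#' @param task `"classify"` (behavioral-state decoding) or `"predict"`
#'   (Markovian trajectory prediction).
#' @param n_neurons number of neurons N.
#' @param n_states number of behavioral states k (classification only).
#' @param hidden hidden width of all perceptrons.
#' @param embed_dim node-embedding dimension of `g_node`.
#' @param aggregation `"concat"` (default; performs better) or `"sum"`.
#' @param edge_mode `"dynamic"` (edges re-inferred each timestep), `"static"`
#'   (one adjacency per individual, from the whole recording), or
#'   `"provided"` (user-supplied, e.g. connectome-derived). Default:
#'   `"dynamic"` for classification, `"static"` for prediction.
#' @param message_steps number of message-passing applications (default 1;
#'   more steps brought no improvement in our experiments).
#' @param batchnorm use per-individual feature normalization layers.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param window training window length in timesteps (default 8).
#' @param windows_per_update windows concatenated into one optimization
#'   minibatch (default 8). Windows hold independent timesteps for
#'   classification; drawing several shuffled windows per update lets the
#'   feature-normalization statistics mix behavioral states, which matters
#'   because a single 8-timestep window usually sits inside one state.
#' @param shuffle_individuals visit individuals in shuffled order each epoch
#'   (default `FALSE`: fixed input order, reproducible).
#' @return object of class `elegnn_config`.
#' @export
elegnn_config <- function(model = c("gnn", "mlp"),
                          task = c("classify", "predict"),
                          n_neurons,
                          n_states = NULL,
                          hidden = 64L,
                          embed_dim = 16L,
                          aggregation = c("concat", "sum"),
                          edge_mode = NULL,
                          message_steps = 1L,
                          batchnorm = TRUE,
                          lr = 1e-3,
                          epochs = 200L,
                          window = 8L,
                          windows_per_update = NULL,
                          shuffle_individuals = FALSE) {
  model <- match.arg(model)
  task <- match.arg(task)
  aggregation <- match.arg(aggregation)
  if (is.null(edge_mode)) {
    edge_mode <- if (task == "classify") "dynamic" else "static"
  }
  edge_mode <- match.arg(edge_mode, c("dynamic", "static", "provided"))
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 1L, hidden >= 1L, embed_dim >= 1L,
            message_steps >= 1L, lr > 0, epochs >= 1L, window >= 1L)
  if (task == "classify") {
    if (is.null(n_states) || n_states < 2L) {
      stop("classification requires n_states >= 2")
    }
    n_states <- as.integer(n_states)
  }
  if (is.null(windows_per_update)) windows_per_update <- 8L
  structure(list(
    model = model, task = task, n_neurons = n_neurons, n_states = n_states,
    hidden = as.integer(hidden), embed_dim = as.integer(embed_dim),
    aggregation = aggregation, edge_mode = edge_mode,
    message_steps = as.integer(message_steps), batchnorm = isTRUE(batchnorm),
    lr = lr, epochs = as.integer(epochs), window = as.integer(window),
    windows_per_update = as.integer(windows_per_update),
    shuffle_individuals = isTRUE(shuffle_individuals)
  ), class = "elegnn_config")
}

n_out_of <- function(cfg) {
  if (cfg$task == "classify") cfg$n_states else 2L * cfg$n_neurons
}

n_graph_in <- function(cfg) {
  if (cfg$aggregation == "concat") 2L * cfg$n_neurons else 2L
}

#' Construct an untrained model
#'
#' Initializes the parameter set of an MLP or GNN model for a given
#' configuration, with seeded random weights. Mostly useful for inspecting
#' the architecture and for tests; [elegnn()] both constructs and trains.
#'
#' @param config an [elegnn_config()].
#' @param seed integer seed for weight initialization.
#' @param neuron_names optional neuron names recorded on the model.
#' @return object of class `elegnn` with `trained = FALSE`.
#' @export
elegnn_model <- function(config, seed = 1L, neuron_names = NULL) {
  stopifnot(inherits(config, "elegnn_config"))
  params <- with_seed(seed, init_params(config))
  structure(list(
    params = params, config = config, trained = FALSE,
    neuron_names = neuron_names, vocabulary = NULL, log = NULL,
    seed = as.integer(seed)
  ), class = "elegnn")
}

init_params <- function(cfg) {
  if (cfg$model == "mlp") {
    list(ggraph = mlp_init(n_graph_in(cfg), cfg$hidden, n_out_of(cfg),
                           bn = cfg$batchnorm))
  } else {
    list(
      gnode = mlp_init(2L, cfg$hidden, cfg$embed_dim, bn = cfg$batchnorm),
      gedge = mlp_init(2L * cfg$embed_dim, cfg$hidden, 1L, bn = FALSE),
      ggraph = mlp_init(n_graph_in(cfg), cfg$hidden, n_out_of(cfg),
                        bn = cfg$batchnorm)
    )
  }
}

# --- feature reshaping ----------------------------------------------------

# B x N x 2 -> B x 2N, node-major (trace, derivative per node)
flat_nodes <- function(Xb) {
  d <- dim(Xb)
  Y <- aperm(Xb, c(1L, 3L, 2L))
  dim(Y) <- c(d[1L], 2L * d[2L])
  Y
}

unflat_nodes <- function(Y, N) {
  B <- nrow(Y)
  dim(Y) <- c(B, 2L, N)
  aperm(Y, c(1L, 3L, 2L))
}

# B x N x 2 -> (B*N) x 2 with row index b + (n-1)*B
stack_nodes <- function(Xb) {
  d <- dim(Xb)
  dim(Xb) <- c(d[1L] * d[2L], d[3L])
  Xb
}

aggregate_nodes <- function(Xb, aggregation) {
  if (aggregation == "concat") {
    flat_nodes(Xb)
  } else {
    B <- dim(Xb)[1L]
    cbind(rowSums(Xb[, , 1L, drop = FALSE]), rowSums(Xb[, , 2L, drop = FALSE]))
  }
}

aggregate_nodes_bwd <- function(dY, aggregation, N) {
  B <- nrow(dY)
  if (aggregation == "concat") {
    unflat_nodes(dY, N)
  } else {
    aperm(array(dY, c(B, 2L, N)), c(1L, 3L, 2L))
  }
}

# --- edge encoder ---------------------------------------------------------

edges_fwd <- function(params, cfg, Xb, stats = NULL) {
  B <- dim(Xb)[1L]
  N <- dim(Xb)[2L]
  cn <- mlp_fwd(params$gnode, stack_nodes(Xb), stats$gnode)
  V <- cn$out
  d <- ncol(V)
  if (cfg$edge_mode == "static") {
    Vbar <- rowsum(V, rep(seq_len(N), each = B), reorder = TRUE) / B
    ii <- rep(seq_len(N), times = N)
    jj <- rep(seq_len(N), each = N)
    P <- cbind(Vbar[ii, , drop = FALSE], Vbar[jj, , drop = FALSE])
    ce <- mlp_fwd(params$gedge, P, NULL)
    Avec <- sigmoid(as.numeric(ce$out))
    A <- matrix(Avec, N, N)
  } else {
    ii <- rep(rep(seq_len(N), times = N), times = B)
    jj <- rep(rep(seq_len(N), each = N), times = B)
    bb <- rep(seq_len(B), each = N * N)
    ii <- (ii - 1L) * B + bb
    jj <- (jj - 1L) * B + bb
    P <- cbind(V[ii, , drop = FALSE], V[jj, , drop = FALSE])
    ce <- mlp_fwd(params$gedge, P, NULL)
    Avec <- sigmoid(as.numeric(ce$out))
    A <- array(Avec, c(N, N, B))
  }
  list(A = A, Avec = Avec, cn = cn, ce = ce, ii = ii, jj = jj,
       B = B, N = N, d = d, static = cfg$edge_mode == "static")
}

edges_bwd <- function(params, ec, dA) {
  dAvec <- as.numeric(dA) * ec$Avec * (1 - ec$Avec)
  be <- mlp_bwd(params$gedge, ec$ce, matrix(dAvec, ncol = 1L))
  dP <- be$dX
  d <- ec$d
  dPi <- dP[, seq_len(d), drop = FALSE]
  dPj <- dP[, d + seq_len(d), drop = FALSE]
  if (ec$static) {
    dVbar <- rowsum(dPi, ec$ii, reorder = TRUE) +
      rowsum(dPj, ec$jj, reorder = TRUE)
    dV <- dVbar[rep(seq_len(ec$N), each = ec$B), , drop = FALSE] / ec$B
  } else {
    dV <- rowsum(dPi, ec$ii, reorder = TRUE) +
      rowsum(dPj, ec$jj, reorder = TRUE)
  }
  bn <- mlp_bwd(params$gnode, ec$cn, dV)
  list(gedge = be$grads, gnode = bn$grads)
}

# --- message passing ------------------------------------------------------

message_fwd <- function(A, Xb, steps) {
  B <- dim(Xb)[1L]
  N <- dim(Xb)[2L]
  dynamic <- length(dim(A)) == 3L
  Ms <- vector("list", steps + 1L)
  Ms[[1L]] <- Xb
  for (s in seq_len(steps)) {
    prev <- Ms[[s]]
    if (dynamic) {
      M <- prev
      for (b in seq_len(B)) M[b, , ] <- A[, , b] %*% prev[b, , ]
    } else {
      Pm <- aperm(prev, c(2L, 1L, 3L))
      dim(Pm) <- c(N, B * 2L)
      Mm <- A %*% Pm
      dim(Mm) <- c(N, B, 2L)
      M <- aperm(Mm, c(2L, 1L, 3L))
    }
    Ms[[s + 1L]] <- M
  }
  list(M = Ms[[steps + 1L]], Ms = Ms, A = A, dynamic = dynamic, B = B, N = N)
}

message_bwd <- function(mp, dM) {
  A <- mp$A
  B <- mp$B
  N <- mp$N
  steps <- length(mp$Ms) - 1L
  dA <- if (mp$dynamic) array(0, dim(A)) else A * 0
  for (s in steps:1L) {
    prev <- mp$Ms[[s]]
    if (mp$dynamic) {
      for (b in seq_len(B)) {
        dA[, , b] <- dA[, , b] + dM[b, , ] %*% t(prev[b, , ])
        if (s > 1L) dM[b, , ] <- crossprod(A[, , b], dM[b, , ])
      }
    } else {
      Pm <- aperm(prev, c(2L, 1L, 3L))
      dim(Pm) <- c(N, B * 2L)
      Dm <- aperm(dM, c(2L, 1L, 3L))
      dim(Dm) <- c(N, B * 2L)
      dA <- dA + tcrossprod(Dm, Pm)
      if (s > 1L) {
        D2 <- crossprod(A, Dm)
        dim(D2) <- c(N, B, 2L)
        dM <- aperm(D2, c(2L, 1L, 3L))
      }
    }
  }
  dA
}

# --- full model forward / backward ---------------------------------------

# Xb: B x N x 2; A_fixed: N x N matrix (provided edges or static-eval edges)
net_forward <- function(params, cfg, Xb, A_fixed = NULL, stats = NULL) {
  if (cfg$model == "mlp") {
    Xin <- aggregate_nodes(Xb, cfg$aggregation)
    cg <- mlp_fwd(params$ggraph, Xin, stats$ggraph)
    return(list(H = cg$out,
                cache = list(kind = "mlp", cg = cg, N = dim(Xb)[2L])))
  }
  edge <- NULL
  if (is.null(A_fixed)) {
    if (cfg$edge_mode == "provided") {
      stop("edge_mode 'provided' requires a supplied adjacency; ",
           "the edge encoder is bypassed in this mode")
    }
    edge <- edges_fwd(params, cfg, Xb, stats)
    A <- edge$A
  } else {
    A <- A_fixed
  }
  mp <- message_fwd(A, Xb, cfg$message_steps)
  Magg <- aggregate_nodes(mp$M, cfg$aggregation)
  cg <- mlp_fwd(params$ggraph, Magg, stats$ggraph)
  list(H = cg$out,
       cache = list(kind = "gnn", cg = cg, mp = mp, edge = edge,
                    N = dim(Xb)[2L]))
}

# returns list(grads = full parameter tree, dA = adjacency gradient when the
# adjacency was fixed externally (static rollouts accumulate it))
net_backward <- function(params, cfg, cache, dH) {
  grads <- tree_zero(params)
  bg <- mlp_bwd(params$ggraph, cache$cg, dH)
  grads$ggraph <- bg$grads
  if (cache$kind == "mlp") {
    return(list(grads = grads, dA = NULL))
  }
  dM <- aggregate_nodes_bwd(bg$dX, cfg$aggregation, cache$N)
  dA <- message_bwd(cache$mp, dM)
  if (!is.null(cache$edge)) {
    ge <- edges_bwd(params, cache$edge, dA)
    grads$gedge <- ge$gedge
    grads$gnode <- ge$gnode
    return(list(grads = grads, dA = NULL))
  }
  list(grads = grads, dA = dA)
}

# backprop an accumulated adjacency gradient through the edge encoder
edge_grads_from_dA <- function(params, edge_cache, dA, grads) {
  ge <- edges_bwd(params, edge_cache, dA)
  grads$gedge <- tree_add(grads$gedge, ge$gedge)
  grads$gnode <- tree_add(grads$gnode, ge$gnode)
  grads
}

# --- evaluation-time normalization statistics ----------------------------

# Per-individual statistics for the feature-normalization layers, computed
# from an evaluated individual's own recording (no labels used). Returns
# list(gnode=, ggraph=, A=) where A is the inferred static adjacency when
# edge_mode == "static".
collect_stats <- function(params, cfg, Xall, A_fixed = NULL, chunk = 256L) {
  T_ <- dim(Xall)[1L]
  N <- dim(Xall)[2L]
  out <- list(gnode = NULL, ggraph = NULL, A = A_fixed)
  if (!cfg$batchnorm && cfg$edge_mode != "static") {
    return(out)
  }
  if (cfg$model == "mlp") {
    if (cfg$batchnorm) {
      Z <- mlp_preact(params$ggraph, aggregate_nodes(Xall, cfg$aggregation))
      out$ggraph <- list(mu = colMeans(Z), va = pmax(colMeans(Z * Z) -
                                                       colMeans(Z)^2, 0))
    }
    return(out)
  }
  if (cfg$batchnorm) {
    Z <- mlp_preact(params$gnode, stack_nodes(Xall))
    out$gnode <- list(mu = colMeans(Z), va = pmax(colMeans(Z * Z) -
                                                    colMeans(Z)^2, 0))
  }
  if (cfg$edge_mode == "static" && is.null(A_fixed)) {
    ec <- edges_fwd(params, cfg, Xall, stats = out)
    out$A <- ec$A
  }
  if (cfg$batchnorm) {
    s1 <- numeric(cfg$hidden)
    s2 <- numeric(cfg$hidden)
    starts <- seq(1L, T_, by = chunk)
    for (t0 in starts) {
      rows <- t0:min(t0 + chunk - 1L, T_)
      Xc <- Xall[rows, , , drop = FALSE]
      if (cfg$edge_mode == "dynamic") {
        ec <- edges_fwd(params, cfg, Xc, stats = out)
        A <- ec$A
      } else {
        A <- out$A
        if (is.null(A)) stop("provided edge_mode requires an adjacency")
      }
      mp <- message_fwd(A, Xc, cfg$message_steps)
      Z <- mlp_preact(params$ggraph, aggregate_nodes(mp$M, cfg$aggregation))
      s1 <- s1 + colSums(Z)
      s2 <- s2 + colSums(Z * Z)
    }
    mu <- s1 / T_
    out$ggraph <- list(mu = mu, va = pmax(s2 / T_ - mu * mu, 0))
  }
  out
}

# chunked deterministic forward over a whole recording with fixed stats
net_forward_all <- function(params, cfg, Xall, stats, chunk = 256L) {
  T_ <- dim(Xall)[1L]
  H <- NULL
  starts <- seq(1L, T_, by = chunk)
  A_fixed <- stats$A
  for (t0 in starts) {
    rows <- t0:min(t0 + chunk - 1L, T_)
    fw <- net_forward(params, cfg, Xall[rows, , , drop = FALSE],
                      A_fixed = A_fixed, stats = stats)
    H <- rbind(H, fw$H)
  }
  H
}

# --- exported graph operations -------------------------------------------

#' Message passing over a weighted adjacency
#'
#' Computes `M = A %*% X`, i.e. each node's message is the adjacency-weighted
#' sum of all node features, applied `steps` times.
#'
#' @param A [edge_weights()] or N x N numeric matrix.
#' @param X N x 2 node-feature matrix (or any N x p matrix).
#' @param steps number of applications (default 1).
#' @return matrix of the same shape as `X`.
#' @export
message_pass <- function(A, X, steps = 1L) {
  if (inherits(A, "edge_weights")) A <- A$matrix
  A <- as.matrix(A)
  X <- as.matrix(X)
  if (nrow(A) != ncol(A) || nrow(A) != nrow(X)) {
    stop("A must be N x N and X must be N x p with matching N")
  }
  for (s in seq_len(steps)) X <- A %*% X
  X
}

#' Infer edge weights from activity
#'
#' Runs the edge encoder of a GNN model: per-node embeddings through
#' `g_node`, pairwise ordered concatenation through `g_edge`, and a sigmoid,
#' producing weights in `(0, 1)`. In `"dynamic"` mode one timestep yields one
#' adjacency per timestep; in `"static"` mode node embeddings are averaged
#' across all timesteps of the recording, yielding a single adjacency for the
#' individual. No labels are used.
#'
#' @param object an `elegnn` model with `model = "gnn"`.
#' @param data a [trace_set()], or a `T x N x 2` feature array, or an `N x 2`
#'   matrix for a single timestep.
#' @return An [edge_weights()] in static mode; in dynamic mode an
#'   [edge_weights()] for a single timestep, or a `N x N x T` array when
#'   several timesteps are given.
#' @export
infer_edges <- function(object, data) {
  stopifnot(inherits(object, "elegnn"))
  cfg <- object$config
  if (cfg$model != "gnn") stop("edge inference requires a GNN model")
  if (cfg$edge_mode == "provided") {
    stop("edge_mode 'provided' bypasses the edge encoder")
  }
  nms <- NULL
  if (inherits(data, "trace_set")) {
    nms <- data$neuron_names
    data <- trace_features(normalize_trace_set(data))
  }
  if (length(dim(data)) == 2L) {
    data <- array(data, c(1L, nrow(data), ncol(data)))
  }
  if (is.null(nms)) nms <- dimnames(data)[[2]] %||% paste0("n", seq_len(dim(data)[2L]))
  stats <- list(gnode = NULL)
  if (cfg$batchnorm) {
    Z <- mlp_preact(object$params$gnode, stack_nodes(data))
    n <- nrow(Z)
    mu <- colMeans(Z)
    va <- if (n > 1L) pmax(colMeans(Z * Z) - mu * mu, 0) else rep(1, length(mu))
    stats$gnode <- list(mu = mu, va = va)
  }
  ec <- edges_fwd(object$params, cfg, data, stats = stats)
  if (cfg$edge_mode == "static") {
    edge_weights(ec$A, nms, mode = "static")
  } else if (dim(data)[1L] == 1L) {
    edge_weights(ec$A[, , 1L], nms, mode = "dynamic")
  } else {
    ec$A
  }
}

#' State probabilities and decision from classifier scores
#'
#' Applies a softmax to the embedded features and takes the most probable
#' state; ties break toward the lowest state code for reproducibility.
#'
#' @param H length-k numeric vector of scores, or a B x k matrix.
#' @return list with `prob` (same shape, rows summing to 1) and `state`
#'   (integer codes `0..k-1`).
#' @export
classify_states <- function(H) {
  vec <- is.null(dim(H))
  H <- rbind(H)
  if (ncol(H) < 2L) stop("classification requires k >= 2 states")
  p <- softmax_rows(H)
  state <- max.col(p, ties.method = "first") - 1L
  if (vec) list(prob = p[1L, ], state = state[1L]) else list(prob = p, state = state)
}

#' One Markovian prediction step
#'
#' Residual update `X_{t+1} = X_t + H` where `H` is the model's predicted
#' change of the trajectory.
#'
#' @param X current node features (N x 2 or B x N x 2).
#' @param H predicted change, same shape as `X`.
#' @return predicted node features at the next timestep.
#' @export
predict_step <- function(X, H) {
  if (!identical(dim(X), dim(H))) {
    stop("X and H must share the same shape")
  }
  X + H
}

#' Autoregressive rollout of a trajectory model
#'
#' Starting from one timestep as the initial condition, repeatedly applies
#' the Markovian predictor, feeding each prediction back as the next input.
#' Dynamic edges are re-inferred from each predicted step; static or provided
#' edges stay fixed for the whole rollout.
#'
#' @param object an `elegnn` model with `task = "predict"`.
#' @param X0 initial node features: N x 2 matrix, or nw x N x 2 array to roll
#'   several windows forward at once.
#' @param n_steps number of predicted timesteps.
#' @param A fixed adjacency ([edge_weights()] or matrix) for static/provided
#'   edge modes; if `NULL` in static mode it is inferred from `X0`.
#' @param stats optional per-individual normalization statistics from the
#'   evaluated recording (computed internally by [evaluate_trajectory()]).
#' @return `n_steps x N x 2` array (single start) or `nw x n_steps x N x 2`.
#' @export
rollout <- function(object, X0, n_steps, A = NULL, stats = NULL) {
  stopifnot(inherits(object, "elegnn"), n_steps >= 1L)
  cfg <- object$config
  if (cfg$task != "predict") stop("rollout requires a trajectory model")
  single <- length(dim(X0)) == 2L || is.null(dim(X0))
  if (single) X0 <- array(as.matrix(X0), c(1L, nrow(as.matrix(X0)), 2L))
  if (inherits(A, "edge_weights")) A <- A$matrix
  if (is.null(A) && !is.null(stats)) A <- stats$A
  if (is.null(A) && cfg$model == "gnn" && cfg$edge_mode != "dynamic") {
    if (cfg$edge_mode == "provided") stop("provided edge_mode requires A")
    ec <- edges_fwd(object$params, cfg, X0, stats = stats)
    A <- ec$A
  }
  nw <- dim(X0)[1L]
  N <- dim(X0)[2L]
  out <- array(0, c(nw, n_steps, N, 2L))
  cur <- X0
  for (s in seq_len(n_steps)) {
    fw <- net_forward(object$params, cfg, cur, A_fixed = A, stats = stats)
    # H rows are node-major concatenations; reshape back to nw x N x 2
    cur <- cur + unflat_nodes(fw$H, N)
    out[, s, , ] <- cur
  }
  if (single) array(out[1L, , , ], c(n_steps, N, 2L)) else out
}
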