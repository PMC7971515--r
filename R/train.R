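#' Scheduled-sampling teacher-forcing probability
#'
#' During rollout training, each fed-back input is the ground truth with this
#' probability and the model's own prediction otherwise. The schedule decays
#' linearly from 1.0 at the first epoch to 0.0 at the final epoch, so training
#' moves gradually from teacher forcing to free-running prediction,
#' minimizing the accumulation of error.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`.
#' @param total_epochs total number of training epochs.
#' @return probability in `[0, 1]`.
#' @export
sampling_schedule <- function(epoch, total_epochs) {
  epoch <- as.integer(epoch)
  total_epochs <- as.integer(total_epochs)
  if (epoch < 0L || epoch >= total_epochs) {
    stop("epoch must satisfy 0 <= epoch < total_epochs")
  }
  1 - epoch / max(total_epochs - 1L, 1L)
}

# --- minibatch assembly ---------------------------------------------------

# concatenate windows along the time axis -> B x N x 2 plus labels
bind_windows <- function(wins) {
  W <- dim(wins[[1L]]$features)[1L]
  N <- dim(wins[[1L]]$features)[2L]
  nw <- length(wins)
  X <- array(0, c(nw * W, N, 2L))
  has_lab <- !is.null(wins[[1L]]$labels)
  labs <- if (has_lab) integer(nw * W) else NULL
  for (i in seq_len(nw)) {
    rows <- ((i - 1L) * W + 1L):(i * W)
    X[rows, , ] <- wins[[i]]$features
    if (has_lab) labs[rows] <- wins[[i]]$labels
  }
  list(X = X, labels = labs, nw = nw, W = W)
}

# stack windows window-major -> nw x W x N x 2
stack_windows <- function(wins) {
  W <- dim(wins[[1L]]$features)[1L]
  N <- dim(wins[[1L]]$features)[2L]
  nw <- length(wins)
  X <- array(0, c(nw, W, N, 2L))
  for (i in seq_len(nw)) X[i, , , ] <- wins[[i]]$features
  X
}

# --- training cores -------------------------------------------------------

# worm_windows: named list (one element per individual) of window lists.
# Each epoch visits individuals one at a time and optimizes the loss on that
# individual's minibatches only, so feature-normalization statistics are
# always single-individual ("dataset enlargement").
train_classifier_core <- function(worm_windows, cfg, seed, adjacency = NULL) {
  set.seed(as.integer(seed))
  params <- init_params(cfg)
  opt <- adam_init(params)
  n_ind <- length(worm_windows)
  ids <- names(worm_windows) %||% paste0("worm", seq_len(n_ind))
  n_log <- cfg$epochs * n_ind
  log_epoch <- integer(n_log)
  log_ind <- character(n_log)
  log_loss <- numeric(n_log)
  r <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    order_w <- if (cfg$shuffle_individuals) sample.int(n_ind) else seq_len(n_ind)
    for (w in order_w) {
      wins <- worm_windows[[w]]
      ord <- sample.int(length(wins))
      groups <- split(ord, ceiling(seq_along(ord) / cfg$windows_per_update))
      losses <- numeric(length(groups))
      gi <- 0L
      for (g in groups) {
        mb <- bind_windows(wins[g])
        fw <- net_forward(params, cfg, mb$X, A_fixed = adjacency)
        p <- softmax_rows(fw$H)
        B <- nrow(p)
        idx <- cbind(seq_len(B), mb$labels + 1L)
        loss <- -mean(log(pmax(p[idx], 1e-12)))
        if (!is.finite(loss)) {
          stop("non-finite classification loss at epoch ", epoch,
               ", individual ", ids[w], ": optimization diverged")
        }
        dH <- p
        dH[idx] <- dH[idx] - 1
        bw <- net_backward(params, cfg, fw$cache, dH / B)
        st <- adam_step(params, bw$grads, opt, cfg$lr)
        params <- st$params
        opt <- st$state
        gi <- gi + 1L
        losses[gi] <- loss
      }
      r <- r + 1L
      log_epoch[r] <- epoch
      log_ind[r] <- ids[w]
      log_loss[r] <- mean(losses)
    }
  }
  list(params = params,
       log = data.frame(epoch = log_epoch, individual = log_ind,
                        loss = log_loss, sampling_prob = NA_real_))
}

# one optimization step of scheduled-sampling rollout training
rollout_train_step <- function(params, cfg, Xw, p_tf, adjacency = NULL) {
  nw <- dim(Xw)[1L]
  W <- dim(Xw)[2L]
  N <- dim(Xw)[3L]
  if (W < 2L) stop("prediction training requires windows of at least 2 timesteps")
  grads <- tree_zero(params)
  A <- NULL
  edge_cache <- NULL
  dA_tot <- NULL
  dynamic <- cfg$model == "gnn" && cfg$edge_mode == "dynamic"
  if (cfg$model == "gnn" && cfg$edge_mode == "provided") A <- adjacency
  if (cfg$model == "gnn" && cfg$edge_mode == "static") {
    # recording-mean node embeddings approximated by the minibatch mean
    Xall <- array(aperm(Xw, c(2L, 1L, 3L, 4L)), c(nw * W, N, 2L))
    edge_cache <- edges_fwd(params, cfg, Xall)
    A <- edge_cache$A
    dA_tot <- A * 0
  }
  cur <- array(Xw[, 1L, , ], c(nw, N, 2L))
  n_pred <- W - 1L
  denom <- nw * N * 2L * n_pred
  total_sq <- 0
  for (s in seq_len(n_pred)) {
    truth <- array(Xw[, s + 1L, , ], c(nw, N, 2L))
    fw <- net_forward(params, cfg, cur, A_fixed = if (dynamic) NULL else A)
    pred <- cur + unflat_nodes(fw$H, N)
    err <- pred - truth
    total_sq <- total_sq + sum(err * err)
    bw <- net_backward(params, cfg, fw$cache, flat_nodes(err) * (2 / denom))
    grads <- tree_add(grads, bw$grads)
    if (!is.null(dA_tot) && !is.null(bw$dA)) dA_tot <- dA_tot + bw$dA
    if (s < n_pred) {
      # scheduled-sampling coin per window per step; gradients are not
      # propagated through fed-back predictions
      use_truth <- stats::runif(nw) < p_tf
      cur <- pred
      if (any(use_truth)) cur[use_truth, , ] <- truth[use_truth, , ]
    }
  }
  if (!is.null(edge_cache)) {
    grads <- edge_grads_from_dA(params, edge_cache, dA_tot, grads)
  }
  list(grads = grads, loss = total_sq / denom)
}

train_predictor_core <- function(worm_windows, cfg, seed, adjacency = NULL) {
  set.seed(as.integer(seed))
  params <- init_params(cfg)
  opt <- adam_init(params)
  n_ind <- length(worm_windows)
  ids <- names(worm_windows) %||% paste0("worm", seq_len(n_ind))
  n_log <- cfg$epochs * n_ind
  log_epoch <- integer(n_log)
  log_ind <- character(n_log)
  log_loss <- numeric(n_log)
  log_p <- numeric(n_log)
  r <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    p_tf <- sampling_schedule(epoch - 1L, cfg$epochs)
    order_w <- if (cfg$shuffle_individuals) sample.int(n_ind) else seq_len(n_ind)
    for (w in order_w) {
      wins <- worm_windows[[w]]
      ord <- sample.int(length(wins))
      groups <- split(ord, ceiling(seq_along(ord) / cfg$windows_per_update))
      losses <- numeric(length(groups))
      gi <- 0L
      for (g in groups) {
        Xw <- stack_windows(wins[g])
        step <- rollout_train_step(params, cfg, Xw, p_tf, adjacency)
        if (!is.finite(step$loss)) {
          stop("non-finite trajectory loss at epoch ", epoch,
               ", individual ", ids[w], ": optimization diverged")
        }
        st <- adam_step(params, step$grads, opt, cfg$lr)
        params <- st$params
        opt <- st$state
        gi <- gi + 1L
        losses[gi] <- step$loss
      }
      r <- r + 1L
      log_epoch[r] <- epoch
      log_ind[r] <- ids[w]
      log_loss[r] <- mean(losses)
      log_p[r] <- p_tf
    }
  }
  list(params = params,
       log = data.frame(epoch = log_epoch, individual = log_ind,
                        loss = log_loss, sampling_prob = log_p))
}

# --- user-facing fit ------------------------------------------------------

#' Fit a behavioral-state classifier or trajectory predictor
#'
#' Trains an edge-inferring graph neural network (or the structure-agnostic
#' MLP baseline) on one or more individuals' recordings. Recordings are
#' normalized per neuron to the unit interval over the full recording, cut
#' into fixed-length windows, and optimized with Adam. With several
#' individuals, each epoch iterates over them one at a time and optimizes the
#' loss on that individual's minibatches only, so feature-normalization
#' statistics stay per-individual (dataset enlargement). Classification
#' minimizes cross-entropy on per-timestep softmax probabilities; trajectory
#' prediction minimizes the mean squared error of multi-step rollouts inside
#' each window, trained with scheduled sampling.
#'
#' @param data a [trace_set()] or list of them (all sharing the same neuron
#'   names in the same order; classification requires labels).
#' @param task `"classify"` or `"predict"`.
#' @param model `"gnn"` or `"mlp"`.
#' @param adjacency optional [edge_weights()] (or matrix) of provided edges,
#'   e.g. connectome-derived; implies `edge_mode = "provided"`.
#' @param config an [elegnn_config()]; if `NULL`, one is built from `...`.
#' @param seed integer seed covering initialization, shuffling and
#'   scheduled-sampling coins; identical seeds give identical fits.
#' @param ... passed to [elegnn_config()] when `config` is `NULL`
#'   (e.g. `epochs`, `hidden`, `edge_mode`, `aggregation`).
#' @return An object of class `elegnn` with components `params` (weights),
#'   `config`, `log` (per epoch x individual losses and sampling
#'   probabilities), `vocabulary`, `neuron_names`, and the training data.
#' @examples
#' pop <- generate_population(synth_config(n_individuals = 2, n_neurons = 5,
#'                                         timesteps = 240), master_seed = 1)
#' fit <- elegnn(pop, task = "classify", model = "mlp", epochs = 3)
#' print(fit)
#' @export
elegnn <- function(data, task = c("classify", "predict"),
                   model = c("gnn", "mlp"), adjacency = NULL,
                   config = NULL, seed = 1L, ...) {
  task <- match.arg(task)
  model <- match.arg(model)
  if (inherits(data, "trace_set")) data <- list(data)
  if (!length(data) || !all(vapply(data, inherits, logical(1L), "trace_set"))) {
    stop("data must be a trace_set or a list of trace_sets")
  }
  nms <- data[[1L]]$neuron_names
  for (ts in data) {
    if (!identical(ts$neuron_names, nms)) {
      stop("all individuals must share the same neuron names in the same order")
    }
  }
  vocab <- data[[1L]]$vocabulary
  if (task == "classify") {
    for (ts in data) {
      if (is.null(ts$labels)) stop("classification requires labels on every individual")
    }
    n_states <- if (!is.null(vocab)) length(vocab)
                else max(unlist(lapply(data, `[[`, "labels"))) + 1L
  } else {
    n_states <- NULL
  }
  if (is.null(config)) {
    cargs <- list(model = model, task = task, n_neurons = length(nms),
                  n_states = n_states, ...)
    if (is.null(cargs$edge_mode) && !is.null(adjacency)) {
      cargs$edge_mode <- "provided"
    }
    config <- do.call(elegnn_config, cargs)
  }
  stopifnot(inherits(config, "elegnn_config"))
  if (config$n_neurons != length(nms)) {
    stop("config n_neurons does not match the data")
  }
  A <- NULL
  if (!is.null(adjacency)) {
    if (inherits(adjacency, "edge_weights")) {
      if (!identical(adjacency$neuron_names, nms)) {
        stop("adjacency neuron order does not match the data")
      }
      A <- adjacency$matrix
    } else {
      A <- as.matrix(adjacency)
    }
    if (config$model == "gnn" && config$edge_mode != "provided") {
      stop("an adjacency was supplied but edge_mode is not 'provided'")
    }
  } else if (config$model == "gnn" && config$edge_mode == "provided") {
    stop("edge_mode 'provided' requires an adjacency")
  }
  data <- lapply(data, normalize_trace_set)
  worm_windows <- lapply(data, make_windows, W = config$window)
  names(worm_windows) <- vapply(data, `[[`, character(1L), "individual_id")
  fitfun <- if (task == "classify") train_classifier_core else train_predictor_core
  fit <- fitfun(worm_windows, config, seed = seed, adjacency = A)
  structure(list(
    params = fit$params, config = config, log = fit$log, trained = TRUE,
    neuron_names = nms, vocabulary = vocab, adjacency = A,
    data = data, seed = as.integer(seed)
  ), class = "elegnn")
}

# --- S3 methods -----------------------------------------------------------

#' @export
print.elegnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("elegnn %s model, task '%s' (%s)\n",
              toupper(cfg$model), cfg$task,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  N = %d neurons; edge mode '%s'; aggregation '%s'; %d message step(s)\n",
              cfg$n_neurons, cfg$edge_mode, cfg$aggregation, cfg$message_steps))
  if (cfg$task == "classify") cat(sprintf("  k = %d states\n", cfg$n_states))
  if (!is.null(x$log)) {
    last <- x$log[x$log$epoch == max(x$log$epoch), ]
    cat(sprintf("  %d epochs on %d individual(s); final loss %.4g\n",
                max(x$log$epoch), length(unique(x$log$individual)),
                mean(last$loss)))
  }
  invisible(x)
}

#' @export
summary.elegnn <- function(object, ...) {
  out <- list(config = object$config, trained = object$trained)
  if (!is.null(object$log)) {
    out$loss_by_epoch <- stats::aggregate(loss ~ epoch, object$log, mean)
    out$final_loss <- stats::aggregate(
      loss ~ individual, object$log[object$log$epoch == max(object$log$epoch), ],
      mean)
  }
  class(out) <- "summary.elegnn"
  out
}

#' @export
print.summary.elegnn <- function(x, ...) {
  print.elegnn(structure(list(config = x$config, trained = x$trained,
                              log = NULL), class = "elegnn"))
  if (!is.null(x$final_loss)) {
    cat("final per-individual training loss:\n")
    print(x$final_loss, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.elegnn <- function(object, ...) object$params

#' @export
plot.elegnn <- function(x, ...) {
  if (is.null(x$log)) stop("no training log to plot")
  agg <- stats::aggregate(loss ~ epoch, x$log, mean)
  graphics::plot(agg$epoch, agg$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "elegnn training", ...)
  invisible(x)
}

#' Predict from a fitted model
#'
#' For classifiers, runs the model separately on each timestep of a recording
#' and returns per-timestep state codes (`type = "state"`) or softmax
#' probabilities (`type = "prob"`). For trajectory models, returns one-step
#' predictions for every timestep (`type = "step"`). Per-individual
#' normalization statistics (and, in static edge mode, the adjacency) are
#' computed from the supplied recording itself, without using its labels.
#'
#' @param object a fitted `elegnn`.
#' @param newdata a [trace_set()]; defaults to the first training individual.
#' @param type `"state"`, `"prob"`, or `"step"`.
#' @param ... unused.
#' @export
predict.elegnn <- function(object, newdata = NULL,
                           type = c("state", "prob", "step"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  if (is.null(newdata)) newdata <- object$data[[1L]]
  stopifnot(inherits(newdata, "trace_set"))
  if (!identical(newdata$neuron_names, object$neuron_names)) {
    stop("newdata neuron set/order differs from the model's")
  }
  X <- trace_features(normalize_trace_set(newdata))
  stats <- collect_stats(object$params, cfg, X, A_fixed = object$adjacency)
  H <- net_forward_all(object$params, cfg, X, stats)
  if (cfg$task == "classify") {
    if (type == "step") stop("type 'step' applies to trajectory models")
    cl <- classify_states(H)
    if (type == "prob") cl$prob else cl$state
  } else {
    if (type != "step") stop("classification types apply to classifier models")
    N <- cfg$n_neurons
    pred <- X + unflat_nodes(H, N)
    # prediction for timestep t+1 made from timestep t
    pred[-dim(X)[1L], , , drop = FALSE]
  }
}

#' @export
residuals.elegnn <- function(object, newdata = NULL, ...) {
  cfg <- object$config
  if (is.null(newdata)) newdata <- object$data[[1L]]
  if (cfg$task == "classify") {
    p <- predict(object, newdata, type = "prob")
    y <- newdata$labels
    if (is.null(y)) stop("residuals for a classifier require labels")
    onehot <- matrix(0, nrow(p), ncol(p))
    onehot[cbind(seq_len(nrow(p)), y + 1L)] <- 1
    onehot - p
  } else {
    pred <- predict(object, newdata, type = "step")
    X <- trace_features(normalize_trace_set(newdata))
    X[-1L, , , drop = FALSE] - pred
  }
}

#' Simulate trajectories from a fitted trajectory model
#'
#' Rolls the Markovian predictor forward from the first timestep of a
#' recording (see [rollout()]), using the recording's own normalization
#' statistics and, for static edges, its inferred adjacency.
#'
#' @param object a fitted `elegnn` with `task = "predict"`.
#' @param nsim number of independent rollouts (the model is deterministic, so
#'   these are identical; kept for the `simulate()` contract).
#' @param seed unused (deterministic model); kept for the generic.
#' @param newdata a [trace_set()]; defaults to the first training individual.
#' @param n_steps number of predicted timesteps (default 16).
#' @param ... unused.
#' @return an `n_steps x N x 2` array, or a list of `nsim` such arrays.
#' @export
simulate.elegnn <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            n_steps = 16L, ...) {
  cfg <- object$config
  if (cfg$task != "predict") stop("simulate() requires a trajectory model")
  if (is.null(newdata)) newdata <- object$data[[1L]]
  X <- trace_features(normalize_trace_set(newdata))
  stats <- collect_stats(object$params, cfg, X, A_fixed = object$adjacency)
  X0 <- array(X[1L, , ], c(dim(X)[2L], 2L))
  out <- rollout(object, X0, n_steps, A = stats$A, stats = stats)
  if (nsim == 1L) out else replicate(nsim, out, simplify = FALSE)
}
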