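#' Evaluation reports
#'
#' Bundles the measurements the protocols produce: overall accuracy,
#' per-fold or per-individual accuracies, a confusion matrix in row
#' percentages (rows are labeled states, columns predicted states; each row
#' with at least one true instance sums to 100), and/or a per-horizon MSE
#' vector.
#'
#' @param accuracy overall accuracy (fraction), or `NULL`.
#' @param per_fold numeric vector of per-fold (or per-individual) accuracies.
#' @param confusion k x k row-percentage matrix.
#' @param per_step_mse numeric vector of per-prediction-step MSE.
#' @param meta list of metadata (individuals, seeds, folds).
#' @return object of class `elegnn_eval`.
#' @export
eval_report <- function(accuracy = NULL, per_fold = NULL, confusion = NULL,
                        per_step_mse = NULL, meta = list()) {
  if (!is.null(per_step_mse) && any(per_step_mse < -1e-12)) {
    stop("per-step MSE must be nonnegative")
  }
  structure(list(accuracy = accuracy, per_fold = per_fold,
                 confusion = confusion, per_step_mse = per_step_mse,
                 meta = meta),
            class = "elegnn_eval")
}

#' @export
print.elegnn_eval <- function(x, ...) {
  cat("elegnn evaluation report\n")
  if (!is.null(x$accuracy)) {
    cat(sprintf("  accuracy: %.1f%%", 100 * x$accuracy))
    if (!is.null(x$per_fold) && length(x$per_fold) > 1L) {
      cat(sprintf(" (sd over %d folds/individuals: %.1f%%)",
                  length(x$per_fold), 100 * stats::sd(x$per_fold)))
    }
    cat("\n")
  }
  if (!is.null(x$confusion)) {
    cat("  confusion (row % of labeled states):\n")
    print(round(x$confusion, 1))
  }
  if (!is.null(x$per_step_mse)) {
    cat(sprintf("  per-step MSE over %d steps: %.4g (step 1) -> %.4g (step %d)\n",
                length(x$per_step_mse), x$per_step_mse[1L],
                x$per_step_mse[length(x$per_step_mse)],
                length(x$per_step_mse)))
  }
  invisible(x)
}

#' @export
plot.elegnn_eval <- function(x, ...) {
  if (!is.null(x$per_step_mse)) {
    graphics::plot(seq_along(x$per_step_mse), x$per_step_mse, type = "b",
                   xlab = "prediction step", ylab = "MSE",
                   main = "Trajectory prediction error", ...)
    if (!is.null(x$meta$persistence_mse)) {
      graphics::lines(seq_along(x$meta$persistence_mse),
                      x$meta$persistence_mse, lty = 2)
      graphics::legend("topleft", legend = c("model", "persistence"),
                       lty = c(1, 2), bty = "n")
    }
  } else if (!is.null(x$confusion)) {
    k <- nrow(x$confusion)
    graphics::image(seq_len(k), seq_len(k), t(x$confusion[k:1, , drop = FALSE]),
                    xlab = "predicted state", ylab = "labeled state",
                    axes = FALSE, main = "Confusion (row %)", ...)
    graphics::axis(1, at = seq_len(k), labels = colnames(x$confusion))
    graphics::axis(2, at = seq_len(k), labels = rev(rownames(x$confusion)),
                   las = 2)
  } else {
    stop("nothing to plot in this report")
  }
  invisible(x)
}

# row-percentage confusion matrix; rows = labeled, cols = predicted
confusion_percent <- function(truth, pred, k, state_names = NULL) {
  M <- matrix(0, k, k)
  tab <- table(factor(truth, levels = 0:(k - 1L)),
               factor(pred, levels = 0:(k - 1L)))
  M[] <- as.numeric(tab)
  rs <- rowSums(M)
  M[rs > 0, ] <- 100 * M[rs > 0, , drop = FALSE] / rs[rs > 0]
  if (is.null(state_names)) state_names <- as.character(0:(k - 1L))
  dimnames(M) <- list(labeled = state_names, predicted = state_names)
  M
}

#' 10-fold cross-validation on a seen individual
#'
#' The seen-population protocol: the recording is cut into 8-timestep
#' windows, the windows are shuffled and dealt into `kfold` folds, and for
#' each fold a fresh model is trained on the other folds and scored
#' per-timestep on the held-out fold. Normalization statistics and (in static
#' edge mode) the adjacency come from the training windows.
#'
#' @param ts a labeled [trace_set()].
#' @param model `"gnn"` or `"mlp"`.
#' @param kfold number of folds (default 10).
#' @param seed seed covering fold shuffling and every per-fold fit.
#' @param config optional [elegnn_config()]; built from `...` otherwise.
#' @param adjacency optional provided [edge_weights()].
#' @param ... passed to [elegnn_config()].
#' @return [eval_report()] with mean accuracy, the `kfold` per-fold
#'   accuracies, and a pooled confusion matrix.
#' @export
crossval_states <- function(ts, model = c("gnn", "mlp"), kfold = 10L,
                            seed = 1L, config = NULL, adjacency = NULL, ...) {
  model <- match.arg(model)
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(ts$labels)) stop("cross-validation requires labels")
  k <- if (!is.null(ts$vocabulary)) length(ts$vocabulary)
       else max(ts$labels) + 1L
  if (is.null(config)) {
    cargs <- list(model = model, task = "classify",
                  n_neurons = n_neurons(ts), n_states = k, ...)
    if (is.null(cargs$edge_mode) && !is.null(adjacency)) {
      cargs$edge_mode <- "provided"
    }
    config <- do.call(elegnn_config, cargs)
  }
  A <- if (inherits(adjacency, "edge_weights")) adjacency$matrix else adjacency
  ts <- normalize_trace_set(ts)
  wins <- make_windows(ts, config$window)
  folds <- make_folds(wins, kfold = kfold, seed = seed)
  acc <- numeric(folds$kfold)
  truth_all <- integer(0)
  pred_all <- integer(0)
  for (f in seq_len(folds$kfold)) {
    train_w <- wins[folds$fold != f]
    test_w <- wins[folds$fold == f]
    fit <- train_classifier_core(
      stats::setNames(list(train_w), ts$individual_id), config,
      seed = seed + f, adjacency = A)
    Xtr <- bind_windows(train_w)$X
    st <- collect_stats(fit$params, config, Xtr, A_fixed = A)
    mb <- bind_windows(test_w)
    H <- net_forward_all(fit$params, config, mb$X, st)
    pred <- classify_states(H)$state
    acc[f] <- mean(pred == mb$labels)
    truth_all <- c(truth_all, mb$labels)
    pred_all <- c(pred_all, pred)
  }
  eval_report(
    accuracy = mean(acc), per_fold = acc,
    confusion = confusion_percent(truth_all, pred_all, k,
                                  names(ts$vocabulary)),
    meta = list(kfold = folds$kfold, seed = seed,
                individual = ts$individual_id, model = config$model)
  )
}

#' Per-timestep classification of an unseen individual
#'
#' Runs the classifier separately on each timestep of a recording the model
#' never saw in training. Normalization statistics and, for static edges, the
#' adjacency are inferred from the unseen recording itself without its
#' labels. When the model's vocabulary differs from the recording's (e.g. a
#' 7-state model scored against 4-state labels), supply `state_map` to
#' collapse the predictions.
#'
#' @param object a fitted `elegnn` classifier.
#' @param ts a labeled [trace_set()].
#' @param state_map optional mapping passed to [map_states()] applied to the
#'   model's predicted states; use [default_state_map()] for the standard
#'   7-to-4 collapse.
#' @return [eval_report()] with accuracy and confusion matrix; exactly one
#'   prediction per timestep.
#' @export
evaluate_states <- function(object, ts, state_map = NULL) {
  stopifnot(inherits(object, "elegnn"), inherits(ts, "trace_set"))
  if (is.null(ts$labels)) stop("evaluation requires labels for scoring")
  pred <- predict(object, ts, type = "state")
  if (!is.null(state_map)) {
    pred <- map_states(pred, state_map,
                       from = object$vocabulary %||% default_vocabulary("kato7"),
                       to = ts$vocabulary %||% default_vocabulary("nichols4"))
  }
  k <- if (!is.null(ts$vocabulary)) length(ts$vocabulary)
       else max(ts$labels, pred) + 1L
  if (any(pred >= k)) {
    stop("predicted states fall outside the recording's vocabulary; ",
         "supply a state_map collapsing the model's states")
  }
  eval_report(
    accuracy = mean(pred == ts$labels),
    confusion = confusion_percent(ts$labels, pred, k, names(ts$vocabulary)),
    meta = list(individual = ts$individual_id, n_timesteps = length(pred))
  )
}

#' Unseen-population accuracy
#'
#' Scores a classifier on each unseen individual separately and averages the
#' per-individual accuracies with equal weight per individual, regardless of
#' recording length.
#'
#' @param object a fitted `elegnn` classifier.
#' @param population list of labeled [trace_set()]s.
#' @param state_map optional mapping as in [evaluate_states()].
#' @return [eval_report()]; `per_fold` holds the per-individual accuracies.
#' @export
evaluate_population <- function(object, population, state_map = NULL) {
  reports <- lapply(population, evaluate_states, object = object,
                    state_map = state_map)
  acc <- vapply(reports, `[[`, numeric(1L), "accuracy")
  eval_report(
    accuracy = mean(acc), per_fold = acc,
    meta = list(individuals = vapply(population, `[[`, character(1L),
                                     "individual_id"))
  )
}

# evaluation windows: starts t0 = 1, 1+h, ... with t0 + h <= T
eval_starts <- function(T_, horizon) {
  starts <- seq(1L, T_, by = horizon)
  starts[starts + horizon <= T_]
}

#' Per-step trajectory MSE on a recording
#'
#' Splits the recording into evaluation windows, gives the model the first
#' timestep of each window as the initial condition, rolls it forward
#' `horizon` timesteps, and reports the mean squared error of each prediction
#' step relative to the true trajectory, averaged over windows, neurons and
#' feature channels.
#'
#' @param object a fitted `elegnn` with `task = "predict"`.
#' @param ts a [trace_set()] (labels not needed).
#' @param horizon number of predicted timesteps per window (default 16, the
#'   unseen-population protocol).
#' @return [eval_report()] with `per_step_mse` of length `horizon`; the
#'   persistence baseline over the same windows is included in `meta`.
#' @export
evaluate_trajectory <- function(object, ts, horizon = 16L) {
  stopifnot(inherits(object, "elegnn"), inherits(ts, "trace_set"))
  cfg <- object$config
  if (cfg$task != "predict") stop("evaluate_trajectory requires a trajectory model")
  horizon <- as.integer(horizon)
  ts <- normalize_trace_set(ts)
  T_ <- n_timesteps(ts)
  if (horizon >= T_) stop("horizon must be smaller than the recording length")
  X <- trace_features(ts)
  stats <- collect_stats(object$params, cfg, X, A_fixed = object$adjacency)
  starts <- eval_starts(T_, horizon)
  nw <- length(starts)
  N <- n_neurons(ts)
  X0 <- array(X[starts, , ], c(nw, N, 2L))
  pred <- rollout(object, X0, horizon, A = stats$A, stats = stats)
  mse <- numeric(horizon)
  for (s in seq_len(horizon)) {
    truth <- array(X[starts + s, , ], c(nw, N, 2L))
    ps <- array(pred[, s, , ], c(nw, N, 2L))
    mse[s] <- mean((ps - truth)^2)
  }
  eval_report(
    per_step_mse = mse,
    meta = list(individual = ts$individual_id, n_windows = nw,
                horizon = horizon,
                persistence_mse = persistence_baseline_mse(ts, horizon)$per_step_mse)
  )
}

#' Persistence baseline for trajectory prediction
#'
#' The no-dynamics reference: predicts `X_{t+s} = X_t` for every step of
#' every evaluation window. A learned one-step model should beat this
#' baseline at step 1.
#'
#' @inheritParams evaluate_trajectory
#' @return [eval_report()] with `per_step_mse` of length `horizon`.
#' @export
persistence_baseline_mse <- function(ts, horizon = 16L) {
  stopifnot(inherits(ts, "trace_set"))
  horizon <- as.integer(horizon)
  ts <- normalize_trace_set(ts)
  T_ <- n_timesteps(ts)
  if (horizon >= T_) stop("horizon must be smaller than the recording length")
  X <- trace_features(ts)
  starts <- eval_starts(T_, horizon)
  N <- n_neurons(ts)
  base <- array(X[starts, , ], c(length(starts), N, 2L))
  mse <- numeric(horizon)
  for (s in seq_len(horizon)) {
    truth <- array(X[starts + s, , ], c(length(starts), N, 2L))
    mse[s] <- mean((base - truth)^2)
  }
  eval_report(per_step_mse = mse,
              meta = list(individual = ts$individual_id, horizon = horizon,
                          n_windows = length(starts)))
}

#' Directed-edge recovery score
#'
#' Given an inferred adjacency and a ground-truth coupling matrix, ranks the
#' off-diagonal inferred weights and reports the area under the ROC curve for
#' separating true directed edges (nonzero couplings) from absent ones.
#'
#' @param A inferred [edge_weights()] or N x N matrix.
#' @param W_true ground-truth coupling matrix (nonzero entries are edges).
#' @return AUROC in `[0, 1]` (0.5 is chance).
#' @export
edge_recovery_auroc <- function(A, W_true) {
  if (inherits(A, "edge_weights")) A <- A$matrix
  A <- as.matrix(A)
  W_true <- as.matrix(W_true)
  stopifnot(identical(dim(A), dim(W_true)))
  off <- !diag(nrow(A))
  rank_auroc(A[off], W_true[off] != 0)
}
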