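#' Temporal derivative of trace columns
#'
#' Finite-difference derivative of each neuron's trace: central differences at
#' interior timesteps, one-sided differences at both ends, divided by the
#' sampling interval.
#'
#' @param traces numeric T x N matrix (T >= 2).
#' @param dt sampling interval in seconds.
#' @return T x N matrix of derivatives (units of trace per second).
#' @export
compute_derivative <- function(traces, dt = 1 / 3) {
  traces <- as.matrix(traces)
  T_ <- nrow(traces)
  if (T_ < 2L) stop("need at least 2 timesteps to differentiate")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  d <- traces
  d[1L, ] <- traces[2L, ] - traces[1L, ]
  d[T_, ] <- traces[T_, ] - traces[T_ - 1L, ]
  if (T_ > 2L) {
    d[2:(T_ - 1L), ] <- (traces[3:T_, , drop = FALSE] -
                           traces[1:(T_ - 2L), , drop = FALSE]) / 2
  }
  d / dt
}

#' Per-neuron unit-interval normalization
#'
#' Maps each column to `[0, 1]` by `(x - min) / (max - min)` computed over the
#' entire recording (never per window): the relative magnitude of a trace
#' carries graded behavioral information (e.g. crawling speed), so
#' within-window normalization would destroy it. Constant columns map to all
#' zeros.
#'
#' @param x numeric T x N matrix with no missing values.
#' @return matrix of the same shape with entries in `[0, 1]`.
#' @export
normalize_unit_interval <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not allowed")
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1   # constant columns -> zeros
  sweep(sweep(x, 2L, lo, "-"), 2L, rng, "/")
}

#' Normalize both feature channels of a recording
#'
#' Applies [normalize_unit_interval()] to the traces and derivatives of a
#' [trace_set()] independently, over the full recording.
#'
#' @param ts a [trace_set()].
#' @return the normalized [trace_set()].
#' @export
normalize_trace_set <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  ts$traces <- normalize_unit_interval(ts$traces)
  ts$derivatives <- normalize_unit_interval(ts$derivatives)
  ts
}

#' Split a recording into fixed-length windows
#'
#' Cuts the recording into `floor(T / W)` non-overlapping windows of `W`
#' consecutive timesteps; a trailing remainder shorter than `W` is dropped
#' (windows must be fully observed for rollout training). The defaults in the
#' training and evaluation protocols are `W = 8` (training; about 3 s, the
#' time a worm needs to execute a behavioral change) and `W = 16`
#' (trajectory evaluation).
#'
#' @param ts a [trace_set()].
#' @param W window length in timesteps.
#' @return A list of windows; each has `features` (a `W x N x 2` array with
#'   channel 1 the trace and channel 2 the derivative), `labels` (length-W
#'   integer vector or `NULL`), `individual_id`, and `start` (1-based index of
#'   the window's first timestep).
#' @export
make_windows <- function(ts, W) {
  stopifnot(inherits(ts, "trace_set"))
  W <- as.integer(W)
  T_ <- n_timesteps(ts)
  if (W < 1L) stop("W must be at least 1")
  if (W > T_) stop("window length W = ", W, " exceeds recording length T = ", T_)
  n_win <- T_ %/% W
  X <- trace_features(ts)
  lapply(seq_len(n_win), function(w) {
    rows <- ((w - 1L) * W + 1L):(w * W)
    list(
      features = X[rows, , , drop = FALSE],
      labels = if (!is.null(ts$labels)) ts$labels[rows] else NULL,
      individual_id = ts$individual_id,
      start = rows[1L]
    )
  })
}

#' Per-timestep node features
#'
#' @param ts a [trace_set()].
#' @return A `T x N x 2` array: channel 1 the trace, channel 2 the derivative.
#' @export
trace_features <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  X <- array(0, dim = c(n_timesteps(ts), n_neurons(ts), 2L),
             dimnames = list(NULL, ts$neuron_names, c("trace", "derivative")))
  X[, , 1L] <- ts$traces
  X[, , 2L] <- ts$derivatives
  X
}

#' Shuffled k-fold assignment of windows
#'
#' Shuffles windows with a seeded permutation, then deals them into `kfold`
#' folds whose sizes differ by at most one. The folds are disjoint and cover
#' every window; the assignment is deterministic given the seed.
#'
#' @param batches list of windows from [make_windows()] (any list works; only
#'   its length is used).
#' @param kfold number of folds (default 10, the cross-validation protocol).
#' @param seed integer seed for the shuffle.
#' @return An object of class `fold_split`: list with `fold` (integer vector,
#'   fold id 1..kfold per window), `kfold`, `seed`.
#' @export
make_folds <- function(batches, kfold = 10L, seed = 1L) {
  n <- length(batches)
  kfold <- as.integer(kfold)
  if (kfold < 1L) stop("kfold must be at least 1")
  if (kfold > n) stop("kfold = ", kfold, " exceeds the number of windows (", n, ")")
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(kfold), n)  # deal shuffled windows round-robin
  structure(list(fold = fold, kfold = kfold, seed = as.integer(seed)),
            class = "fold_split")
}

#' @rdname make_folds
#' @param x a `fold_split`.
#' @param path CSV path; written with columns `batch_index`, `fold`.
#' @export
write_folds <- function(x, path) {
  stopifnot(inherits(x, "fold_split"))
  utils::write.csv(data.frame(batch_index = seq_along(x$fold),
                              fold = x$fold),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("fold_split: %d windows in %d folds (seed %d)\n",
              length(x$fold), x$kfold, x$seed))
  print(table(fold = x$fold))
  invisible(x)
}

#' Map state labels between vocabularies
#'
#' Relabels a state sequence through a name-to-name mapping, e.g. collapsing
#' the 7-state vocabulary of the freely-moving study onto the 4-state
#' vocabulary of the second study so that models trained on one can be scored
#' on the other.
#'
#' @param labels integer codes (with `from` vocabulary) or character names.
#' @param mapping named character vector or list: `source state -> target
#'   state`. Defaults to [default_state_map()].
#' @param from,to [state_vocabulary()] objects for the source and target
#'   codings; defaults are the 7-state and 4-state vocabularies.
#' @return integer vector of target codes, same length as `labels`.
#' @export
map_states <- function(labels, mapping = default_state_map(),
                       from = default_vocabulary("kato7"),
                       to = default_vocabulary("nichols4")) {
  mapping <- unlist(mapping)
  if (is.numeric(labels)) {
    labels <- names(from)[as.integer(labels) + 1L]
    if (anyNA(labels)) stop("label codes outside the source vocabulary")
  }
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), names(mapping))
  if (length(unknown)) {
    stop("no mapping entry for state(s): ", paste(unknown, collapse = ", "))
  }
  target <- unname(mapping[labels])
  bad <- setdiff(unique(target), names(to))
  if (length(bad)) {
    stop("mapped state(s) absent from target vocabulary: ",
         paste(bad, collapse = ", "))
  }
  unname(to[target])
}

#' Default 7-state to 4-state mapping
#'
#' Collapses forward crawling and forward slowing onto forward crawling, the
#' three reversal states onto reverse crawling, and keeps the two turn states.
#' Users can override any cell by passing their own mapping to
#' [map_states()].
#'
#' @return named character vector (source state -> target state).
#' @export
default_state_map <- function() {
  c(
    "Forward Crawling" = "forward crawling",
    "Forward Slowing" = "forward crawling",
    "Reverse 1" = "reverse crawling",
    "Reverse 2" = "reverse crawling",
    "Sustained Reverse Crawling" = "reverse crawling",
    "Dorsal Turn" = "dorsal turn",
    "Ventral Turn" = "ventral turn"
  )
}
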