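#' Edge weights between neurons
#'
#' An `edge_weights` object wraps an N x N weighted adjacency matrix with all
#' entries in `[0, 1]`, aligned to a fixed neuron order. Entry `(i, j)` is the
#' weight of the directed edge between nodes i and j; `i == j` is a self edge.
#' Matrices may come from the model's edge encoder (`mode` `"dynamic"` or
#' `"static"`) or from a user-supplied source such as the physical connectome
#' (`mode` `"provided"`).
#'
#' @param matrix numeric N x N matrix with entries in `[0, 1]`.
#' @param neuron_names character vector of length N.
#' @param mode one of `"dynamic"`, `"static"`, `"provided"`.
#' @return An object of class `edge_weights`.
#' @export
edge_weights <- function(matrix, neuron_names,
                         mode = c("provided", "dynamic", "static")) {
  mode <- match.arg(mode)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- length(neuron_names)
  if (nrow(matrix) != n || ncol(matrix) != n) {
    stop("adjacency must be square and match the neuron set (N = ", n, ")")
  }
  if (anyNA(matrix)) stop("adjacency contains missing values")
  if (any(matrix < 0 | matrix > 1)) {
    stop("edge weights must lie in [0, 1]; enable max-normalization for raw counts")
  }
  dimnames(matrix) <- list(neuron_names, neuron_names)
  structure(list(matrix = matrix, neuron_names = as.character(neuron_names),
                 mode = mode),
            class = "edge_weights")
}

#' @export
print.edge_weights <- function(x, ...) {
  cat(sprintf("edge_weights (%s): %d x %d, range [%.3f, %.3f]\n",
              x$mode, nrow(x$matrix), ncol(x$matrix),
              min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Load a provided adjacency (e.g. connectome-derived edges)
#'
#' Reads either a square CSV matrix with neuron names as header row and first
#' column, or a 3-column edge list (`source,target,weight`). The result is
#' aligned to `neuron_names` order. Raw synapse counts can be mapped into
#' `[0, 1]` by dividing by the maximum entry (`normalize = TRUE`). The matrix
#' may be directed; no symmetrization is applied.
#'
#' @param path file path.
#' @param neuron_names character vector fixing node order.
#' @param normalize divide by the maximum entry before validation.
#' @return An [edge_weights()] with `mode = "provided"`.
#' @export
load_adjacency <- function(path, neuron_names, normalize = FALSE) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  neuron_names <- as.character(neuron_names)
  n <- length(neuron_names)
  if (identical(tolower(names(df)[1:3]), c("source", "target", "weight")) &&
      ncol(df) == 3L) {
    src <- as.character(df[[1L]])
    dst <- as.character(df[[2L]])
    unknown <- setdiff(unique(c(src, dst)), neuron_names)
    if (length(unknown)) {
      stop("edge-list endpoints not in neuron set: ",
           paste(unknown, collapse = ", "))
    }
    A <- matrix(0, n, n)
    A[cbind(match(src, neuron_names), match(dst, neuron_names))] <- df[[3L]]
  } else {
    rn <- as.character(df[[1L]])
    A <- as.matrix(df[, -1L, drop = FALSE])
    if (!setequal(colnames(A), neuron_names) || !setequal(rn, neuron_names)) {
      stop("adjacency header/rows do not match the neuron set")
    }
    A <- A[match(neuron_names, rn), match(neuron_names, colnames(A)),
           drop = FALSE]
  }
  storage.mode(A) <- "double"
  if (any(A < 0)) stop("negative edge weights are not allowed")
  if (normalize && max(A) > 0) A <- A / max(A)
  edge_weights(A, neuron_names, mode = "provided")
}

#' @rdname load_adjacency
#' @param ew an [edge_weights()] to write as a square CSV matrix.
#' @export
write_adjacency <- function(ew, path) {
  stopifnot(inherits(ew, "edge_weights"))
  df <- data.frame(neuron = ew$neuron_names, ew$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
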