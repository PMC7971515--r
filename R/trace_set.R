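#' State vocabularies
#'
#' A state vocabulary maps behavioral-state names to integer codes `0..k-1`.
#' Two vocabularies ship with the package: the 7-state vocabulary used for
#' freely-moving worms (`"kato7"`) and the coarser 4-state vocabulary
#' (`"nichols4"`).
#'
#' @param names character vector of state names, in code order.
#' @return An object of class `state_vocabulary`: a named integer vector of
#'   codes `0..k-1`.
#' @examples
#' v <- state_vocabulary(c("forward crawling", "reverse crawling"))
#' v["reverse crawling"]
#' @export
state_vocabulary <- function(names) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("state names must be unique")
  if (length(names) < 1L) stop("vocabulary must contain at least one state")
  v <- stats::setNames(seq_along(names) - 1L, names)
  class(v) <- "state_vocabulary"
  v
}

#' @rdname state_vocabulary
#' @param which one of `"kato7"` or `"nichols4"`.
#' @export
default_vocabulary <- function(which = c("nichols4", "kato7")) {
  which <- match.arg(which)
  switch(which,
    kato7 = state_vocabulary(c(
      "Forward Crawling", "Forward Slowing", "Reverse 1", "Reverse 2",
      "Sustained Reverse Crawling", "Dorsal Turn", "Ventral Turn"
    )),
    nichols4 = state_vocabulary(c(
      "forward crawling", "reverse crawling", "dorsal turn", "ventral turn"
    ))
  )
}

#' @export
print.state_vocabulary <- function(x, ...) {
  cat("State vocabulary (k = ", length(x), "):\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %d: %s\n", x[[nm]], nm))
  invisible(x)
}

#' Construct a single-individual recording
#'
#' A `trace_set` holds one individual's whole-brain recording: a T x N matrix
#' of normalized fluorescence traces, the matching matrix of temporal
#' derivatives, neuron names, the sampling interval, and (optionally) a
#' per-timestep behavioral-state label vector with its vocabulary.
#'
#' @param traces numeric T x N matrix; columns are neurons.
#' @param neuron_names character vector of length N; unique, case-sensitive
#'   (worm neurons carry fixed uppercase names such as `"AVAL"`).
#' @param derivatives numeric T x N matrix of per-timestep derivatives, or
#'   `NULL` to compute them with [compute_derivative()].
#' @param dt sampling interval in seconds (about 1/3 s in typical whole-brain
#'   recordings).
#' @param labels optional integer vector of length T of state codes, or a
#'   character vector of state names resolved against `vocabulary`.
#' @param vocabulary optional [state_vocabulary()] giving the label coding.
#' @param individual_id identifier for the individual (worm).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, neuron_names, derivatives = NULL, dt = 1 / 3,
                      labels = NULL, vocabulary = NULL,
                      individual_id = "worm") {
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  neuron_names <- as.character(neuron_names)
  if (length(neuron_names) != ncol(traces)) {
    stop("length(neuron_names) must equal ncol(traces)")
  }
  if (anyDuplicated(neuron_names)) {
    stop("duplicate neuron names: ",
         paste(unique(neuron_names[duplicated(neuron_names)]), collapse = ", "))
  }
  if (anyNA(traces) || any(!is.finite(traces))) {
    bad <- which(!is.finite(traces), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite trace value at row %d, neuron %s",
                 bad[1L], neuron_names[bad[2L]]))
  }
  if (!is.null(derivatives)) {
    derivatives <- as.matrix(derivatives)
    storage.mode(derivatives) <- "double"
    if (!identical(dim(derivatives), dim(traces))) {
      stop("derivatives must share the shape of traces")
    }
    if (anyNA(derivatives) || any(!is.finite(derivatives))) {
      bad <- which(!is.finite(derivatives), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-finite derivative value at row %d, neuron %s",
                   bad[1L], neuron_names[bad[2L]]))
    }
    derived <- FALSE
  } else {
    derivatives <- compute_derivative(traces, dt)
    derived <- TRUE
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(traces)) {
      stop("labels must have one entry per timestep")
    }
    if (is.character(labels) || is.factor(labels)) {
      if (is.null(vocabulary)) stop("character labels require a vocabulary")
      labels <- as.character(labels)
      unknown <- setdiff(unique(labels), names(vocabulary))
      if (length(unknown)) {
        stop("labels outside vocabulary: ", paste(unknown, collapse = ", "))
      }
      labels <- unname(vocabulary[labels])
    }
    labels <- as.integer(labels)
    if (anyNA(labels)) stop("labels contain missing values")
    if (!is.null(vocabulary) && any(labels < 0L | labels >= length(vocabulary))) {
      stop("label codes outside vocabulary range 0..k-1")
    }
  }
  colnames(traces) <- neuron_names
  colnames(derivatives) <- neuron_names
  structure(
    list(
      individual_id = as.character(individual_id),
      neuron_names = neuron_names,
      traces = traces,
      derivatives = derivatives,
      derivatives_computed = derived,
      dt = as.numeric(dt),
      labels = labels,
      vocabulary = vocabulary
    ),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set '%s': %d timesteps x %d neurons (dt = %.3g s)\n",
              x$individual_id, nrow(x$traces), ncol(x$traces), x$dt))
  cat("  neurons:", paste(utils::head(x$neuron_names, 8L), collapse = ", "),
      if (length(x$neuron_names) > 8L) "...", "\n")
  if (!is.null(x$labels)) {
    k <- if (!is.null(x$vocabulary)) length(x$vocabulary)
         else length(unique(x$labels))
    cat(sprintf("  labels: present (%d states)\n", k))
  } else {
    cat("  labels: absent\n")
  }
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$traces)

n_timesteps <- function(ts) nrow(ts$traces)
n_neurons <- function(ts) ncol(ts$traces)

#' Restrict a recording to a subset of neurons
#'
#' Used to restrict recordings to the neurons uniquely identified across all
#' individuals of a study (e.g. the 15-neuron set shared by the five worms of
#' the freely-moving study, or the 3-neuron set shared across studies).
#' Matching is case-sensitive and exact; the output column order follows the
#' requested order.
#'
#' @param ts a [trace_set()].
#' @param names character vector of neuron names to keep, in the desired order.
#' @return A [trace_set()] with `N = length(names)`.
#' @export
select_neurons <- function(ts, names) {
  stopifnot(inherits(ts, "trace_set"))
  names <- as.character(names)
  missing <- setdiff(names, ts$neuron_names)
  if (length(missing)) {
    stop("neurons not present in recording: ", paste(missing, collapse = ", "))
  }
  idx <- match(names, ts$neuron_names)
  out <- ts
  out$neuron_names <- names
  out$traces <- ts$traces[, idx, drop = FALSE]
  out$derivatives <- ts$derivatives[, idx, drop = FALSE]
  out
}

#' The neuron sets shared across the two source studies
#'
#' `shared_neurons("study15")` returns the 15 neurons uniquely identified in
#' all five worms of the freely-moving dataset; `shared_neurons("shared3")`
#' the 3 neurons identified in every worm of both datasets.
#'
#' @param which one of `"study15"`, `"shared3"`.
#' @return character vector of neuron names.
#' @export
shared_neurons <- function(which = c("study15", "shared3")) {
  which <- match.arg(which)
  switch(which,
    study15 = c("AIBL", "AIBR", "ALA", "AVAL", "AVAR", "AVBL", "AVER", "RID",
                "RIML", "RIMR", "RMED", "RMEL", "RMER", "VB01", "VB02"),
    shared3 = c("AIBR", "AVAL", "VB02")
  )
}

#' Read and write trace tables
#'
#' The package's portable trace-table format is CSV (RFC 4180): one `time`
#' column in seconds, one column per neuron holding the normalized
#' fluorescence trace, optional derivative columns named `d_<neuron>`, and an
#' optional `state` column of integer state codes. The sampling interval `dt`
#' is inferred from the `time` column.
#'
#' @param path file path.
#' @param dialect table dialect; only `"csv"` is supported.
#' @param vocabulary optional [state_vocabulary()] attached to the labels.
#' @param individual_id identifier; defaults to the file name without
#'   extension.
#' @return `load_trace_table()` returns a [trace_set()];
#'   `write_trace_table()` returns `path` invisibly.
#' @export
load_trace_table <- function(path, dialect = "csv", vocabulary = NULL,
                             individual_id = NULL) {
  if (!identical(dialect, "csv")) {
    stop("unsupported trace-table dialect: ", dialect, " (only 'csv')")
  }
  if (!file.exists(path)) stop("trace table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("trace table is empty: ", path)
  cols <- names(df)
  if (anyDuplicated(cols)) {
    stop("duplicate column names in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  state_col <- intersect("state", cols)
  time_col <- intersect("time", cols)
  deriv_cols <- grep("^d_", cols, value = TRUE)
  neuron_cols <- setdiff(cols, c(state_col, time_col, deriv_cols))
  if (!length(neuron_cols)) stop("no neuron columns in ", path)
  num <- df[neuron_cols]
  bad <- vapply(num, function(x) !is.numeric(x) || anyNA(x) || any(!is.finite(x)),
                logical(1L))
  if (any(bad)) {
    col <- neuron_cols[which(bad)[1L]]
    x <- df[[col]]
    row <- if (is.numeric(x)) which(!is.finite(x))[1L] else 1L
    stop(sprintf("non-numeric or missing trace value in column '%s', row %d of %s",
                 col, row, path))
  }
  traces <- as.matrix(num)
  derivs <- NULL
  if (length(deriv_cols)) {
    wanted <- paste0("d_", neuron_cols)
    if (!all(wanted %in% deriv_cols)) {
      stop("derivative columns present but incomplete in ", path)
    }
    derivs <- as.matrix(df[wanted])
    colnames(derivs) <- neuron_cols
  }
  dt <- 1 / 3
  if (length(time_col)) {
    tv <- df[[time_col]]
    if (length(tv) > 1L) dt <- stats::median(diff(tv))
  }
  labels <- if (length(state_col)) df[[state_col]] else NULL
  if (is.null(individual_id)) {
    individual_id <- sub("\\.[^.]*$", "", basename(path))
  }
  trace_set(traces, neuron_cols, derivatives = derivs, dt = dt,
            labels = labels, vocabulary = vocabulary,
            individual_id = individual_id)
}

#' @rdname load_trace_table
#' @param ts a [trace_set()] to write.
#' @export
write_trace_table <- function(ts, path, dialect = "csv") {
  stopifnot(inherits(ts, "trace_set"))
  if (!identical(dialect, "csv")) {
    stop("unsupported trace-table dialect: ", dialect, " (only 'csv')")
  }
  df <- data.frame(time = (seq_len(nrow(ts$traces)) - 1) * ts$dt,
                   check.names = FALSE)
  for (nm in ts$neuron_names) df[[nm]] <- ts$traces[, nm]
  for (nm in ts$neuron_names) df[[paste0("d_", nm)]] <- ts$derivatives[, nm]
  if (!is.null(ts$labels)) df[["state"]] <- ts$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
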