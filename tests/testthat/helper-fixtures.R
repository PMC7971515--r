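# fixtures are built in code at test time; no binary data ships with the tests

# a tiny deterministic labeled recording
tiny_trace_set <- function(T_ = 40L, N = 3L, seed = 7L, labels = TRUE,
                           k = 2L) {
  set.seed(seed)
  tr <- matrix(runif(T_ * N), T_, N)
  labs <- if (labels) rep_len(rep(0:(k - 1L), each = 5L), T_) else NULL
  vocab <- if (labels) state_vocabulary(paste0("s", 0:(k - 1L))) else NULL
  trace_set(tr, paste0("N", seq_len(N)), dt = 1 / 3, labels = labs,
            vocabulary = vocab, individual_id = "tiny")
}

# write a trace-table CSV for loader tests; returns the path
write_tiny_csv <- function(dir, name = "worm.csv", n_rows = 4L,
                           neurons = c("AVAL", "VB02"), with_state = TRUE) {
  df <- data.frame(time = (seq_len(n_rows) - 1) / 3)
  for (i in seq_along(neurons)) {
    df[[neurons[i]]] <- seq_len(n_rows) / (n_rows + i)
  }
  if (with_state) df$state <- rep_len(c(0L, 1L), n_rows)
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

# small synthetic population shared across tests (cheap: short recordings)
small_population <- function(n = 2L, T_ = 400L, N = 6L, seed = 11L,
                             n_states = 4L) {
  cfg <- synth_config(n_individuals = n, n_neurons = N, timesteps = T_,
                      n_states = n_states)
  generate_population(cfg, master_seed = seed)
}

# zero out every weight of a model (output becomes exactly zero)
zero_model <- function(object) {
  object$params <- rapply(object$params, function(x) x * 0, how = "replace")
  object
}
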