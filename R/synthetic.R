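#' Configuration of the synthetic population generator
#'
#' The generator emulates the statistical structure of multi-individual
#' whole-brain recordings: a shared low-dimensional cyclic latent process
#' whose phase arcs are the behavioral states (mirroring the stereotyped
#' forward -> reverse -> turn -> forward sequence), read out into neuron
#' traces through individual-specific linear mixings, smoothed with a
#' first-order exponential kernel as a calcium-indicator proxy, and observed
#' with additive noise. Individuals therefore share dynamics and labels
#' statistics but differ in neuron-level mixing — the structure on which
#' cross-individual generalization rests.
#'
#' @param n_individuals number of individuals.
#' @param n_neurons neurons per individual (default 15, the shared set size).
#' @param timesteps recording length T (default 3200, within the typical
#'   3,000–4,000 range at ~1/3 s per timestep).
#' @param latent_dim latent dimensionality (default 3).
#' @param n_states 4 or 7 behavioral states.
#' @param dwell mean dwell time per state in timesteps; default scales the
#'   standard profile (long forward runs, shorter reversals, brief turns) to
#'   `n_states`.
#' @param state_weights arc length share of the cycle per state.
#' @param noise_sd observation noise standard deviation (trace units).
#' @param tau calcium smoothing time constant in seconds.
#' @param speed_noise_sd lognormal sd of the angular-speed fluctuations (the
#'   phase only moves forward, so states follow the cyclic order).
#' @param readout_sd standard deviation of the entries of each individual's
#'   readout matrix.
#' @param dt seconds per timestep.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 5L, n_neurons = 15L,
                         timesteps = 3200L, latent_dim = 3L, n_states = 4L,
                         dwell = NULL, state_weights = NULL,
                         noise_sd = 0.05, tau = 1.0, speed_noise_sd = 0.3,
                         readout_sd = 0.8, dt = 1 / 3) {
  n_states <- as.integer(n_states)
  stopifnot(n_states >= 2L, latent_dim >= 2L, noise_sd >= 0,
            n_neurons >= 1L, timesteps >= 2L, n_individuals >= 1L)
  if (is.null(dwell)) {
    dwell <- switch(as.character(n_states),
      "4" = c(90, 50, 20, 20),
      "7" = c(80, 40, 25, 25, 50, 25, 25),
      rep(round(200 / n_states), n_states))
  }
  if (is.null(state_weights)) {
    state_weights <- switch(as.character(n_states),
      "4" = c(0.45, 0.30, 0.125, 0.125),
      "7" = c(0.30, 0.12, 0.08, 0.08, 0.18, 0.12, 0.12),
      rep(1 / n_states, n_states))
  }
  stopifnot(length(dwell) == n_states, length(state_weights) == n_states)
  state_weights <- state_weights / sum(state_weights)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_neurons = as.integer(n_neurons),
    timesteps = as.integer(timesteps), latent_dim = as.integer(latent_dim),
    n_states = n_states, dwell = dwell, state_weights = state_weights,
    noise_sd = noise_sd, tau = tau, speed_noise_sd = speed_noise_sd,
    readout_sd = readout_sd, dt = dt
  ), class = "synth_config")
}

synth_vocabulary <- function(n_states) {
  if (n_states == 4L) return(default_vocabulary("nichols4"))
  if (n_states == 7L) return(default_vocabulary("kato7"))
  state_vocabulary(paste0("state", seq_len(n_states) - 1L))
}

#' Generate the shared cyclic latent process
#'
#' A phase variable moves forward around a closed loop; the loop is divided
#' into contiguous arcs, one per behavioral state, visited in a fixed cyclic
#' order. The angular speed is state-dependent (arc length / mean dwell time)
#' with multiplicative lognormal fluctuations, so the phase never moves
#' backwards and the label sequence follows the cyclic state order. The
#' latent coordinates are smooth functions of the phase.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return list with `latent` (T x latent_dim), `labels` (length-T integer
#'   codes), `phase` (length-T), `vocabulary`, and `all_states_visited`
#'   (FALSE flags a recording too short to visit every state).
#' @export
generate_latent_cycle <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  T_ <- cfg$timesteps
  bounds <- c(0, cumsum(cfg$state_weights)) * 2 * pi
  arc_len <- diff(bounds)
  omega <- arc_len / cfg$dwell   # radians per timestep within each state
  with_seed(seed, {
    phase <- numeric(T_)
    phase[1L] <- stats::runif(1L, 0, 2 * pi)
    mult <- exp(stats::rnorm(T_, -cfg$speed_noise_sd^2 / 2, cfg$speed_noise_sd))
    for (t in 2:T_) {
      s <- findInterval(phase[t - 1L] %% (2 * pi), bounds,
                        rightmost.closed = TRUE)
      phase[t] <- phase[t - 1L] + omega[s] * mult[t]
    }
    wrapped <- phase %% (2 * pi)
    labels <- findInterval(wrapped, bounds, rightmost.closed = TRUE) - 1L
    latent <- matrix(0, T_, cfg$latent_dim)
    latent[, 1L] <- cos(wrapped)
    latent[, 2L] <- sin(wrapped)
    if (cfg$latent_dim >= 3L) {
      for (d in 3:cfg$latent_dim) {
        latent[, d] <- 0.6 * cos((d - 1L) * wrapped + 0.7 * d)
      }
    }
    list(latent = latent, labels = labels, phase = phase,
         vocabulary = synth_vocabulary(cfg$n_states),
         all_states_visited = length(unique(labels)) == cfg$n_states)
  })
}

# first-order exponential smoothing (calcium-indicator proxy)
exp_smooth <- function(x, a) {
  if (a <= 0) return(x)
  apply(x, 2L, function(col) {
    as.numeric(stats::filter(col * (1 - a), a, method = "recursive",
                             init = col[1L]))
  })
}

#' Generate one individual's recording from the shared latent process
#'
#' Traces are `smooth(softplus(R_a latent + b_a)) + noise` where `R_a` is an
#' individual-specific random readout: individuals share the latent dynamics
#' and label sequence but mix it into neurons differently. Derivatives are
#' computed by finite differences and both channels are normalized to the
#' unit interval over the full recording.
#'
#' @param latent,labels from [generate_latent_cycle()].
#' @param cfg a [synth_config()].
#' @param individual_seed seed of this individual's readout and noise.
#' @param individual_id identifier.
#' @param vocabulary [state_vocabulary()] for the labels.
#' @return a [trace_set()] satisfying all invariants, with a `ground_truth`
#'   attribute holding the readout.
#' @export
generate_individual <- function(latent, labels, cfg, individual_seed = 1L,
                                individual_id = "synthetic_worm",
                                vocabulary = synth_vocabulary(cfg$n_states)) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(individual_seed, {
    N <- cfg$n_neurons
    R <- matrix(stats::rnorm(N * ncol(latent), sd = cfg$readout_sd), N)
    b <- stats::rnorm(N, mean = 1, sd = 0.5)
    raw <- softplus(latent %*% t(R) + rep(b, each = nrow(latent)))
    a <- exp(-cfg$dt / cfg$tau)
    sm <- exp_smooth(raw, a)
    obs <- sm + matrix(stats::rnorm(length(sm), sd = cfg$noise_sd), nrow(sm))
    traces <- normalize_unit_interval(obs)
    derivs <- normalize_unit_interval(compute_derivative(traces, cfg$dt))
    ts <- trace_set(traces, paste0("SYN", sprintf("%02d", seq_len(N))),
                    derivatives = derivs, dt = cfg$dt, labels = labels,
                    vocabulary = vocabulary, individual_id = individual_id)
    attr(ts, "ground_truth") <- list(readout = R, bias = b)
    ts
  })
}

#' Generate a synthetic population
#'
#' One fresh realization of the shared cyclic latent process per individual
#' (same generator, same state statistics) with an independent readout each,
#' mirroring a study population (e.g. 5 seen individuals, 21 unseen).
#'
#' @param cfg a [synth_config()].
#' @param master_seed seed controlling the whole population.
#' @return list of `cfg$n_individuals` [trace_set()]s.
#' @export
generate_population <- function(cfg, master_seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  seeds <- with_seed(master_seed,
                     sample.int(2147483, 2L * cfg$n_individuals))
  lapply(seq_len(cfg$n_individuals), function(i) {
    lat <- generate_latent_cycle(cfg, seed = seeds[2L * i - 1L])
    ts <- generate_individual(lat$latent, lat$labels, cfg,
                              individual_seed = seeds[2L * i],
                              individual_id = sprintf("synworm%02d", i),
                              vocabulary = lat$vocabulary)
    attr(ts, "ground_truth")$latent <- lat$latent
    attr(ts, "ground_truth")$all_states_visited <- lat$all_states_visited
    ts
  })
}

#' Ground-truth coupled dynamical system
#'
#' Defines a sparse directed coupling matrix `W` and the update rule of a
#' coupled system used as an oracle for edge-recovery and
#' parameter-recovery experiments: `X_{t+1} = X_t + eps * tanh(W X_t) +
#' noise` (rule `"tanh"`) or the linear map `X_{t+1} = (I + eps W) X_t +
#' noise` (rule `"linear"`). `W` is rescaled so the dynamics stay bounded
#' (spectral radius of `eps W` at most 0.9, and of `I + eps W` below 1 for
#' the linear rule).
#'
#' @param n_neurons system size N.
#' @param density fraction of nonzero off-diagonal couplings (default 0.1).
#' @param eps update step size (default 0.1).
#' @param noise_sd process noise sd per step.
#' @param rule `"tanh"` or `"linear"`.
#' @param seed seed for the coupling draw.
#' @return object of class `ground_truth_system` with fields `W`, `eps`,
#'   `noise_sd`, `rule`.
#' @export
ground_truth_system <- function(n_neurons = 10L, density = 0.1, eps = 0.1,
                                noise_sd = 0.01, rule = c("tanh", "linear"),
                                seed = 1L) {
  rule <- match.arg(rule)
  N <- as.integer(n_neurons)
  W <- with_seed(seed, {
    W <- matrix(0, N, N)
    off <- which(!diag(N))
    n_edges <- if (density > 0) max(1L, round(density * length(off))) else 0L
    if (n_edges > 0L) {
      picked <- sample(off, n_edges)
      W[picked] <- stats::runif(n_edges, 0.5, 1.5) *
        sample(c(-1, 1), n_edges, replace = TRUE)
    }
    W
  })
  rad <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rule == "tanh") {
    if (rad > 0 && eps * rad > 0.9) W <- W * 0.9 / (eps * rad)
  } else {
    # linear rule: a lightly damped rotation, so trajectories oscillate for
    # the whole recording instead of decaying to a fixed point (a flat
    # recording carries no information about the map). Antisymmetrize, add a
    # weak self-decay, and shrink until I + eps*W is a (near-)contraction.
    W <- (W - t(W)) / 2 - 0.02 * diag(N)
    repeat {
      rad2 <- max(Mod(eigen(diag(N) + eps * W, only.values = TRUE)$values))
      if (rad2 <= 0.9995) break
      W <- W * 0.9 - 0.002 * diag(N)
    }
  }
  structure(list(W = W, eps = eps, noise_sd = noise_sd, rule = rule, N = N),
            class = "ground_truth_system")
}

#' Simulate a coupled system as an unlabeled recording
#'
#' Iterates the ground-truth update rule from a random interior initial
#' condition, clipping to the unit interval, and wraps the result as a
#' [trace_set()] (trace channel = state, derivative channel computed and
#' normalized). The coupling matrix is kept as ground truth for
#' edge-recovery scoring via [edge_recovery_auroc()].
#'
#' @param gt a [ground_truth_system()].
#' @param timesteps number of timesteps.
#' @param seed seed for initial condition and noise.
#' @param x0 optional length-N initial state in `[0, 1]`; random interior
#'   point by default.
#' @return an unlabeled [trace_set()] with a `ground_truth` attribute
#'   holding `W`.
#' @export
generate_coupled_system <- function(gt, timesteps = 2000L, seed = 1L,
                                    x0 = NULL) {
  stopifnot(inherits(gt, "ground_truth_system"))
  T_ <- as.integer(timesteps)
  with_seed(seed, {
    N <- gt$N
    X <- matrix(0, T_, N)
    X[1L, ] <- if (is.null(x0)) stats::runif(N, 0.3, 0.7) else x0
    for (t in 2:T_) {
      x <- X[t - 1L, ]
      dx <- if (gt$rule == "tanh") gt$eps * tanh(gt$W %*% x)
            else gt$eps * (gt$W %*% x)
      x2 <- x + as.numeric(dx)
      if (gt$noise_sd > 0) x2 <- x2 + stats::rnorm(N, sd = gt$noise_sd)
      if (any(!is.finite(x2)) || max(abs(x2)) > 1e3) {
        stop("coupled system diverged; check the stability of W")
      }
      # the tanh rule lives on the unit interval; the linear (rotational)
      # rule orbits the origin and is mapped to [0,1] afterwards
      X[t, ] <- if (gt$rule == "tanh") pmin(pmax(x2, 0), 1) else x2
    }
    if (gt$rule == "linear") X <- normalize_unit_interval(X)
    derivs <- normalize_unit_interval(compute_derivative(X, 1))
    ts <- trace_set(X, paste0("unit", sprintf("%02d", seq_len(N))),
                    derivatives = derivs, dt = 1,
                    individual_id = "coupled_system")
    attr(ts, "ground_truth") <- list(W = gt$W, eps = gt$eps, rule = gt$rule)
    ts
  })
}
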