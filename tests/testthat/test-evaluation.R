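test_that("cross-validation reports one accuracy per fold and stays calibrated", {
  pop <- small_population(n = 1L, T_ = 400L, N = 5L)
  ts <- pop[[1L]]
  rep_ <- crossval_states(ts, model = "mlp", kfold = 5, seed = 2, epochs = 8)
  expect_s3_class(rep_, "elegnn_eval")
  expect_length(rep_$per_fold, 5L)
  expect_true(all(rep_$per_fold >= 0 & rep_$per_fold <= 1))
  expect_equal(rep_$accuracy, mean(rep_$per_fold))
  rs <- rowSums(rep_$confusion)
  expect_true(all(abs(rs[rs > 0] - 100) < 1e-6))
  # labels drawn uniformly over the 4 states -> accuracy near the 25% chance
  # level (binomial sampling error over ~400 test timesteps, plus a small
  # overfitting margin)
  shuf <- ts
  set.seed(9)
  shuf$labels <- sample(0:3, nrow(ts$traces), replace = TRUE)
  rep_chance <- crossval_states(shuf, model = "mlp", kfold = 5, seed = 2,
                                epochs = 8)
  expect_lt(abs(rep_chance$accuracy - 0.25), 0.10)
})

test_that("unseen-individual classification scores one prediction per timestep", {
  pop <- small_population(n = 2L, T_ = 240L, N = 4L)
  fit <- elegnn(pop[[1L]], task = "classify", model = "mlp", epochs = 5,
                seed = 1)
  pred <- predict(fit, pop[[2L]])
  expect_length(pred, 240L)
  rep_ <- evaluate_states(fit, pop[[2L]])
  expect_gte(rep_$accuracy, 0)
  expect_lte(rep_$accuracy, 1)
  expect_equal(rep_$meta$n_timesteps, 240L)
  rs <- rowSums(rep_$confusion)
  expect_true(all(abs(rs[rs > 0] - 100) < 1e-6))
})

test_that("a constant predictor scores the base rate of its constant state", {
  # zero-weight classifier emits identical scores everywhere; ties break to
  # state 0, so accuracy equals the fraction of state-0 timesteps
  ts <- tiny_trace_set(T_ = 40L, N = 3L, k = 4L)
  cfg <- elegnn_config(model = "mlp", task = "classify", n_neurons = 3,
                       n_states = 4)
  z <- zero_model(elegnn_model(cfg))
  z$trained <- TRUE
  z$neuron_names <- ts$neuron_names
  z$vocabulary <- ts$vocabulary
  rep_ <- evaluate_states(z, ts)
  expect_equal(rep_$accuracy, mean(ts$labels == 0L))
  # balanced labels -> exactly 1/k
  ts$labels <- rep_len(0:3, 40L)
  expect_equal(evaluate_states(z, ts)$accuracy, 0.25)
})

test_that("population accuracy weighs individuals equally", {
  pop <- small_population(n = 3L, T_ = 240L, N = 4L)
  fit <- elegnn(pop[[1L]], task = "classify", model = "mlp", epochs = 5,
                seed = 1)
  rep_ <- evaluate_population(fit, pop[2:3])
  expect_length(rep_$per_fold, 2L)
  expect_equal(rep_$accuracy, mean(rep_$per_fold))
})

test_that("vocabulary mismatches require an explicit state map", {
  pop7 <- generate_population(
    synth_config(n_individuals = 1L, n_neurons = 5L, timesteps = 400L,
                 n_states = 7L), master_seed = 3)
  pop4 <- small_population(n = 1L, T_ = 240L, N = 5L)
  fit7 <- elegnn(pop7[[1L]], task = "classify", model = "mlp", epochs = 4,
                 seed = 1)
  expect_error(evaluate_states(fit7, pop4[[1L]]), "state_map")
  rep_ <- evaluate_states(fit7, pop4[[1L]], state_map = default_state_map())
  expect_true(rep_$accuracy >= 0 && rep_$accuracy <= 1)
  expect_equal(dim(rep_$confusion), c(4L, 4L))
})

test_that("zero-residual trajectory model equals the persistence baseline exactly", {
  pop <- small_population(n = 1L, T_ = 200L, N = 4L)
  ts <- pop[[1L]]
  cfg <- elegnn_config(model = "gnn", task = "predict", n_neurons = 4,
                       edge_mode = "static")
  z <- zero_model(elegnn_model(cfg))
  z$trained <- TRUE
  z$neuron_names <- ts$neuron_names
  ev <- evaluate_trajectory(z, ts, horizon = 16)
  base <- persistence_baseline_mse(ts, horizon = 16)
  expect_length(ev$per_step_mse, 16L)
  expect_equal(ev$per_step_mse, base$per_step_mse, tolerance = 1e-12)
})

test_that("persistence baseline matches analytic values on simple signals", {
  # constant recording -> all zeros
  const <- trace_set(matrix(0.5, 30, 2), c("A", "B"),
                     derivatives = matrix(0.25, 30, 2))
  expect_equal(persistence_baseline_mse(const, 4)$per_step_mse, rep(0, 4))
  # linear ramp with slope c per step: MSE (c^2, 4 c^2)
  T_ <- 21L
  ramp <- matrix(seq(0, 1, length.out = T_), T_, 2)
  ts <- trace_set(ramp, c("A", "B"), derivatives = ramp)
  cc <- 1 / (T_ - 1)
  mse <- persistence_baseline_mse(ts, 2)$per_step_mse
  expect_equal(mse, c(cc^2, 4 * cc^2), tolerance = 1e-12)
  # non-decreasing in s for a monotone drifting signal
  mse5 <- persistence_baseline_mse(ts, 5)$per_step_mse
  expect_true(all(diff(mse5) > 0))
})

test_that("a constant-offset residual accumulates quadratically in the rollout", {
  T_ <- 40L
  const <- trace_set(matrix(0.5, T_, 3), c("A", "B", "C"),
                     derivatives = matrix(0.5, T_, 3))
  cfg <- elegnn_config(model = "mlp", task = "predict", n_neurons = 3)
  m <- zero_model(elegnn_model(cfg))
  m$params$ggraph$l2$b <- rep(0.1, 6)  # H = +0.1 everywhere
  m$trained <- TRUE
  m$neuron_names <- const$neuron_names
  ev <- evaluate_trajectory(m, const, horizon = 4)
  expect_equal(ev$per_step_mse, (0.1 * (1:4))^2, tolerance = 1e-10)
})

test_that("edge-recovery AUROC separates true couplings from noise", {
  gt <- ground_truth_system(n_neurons = 8L, density = 0.15, seed = 4)
  # scoring the truth itself is perfect
  expect_equal(edge_recovery_auroc(abs(gt$W) / max(abs(gt$W)), gt$W), 1)
  # a constant score carries no ranking information
  expect_equal(edge_recovery_auroc(matrix(0.5, 8, 8), gt$W), 0.5)
})
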