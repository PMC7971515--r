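test_that("the latent cycle is seeded, cyclic and visits every state", {
  cfg <- synth_config(n_individuals = 1L, n_neurons = 5L, timesteps = 1000L,
                      n_states = 4L)
  a <- generate_latent_cycle(cfg, seed = 8)
  b <- generate_latent_cycle(cfg, seed = 8)
  expect_identical(a, b)
  expect_setequal(unique(a$labels), 0:3)
  expect_true(a$all_states_visited)
  # labels only move to the same state or the cyclic successor
  k <- cfg$n_states
  trans <- unique(cbind(a$labels[-length(a$labels)], a$labels[-1L]))
  ok <- trans[, 2L] == trans[, 1L] | trans[, 2L] == (trans[, 1L] + 1L) %% k
  expect_true(all(ok))
})

test_that("zero speed noise with uniform dwell gives a linear phase", {
  cfg <- synth_config(n_individuals = 1L, n_neurons = 3L, timesteps = 200L,
                      n_states = 4L, speed_noise_sd = 0,
                      dwell = rep(50, 4), state_weights = rep(0.25, 4))
  lat <- generate_latent_cycle(cfg, seed = 1)
  incr <- diff(lat$phase)
  expect_equal(incr, rep(incr[1L], length(incr)), tolerance = 1e-9)
})

test_that("individuals satisfy recording invariants and share the label sequence", {
  cfg <- synth_config(n_individuals = 2L, n_neurons = 6L, timesteps = 500L,
                      n_states = 4L)
  lat <- generate_latent_cycle(cfg, seed = 3)
  w1 <- generate_individual(lat$latent, lat$labels, cfg, individual_seed = 10,
                            individual_id = "a")
  w2 <- generate_individual(lat$latent, lat$labels, cfg, individual_seed = 20,
                            individual_id = "b")
  for (w in list(w1, w2)) {
    expect_identical(dim(w$traces), dim(w$derivatives))
    expect_true(all(w$traces >= 0 & w$traces <= 1))
    expect_true(all(w$derivatives >= 0 & w$derivatives <= 1))
    expect_length(w$labels, 500L)
  }
  expect_identical(w1$labels, w2$labels)      # shared latent
  expect_gt(max(abs(w1$traces - w2$traces)), 0.1)  # different readouts
  # determinism of a single individual
  w1b <- generate_individual(lat$latent, lat$labels, cfg, individual_seed = 10,
                             individual_id = "a")
  expect_equal(w1$traces, w1b$traces)
})

test_that("population generation is reproducible and sized as requested", {
  cfg <- synth_config(n_individuals = 5L, n_neurons = 4L, timesteps = 150L)
  pop <- generate_population(cfg, master_seed = 2)
  expect_length(pop, 5L)
  cfg21 <- synth_config(n_individuals = 21L, n_neurons = 4L, timesteps = 60L)
  expect_length(generate_population(cfg21, master_seed = 2), 21L)
  pop2 <- generate_population(cfg, master_seed = 2)
  expect_equal(pop[[3L]]$traces, pop2[[3L]]$traces)
  expect_false(isTRUE(all.equal(pop[[1L]]$traces, pop[[2L]]$traces)))
})

test_that("a noiseless individual is low-dimensional: 3 PCs explain >= 95%", {
  cfg <- synth_config(n_individuals = 1L, n_neurons = 15L, timesteps = 800L,
                      latent_dim = 3L, noise_sd = 0)
  lat <- generate_latent_cycle(cfg, seed = 5)
  w <- generate_individual(lat$latent, lat$labels, cfg, individual_seed = 6)
  pc <- stats::prcomp(w$traces, center = TRUE, scale. = FALSE)
  explained <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  expect_gte(explained[3L], 0.95)
})

test_that("neuron-level decoders do not transfer across readouts but latent decoders do", {
  cfg <- synth_config(n_individuals = 2L, n_neurons = 15L, timesteps = 800L,
                      n_states = 4L)
  latA <- generate_latent_cycle(cfg, seed = 31)
  latB <- generate_latent_cycle(cfg, seed = 32)
  wA <- generate_individual(latA$latent, latA$labels, cfg, individual_seed = 41)
  wB <- generate_individual(latB$latent, latB$labels, cfg, individual_seed = 42)
  # linear decoder on individual A's neurons
  dfA <- data.frame(wA$traces, lab = factor(wA$labels))
  dfB <- data.frame(wB$traces, lab = factor(wB$labels))
  names(dfB) <- names(dfA)
  ld <- MASS::lda(lab ~ ., dfA)
  within_acc <- mean(predict(ld, dfA)$class == dfA$lab)
  cross_acc <- mean(predict(ld, dfB)$class == dfB$lab)
  # decoder on the shared latent coordinates transfers
  dlA <- data.frame(latA$latent, lab = factor(latA$labels))
  dlB <- data.frame(latB$latent, lab = factor(latB$labels))
  names(dlB) <- names(dlA)
  ll <- MASS::lda(lab ~ ., dlA)
  latent_acc <- mean(predict(ll, dlB)$class == dlB$lab)
  expect_gt(within_acc, 0.8)
  expect_lt(cross_acc, within_acc - 0.15)
  expect_gt(latent_acc, cross_acc + 0.15)
})

test_that("coupled systems follow the stated update rule and stay stable", {
  # W = 0, no noise -> constant trajectory
  gt0 <- ground_truth_system(n_neurons = 3L, density = 0, noise_sd = 0)
  ts0 <- generate_coupled_system(gt0, timesteps = 50L, seed = 1)
  expect_equal(max(abs(diff(ts0$traces))), 0)
  # single coupling w21: one step from (0.5, 0.5) moves x2 by eps*tanh(w*0.5)
  gt <- ground_truth_system(n_neurons = 2L, density = 0.5, eps = 0.1,
                            noise_sd = 0, seed = 3)
  gt$W <- matrix(c(0, 0.8, 0, 0), 2, 2)  # W[2,1] = 0.8
  ts <- generate_coupled_system(gt, timesteps = 2L, seed = 1,
                                x0 = c(0.5, 0.5))
  expect_equal(unname(ts$traces[2L, 2L] - ts$traces[1L, 2L]),
               0.1 * tanh(0.8 * 0.5), tolerance = 1e-12)
  expect_equal(unname(ts$traces[2L, 1L]), 0.5)
  # determinism
  gt2 <- ground_truth_system(n_neurons = 6L, density = 0.2, seed = 9)
  t1 <- generate_coupled_system(gt2, timesteps = 100L, seed = 5)
  t2 <- generate_coupled_system(gt2, timesteps = 100L, seed = 5)
  expect_equal(t1$traces, t2$traces)
  # linear rule
  gtl <- ground_truth_system(n_neurons = 4L, density = 0.3, rule = "linear",
                             noise_sd = 0, seed = 7)
  rad <- max(Mod(eigen(diag(4) + gtl$eps * gtl$W)$values))
  expect_lte(rad, 1)
})
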