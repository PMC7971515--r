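nf <- function(...) elegnn:::net_forward(...)

test_that("MLP aggregates node features and respects dimensional bookkeeping", {
  cfg <- elegnn_config(model = "mlp", task = "classify", n_neurons = 15,
                       n_states = 4)
  m <- elegnn_model(cfg, seed = 1)
  # concat aggregation: first-layer input length 2 * 15 = 30
  expect_equal(nrow(m$params$ggraph$l1$W), 30L)
  # zero weights and biases -> output exactly zero
  z <- zero_model(m)
  Xb <- array(runif(6 * 15 * 2), c(6, 15, 2))
  H <- nf(z$params, cfg, Xb)$H
  expect_equal(H, matrix(0, 6, 4), ignore_attr = TRUE)
  # determinism: same input, same seed -> bitwise identical output
  m2 <- elegnn_model(cfg, seed = 1)
  expect_identical(nf(m$params, cfg, Xb)$H, nf(m2$params, cfg, Xb)$H)
  # sum aggregation input is one feature pair
  cfg_s <- elegnn_config(model = "mlp", task = "classify", n_neurons = 15,
                         n_states = 4, aggregation = "sum")
  expect_equal(nrow(elegnn_model(cfg_s)$params$ggraph$l1$W), 2L)
})

test_that("edge encoder produces sigmoid weights with the contract's identities", {
  cfg <- elegnn_config(model = "gnn", task = "classify", n_neurons = 4,
                       n_states = 3, edge_mode = "dynamic")
  m <- elegnn_model(cfg, seed = 3)
  X1 <- matrix(runif(8), 4, 2)
  # zero edge-perceptron -> every weight sigmoid(0) = 0.5
  mz <- m
  mz$params$gedge <- rapply(mz$params$gedge, function(x) x * 0, how = "replace")
  A0 <- infer_edges(mz, X1)
  expect_s3_class(A0, "edge_weights")
  expect_equal(A0$matrix, matrix(0.5, 4, 4), ignore_attr = TRUE)
  # any input -> strictly inside (0, 1)
  A <- infer_edges(m, X1)
  expect_true(all(A$matrix > 0 & A$matrix < 1))
  # provided mode bypasses the encoder
  cfg_p <- elegnn_config(model = "gnn", task = "classify", n_neurons = 4,
                         n_states = 3, edge_mode = "provided")
  expect_error(infer_edges(elegnn_model(cfg_p), X1), "bypass")
})

test_that("static-mode edges are invariant to timestep permutation", {
  cfg <- elegnn_config(model = "gnn", task = "predict", n_neurons = 5,
                       edge_mode = "static")
  m <- elegnn_model(cfg, seed = 9)
  set.seed(21)
  X <- array(runif(5 * 5 * 2), c(5, 5, 2))  # T = 5 timesteps
  A1 <- infer_edges(m, X)$matrix
  perm <- c(3, 1, 5, 2, 4)
  A2 <- infer_edges(m, X[perm, , , drop = FALSE])$matrix
  expect_equal(A1, A2, tolerance = 1e-12)
})

test_that("message passing equals the double-loop oracle", {
  # explicit summation oracle M_i = sum_j A_ij x_j
  oracle <- function(A, X) {
    M <- X * 0
    for (i in seq_len(nrow(A))) {
      for (j in seq_len(ncol(A))) M[i, ] <- M[i, ] + A[i, j] * X[j, ]
    }
    M
  }
  set.seed(13)
  for (rep in 1:25) {
    N <- sample(2:8, 1)
    A <- matrix(runif(N * N), N, N)
    X <- matrix(rnorm(N * 2), N, 2)
    expect_lt(max(abs(message_pass(A, X) - oracle(A, X))), 1e-10)
  }
  # identities
  X <- matrix(runif(12), 6, 2)
  expect_equal(message_pass(diag(6), X), X, ignore_attr = TRUE)
  A1 <- matrix(1, 2, 2)
  X2 <- rbind(c(1, 2), c(3, 5))
  M <- message_pass(A1, X2)
  expect_equal(M[1, ], c(4, 7))
  expect_equal(M[2, ], c(4, 7))
  # two steps = A %*% (A %*% X)
  A <- matrix(runif(9), 3, 3)
  X3 <- matrix(rnorm(6), 3, 2)
  expect_equal(message_pass(A, X3, steps = 2), A %*% (A %*% X3))
  expect_error(message_pass(matrix(1, 2, 3), X3), "N x N")
})

test_that("GNN head has the vocabulary dimension and zero g_graph kills output", {
  cfg <- elegnn_config(model = "gnn", task = "classify", n_neurons = 15,
                       n_states = 7)
  m <- elegnn_model(cfg, seed = 2)
  Xb <- array(runif(3 * 15 * 2), c(3, 15, 2))
  H <- nf(m$params, cfg, Xb)$H
  expect_equal(dim(H), c(3L, 7L))  # k = 7 for the full state vocabulary
  mz <- m
  mz$params$ggraph <- rapply(mz$params$ggraph, function(x) x * 0,
                             how = "replace")
  expect_equal(nf(mz$params, cfg, Xb)$H, matrix(0, 3, 7), ignore_attr = TRUE)
})

test_that("with identity edges and sum aggregation the GNN equals the MLP", {
  cfg_g <- elegnn_config(model = "gnn", task = "classify", n_neurons = 6,
                         n_states = 3, aggregation = "sum",
                         edge_mode = "provided")
  cfg_m <- elegnn_config(model = "mlp", task = "classify", n_neurons = 6,
                         n_states = 3, aggregation = "sum")
  g <- elegnn_model(cfg_g, seed = 5)
  m <- elegnn_model(cfg_m, seed = 5)
  m$params$ggraph <- g$params$ggraph  # parameter-matched
  set.seed(6)
  Xb <- array(runif(10 * 6 * 2), c(10, 6, 2))
  Hg <- nf(g$params, cfg_g, Xb, A_fixed = diag(6))$H
  Hm <- nf(m$params, cfg_m, Xb)$H
  expect_equal(Hg, Hm, tolerance = 1e-12)
})

test_that("classification output is a proper, shift-invariant softmax", {
  r <- classify_states(c(0, 0, 0, 0))
  expect_equal(r$prob, rep(0.25, 4))
  expect_equal(r$state, 0L)  # tie breaks to the lowest code
  r2 <- classify_states(c(1, 0))
  expect_equal(r2$prob, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-4)
  expect_equal(r2$state, 0L)
  set.seed(8)
  for (rep in 1:20) {
    H <- rnorm(sample(2:9, 1), sd = 5)
    p <- classify_states(H)$prob
    expect_lt(abs(sum(p) - 1), 1e-6)
    expect_true(all(p >= 0))
    expect_equal(p, classify_states(H + 3.7)$prob, tolerance = 1e-9)
  }
  expect_error(classify_states(2), "k >= 2")
})

test_that("the residual step and rollout satisfy their exact identities", {
  X <- matrix(runif(10), 5, 2)
  expect_equal(predict_step(X, X * 0), X)
  expect_equal(predict_step(matrix(0.5, 4, 2), matrix(0.1, 4, 2)),
               matrix(0.6, 4, 2))
  H <- matrix(0.05, 5, 2)
  expect_equal(predict_step(predict_step(X, H), H), X + 2 * H)
  expect_error(predict_step(X, matrix(0, 2, 2)), "shape")

  cfg <- elegnn_config(model = "gnn", task = "predict", n_neurons = 5,
                       edge_mode = "static")
  z <- zero_model(elegnn_model(cfg, seed = 1))
  # zero model -> constant rollout equal to X0
  out <- rollout(z, X, n_steps = 16)
  expect_equal(dim(out), c(16L, 5L, 2L))
  for (s in 1:16) expect_equal(out[s, , ], X, ignore_attr = TRUE)
  # rollout(2) equals predict_step applied twice (manual composition)
  m <- elegnn_model(cfg, seed = 4)
  A <- infer_edges(m, array(X, c(1, 5, 2)))$matrix
  two <- rollout(m, X, n_steps = 2, A = A)
  step1 <- X + elegnn:::unflat_nodes(
    nf(m$params, cfg, array(X, c(1, 5, 2)), A_fixed = A)$H, 5)[1, , ]
  step2 <- step1 + elegnn:::unflat_nodes(
    nf(m$params, cfg, array(step1, c(1, 5, 2)), A_fixed = A)$H, 5)[1, , ]
  expect_equal(two[1, , ], step1, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(two[2, , ], step2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences on a small toy", {
  cfg <- elegnn_config(model = "gnn", task = "classify", n_neurons = 3,
                       n_states = 2, hidden = 5, embed_dim = 4)
  params <- elegnn_model(cfg, seed = 2)$params
  set.seed(31)
  Xb <- array(runif(6 * 3 * 2), c(6, 3, 2))
  y <- sample(0:1, 6, TRUE)
  lossfun <- function(p) {
    pr <- elegnn:::softmax_rows(nf(p, cfg, Xb)$H)
    -mean(log(pr[cbind(1:6, y + 1)]))
  }
  fw <- nf(params, cfg, Xb)
  pr <- elegnn:::softmax_rows(fw$H)
  dH <- pr
  dH[cbind(1:6, y + 1)] <- dH[cbind(1:6, y + 1)] - 1
  bw <- elegnn:::net_backward(params, cfg, fw$cache, dH / 6)
  g <- elegnn:::flatten_tree(bw$grads)
  pv <- elegnn:::flatten_tree(params)
  eps <- 1e-5
  idx <- sort(sample(length(pv), 50))
  fd <- vapply(idx, function(i) {
    a <- pv; a[i] <- a[i] + eps
    b <- pv; b[i] <- b[i] - eps
    (lossfun(elegnn:::unflatten_tree(a, params)) -
       lossfun(elegnn:::unflatten_tree(b, params))) / (2 * eps)
  }, numeric(1))
  expect_true(all(abs(fd - g[idx]) < 1e-6 + 1e-4 * abs(fd)))
})
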