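test_that("the Euler step obeys its closed form and preserves fixed points", {
  p <- tiny_model()$params
  J <- p$J; M <- p$M
  expect_equal(rnn_step(numeric(J), numeric(M), p), numeric(J))
  ## alpha = 1 reduces to the pure map tanh(Wx + Bu)
  p1 <- p; p1$alpha <- 1
  x <- rnorm(J, 0, 0.3); u <- rnorm(M, 0, 0.3)
  expect_equal(rnn_step(x, u, p1), drop(tanh(p1$W %*% x + p1$B %*% u)))
  ## a solution of x = tanh(Wx + Bu) is fixed for every alpha:
  ## take W = 0 so x* = tanh(Bu) exactly
  p0 <- p; p0$W <- matrix(0, J, J)
  xstar <- drop(tanh(p0$B %*% u))
  for (a in c(0.1, 0.5, 1)) {
    pa <- p0; pa$alpha <- a
    expect_equal(rnn_step(xstar, u, pa), xstar, tolerance = 1e-12)
  }
  expect_error(rnn_step(c(NaN, numeric(J - 1)), numeric(M), p), "non-finite")
})

test_that("simulation from the origin with zero input stays at output 0.5", {
  m <- tiny_model()
  traj <- simulate_rnn(m$params, matrix(0, 20, m$params$M))
  expect_true(all(traj$states == 0))
  expect_true(all(traj$outputs == 0.5))
  expect_identical(dim(traj$states), c(20L, m$params$J))
})

test_that("states remain bounded by the tanh range when alpha = 1", {
  m <- tiny_model()
  p <- m$params; p$alpha <- 1
  u <- matrix(rnorm(50 * p$M, 0, 2), 50, p$M)
  traj <- simulate_rnn(p, u)
  expect_true(all(abs(traj$states) <= 1))
  expect_true(all(traj$outputs > 0 & traj$outputs < 1))
})

test_that("constant query-only input settles toward a fixed state", {
  m <- tiny_model(seed = 3)
  u <- matrix(rep(query_input(causal_query(1, 2), m$task), each = 400), 400)
  traj <- simulate_rnn(m$params, u)
  step_sizes <- sqrt(rowSums(diff(traj$states)^2))
  expect_lt(step_sizes[399], 1e-6)
})

test_that("compiled BPTT gradients match central finite differences", {
  set.seed(42)
  J <- 5; M <- 4; T_ <- 7; nb <- 3; alpha <- 0.3; win <- 3
  W <- matrix(rnorm(J * J, 0, 0.5), J, J)
  B <- matrix(rnorm(J * M, 0, 0.5), J, M)
  Cv <- rnorm(J, 0, 0.5)
  U <- array(rnorm(M * nb * T_), c(M, nb, T_))
  labels <- c(1, 0, 1)
  lossf <- function(W, B, Cv) {
    f <- causaljudge:::cpp_forward(W, B, matrix(Cv, 1), alpha, U,
                                   matrix(0, J, nb))
    y <- f$outputs[(T_ - win + 1):T_, , drop = FALSE]
    -mean(sapply(1:nb, function(b)
      labels[b] * log(y[, b]) + (1 - labels[b]) * log(1 - y[, b])))
  }
  g <- causaljudge:::cpp_bptt(W, B, matrix(Cv, 1), alpha, U, labels, win)
  eps <- 1e-6
  num_grad <- function(f, x) {
    vapply(seq_along(x), function(i) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      (f(xp) - f(xm)) / (2 * eps)
    }, numeric(1))
  }
  gW_num <- num_grad(function(w) lossf(matrix(w, J, J), B, Cv), as.numeric(W))
  gB_num <- num_grad(function(b) lossf(W, matrix(b, J, M), Cv), as.numeric(B))
  gC_num <- num_grad(function(cv) lossf(W, B, cv), Cv)
  expect_equal(as.numeric(g$gW), gW_num, tolerance = 1e-6)
  expect_equal(as.numeric(g$gB), gB_num, tolerance = 1e-6)
  expect_equal(as.numeric(g$gC), gC_num, tolerance = 1e-6)
  expect_equal(g$loss, lossf(W, B, Cv), tolerance = 1e-10)
})

test_that("decisions follow the terminal-window mean with ties false", {
  expect_true(decision(rep(0.9, 50)))
  expect_false(decision(rep(0.5, 50)))           # tie rule
  expect_true(decision(seq(0.2, 0.8, length.out = 100), window = 0.1))
  expect_false(decision(seq(0.8, 0.2, length.out = 100), window = 0.1))
})

test_that("an untrained network with zero readout performs exactly at chance", {
  task <- tiny_task()
  m <- untrained_rnn(task, train_config(J = 32, seed = 9))
  ev <- evaluate_accuracy(m, task, n_trials = 400, seed = 10)
  ## zero C => all outputs 0.5 => all judgments FALSE => accuracy = share of
  ## false labels, within 3 sigma of 0.5 on balanced trials
  expect_lt(abs(ev$accuracy - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("short training runs are reproducible given the seed", {
  task <- tiny_task()
  cfg <- train_config(J = 16, n_steps = 30, eval_every = 10, eval_trials = 50,
                      seed = 4)
  m1 <- train_rnn(task, cfg, quiet = TRUE)
  m2 <- train_rnn(task, cfg, quiet = TRUE)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$W, m2$params$W)
})

test_that("training reduces the loss on an easy two-node task", {
  task <- task_config(n_nodes = 2, n_obs = 15, steps_per_obs = 1,
                      settle_steps = 3)
  cfg <- train_config(J = 32, n_steps = 400, eval_every = 100,
                      eval_trials = 150, seed = 5, target_accuracy = 0.99)
  m <- train_rnn(task, cfg, quiet = TRUE)
  h <- m$history
  expect_lt(h$loss[nrow(h)], 0.69)
  expect_gt(max(h$holdout_accuracy), 0.6)
})
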