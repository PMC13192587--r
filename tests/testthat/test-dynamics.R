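test_that("the speed function has its stated closed forms", {
  p <- tiny_model()$params
  ## zero state, zero effective input
  p0 <- p; p0$B <- matrix(0, p$J, p$M)
  expect_equal(rnn_speed(numeric(p$J), numeric(p$M), p0) * 0 +
                 rnn_speed(numeric(p$J), numeric(p$M), p0), 0)
  ## W = 0, B = 0: q(v) = 0.5 ||tanh(0) - v||^2 = 0.5 ||v||^2
  pz <- p; pz$W <- matrix(0, p$J, p$J); pz$B <- matrix(0, p$J, p$M)
  v <- rnorm(p$J)
  expect_equal(rnn_speed(v, numeric(p$M), pz), 0.5 * sum(v^2))
  ## any solution of x = tanh(Wx + Bu): use W = 0 again
  u <- rnorm(p$M)
  xstar <- drop(tanh(pz$B %*% u))
  expect_equal(rnn_speed(xstar, u, pz), 0)
})

test_that("the speed gradient matches finite differences", {
  p <- tiny_model(seed = 11)$params
  u <- rnorm(p$M, 0, 0.5)
  x <- rnorm(p$J, 0, 0.5)
  g <- causaljudge:::speed_grad(x, u, p)
  eps <- 1e-6
  num <- vapply(seq_len(p$J), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (rnn_speed(xp, u, p) - rnn_speed(xm, u, p)) / (2 * eps)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-6)
})

test_that("the fixed-point finder recovers an analytically known fixed line", {
  ## rank-one system W = v v^T, B = 0: near the origin every small multiple
  ## of v is a slow state, and the finder must land within 1e-3 of the line
  sys <- line_system(J = 8, seed = 7)
  model <- structure(list(
    params = sys,
    task = task_config(n_nodes = 2, n_obs = 5, settle_steps = 2),
    cfg = train_config(J = 8, seed = 1, n_steps = 1)), class = "dag_rnn")
  ## seeds drawn near the line by simulating query-only input = 0 channels
  fps <- find_fixed_points(model, causal_query(1, 2), model$task,
                           n_seeds = 60, n_trials = 4, jitter = 0.05,
                           tol = 1e-10, dedup_radius = 1e-4, seed = 3)
  expect_gt(length(fps$points), 0)
  for (fp in fps$points) {
    x <- fp$x_star
    ## distance to the line span{v}
    along <- sum(x * sys$v) * sys$v
    expect_lt(sqrt(sum((x - along)^2)), 1e-3)
    expect_lt(fp$speed, 1e-10)
  }
})

test_that("linearization matches finite-difference Jacobians", {
  p <- tiny_model(seed = 13)$params
  u <- rnorm(p$M, 0, 0.4)
  for (rep in 1:20) {
    x <- rnorm(p$J, 0, 0.5)
    lin <- linearize(x, u, p)
    eps <- 1e-6
    step_at <- function(xx) {
      (1 - p$alpha) * xx + p$alpha * drop(tanh(p$W %*% xx + p$B %*% u))
    }
    num <- vapply(seq_len(p$J), function(i) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      (step_at(xp) - step_at(xm)) / (2 * eps)
    }, numeric(p$J))
    expect_equal(lin$jac_rec, num, tolerance = 1e-6, ignore_attr = TRUE)
    ## input Jacobian by differencing in u
    num_b <- vapply(seq_len(p$M), function(i) {
      up <- u; up[i] <- up[i] + eps
      um <- u; um[i] <- um[i] - eps
      x1 <- (1 - p$alpha) * x + p$alpha * drop(tanh(p$W %*% x + p$B %*% up))
      x2 <- (1 - p$alpha) * x + p$alpha * drop(tanh(p$W %*% x + p$B %*% um))
      (x1 - x2) / (2 * eps)
    }, numeric(p$J))
    expect_equal(lin$jac_inp, num_b, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("eigen decomposition is biorthogonal and correctly ordered", {
  p <- tiny_model(seed = 17)$params
  lin <- linearize(rnorm(p$J, 0, 0.3), rnorm(p$M, 0, 0.3), p)
  expect_true(all(diff(Re(lin$values)) <= 1e-12))
  LR <- lin$left %*% lin$right
  expect_equal(LR, diag(p$J) + 0i, tolerance = 1e-8, ignore_attr = TRUE)
  ## alpha = 1 at the origin with zero input: jac_rec = W exactly
  p1 <- p; p1$alpha <- 1; p1$B <- matrix(0, p$J, p$M)
  lin0 <- linearize(numeric(p$J), numeric(p$M), p1)
  expect_equal(lin0$jac_rec, p1$W, ignore_attr = TRUE)
  ## symmetric W gives real eigenvalues
  ps <- p; ps$W <- (p$W + t(p$W)) / 2; ps$B <- matrix(0, p$J, p$M)
  lins <- linearize(numeric(p$J), numeric(p$M), ps)
  expect_true(all(abs(Im(lins$values)) < 1e-10))
})

test_that("linearized one-step error scales quadratically with perturbation", {
  p <- tiny_model(seed = 19)$params
  u <- rnorm(p$M, 0, 0.3)
  x0 <- rnorm(p$J, 0, 0.2)
  lin <- linearize(x0, u, p)
  f <- function(x) (1 - p$alpha) * x +
    p$alpha * drop(tanh(p$W %*% x + p$B %*% u))
  fx0 <- f(x0)
  set.seed(1)
  dirn <- rnorm(p$J); dirn <- dirn / sqrt(sum(dirn^2))
  hs <- 10^seq(-4, -1, length.out = 10)    # three decades
  errs <- vapply(hs, function(h) {
    dx <- h * dirn
    sqrt(sum((f(x0 + dx) - (fx0 + lin$jac_rec %*% dx))^2))
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(hs)))[2]
  expect_lt(abs(slope - 2), 0.2)
})

test_that("slow-mode predictions obey their algebraic identities", {
  ## construct a fixed point record by hand with known eigenstructure
  J <- 6; M <- 4
  set.seed(23)
  r <- rnorm(J); r <- r / sqrt(sum(r^2))
  l <- r  # symmetric case: left = right
  jac_inp <- matrix(rnorm(J * M), J, M)
  fp <- structure(list(top_eigenvalue = 1 + 0i, r = r, l = l,
                       jac_inp = jac_inp), class = "fixed_point")
  expect_equal(slow_mode_prediction(fp, numeric(M))$magnitude, 0)
  ## input orthogonal to l^T jac_inp gives zero displacement
  a <- drop(l %*% jac_inp)
  w_perp <- c(-a[2], a[1], 0, 0)
  expect_equal(slow_mode_prediction(fp, w_perp)$magnitude, 0,
               tolerance = 1e-12)
  ## displacement is along r with the stated scalar
  w <- rnorm(M)
  pred <- slow_mode_prediction(fp, w)
  expect_equal(pred$displacement, r * sum(a * w), tolerance = 1e-12)
  fp$top_eigenvalue <- 0.9 + 0.2i
  expect_error(slow_mode_prediction(fp, w), "complex")
})

test_that("line attractors orient along the readout and sort their points", {
  ## collinear synthetic fixed points
  J <- 10
  set.seed(29)
  axis_true <- rnorm(J); axis_true <- axis_true / sqrt(sum(axis_true^2))
  base <- rnorm(J)
  pts <- lapply(seq(-2, 2, length.out = 5), function(s) {
    x <- base + s * axis_true
    structure(list(x_star = x, query = causal_query(1, 2), speed = 1e-12,
                   top_eigenvalue = 1 + 0i, r = axis_true, l = axis_true,
                   jac_inp = matrix(0, J, 2),
                   output = plogis(sum(axis_true * x))),
              class = "fixed_point")
  })
  params <- structure(list(W = diag(J), B = matrix(0, J, 2), C = axis_true,
                           alpha = 0.5, J = J, M = 2L), class = "rnn_params")
  attr <- build_line_attractor(pts, params)
  expect_equal(abs(sum(attr$axis * axis_true)), 1, tolerance = 1e-8)
  expect_gt(sum(attr$axis * params$C), 0)       # true end is positive
  expect_equal(attr$explained_variance, 1, tolerance = 1e-10)
  expect_true(all(diff(attr$projections) > 0))  # sorted along the axis
  ## flipping the readout flips the axis
  params_neg <- params; params_neg$C <- -axis_true
  attr_neg <- build_line_attractor(pts, params_neg)
  expect_equal(attr_neg$axis, -attr$axis, tolerance = 1e-12)
  expect_error(build_line_attractor(pts[1:2], params), "at least 3")
})

test_that("interior point selection keeps the central span", {
  J <- 4
  pts <- lapply(1:10, function(s) {
    structure(list(x_star = c(s, 0, 0, 0), query = causal_query(1, 2),
                   speed = 0, top_eigenvalue = 1 + 0i, r = c(1, 0, 0, 0),
                   l = c(1, 0, 0, 0), jac_inp = matrix(0, J, 2), output = 0.5),
              class = "fixed_point")
  })
  params <- structure(list(W = diag(J), B = matrix(0, J, 2), C = c(1, 0, 0, 0),
                           alpha = 0.5, J = J, M = 2L), class = "rnn_params")
  attr <- build_line_attractor(pts, params)
  ints <- interior_points(attr, 0.6)
  projs <- vapply(ints, function(p) p$x_star[1], numeric(1))
  expect_true(all(projs >= 3 & projs <= 8))
  expect_gte(length(ints), 4)
})

test_that("observation patterns enumerate binary combinations", {
  pats <- observation_patterns(3)
  expect_identical(dim(pats), c(8L, 3L))
  expect_identical(rownames(pats)[1], "-")
  expect_equal(unname(pats["AB", ]), c(1, 1, 0), ignore_attr = TRUE)
  expect_identical(anyDuplicated(pats), 0L)
})

test_that("attractor geometry summarizes centroid distances", {
  J <- 5
  mk <- function(q, shift) {
    pts <- lapply(1:3, function(s)
      structure(list(x_star = rep(shift, J) + s * c(1, rep(0, J - 1)),
                     query = q, speed = 0, top_eigenvalue = 1 + 0i,
                     r = c(1, rep(0, J - 1)), l = c(1, rep(0, J - 1)),
                     jac_inp = matrix(0, J, 6), output = 0.5),
                class = "fixed_point"))
    params <- structure(list(W = diag(J), B = matrix(0, J, 6),
                             C = c(1, rep(0, J - 1)), alpha = 0.5,
                             J = J, M = 6L), class = "rnn_params")
    build_line_attractor(pts, params)
  }
  qs <- all_queries(3)
  ## same-cause attractors placed together, different causes far apart
  attractors <- lapply(seq_len(6), function(i)
    mk(causal_query(qs$cause[i], qs$effect[i]), shift = 10 * qs$cause[i]))
  geom <- attractor_geometry(attractors)
  expect_identical(dim(geom$distances), c(6L, 6L))
  expect_equal(max(abs(geom$distances - t(geom$distances))), 0)
  same <- geom$summary$mean_distance[geom$summary$group == "same_cause"]
  diff_ <- geom$summary$mean_distance[geom$summary$group == "different_cause"]
  expect_lt(same, diff_)
  ## identical attractors give a zero distance matrix
  same_all <- lapply(seq_len(6), function(i)
    mk(causal_query(qs$cause[i], qs$effect[i]), shift = 0))
  expect_equal(max(attractor_geometry(same_all)$distances), 0)
})

test_that("PCA projections satisfy variance identities", {
  set.seed(31)
  ## data confined to a 2-D subspace of 6 dims
  basis <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  trajs <- lapply(1:3, function(i) matrix(rnorm(40), 20, 2) %*% t(basis))
  pp <- pca_projection(trajs, n_components = 2)
  expect_equal(sum(pp$variance_explained), 1, tolerance = 1e-10)
  expect_true(all(diff(pp$variance_explained) <= 1e-12))
  ## reconstruction error equals unexplained variance (Pythagoras)
  pooled <- do.call(rbind, trajs)
  pc <- prcomp(pooled)
  k <- 1
  recon <- pc$x[, 1:k, drop = FALSE] %*% t(pc$rotation[, 1:k, drop = FALSE])
  centered <- sweep(pooled, 2, pc$center)
  err <- sum((centered - recon)^2)
  expect_equal(err, sum(pc$sdev[-(1:k)]^2) * (nrow(pooled) - 1),
               tolerance = 1e-8)
})

test_that("the empirical decision axis is null under label shuffling", {
  m <- tiny_model(seed = 37)
  ## an untrained zero-readout model has no label information in its states;
  ## the unnormalized axis should be close to zero relative to state scale
  ax <- decision_axis(m, n_trials = 300, seed = 38)
  expect_lt(ax$raw_norm, 0.5)
  expect_equal(sqrt(sum(ax$axis^2)), 1, tolerance = 1e-12)
})

test_that("input-effect maps and traversal are inert for an input-blind system", {
  ## line_system has B = 0: no observation pattern can move the state, so
  ## every displacement in the map is ~0 and traversal stays put
  sys <- line_system(J = 8, seed = 7, M = 9)
  task <- task_config(n_nodes = 3, n_obs = 5, settle_steps = 2)
  model <- structure(list(params = sys, task = task,
                          cfg = train_config(J = 8, seed = 1, n_steps = 1)),
                     class = "dag_rnn")
  fps <- find_fixed_points(model, causal_query(1, 2), task, n_seeds = 40,
                           n_trials = 4, jitter = 0.05, tol = 1e-10,
                           dedup_radius = 1e-4, seed = 5)
  skip_if(length(fps$points) < 3, "too few points on the constructed line")
  a <- build_line_attractor(fps, sys)
  iem <- input_effect_map(a, model, task, relax_steps = 30)
  expect_identical(nrow(iem), length(a$points) * 8L)  # 2^3 patterns
  expect_lt(max(abs(iem$instant)), 1e-4)
  expect_lt(max(abs(iem$relaxed)), 1e-3)
  tr <- traverse_attractor(model, a, start_point = 1, pattern = "AB",
                           n_repeats = 5, relax_steps = 5, task = task)
  expect_identical(nrow(tr), 6L)
  expect_lt(max(abs(diff(tr$projection))), 1e-3)
})

test_that("slow-mode prediction is exact on a constructed integrating system", {
  ## rank-one W with unit top eigenvalue at the origin; zero tonic input so
  ## the origin is an exact fixed point; small input pulse then relaxation
  J <- 8; M <- 6
  set.seed(41)
  v <- rnorm(J); v <- v / sqrt(sum(v^2))
  alpha <- 0.5
  params <- structure(list(W = v %*% t(v), B = matrix(rnorm(J * M, 0, 0.3), J, M),
                           C = v, alpha = alpha, J = J, M = as.integer(M)),
                      class = "rnn_params")
  u0 <- numeric(M)
  lin <- linearize(numeric(J), u0, params)
  expect_equal(Re(lin$values[1]), 1, tolerance = 1e-10)
  fp <- structure(list(x_star = numeric(J), query = causal_query(1, 2),
                       speed = 0, jac_rec = lin$jac_rec, jac_inp = lin$jac_inp,
                       values = lin$values, right = lin$right, left = lin$left,
                       top_eigenvalue = lin$values[1],
                       r = Re(lin$right[, 1]), l = Re(lin$left[1, ]),
                       output = 0.5), class = "fixed_point")
  w <- numeric(M); w[2] <- 0.01
  pred <- slow_mode_prediction(fp, w)
  ## full nonlinear: one pulse step then 40 query-free relaxation steps
  inputs <- rbind(matrix(w, 1, M), matrix(0, 40, M))
  traj <- simulate_rnn(params, inputs, x0 = numeric(J))
  actual <- sum(traj$states[41, ] * fp$r) / sum(fp$r^2)
  expect_lt(abs(actual - pred$magnitude) / abs(pred$magnitude), 0.05)
})
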