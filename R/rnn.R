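#' Leaky tanh RNN parameters
#'
#' The network follows the continuous-time rate equation
#' \deqn{\tau \dot x = -x + \tanh(W x + B u), \qquad y = \sigma(C x)}
#' integrated by forward Euler with step `alpha = dt / tau`, giving the
#' discrete update
#' \deqn{x_{t+1} = (1-\alpha) x_t + \alpha \tanh(W x_t + B u_{t+1}).}
#'
#' Initialization: `W` entries are Gaussian with variance `gain^2 / J`
#' (variance-preserving scaling of the recurrent weights), `B` is
#' Glorot-scaled (variance `2 / (J + M)`), and the readout `C` is zero so
#' the untrained network reports 0.5 on every trial.
#'
#' @param J hidden size.
#' @param M input dimension (3 * n_nodes for the judgment task).
#' @param alpha Euler step dt/tau, in (0, 1].
#' @param gain scale of the recurrent weight initialization.
#' @param seed optional integer seed for the initialization.
#' @return object of class `rnn_params` with fields `W` (J x J), `B` (J x M),
#'   `C` (length J), `alpha`, `J`, `M`.
#' @export
rnn_params <- function(J = 128, M = 9, alpha = 0.2, gain = 1.0, seed = NULL) {
  stopifnot(J >= 1, M >= 1, alpha > 0, alpha <= 1)
  with_seed(seed, {
    structure(list(
      W = matrix(stats::rnorm(J * J, 0, gain / sqrt(J)), J, J),
      B = matrix(stats::rnorm(J * M, 0, sqrt(2 / (J + M))), J, M),
      C = numeric(J),
      alpha = alpha, J = as.integer(J), M = as.integer(M)
    ), class = "rnn_params")
  })
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("<rnn_params: J=%d hidden units, M=%d inputs, alpha=%g>\n",
              x$J, x$M, x$alpha))
  invisible(x)
}

#' One Euler step of the RNN
#'
#' @param x hidden state (length-J vector).
#' @param u input (length-M vector).
#' @param params an `rnn_params`.
#' @return the next hidden state `(1-alpha) x + alpha tanh(W x + B u)`.
#' @export
rnn_step <- function(x, u, params) {
  if (!all(is.finite(x)) || !all(is.finite(u))) stop("non-finite state or input")
  drop((1 - params$alpha) * x +
         params$alpha * tanh(params$W %*% x + params$B %*% u))
}

#' Simulate the RNN over an input time series
#'
#' Iterates [rnn_step()] over the rows of `inputs` starting from `x0`
#' (default: the origin, the common starting point of every trial).
#'
#' @param params an `rnn_params`.
#' @param inputs T x M input matrix.
#' @param x0 initial hidden state (length J), default zeros.
#' @return object of class `rnn_trajectory`: list with `states` (T x J) and
#'   `outputs` (length-T vector of sigmoid readouts in (0,1)).
#' @export
simulate_rnn <- function(params, inputs, x0 = NULL) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != params$M) stop("input columns do not match `params$M`")
  if (is.null(x0)) x0 <- numeric(params$J)
  res <- cpp_forward(params$W, params$B, matrix(params$C, 1), params$alpha,
                     array(t(inputs), c(params$M, 1L, nrow(inputs))),
                     matrix(x0, params$J, 1))
  structure(list(states = t(res$states[, 1, , drop = TRUE]),
                 outputs = as.numeric(res$outputs)),
            class = "rnn_trajectory")
}

#' @export
print.rnn_trajectory <- function(x, ...) {
  cat(sprintf("<rnn_trajectory: %d steps x %d units, final output %.3f>\n",
              nrow(x$states), ncol(x$states), utils::tail(x$outputs, 1)))
  invisible(x)
}

#' Binary judgment from a trajectory
#'
#' The judgment is `TRUE` iff the mean sigmoid output over the final
#' `window` fraction of timesteps exceeds 0.5; an exact tie resolves to
#' `FALSE`.
#'
#' @param traj an `rnn_trajectory` (or a numeric vector of outputs).
#' @param window fraction of trailing timesteps to average, in (0, 1].
#' @return logical judgment.
#' @export
decision <- function(traj, window = 0.1) {
  stopifnot(window > 0, window <= 1)
  y <- if (inherits(traj, "rnn_trajectory")) traj$outputs else as.numeric(traj)
  nw <- max(1L, ceiling(window * length(y)))
  mean(utils::tail(y, nw)) > 0.5
}

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size trials per gradient step.
#' @param n_steps maximum number of gradient steps.
#' @param J hidden size.
#' @param alpha Euler step dt/tau.
#' @param gain recurrent initialization gain.
#' @param seed integer seed controlling initialization and batch sampling.
#' @param loss_window fraction of trailing timesteps entering the
#'   cross-entropy loss (judgments are read out after evidence ends).
#' @param eval_every evaluate held-out accuracy every this many steps.
#' @param eval_trials number of fresh held-out trials per evaluation.
#' @param target_accuracy early-stop once held-out accuracy reaches this.
#' @param lr_halving_every halve the learning rate every this many steps
#'   (0 disables the schedule); consolidates the oscillatory late phase.
#' @param weight_decay decoupled (AdamW-style) weight decay on the recurrent
#'   and input weights; keeps the trained dynamics out of the chaotic
#'   regime so the attractor analysis applies (0 disables).
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64,
                         n_steps = 20000, J = 128, alpha = 0.2, gain = 1.5,
                         seed = 1, loss_window = 0.1, eval_every = 200,
                         eval_trials = 400, target_accuracy = 0.95,
                         lr_halving_every = 6000, weight_decay = 0.01) {
  stopifnot(learning_rate > 0, batch_size >= 1, n_steps >= 1, J >= 1,
            alpha > 0, alpha <= 1, loss_window > 0, loss_window <= 1,
            eval_every >= 1, eval_trials >= 1,
            target_accuracy > 0, target_accuracy <= 1, lr_halving_every >= 0,
            weight_decay >= 0)
  structure(as.list(environment()), class = "train_config")
}

#' Construct an untrained network for the judgment task
#'
#' Fresh initialization wrapped in the same `dag_rnn` container returned by
#' [train_rnn()]; used as the chance-level control (zero readout weights
#' make every output exactly 0.5 before training).
#'
#' @param task a `task_config`.
#' @param cfg a `train_config` (initialization settings are read from it).
#' @return a `dag_rnn` with empty training history.
#' @export
untrained_rnn <- function(task, cfg = train_config()) {
  params <- rnn_params(cfg$J, input_dim(task), cfg$alpha, cfg$gain,
                       seed = split_seed(cfg$seed, 1))
  structure(list(params = params, task = task, cfg = cfg,
                 history = tibble::tibble(step = integer(), loss = numeric(),
                                          train_accuracy = numeric(),
                                          holdout_accuracy = numeric())),
            class = "dag_rnn")
}

#' Train a leaky tanh RNN on the causal-judgment task
#'
#' Minimizes the binary cross-entropy between the trial label and the sigmoid
#' output over the final `loss_window` fraction of timesteps, by Adam on
#' (W, B, C) with gradients from backpropagation through time (compiled).
#' Held-out accuracy is monitored on freshly generated balanced trials;
#' training stops early once it reaches `cfg$target_accuracy`.
#'
#' @param task a `task_config`.
#' @param cfg a `train_config`.
#' @param quiet suppress progress messages.
#' @return object of class `dag_rnn`: list with `params` (`rnn_params`),
#'   `task`, `cfg`, and `history` (tibble: `step`, `loss`, `train_accuracy`,
#'   `holdout_accuracy`).
#' @export
train_rnn <- function(task, cfg = train_config(), quiet = FALSE) {
  M <- input_dim(task)
  params <- rnn_params(cfg$J, M, cfg$alpha, cfg$gain, seed = split_seed(cfg$seed, 1))
  T_ <- trial_length(task)
  win <- max(1L, as.integer(ceiling(cfg$loss_window * T_)))
  opt <- adam_state(params, cfg$learning_rate)
  hist <- list()
  best <- list(params = params, acc = -Inf)
  gen <- fast_batch_generator(task)
  with_seed(split_seed(cfg$seed, 2), {
    for (step in seq_len(cfg$n_steps)) {
      batch <- gen(cfg$batch_size)
      g <- cpp_bptt(params$W, params$B, matrix(params$C, 1), params$alpha,
                    batch$inputs, as.numeric(batch$labels), win)
      if (!is.finite(g$loss))
        stop(sprintf("training diverged at step %d (loss = %g)", step, g$loss))
      if (cfg$lr_halving_every > 0)
        opt$lr <- cfg$learning_rate *
          0.5^((step - 1) %/% cfg$lr_halving_every)
      opt <- adam_update(opt, params, g, step)
      params <- opt$params
      if (cfg$weight_decay > 0) {
        wdf <- 1 - opt$lr * cfg$weight_decay
        params$W <- params$W * wdf
        params$B <- params$B * wdf
      }
      if (step %% cfg$eval_every == 0 || step == cfg$n_steps) {
        hb <- gen(cfg$eval_trials)
        acc <- batch_accuracy(params, hb, win)
        hist[[length(hist) + 1L]] <- tibble::tibble(
          step = step, loss = g$loss, train_accuracy = g$acc,
          holdout_accuracy = acc)
        if (acc > best$acc) best <- list(params = params, acc = acc)
        if (!quiet)
          message(sprintf("step %6d  loss %.4f  held-out accuracy %.3f",
                          step, g$loss, acc))
        if (acc >= cfg$target_accuracy) break
      }
    }
  })
  # held-out accuracy oscillates once near ceiling; return the checkpoint
  # with the best monitored accuracy rather than the last iterate
  structure(list(params = best$params, task = task, cfg = cfg,
                 history = dplyr::bind_rows(hist)),
            class = "dag_rnn")
}

# mean-output decision accuracy of `params` on a generated batch
batch_accuracy <- function(params, batch, win) {
  f <- cpp_forward(params$W, params$B, matrix(params$C, 1), params$alpha,
                   batch$inputs, matrix(0, params$J, dim(batch$inputs)[2]))
  T_ <- nrow(f$outputs)
  ym <- colMeans(f$outputs[(T_ - win + 1):T_, , drop = FALSE])
  mean((ym > 0.5) == (batch$labels == 1))
}

adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  z <- function(p) p * 0
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = list(W = z(params$W), B = z(params$B), C = z(params$C)),
       v = list(W = z(params$W), B = z(params$B), C = z(params$C)))
}

adam_update <- function(opt, params, g, step) {
  bc1 <- 1 - opt$beta1^step
  bc2 <- 1 - opt$beta2^step
  grads <- list(W = g$gW, B = g$gB, C = as.numeric(g$gC))
  for (nm in names(grads)) {
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * grads[[nm]]
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  opt$params <- params
  opt
}

#' @export
print.dag_rnn <- function(x, ...) {
  h <- utils::tail(x$history, 1)
  cat(sprintf("<dag_rnn: J=%d, trained %d steps, held-out accuracy %.3f>\n",
              x$params$J, if (nrow(x$history)) h$step else 0L,
              if (nrow(x$history)) h$holdout_accuracy else NA_real_))
  invisible(x)
}

#' Evaluate judgment accuracy on fresh trials
#'
#' Generates `n_trials` fresh trials (balanced by default, per `task`),
#' simulates the model on each, and scores the terminal-window decisions.
#'
#' @param model a `dag_rnn` (or `rnn_params` with a `dag_rnn`-like wrapper).
#' @param task a `task_config`; defaults to the model's training task.
#' @param n_trials number of evaluation trials.
#' @param seed optional integer seed.
#' @param dag_filter optional: a DAG category name (e.g. `"chain"`) or a
#'   `causal_dag`; trials are then generated only from matching DAGs.
#' @return object of class `rnn_evaluation`: list with `accuracy`, `n_trials`,
#'   `by_category` and `by_query` tibbles, and the per-trial `trials` tibble
#'   (with `judgment` and `correct` columns).
#' @export
evaluate_accuracy <- function(model, task = NULL, n_trials = 2000, seed = NULL,
                              dag_filter = NULL) {
  task <- task %||% model$task
  params <- model$params
  win <- max(1L, as.integer(ceiling(model$cfg$loss_window * trial_length(task))))
  fixed_dag <- NULL
  if (inherits(dag_filter, "causal_dag")) fixed_dag <- dag_filter
  with_seed(seed, {
    if (is.character(dag_filter)) {
      # uniform over DAGs of the category x uniform queries, unbalanced
      dt <- dag_table(task$n_nodes)
      ids <- dt$dag_id[dt$category == dag_filter]
      if (!length(ids)) stop("unknown DAG category: ", dag_filter)
      per <- table(sample(ids, n_trials, replace = TRUE))
      parts <- lapply(names(per), function(id)
        generate_trials(per[[id]], task, fixed_dag = dt$dag[[as.integer(id)]]))
      batch <- list(
        inputs = array(unlist(lapply(parts, `[[`, "inputs")),
                       c(input_dim(task), n_trials, trial_length(task))),
        labels = unlist(lapply(parts, `[[`, "labels")),
        trials = dplyr::bind_rows(lapply(parts, `[[`, "trials")))
      # fix inputs concatenation along trial dim
      batch$inputs <- array(0, c(input_dim(task), n_trials, trial_length(task)))
      b0 <- 0L
      for (p in parts) {
        nb <- dim(p$inputs)[2]
        batch$inputs[, b0 + seq_len(nb), ] <- p$inputs
        b0 <- b0 + nb
      }
      batch$trials$trial <- seq_len(n_trials)
      batch$trials$category <- dag_filter
    } else {
      batch <- generate_trials(n_trials, task, fixed_dag = fixed_dag)
    }
    f <- cpp_forward(params$W, params$B, matrix(params$C, 1), params$alpha,
                     batch$inputs, matrix(0, params$J, n_trials))
    T_ <- nrow(f$outputs)
    ym <- colMeans(f$outputs[(T_ - win + 1):T_, , drop = FALSE])
    tr <- batch$trials
    tr$output <- ym
    tr$judgment <- ym > 0.5
    tr$correct <- tr$judgment == tr$label
    by_query <- dplyr::summarise(
      dplyr::group_by(tr, .data$cause, .data$effect),
      n = dplyr::n(), accuracy = mean(.data$correct), .groups = "drop")
    by_category <- dplyr::summarise(
      dplyr::group_by(tr, .data$category),
      n = dplyr::n(), accuracy = mean(.data$correct), .groups = "drop")
    structure(list(accuracy = mean(tr$correct), n_trials = n_trials,
                   by_category = by_category, by_query = by_query, trials = tr),
              class = "rnn_evaluation")
  })
}

#' @export
print.rnn_evaluation <- function(x, ...) {
  cat(sprintf("<rnn_evaluation: accuracy %.3f on %d trials>\n",
              x$accuracy, x$n_trials))
  print(x$by_category)
  invisible(x)
}


# Compiled balanced batch generator bound to a task; draws flow through R's
# RNG, so the surrounding with_seed() governs reproducibility.
fast_batch_generator <- function(task) {
  dt <- dag_table_cached(task$n_nodes)
  n <- task$n_nodes
  adj <- array(0, c(n, n, nrow(dt)))
  topo <- matrix(0L, nrow(dt), n)
  for (i in seq_len(nrow(dt))) {
    adj[, , i] <- adjacency_matrix(dt$dag[[i]])
    topo[i, ] <- topological_order(dt$dag[[i]])
  }
  design <- trial_design(task$n_nodes)
  dmat <- function(d) as.matrix(data.frame(d$dag_id, d$cause, d$effect))
  dtrue <- dmat(design[design$label, ])
  dfalse <- dmat(design[!design$label, ])
  storage.mode(dtrue) <- "integer"
  storage.mode(dfalse) <- "integer"
  function(nb) {
    b <- cpp_generate_batch(nb, adj, topo, dtrue, dfalse,
                            task$params$p_spont, task$params$p_cause,
                            task$n_obs, task$steps_per_obs, task$gap_steps,
                            task$settle_steps, task$query_amplitude)
    b$labels <- as.integer(b$labels)
    b
  }
}
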