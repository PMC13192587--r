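# keep reporting through genuinely red end-to-end assertions
options(testthat.progress.max_fails = 1000L)

# Shared fixtures built in code.

# small task for fast unit tests (not the study conditions)
tiny_task <- function(...) {
  task_config(n_obs = 10, steps_per_obs = 1, settle_steps = 3, ...)
}

# a tiny random network wrapped as a dag_rnn
tiny_model <- function(task = tiny_task(), J = 16, seed = 42) {
  untrained_rnn(task, train_config(J = J, seed = seed, n_steps = 1))
}

# Rank-one tanh system with an approximate fixed line along `v`:
# W = v v^T (unit v), B = 0. Near the origin tanh is ~identity, so every
# small multiple of v is a near-fixed state; exact fixed points obey
# s = v^T tanh(v s).
line_system <- function(J = 8, seed = 7, M = 6) {
  set.seed(seed)
  v <- rnorm(J)
  v <- v / sqrt(sum(v^2))
  structure(list(W = v %*% t(v), B = matrix(0, J, M), C = rep(0, J),
                 alpha = 0.5, J = as.integer(J), M = as.integer(M),
                 v = v), class = "rnn_params")
}

# brute-force acyclicity oracle: search all node orderings
acyclic_by_enumeration <- function(edges, n_nodes) {
  if (nrow(edges) == 0) return(TRUE)
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    unlist(lapply(seq_along(x), function(i)
      lapply(perms(x[-i]), function(p) c(x[i], p))), recursive = FALSE)
  }
  any(vapply(perms(seq_len(n_nodes)), function(ord) {
    pos <- match(seq_len(n_nodes), ord)
    all(pos[edges[, 1]] < pos[edges[, 2]])
  }, logical(1)))
}
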