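#' Judge a set of causal queries on fixed observations
#'
#' Generic judgment interface shared by trained networks ([train_rnn()]) and
#' the Bayesian [ideal_observer()]: given one observation sequence, return
#' the judgment probability for each requested ordered query. For a
#' `dag_rnn` the probability is the mean sigmoid output over the terminal
#' loss window of one simulation per query (observations held identical);
#' for the ideal observer it is the posterior edge marginal.
#'
#' @param model a `dag_rnn` or `ideal_observer`.
#' @param obs an `observation_sequence`.
#' @param task a `task_config` (defaults to the model's training task for
#'   `dag_rnn`; required layout information for input construction).
#' @param queries tibble of queries (default: all ordered pairs).
#' @return tibble with columns `cause`, `effect`, `query_label`, `prob`,
#'   `judgment` (prob > 0.5).
#' @export
judge_queries <- function(model, obs, task = NULL, queries = NULL) {
  UseMethod("judge_queries")
}

#' @export
judge_queries.dag_rnn <- function(model, obs, task = NULL, queries = NULL) {
  task <- task %||% model$task
  queries <- queries %||% all_queries(task$n_nodes)
  win <- max(1L, as.integer(ceiling(model$cfg$loss_window * trial_length(task))))
  prob <- purrr::map2_dbl(queries$cause, queries$effect, function(ci, ei) {
    u <- build_input_sequence(obs, causal_query(ci, ei), task)
    traj <- simulate_rnn(model$params, u)
    mean(utils::tail(traj$outputs, win))
  })
  dplyr::mutate(queries, prob = prob, judgment = prob > 0.5)
}

#' @export
judge_queries.ideal_observer <- function(model, obs, task = NULL, queries = NULL) {
  n <- nrow(obs$activity)
  queries <- queries %||% all_queries(n)
  post <- posterior_over_dags(obs, model$params)
  prob <- purrr::map2_dbl(queries$cause, queries$effect, function(ci, ei)
    post$edge_posterior[ci, ei])
  dplyr::mutate(queries, prob = prob, judgment = prob > 0.5)
}

#' Implicit whole-graph readout
#'
#' Cycles through every ordered causal query with the observation sequence
#' held fixed and thresholds the terminal judgments, assembling the model's
#' implied adjacency matrix -- although the network is only ever trained on a
#' single query per observation sequence.
#'
#' @param model a `dag_rnn` or `ideal_observer`.
#' @param obs an `observation_sequence`.
#' @param task a `task_config`.
#' @return object of class `adjacency_estimate`: list with `matrix` (N x N
#'   0/1, zero diagonal) and `judgments` (the [judge_queries()] tibble).
#' @export
implicit_graph_readout <- function(model, obs, task = NULL) {
  j <- judge_queries(model, obs, task)
  n <- nrow(obs$activity)
  adj <- matrix(0L, n, n, dimnames = list(node_labels(n), node_labels(n)))
  adj[cbind(j$cause, j$effect)] <- as.integer(j$judgment)
  structure(list(matrix = adj, judgments = j), class = "adjacency_estimate")
}

#' @export
print.adjacency_estimate <- function(x, ...) {
  cat("<adjacency_estimate>\n")
  print(x$matrix)
  invisible(x)
}

#' Fraction of agreeing edge judgments between two adjacency estimates
#'
#' Compares the two boolean matrices over all ordered off-diagonal pairs.
#'
#' @param a,b `adjacency_estimate` objects (or plain 0/1 matrices) on the
#'   same node set.
#' @return fraction in `[0, 1]`; 1 iff the estimates are identical.
#' @export
graph_similarity <- function(a, b) {
  ma <- if (inherits(a, "adjacency_estimate")) a$matrix else as.matrix(a)
  mb <- if (inherits(b, "adjacency_estimate")) b$matrix else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("adjacency estimates differ in size")
  off <- row(ma) != col(ma)
  mean((ma[off] > 0) == (mb[off] > 0))
}

#' Marginal-preserving shuffle control for the implicit graph readout
#'
#' Repeats the whole-graph readout on independently circular-shuffled copies
#' of the observations (all marginal statistics preserved, cross-node
#' covariance destroyed) and reports each copy's similarity to the
#' unshuffled readout. A model relying on joint structure loses the graph
#' under this control; one reading only marginal rates would not.
#'
#' @param model a `dag_rnn` or `ideal_observer`.
#' @param obs an `observation_sequence`.
#' @param task a `task_config`.
#' @param n_shuffles number of shuffled copies.
#' @param seed optional integer seed.
#' @return tibble with columns `shuffle` (0 = the unshuffled reference,
#'   similarity 1 by construction) and `similarity`.
#' @export
marginal_shuffle_control <- function(model, obs, task = NULL, n_shuffles = 100,
                                     seed = NULL) {
  ref <- implicit_graph_readout(model, obs, task)
  with_seed(seed, {
    sims <- vapply(seq_len(n_shuffles), function(i) {
      sh <- circular_shuffle_all(obs)
      graph_similarity(implicit_graph_readout(model, sh, task), ref)
    }, numeric(1))
    tibble::tibble(shuffle = 0:n_shuffles, similarity = c(1, sims))
  })
}

#' Pearson correlation matrix of node activities
#'
#' The symmetric correlation structure of an observation sequence; used as a
#' control showing that asymmetric graph readouts cannot be reproduced by
#' thresholding correlations. Constant rows yield correlation 0 with a
#' warning.
#'
#' @param obs an `observation_sequence` with K >= 2 columns.
#' @return N x N correlation matrix (unit diagonal).
#' @export
correlation_control <- function(obs) {
  v <- obs$activity
  if (ncol(v) < 2) stop("need at least two observation columns")
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    warning("constant node activity: correlations involving it set to 0")
  cc <- suppressWarnings(stats::cor(t(v)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Randomization test: does the model use a non-queried node?
#'
#' Generates trials from a fixed DAG and a fixed query, then scores the
#' model's decisions on intact observations vs observations in which one
#' non-queried node's activity has been circularly shuffled. If the model
#' leverages the shuffled node (e.g. to explain away a common cause), the
#' shuffled accuracy drops. Significance is assessed with a rank-based
#' paired test (Wilcoxon signed-rank) on per-block accuracies.
#'
#' @param model a `dag_rnn` or `ideal_observer`.
#' @param dag the generating `causal_dag`.
#' @param query the judged `causal_query`.
#' @param shuffle_node node to randomize; must not be the queried cause or
#'   effect.
#' @param n_trials number of paired trials.
#' @param task a `task_config`.
#' @param seed optional integer seed.
#' @param block trials per block for the paired test (avoids degenerate
#'   all-0/1 pairs).
#' @return object of class `randomization_test`: list with `accuracy_control`,
#'   `accuracy_shuffled`, `difference`, `p_value`, `blocks` tibble, and the
#'   call parameters.
#' @export
randomization_test <- function(model, dag, query, shuffle_node, n_trials = 500,
                               task = NULL, seed = NULL, block = 50) {
  task <- task %||% model$task
  if (shuffle_node %in% c(query$cause, query$effect))
    stop("`shuffle_node` must not be one of the queried nodes")
  label <- has_edge(dag, query$cause, query$effect)
  with_seed(seed, {
    correct_c <- logical(n_trials)
    correct_s <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      obs <- sample_observations(dag, task$n_obs, task$params)
      sh <- circular_shuffle_node(obs, shuffle_node)
      jc <- judge_queries(model, obs, task,
                          tibble::tibble(cause = query$cause, effect = query$effect))
      js <- judge_queries(model, sh, task,
                          tibble::tibble(cause = query$cause, effect = query$effect))
      correct_c[i] <- jc$judgment == label
      correct_s[i] <- js$judgment == label
    }
    nb <- floor(n_trials / block)
    idx <- rep(seq_len(nb), each = block)
    bc <- tapply(correct_c[seq_len(nb * block)], idx, mean)
    bs <- tapply(correct_s[seq_len(nb * block)], idx, mean)
    pv <- if (all(bc == bs)) 1 else
      suppressWarnings(stats::wilcox.test(bc, bs, paired = TRUE))$p.value
    structure(list(
      accuracy_control = mean(correct_c), accuracy_shuffled = mean(correct_s),
      difference = mean(correct_c) - mean(correct_s), p_value = pv,
      blocks = tibble::tibble(block = seq_len(nb), control = as.numeric(bc),
                              shuffled = as.numeric(bs)),
      dag = dag, query = query, shuffle_node = shuffle_node,
      n_trials = n_trials), class = "randomization_test")
  })
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf(paste0("<randomization_test: node %s shuffled; accuracy %.3f ",
                     "(control) vs %.3f (shuffled), p = %.2g>\n"),
              LETTERS[x$shuffle_node], x$accuracy_control, x$accuracy_shuffled,
              x$p_value))
  invisible(x)
}

#' Transitivity bias on chain DAGs
#'
#' Over chain DAGs X -> Y -> Z (all six relabelings), measures how often the
#' model judges the *absent* transitive edge X -> Z to be present. Chance
#' under balanced training is 0.5; a rate above it is the transitivity bias.
#'
#' @param model a `dag_rnn` or `ideal_observer`.
#' @param task a `task_config`.
#' @param n_trials total number of trials (spread over the six chains).
#' @param seed optional integer seed.
#' @return object of class `transitivity_bias`: list with `bias_rate` (the
#'   X->Z false-positive rate), and `by_query` tibble of accuracy for every
#'   query on chain DAGs.
#' @export
transitivity_bias <- function(model, task = NULL, n_trials = 600, seed = NULL) {
  task <- task %||% model$task
  dt <- dag_table(task$n_nodes)
  chains <- dt$dag[dt$category == "chain"]
  with_seed(seed, {
    rows <- list()
    per <- max(1L, floor(n_trials / length(chains)))
    for (dag in chains) {
      e <- dag$edges
      ## identify X -> Y -> Z
      x <- setdiff(e[, 1], e[, 2]); z <- setdiff(e[, 2], e[, 1])
      for (i in seq_len(per)) {
        obs <- sample_observations(dag, task$n_obs, task$params)
        j <- judge_queries(model, obs, task)
        j$true_label <- purrr::map2_lgl(j$cause, j$effect,
                                        function(ci, ei) has_edge(dag, ci, ei))
        j$correct <- j$judgment == j$true_label
        j$is_transitive <- j$cause == x & j$effect == z
        j$dag_label <- format(dag)
        rows[[length(rows) + 1L]] <- j
      }
    }
    all <- dplyr::bind_rows(rows)
    by_query <- dplyr::summarise(
      dplyr::group_by(all, .data$query_label, .data$is_transitive),
      n = dplyr::n(), accuracy = mean(.data$correct),
      judged_true = mean(.data$judgment), .groups = "drop")
    structure(list(
      bias_rate = mean(all$judgment[all$is_transitive]),
      transitive_accuracy = mean(all$correct[all$is_transitive]),
      other_accuracy = mean(all$correct[!all$is_transitive]),
      by_query = by_query, n_trials = per * length(chains)),
      class = "transitivity_bias")
  })
}

#' @export
print.transitivity_bias <- function(x, ...) {
  cat(sprintf(paste0("<transitivity_bias: judged X->Z true on %.1f%% of chain ",
                     "trials (chance 50%%); X->Z accuracy %.3f vs %.3f on ",
                     "other queries>\n"),
              100 * x$bias_rate, x$transitive_accuracy, x$other_accuracy))
  invisible(x)
}
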