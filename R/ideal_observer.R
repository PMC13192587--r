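#' Log-likelihood of observations under a causal DAG
#'
#' The noisy-or likelihood factorizes over nodes and observation columns:
#' each activity `v[n, k]` is Bernoulli with probability
#' `activation_probability(a[n, k])`, where `a[n, k]` counts the node's
#' active parents in the same column.
#'
#' @param obs an `observation_sequence`.
#' @param dag a `causal_dag` with matching node count.
#' @param params a `noisy_or_params`.
#' @return scalar log-likelihood.
#' @export
dag_log_likelihood <- function(obs, dag, params = noisy_or_params()) {
  v <- obs$activity
  if (nrow(v) != dag$n_nodes) stop("node counts of `obs` and `dag` differ")
  pa <- parent_sets(dag)
  ll <- 0
  for (node in seq_len(dag$n_nodes)) {
    a <- if (length(pa[[node]]))
      colSums(v[pa[[node]], , drop = FALSE]) else rep(0, ncol(v))
    p <- activation_probability(a, params)
    ll <- ll + sum(v[node, ] * log(p) + (1 - v[node, ]) * log1p(-p))
  }
  ll
}

#' Exact Bayesian posterior over all enumerated DAGs
#'
#' Computes the noisy-or likelihood of the observations under every labeled
#' DAG on N nodes and normalizes against a structure prior (uniform by
#' default), yielding the exact posterior and the implied matrix of
#' edge-marginal probabilities. This ideal observer assumes the generative
#' parameters are known; it serves as the performance ceiling for the task.
#'
#' @param obs an `observation_sequence` (K = 0 columns is allowed by passing
#'   a prior-only posterior via `n_obs = 0`; see Details).
#' @param params a `noisy_or_params` (must match the generator for the
#'   ceiling interpretation).
#' @param prior optional nonnegative per-DAG weights (default uniform).
#' @return object of class `dag_posterior`: list with `dags` (tibble from
#'   [dag_table()] plus `log_lik` and `posterior` columns) and
#'   `edge_posterior` (N x N matrix of edge marginals, zero diagonal).
#' @details Log posteriors are normalized with max-subtraction for numerical
#'   stability. An `observation_sequence` always has K >= 1; to obtain the
#'   prior-predictive edge marginals use `prior_edge_marginal()`.
#' @export
posterior_over_dags <- function(obs, params = noisy_or_params(), prior = NULL) {
  n <- nrow(obs$activity)
  dt <- dag_table(n)
  m <- nrow(dt)
  if (is.null(prior)) prior <- rep(1, m)
  if (length(prior) != m || any(prior < 0)) stop("invalid prior weights")
  if (all(prior == 0)) stop("prior weights must not be all zero")
  ll <- vapply(dt$dag, function(d) dag_log_likelihood(obs, d, params), numeric(1))
  lp <- ll + log(prior)
  lp <- lp - max(lp)
  post <- exp(lp) / sum(exp(lp))
  dt$log_lik <- ll
  dt$posterior <- post
  edge_post <- matrix(0, n, n, dimnames = list(node_labels(n), node_labels(n)))
  for (i in seq_len(m)) {
    e <- dt$dag[[i]]$edges
    if (nrow(e)) edge_post[e] <- edge_post[e] + post[i]
  }
  structure(list(dags = dt, edge_posterior = edge_post, params = params),
            class = "dag_posterior")
}

#' @export
print.dag_posterior <- function(x, ...) {
  top <- x$dags[order(-x$dags$posterior), ][1, ]
  cat(sprintf("<dag_posterior over %d DAGs: MAP %s (p = %.3f)>\n",
              nrow(x$dags), top$label, top$posterior))
  invisible(x)
}

#' Prior edge marginal under the uniform structure prior
#'
#' Fraction of enumerated DAGs containing a fixed ordered edge; 8/25 = 0.32
#' for three nodes.
#'
#' @param n_nodes number of nodes.
#' @return scalar prior edge probability.
#' @export
prior_edge_marginal <- function(n_nodes = 3) {
  dags <- enumerate_dags(n_nodes)
  mean(vapply(dags, function(d) has_edge(d, 1, 2), logical(1)))
}

#' Ideal-observer judgment of a single causal query
#'
#' Posterior probability that the queried directed edge is present: the sum
#' of posterior mass over all DAGs containing it.
#'
#' @param obs an `observation_sequence`.
#' @param query a `causal_query`.
#' @param params a `noisy_or_params`.
#' @param posterior optional precomputed `dag_posterior` (avoids recomputation
#'   when judging several queries on the same observations).
#' @return probability in (0, 1); the induced decision is `> 0.5`.
#' @export
ideal_query_judgment <- function(obs, query, params = noisy_or_params(),
                                 posterior = NULL) {
  post <- posterior %||% posterior_over_dags(obs, params)
  post$edge_posterior[query$cause, query$effect]
}

#' Construct an ideal-observer judge
#'
#' A lightweight model object exposing the same judgment interface as a
#' trained `dag_rnn` (see [judge_queries()]), so behavioral probes can be run
#' with the Bayesian ceiling substituted for the network.
#'
#' @param params a `noisy_or_params` (assumed known, matching the generator).
#' @return object of class `ideal_observer`.
#' @export
ideal_observer <- function(params = noisy_or_params()) {
  structure(list(params = params), class = "ideal_observer")
}

#' @export
print.ideal_observer <- function(x, ...) {
  cat(sprintf("<ideal_observer: exact posterior, p_spont=%g, p_cause=%g>\n",
              x$params$p_spont, x$params$p_cause))
  invisible(x)
}
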