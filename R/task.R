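#' Causal query
#'
#' An ordered cause-effect pair. During a trial the query is presented as two
#' tonic one-hot input segments; the network must report whether the directed
#' edge (cause, effect) exists in the DAG that generated the observations.
#'
#' @param cause,effect 1-based node indices, `cause != effect`.
#' @return object of class `causal_query`.
#' @export
causal_query <- function(cause, effect) {
  cause <- as.integer(cause); effect <- as.integer(effect)
  if (cause == effect) stop("`cause` and `effect` must differ")
  if (cause < 1 || effect < 1) stop("node indices are 1-based")
  structure(list(cause = cause, effect = effect), class = "causal_query")
}

#' @export
print.causal_query <- function(x, ...) {
  cat(sprintf("<query: %s -> %s>\n", LETTERS[x$cause], LETTERS[x$effect]))
  invisible(x)
}

#' All ordered causal queries on N nodes
#'
#' @param n_nodes number of nodes.
#' @return tibble with columns `cause`, `effect` (1-based indices) and
#'   `query_label` (e.g. `"A>B"`); N(N-1) rows.
#' @export
all_queries <- function(n_nodes) {
  g <- expand.grid(effect = seq_len(n_nodes), cause = seq_len(n_nodes))
  g <- g[g$cause != g$effect, c("cause", "effect")]
  g <- g[order(g$cause, g$effect), ]
  tibble::tibble(
    cause = g$cause, effect = g$effect,
    query_label = paste0(LETTERS[g$cause], ">", LETTERS[g$effect])
  )
}

#' Task configuration for the causal-judgment task
#'
#' Defines how observation sequences are turned into input time series and
#' how trials are sampled. Each of the K observation columns is presented on
#' the N observation channels for `steps_per_obs` network timesteps, followed
#' by `gap_steps` of zeros; after the last observation the query-only input
#' persists for `settle_steps` further timesteps so the judgment is read out
#' after evidence ends. Total trial length is
#' `T = K (steps_per_obs + gap_steps) + settle_steps`.
#'
#' @param n_nodes number of graph nodes N (input dimension is M = 3N).
#' @param n_obs number of observation columns K per trial.
#' @param steps_per_obs timesteps each observation is held on the input.
#' @param gap_steps zero-input timesteps inserted after each observation.
#' @param settle_steps trailing query-only timesteps.
#' @param query_amplitude value of the active query channels.
#' @param params `noisy_or_params` for the generative model.
#' @param balance_labels if `TRUE`, trials are sampled so true/false labels
#'   are equally frequent (conditional sampling over (DAG, query) pairs,
#'   equivalent in law to rejection sampling of the uniform pair).
#' @return object of class `task_config`.
#' @export
task_config <- function(n_nodes = 3, n_obs = 50, steps_per_obs = 1,
                        gap_steps = 0, settle_steps = 20,
                        query_amplitude = 1.0, params = noisy_or_params(),
                        balance_labels = TRUE) {
  stopifnot(n_nodes >= 2, n_obs >= 1, steps_per_obs >= 1, gap_steps >= 0,
            settle_steps >= 0, query_amplitude > 0,
            inherits(params, "noisy_or_params"))
  cfg <- structure(list(
    n_nodes = as.integer(n_nodes), n_obs = as.integer(n_obs),
    steps_per_obs = as.integer(steps_per_obs), gap_steps = as.integer(gap_steps),
    settle_steps = as.integer(settle_steps), query_amplitude = query_amplitude,
    params = params, balance_labels = isTRUE(balance_labels)
  ), class = "task_config")
  if (trial_length(cfg) < 1) stop("total trial length must be >= 1")
  cfg
}

#' Total trial length in network timesteps
#' @param config a `task_config`.
#' @return integer T.
#' @export
trial_length <- function(config) {
  config$n_obs * (config$steps_per_obs + config$gap_steps) + config$settle_steps
}

#' Input dimension of the task
#' @param config a `task_config`.
#' @return integer M = 3 * n_nodes.
#' @export
input_dim <- function(config) 3L * config$n_nodes

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(paste0("<task_config: N=%d nodes, K=%d obs x %d steps (+%d gap), ",
                     "%d settle steps -> T=%d, M=%d; p_spont=%g, p_cause=%g, ",
                     "balanced=%s>\n"),
              x$n_nodes, x$n_obs, x$steps_per_obs, x$gap_steps, x$settle_steps,
              trial_length(x), input_dim(x), x$params$p_spont, x$params$p_cause,
              x$balance_labels))
  invisible(x)
}

#' Build the RNN input time series for one trial
#'
#' Inputs are M = 3N channels: the N node-observation channels, then N
#' one-hot cause-query channels, then N one-hot effect-query channels. The
#' query channels are tonic (constant over the whole trial); observation
#' channels carry each observation column as a `steps_per_obs`-step pulse.
#'
#' @param obs an `observation_sequence` with `config$n_obs` columns.
#' @param query a `causal_query`.
#' @param config a `task_config`.
#' @return a T x M numeric matrix.
#' @export
build_input_sequence <- function(obs, query, config) {
  v <- obs$activity
  n <- config$n_nodes
  if (nrow(v) != n) stop("observation rows do not match `config$n_nodes`")
  if (ncol(v) != config$n_obs) stop("observation columns do not match `config$n_obs`")
  if (query$cause > n || query$effect > n) stop("query node index out of range")
  T_ <- trial_length(config)
  u <- matrix(0, T_, input_dim(config))
  block <- config$steps_per_obs + config$gap_steps
  on_steps <- rep(seq_len(config$n_obs) - 1L, each = config$steps_per_obs) * block +
    rep(seq_len(config$steps_per_obs), config$n_obs)
  u[on_steps, seq_len(n)] <- t(v)[rep(seq_len(config$n_obs), each = config$steps_per_obs), ]
  u[, n + query$cause] <- config$query_amplitude
  u[, 2L * n + query$effect] <- config$query_amplitude
  u
}

#' Recover observations and query from an input matrix
#'
#' Inverse of [build_input_sequence()] given the same `config`; used for
#' round-trip checks.
#'
#' @param u a T x M input matrix produced by [build_input_sequence()].
#' @param config the `task_config` used to build it.
#' @return list with `activity` (N x K matrix) and `query`.
#' @export
invert_input_sequence <- function(u, config) {
  n <- config$n_nodes
  block <- config$steps_per_obs + config$gap_steps
  first_steps <- (seq_len(config$n_obs) - 1L) * block + 1L
  act <- t(u[first_steps, seq_len(n), drop = FALSE])
  storage.mode(act) <- "integer"
  cause <- which(u[1, n + seq_len(n)] > 0)
  effect <- which(u[1, 2L * n + seq_len(n)] > 0)
  list(activity = act, query = causal_query(cause, effect))
}

# (dag, query, label) design table used for trial sampling; memoized --
# trial generation sits inside the training loop.
.design_cache <- new.env(parent = emptyenv())

trial_design <- function(n_nodes) {
  key <- paste0("design", n_nodes)
  if (!is.null(.design_cache[[key]])) return(.design_cache[[key]])
  dt <- dag_table(n_nodes)
  q <- all_queries(n_nodes)
  design <- tidyr::crossing(dag_id = dt$dag_id, q)
  design$label <- purrr::map2_lgl(design$dag_id, seq_len(nrow(design)), function(d, i)
    has_edge(dt$dag[[d]], design$cause[i], design$effect[i]))
  attr(design, "dags") <- dt$dag
  .design_cache[[key]] <- design
  design
}

dag_table_cached <- function(n_nodes) {
  key <- paste0("dags", n_nodes)
  if (is.null(.design_cache[[key]])) .design_cache[[key]] <- dag_table(n_nodes)
  .design_cache[[key]]
}

#' Generate one trial of the causal-judgment task
#'
#' Draws a DAG uniformly from the enumerated set (unless `fixed_dag`), a
#' query uniformly from ordered pairs (unless `fixed_query`), samples K
#' observations by ancestral sampling, and assembles the input time series.
#' When `config$balance_labels` is `TRUE` and neither DAG nor query is fixed,
#' the label is drawn fair-coin first and the (DAG, query) pair uniformly
#' among pairs with that label (the conditional law of rejection sampling).
#'
#' @param config a `task_config`.
#' @param seed optional integer seed; substreams for the DAG/query draw and
#'   the observation sampling are split deterministically from it.
#' @param fixed_dag optional `causal_dag` to use instead of a random draw.
#' @param fixed_query optional `causal_query`.
#' @return object of class `trial`: list with `observations`, `query`,
#'   `label` (logical), `inputs` (T x M matrix), `dag`.
#' @export
generate_trial <- function(config, seed = NULL, fixed_dag = NULL,
                           fixed_query = NULL) {
  with_seed(seed, {
    dags <- enumerate_dags(config$n_nodes)
    q_tbl <- all_queries(config$n_nodes)
    if (is.null(fixed_dag) && is.null(fixed_query) && config$balance_labels) {
      design <- trial_design(config$n_nodes)
      lab <- stats::runif(1) < 0.5
      sub <- design[design$label == lab, ]
      pick <- sub[sample.int(nrow(sub), 1), ]
      dag <- dags[[pick$dag_id]]
      query <- causal_query(pick$cause, pick$effect)
    } else {
      dag <- if (is.null(fixed_dag)) dags[[sample.int(length(dags), 1)]] else fixed_dag
      if (is.null(fixed_query)) {
        i <- sample.int(nrow(q_tbl), 1)
        query <- causal_query(q_tbl$cause[i], q_tbl$effect[i])
      } else query <- fixed_query
    }
    obs <- sample_observations(dag, config$n_obs, config$params)
    structure(list(
      observations = obs, query = query,
      label = has_edge(dag, query$cause, query$effect),
      inputs = build_input_sequence(obs, query, config),
      dag = dag
    ), class = "trial")
  })
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("<trial: dag %s, query %s->%s, label %s, inputs %d x %d>\n",
              format(x$dag), LETTERS[x$query$cause], LETTERS[x$query$effect],
              x$label, nrow(x$inputs), ncol(x$inputs)))
  invisible(x)
}

#' Generate a batch of trials
#'
#' Vectorized batch generator used for training and evaluation. Returns the
#' inputs as an M x n x T array (the layout consumed by the compiled forward
#' and backward passes) together with a tidy per-trial table.
#'
#' @param n number of trials.
#' @param config a `task_config`.
#' @param seed optional integer seed.
#' @param fixed_dag,fixed_query optional fixed DAG / query for all trials.
#' @return list with `inputs` (M x n x T array), `labels` (0/1 vector), and
#'   `trials` (tibble: `trial`, `dag_id`, `dag_label`, `category`, `cause`,
#'   `effect`, `label`).
#' @export
generate_trials <- function(n, config, seed = NULL, fixed_dag = NULL,
                            fixed_query = NULL) {
  with_seed(seed, {
    dt <- dag_table_cached(config$n_nodes)
    dags <- dt$dag
    design <- trial_design(config$n_nodes)
    q_tbl <- all_queries(config$n_nodes)
    design_true <- design[design$label, ]
    design_false <- design[!design$label, ]
    T_ <- trial_length(config)
    M <- input_dim(config)
    U <- array(0, c(M, n, T_))
    labels <- integer(n)
    dag_ids <- integer(n); causes <- integer(n); effects <- integer(n)
    balanced <- config$balance_labels && is.null(fixed_dag) && is.null(fixed_query)
    for (b in seq_len(n)) {
      if (balanced) {
        sub <- if (stats::runif(1) < 0.5) design_true else design_false
        i <- sample.int(nrow(sub), 1)
        dag <- dags[[sub$dag_id[i]]]
        dag_ids[b] <- sub$dag_id[i]
        causes[b] <- sub$cause[i]; effects[b] <- sub$effect[i]
      } else {
        if (is.null(fixed_dag)) {
          dag_ids[b] <- sample.int(length(dags), 1)
          dag <- dags[[dag_ids[b]]]
        } else { dag <- fixed_dag; dag_ids[b] <- NA_integer_ }
        if (is.null(fixed_query)) {
          qi <- sample.int(nrow(q_tbl), 1)
          causes[b] <- q_tbl$cause[qi]; effects[b] <- q_tbl$effect[qi]
        } else { causes[b] <- fixed_query$cause; effects[b] <- fixed_query$effect }
      }
      obs <- sample_observations(dag, config$n_obs, config$params)
      labels[b] <- as.integer(has_edge(dag, causes[b], effects[b]))
      U[, b, ] <- t(build_input_sequence(obs, causal_query(causes[b], effects[b]),
                                         config))
    }
    trials <- tibble::tibble(
      trial = seq_len(n), dag_id = dag_ids,
      dag_label = ifelse(is.na(dag_ids), format(fixed_dag), dt$label[dag_ids]),
      category = if (config$n_nodes == 3)
        ifelse(is.na(dag_ids), categorize_dag(fixed_dag %||% dags[[1]]),
               dt$category[dag_ids]) else NA_character_,
      cause = causes, effect = effects, label = as.logical(labels)
    )
    list(inputs = U, labels = labels, trials = trials)
  })
}

# --- circular shuffle controls --------------------------------------------

#' Circularly shuffle one node's observation row
#'
#' Rotates the chosen node's length-K activity row by a uniformly random
#' offset in 1..K-1, leaving other rows untouched. The rotation preserves the
#' row's activation count exactly (it is a permutation) while destroying its
#' temporal alignment -- and hence covariance -- with the other nodes.
#'
#' @param obs an `observation_sequence`.
#' @param node node index to shuffle.
#' @param seed optional integer seed.
#' @param offset optional fixed rotation offset (overrides the random draw).
#' @return a new `observation_sequence`.
#' @export
circular_shuffle_node <- function(obs, node, seed = NULL, offset = NULL) {
  v <- obs$activity
  if (node < 1 || node > nrow(v)) stop("invalid node index")
  K <- ncol(v)
  if (K == 1) {
    warning("K = 1: no valid rotation offset; returning observations unchanged")
    return(obs)
  }
  with_seed(seed, {
    off <- if (is.null(offset)) sample.int(K - 1L, 1) else as.integer(offset)
    v[node, ] <- rotate_row(v[node, ], off)
    observation_sequence(v, source_dag = obs$source_dag)
  })
}

rotate_row <- function(x, off) {
  K <- length(x)
  off <- off %% K
  if (off == 0) return(x)
  c(x[(K - off + 1):K], x[1:(K - off)])
}

#' Independently circular-shuffle every node's observation row
#'
#' Applies [circular_shuffle_node()] with an independent random offset per
#' node: all marginal activity statistics are preserved exactly while
#' cross-node covariance is destroyed.
#'
#' @param obs an `observation_sequence`.
#' @param seed optional integer seed.
#' @return a new `observation_sequence`.
#' @export
circular_shuffle_all <- function(obs, seed = NULL) {
  with_seed(seed, {
    out <- obs
    for (node in seq_len(nrow(obs$activity)))
      out <- circular_shuffle_node(out, node)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
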