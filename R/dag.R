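#' Construct a labeled causal DAG
#'
#' A `causal_dag` is a directed acyclic graph over `n_nodes` nodes (labeled
#' `A`, `B`, `C`, ... and indexed 1..N in R) whose directed edges encode
#' causal relations: an edge `(i, j)` means node `i` causes node `j`.
#'
#' @param edges integer matrix with two columns (`cause`, `effect`), one row
#'   per directed edge, using 1-based node indices. `NULL` or a zero-row
#'   matrix gives the empty graph.
#' @param n_nodes number of nodes (positive integer).
#' @return An object of class `causal_dag` with fields `n_nodes` and `edges`
#'   (an m x 2 integer matrix in canonical sorted order).
#' @examples
#' fork <- causal_dag(rbind(c(3, 1), c(3, 2)), n_nodes = 3)  # C causes A and B
#' categorize_dag(fork)
#' @export
causal_dag <- function(edges = NULL, n_nodes = 3) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1, n_nodes >= 1)
  n_nodes <- as.integer(n_nodes)
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0)) {
    edges <- matrix(integer(0), ncol = 2)
  }
  if (!is.matrix(edges)) edges <- matrix(as.integer(edges), ncol = 2, byrow = TRUE)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2) stop("`edges` must have two columns (cause, effect)")
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge indices must lie in [1, n_nodes]")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (!is_acyclic(edges, n_nodes)) stop("edges contain a directed cycle")
  dimnames(edges) <- list(NULL, c("cause", "effect"))
  structure(list(n_nodes = n_nodes, edges = edges), class = "causal_dag")
}

#' @export
print.causal_dag <- function(x, ...) {
  lab <- node_labels(x$n_nodes)
  cat(sprintf("<causal_dag: %d nodes, %d edges>\n", x$n_nodes, nrow(x$edges)))
  if (nrow(x$edges) > 0)
    cat(" ", paste(lab[x$edges[, 1]], "->", lab[x$edges[, 2]], collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.causal_dag <- function(x, ...) {
  lab <- node_labels(x$n_nodes)
  if (nrow(x$edges) == 0) return("(empty)")
  paste(lab[x$edges[, 1]], lab[x$edges[, 2]], sep = ">", collapse = ",")
}

node_labels <- function(n) LETTERS[seq_len(n)]

#' Test whether an edge set is acyclic
#'
#' Kahn peeling: repeatedly remove in-degree-zero nodes; the edge set is
#' acyclic iff every node is removed (equivalently a topological order exists).
#'
#' @param edges m x 2 integer matrix of (cause, effect) pairs, 1-based.
#' @param n_nodes number of nodes.
#' @return `TRUE` iff the directed graph has no cycle.
#' @export
is_acyclic <- function(edges, n_nodes) {
  if (is.null(edges) || nrow(edges) == 0) return(TRUE)
  if (any(edges < 1) || any(edges > n_nodes)) stop("invalid node index in edges")
  indeg <- tabulate(edges[, 2], n_nodes)
  alive <- rep(TRUE, n_nodes)
  repeat {
    src <- which(alive & indeg == 0L)
    if (length(src) == 0) break
    alive[src] <- FALSE
    kids <- edges[edges[, 1] %in% src, 2]
    if (length(kids)) indeg <- indeg - tabulate(kids, n_nodes)
  }
  !any(alive)
}

#' Topological order of a causal DAG
#'
#' @param dag a `causal_dag`.
#' @return integer vector of node indices such that every edge points from an
#'   earlier to a later position.
#' @export
topological_order <- function(dag) {
  n <- dag$n_nodes
  e <- dag$edges
  indeg <- tabulate(e[, 2], n)
  alive <- rep(TRUE, n)
  ord <- integer(0)
  while (length(ord) < n) {
    src <- which(alive & indeg == 0L)
    alive[src] <- FALSE
    ord <- c(ord, src)
    kids <- e[e[, 1] %in% src, 2]
    if (length(kids)) indeg <- indeg - tabulate(kids, n)
  }
  ord
}

#' Does the DAG contain a directed edge?
#'
#' @param dag a `causal_dag`.
#' @param cause,effect 1-based node indices.
#' @return logical.
#' @export
has_edge <- function(dag, cause, effect) {
  any(dag$edges[, 1] == cause & dag$edges[, 2] == effect)
}

#' Adjacency matrix of a causal DAG
#'
#' Row = cause, column = effect.
#'
#' @param dag a `causal_dag`.
#' @return an N x N 0/1 integer matrix with zero diagonal.
#' @export
adjacency_matrix <- function(dag) {
  n <- dag$n_nodes
  adj <- matrix(0L, n, n, dimnames = list(node_labels(n), node_labels(n)))
  if (nrow(dag$edges)) adj[dag$edges] <- 1L
  adj
}

#' Enumerate all labeled DAGs on a small number of nodes
#'
#' Filters every subset of the n(n-1) possible directed edges through the
#' acyclicity test. There are 1, 3, 25 and 543 labeled DAGs on 1-4 nodes;
#' larger node counts are refused as a combinatorial guard. The returned
#' order is deterministic (by edge count, then lexicographic edge set).
#'
#' @param n_nodes number of nodes, between 1 and 4.
#' @return list of `causal_dag` objects.
#' @examples
#' length(enumerate_dags(3))  # 25
#' @export
enumerate_dags <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1 || n_nodes > 4)
    stop("enumerate_dags supports 1 to 4 nodes (4 nodes already yields 543 DAGs)")
  pairs <- which(matrix(TRUE, n_nodes, n_nodes) & !diag(n_nodes) > 0, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  m <- nrow(pairs)
  if (m == 0) return(list(causal_dag(NULL, n_nodes)))
  dags <- list()
  for (code in 0:(2^m - 1)) {
    sel <- bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) != 0L
    e <- pairs[sel, , drop = FALSE]
    if (is_acyclic(e, n_nodes)) dags[[length(dags) + 1L]] <- causal_dag(e, n_nodes)
  }
  key <- vapply(dags, function(d)
    sprintf("%02d|%s", nrow(d$edges),
            paste(sprintf("%d%d", d$edges[, 1], d$edges[, 2]), collapse = ",")),
    character(1))
  dags[order(key)]
}

#' Classify a three-node DAG into one of six structural categories
#'
#' The 25 labeled DAGs on three nodes partition into: the empty DAG (1),
#' single-edge DAGs (6), forks -- two edges sharing a parent (3), colliders
#' -- two edges sharing a child (3), chains -- two edges forming a directed
#' path (6), and mediators -- all three-edge DAGs, a chain plus the direct
#' shortcut edge (6).
#'
#' @param dag a three-node `causal_dag`.
#' @return one of `"empty"`, `"single_edge"`, `"fork"`, `"collider"`,
#'   `"chain"`, `"mediator"`.
#' @export
categorize_dag <- function(dag) {
  if (!inherits(dag, "causal_dag")) stop("`dag` must be a causal_dag")
  if (dag$n_nodes != 3) stop("DAG categories are defined for 3-node DAGs only")
  e <- dag$edges
  switch(as.character(nrow(e)),
    "0" = "empty",
    "1" = "single_edge",
    "3" = "mediator",
    "2" = {
      if (e[1, 1] == e[2, 1]) "fork"
      else if (e[1, 2] == e[2, 2]) "collider"
      else "chain"
    },
    stop("unreachable: a 3-node DAG has at most 3 edges"))
}

#' Enumerated three-node DAGs as a tibble
#'
#' One row per labeled DAG with its category and edge count; a tidy entry
#' point to the enumeration.
#'
#' @param n_nodes number of nodes (categories are only filled for 3).
#' @return tibble with columns `dag_id`, `dag` (list column of `causal_dag`),
#'   `label` (compact edge string), `n_edges`, `category`.
#' @export
dag_table <- function(n_nodes = 3) {
  dags <- enumerate_dags(n_nodes)
  tibble::tibble(
    dag_id = seq_along(dags),
    dag = dags,
    label = vapply(dags, format, character(1)),
    n_edges = vapply(dags, function(d) nrow(d$edges), integer(1)),
    category = if (n_nodes == 3)
      vapply(dags, categorize_dag, character(1)) else NA_character_
  )
}

# --- noisy-or parameterization -------------------------------------------

#' Noisy-or parameters
#'
#' Under the noisy-or model a node activates spontaneously with probability
#' `p_spont`, or is activated by each currently-active parent independently
#' with probability `p_cause`, giving activation probability
#' \deqn{p(v = 1 \mid a) = 1 - (1 - p_{spont}) (1 - p_{cause})^{a}}
#' where `a` is the number of active parents.
#'
#' @param p_spont spontaneous activation probability, strictly in (0, 1).
#' @param p_cause per-parent transmission probability, strictly in (0, 1).
#' @return object of class `noisy_or_params`.
#' @export
noisy_or_params <- function(p_spont = 0.1, p_cause = 0.9) {
  stopifnot(length(p_spont) == 1, length(p_cause) == 1)
  if (!(p_spont > 0 && p_spont < 1)) stop("`p_spont` must be strictly inside (0, 1)")
  if (!(p_cause > 0 && p_cause < 1)) stop("`p_cause` must be strictly inside (0, 1)")
  structure(list(p_spont = p_spont, p_cause = p_cause), class = "noisy_or_params")
}

#' @export
print.noisy_or_params <- function(x, ...) {
  cat(sprintf("<noisy_or_params: p_spont = %g, p_cause = %g>\n", x$p_spont, x$p_cause))
  invisible(x)
}

#' Noisy-or activation probability
#'
#' @param n_active_parents nonnegative integer (vectorized).
#' @param params a `noisy_or_params`.
#' @return probability of activation; strictly increasing in
#'   `n_active_parents` and bounded in `[p_spont, 1)`.
#' @examples
#' activation_probability(2, noisy_or_params(0.1, 0.5))  # 0.775
#' @export
activation_probability <- function(n_active_parents, params = noisy_or_params()) {
  if (any(n_active_parents < 0)) stop("`n_active_parents` must be nonnegative")
  1 - (1 - params$p_spont) * (1 - params$p_cause)^n_active_parents
}

#' Sample binary observations from a causal DAG by ancestral sampling
#'
#' Each observation column is drawn independently: nodes are visited in
#' topological order and each node makes a Bernoulli draw with the noisy-or
#' activation probability given its currently-active parent count in the
#' same column.
#'
#' @param dag a `causal_dag`.
#' @param n_obs number of observation columns K (>= 1).
#' @param params a `noisy_or_params`.
#' @param seed optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is untouched.
#' @return an `observation_sequence`: an N x K 0/1 integer matrix (`activity`)
#'   with the generating DAG attached as `source_dag`.
#' @export
sample_observations <- function(dag, n_obs, params = noisy_or_params(), seed = NULL) {
  stopifnot(inherits(dag, "causal_dag"), n_obs >= 1)
  with_seed(seed, {
    n <- dag$n_nodes
    v <- matrix(0L, n, n_obs)
    pa <- parent_sets(dag)
    for (node in topological_order(dag)) {
      a <- if (length(pa[[node]]))
        colSums(v[pa[[node]], , drop = FALSE]) else rep(0, n_obs)
      v[node, ] <- stats::rbinom(n_obs, 1L, activation_probability(a, params))
    }
    observation_sequence(v, source_dag = dag)
  })
}

parent_sets <- function(dag) {
  lapply(seq_len(dag$n_nodes), function(j) dag$edges[dag$edges[, 2] == j, 1])
}

#' Construct an observation sequence
#'
#' @param activity N x K matrix of 0/1 node activities (rows = nodes,
#'   columns = observation index).
#' @param source_dag optional `causal_dag` provenance.
#' @return object of class `observation_sequence`.
#' @export
observation_sequence <- function(activity, source_dag = NULL) {
  activity <- as.matrix(activity)
  if (!all(activity %in% c(0, 1))) stop("activities must be exactly 0 or 1")
  if (ncol(activity) < 1) stop("need at least one observation column")
  storage.mode(activity) <- "integer"
  rownames(activity) <- node_labels(nrow(activity))
  structure(list(activity = activity, source_dag = source_dag),
            class = "observation_sequence")
}

#' @export
print.observation_sequence <- function(x, ...) {
  cat(sprintf("<observation_sequence: %d nodes x %d observations, mean activity %.3f>\n",
              nrow(x$activity), ncol(x$activity), mean(x$activity)))
  invisible(x)
}

#' @export
dim.observation_sequence <- function(x) dim(x$activity)

# --- seeding helper -------------------------------------------------------

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's state afterwards. seed = NULL uses (and advances) the current RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic substream seeds: mix a master seed with a stream index.
# Kept below 2^31 so the result is a valid R integer seed.
split_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}
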