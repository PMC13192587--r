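#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted network
#'
#' @param x a `dag_rnn`.
#' @param ... unused.
#' @return tibble with one row per held-out evaluation: `step`, `loss`,
#'   `train_accuracy`, `holdout_accuracy`.
#' @export
tidy.dag_rnn <- function(x, ...) x$history

#' One-row summary of a fitted network
#'
#' @param x a `dag_rnn`.
#' @param ... unused.
#' @return tibble with `J`, `alpha`, `n_nodes`, `steps_trained`,
#'   `final_loss`, `holdout_accuracy` (best monitored).
#' @export
glance.dag_rnn <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    J = x$params$J, alpha = x$params$alpha, n_nodes = x$task$n_nodes,
    steps_trained = if (nrow(h)) max(h$step) else 0L,
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    holdout_accuracy = if (nrow(h)) max(h$holdout_accuracy) else NA_real_)
}

#' Tidy a DAG posterior
#'
#' @param x a `dag_posterior`.
#' @param ... unused.
#' @return tibble with one row per enumerated DAG: `dag_id`, `label`,
#'   `category`, `n_edges`, `log_lik`, `posterior`.
#' @export
tidy.dag_posterior <- function(x, ...) {
  dplyr::select(x$dags, "dag_id", "label", "category", "n_edges",
                "log_lik", "posterior")
}

#' One-row summary of a DAG posterior
#'
#' @param x a `dag_posterior`.
#' @param ... unused.
#' @return tibble with `map_label` (posterior-mode DAG), `map_posterior`,
#'   `entropy` (nats), `n_dags`.
#' @export
glance.dag_posterior <- function(x, ...) {
  p <- x$dags$posterior
  i <- which.max(p)
  tibble::tibble(map_label = x$dags$label[i], map_posterior = p[i],
                 entropy = -sum(ifelse(p > 0, p * log(p), 0)),
                 n_dags = nrow(x$dags))
}

#' Tidy an accuracy evaluation
#'
#' @param x an `rnn_evaluation`.
#' @param ... unused.
#' @return the per-query accuracy tibble.
#' @export
tidy.rnn_evaluation <- function(x, ...) x$by_query

#' One-row summary of an accuracy evaluation
#'
#' @param x an `rnn_evaluation`.
#' @param ... unused.
#' @return tibble with `accuracy` and `n_trials`.
#' @export
glance.rnn_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_trials = x$n_trials)
}

#' Tidy a line attractor
#'
#' @param x a `line_attractor`.
#' @param ... unused.
#' @return tibble with one row per fixed point, ordered along the judgment
#'   axis: `point`, `projection`, `output`, `speed`, `top_eigenvalue_re`.
#' @export
tidy.line_attractor <- function(x, ...) {
  tibble::tibble(
    point = seq_along(x$points),
    projection = x$projections,
    output = x$outputs,
    speed = vapply(x$points, `[[`, numeric(1), "speed"),
    top_eigenvalue_re = vapply(x$points, function(p) Re(p$top_eigenvalue),
                               numeric(1)))
}

#' One-row summary of a line attractor
#'
#' @param x a `line_attractor`.
#' @param ... unused.
#' @return tibble with `query`, `n_points`, `explained_variance`,
#'   `length` (span of axis projections), `mean_interior_eigenvalue`.
#' @export
glance.line_attractor <- function(x, ...) {
  tibble::tibble(
    query = paste0(LETTERS[x$query$cause], ">", LETTERS[x$query$effect]),
    n_points = length(x$points),
    explained_variance = x$explained_variance,
    length = diff(range(x$projections)),
    mean_interior_eigenvalue = mean(vapply(interior_points(x),
                                           function(p) Re(p$top_eigenvalue),
                                           numeric(1))))
}
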