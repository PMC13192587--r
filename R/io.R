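#' Serialize a causal DAG to JSON
#'
#' The on-disk schema uses 0-based node indices
#' (`{"n_nodes": 3, "edges": [[0,1], ...]}`); the R API is 1-based.
#'
#' @param dag a `causal_dag`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
dag_to_json <- function(dag, path = NULL) {
  edges <- lapply(seq_len(nrow(dag$edges)), function(i)
    unname(dag$edges[i, ] - 1L))
  obj <- list(n_nodes = dag$n_nodes, edges = edges)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a causal DAG from JSON
#'
#' @param path file path or a JSON string.
#' @return a `causal_dag`.
#' @export
dag_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  e <- obj$edges
  e <- if (length(e) == 0) NULL
  else if (is.matrix(e)) matrix(as.integer(e), ncol = 2) + 1L
  else matrix(as.integer(do.call(rbind, e)), ncol = 2) + 1L
  causal_dag(e, obj$n_nodes)
}

#' Save observations with provenance
#'
#' Writes the activity matrix together with the generating DAG, noisy-or
#' parameters and seed (when known) as a single JSON document.
#'
#' @param obs an `observation_sequence`.
#' @param path output file.
#' @param params optional `noisy_or_params` provenance.
#' @param seed optional seed provenance.
#' @return `path`, invisibly.
#' @export
save_observations <- function(obs, path, params = NULL, seed = NULL) {
  obj <- list(
    schema = "causaljudge/observations/v1",
    activity = unname(apply(obs$activity, 1, as.integer, simplify = FALSE)),
    dag = if (!is.null(obs$source_dag))
      jsonlite::fromJSON(dag_to_json(obs$source_dag)) else NULL,
    params = if (!is.null(params)) unclass(params) else NULL,
    seed = seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load observations saved by [save_observations()]
#'
#' @param path input file.
#' @return an `observation_sequence` (with `source_dag` when recorded).
#' @export
load_observations <- function(path) {
  obj <- jsonlite::fromJSON(path)
  act <- if (is.matrix(obj$activity)) obj$activity
  else do.call(rbind, lapply(obj$activity, as.integer))
  dag <- if (!is.null(obj$dag)) {
    e <- obj$dag$edges
    causal_dag(if (length(e)) matrix(as.integer(e), ncol = 2) + 1L else NULL,
               obj$dag$n_nodes)
  } else NULL
  observation_sequence(act, source_dag = dag)
}

MODEL_SCHEMA <- "causaljudge/model/v1"

#' Save a trained model
#'
#' Writes the weights, task and training configuration, training history and
#' provenance as a versioned hierarchical JSON archive at full double
#' precision, so save/load round-trips are lossless.
#'
#' @param model a `dag_rnn`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(
    schema = MODEL_SCHEMA,
    package_version = as.character(utils::packageVersion("causaljudge")),
    params = list(W = model$params$W, B = model$params$B, C = model$params$C,
                  alpha = model$params$alpha, J = model$params$J,
                  M = model$params$M),
    task = c(unclass(model$task)[setdiff(names(model$task), "params")],
             list(params = unclass(model$task$params))),
    cfg = unclass(model$cfg),
    history = as.list(model$history))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path input file.
#' @return a `dag_rnn`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e)))
  if (!identical(obj$schema, MODEL_SCHEMA))
    stop("unsupported model schema: ", obj$schema %||% "<missing>")
  p <- obj$params
  params <- structure(list(
    W = matrix(unlist(p$W), p$J, p$J), B = matrix(unlist(p$B), p$J, p$M),
    C = as.numeric(p$C), alpha = p$alpha, J = as.integer(p$J),
    M = as.integer(p$M)), class = "rnn_params")
  tk <- obj$task
  task <- task_config(tk$n_nodes, tk$n_obs, tk$steps_per_obs, tk$gap_steps,
                      tk$settle_steps, tk$query_amplitude,
                      noisy_or_params(tk$params$p_spont, tk$params$p_cause),
                      tk$balance_labels)
  cfg <- do.call(train_config,
                 obj$cfg[intersect(names(obj$cfg), names(formals(train_config)))])
  structure(list(params = params, task = task, cfg = cfg,
                 history = tibble::as_tibble(obj$history)),
            class = "dag_rnn")
}

#' Run the full reproduction pipeline
#'
#' Trains (or loads) a model on the judgment task, then runs the behavioral
#' and dynamical analysis suites, writing CSV/JSON outputs and a
#' machine-readable summary of every check to `out_dir`.
#'
#' @param task a `task_config`.
#' @param cfg a `train_config`.
#' @param out_dir output directory (created if needed).
#' @param model optional pre-trained `dag_rnn` (skips training).
#' @param seed master seed; all stage seeds derive from it deterministically.
#' @param n_eval_trials trials for the headline accuracy evaluation.
#' @param dynamics run the fixed-point / line-attractor suite.
#' @param behavior run the behavioral suite.
#' @param dry_run validate the configuration and print the plan only.
#' @param quiet suppress progress output.
#' @return invisible list with `model`, `evaluation`, `behavior`, `dynamics`,
#'   `summary` (tibble of named checks and values).
#' @export
run_pipeline <- function(task = task_config(), cfg = train_config(),
                         out_dir = "causaljudge_run", model = NULL,
                         seed = 1, n_eval_trials = 2000, dynamics = TRUE,
                         behavior = TRUE, dry_run = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  plan <- sprintf(
    "pipeline: %d-node task (K=%d, T=%d) | J=%d, <=%d steps | eval %d trials | behavior=%s dynamics=%s",
    task$n_nodes, task$n_obs, trial_length(task), cfg$J, cfg$n_steps,
    n_eval_trials, behavior, dynamics)
  say(plan)
  if (dry_run) return(invisible(list(plan = plan)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checks <- list()
  add <- function(name, value)
    checks[[length(checks) + 1L]] <<- tibble::tibble(check = name, value = value)

  if (is.null(model)) {
    cfg$seed <- split_seed(seed, 10)
    say("training...")
    model <- train_rnn(task, cfg, quiet = quiet)
    save_model(model, file.path(out_dir, "model.json"))
    utils::write.csv(model$history, file.path(out_dir, "training_history.csv"),
                     row.names = FALSE)
  }
  ev <- evaluate_accuracy(model, task, n_trials = n_eval_trials,
                          seed = split_seed(seed, 11))
  add("holdout_accuracy", ev$accuracy)
  utils::write.csv(ev$by_query, file.path(out_dir, "accuracy_by_query.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$by_category,
                   file.path(out_dir, "accuracy_by_category.csv"),
                   row.names = FALSE)
  beh <- dyn <- NULL
  if (behavior) {
    say("behavioral suite...")
    tb <- transitivity_bias(model, task, n_trials = 300,
                            seed = split_seed(seed, 12))
    add("transitivity_bias_rate", tb$bias_rate)
    chain_acc <- ev$by_category$accuracy[ev$by_category$category == "chain"]
    add("chain_category_accuracy", chain_acc)
    dt <- dag_table(task$n_nodes)
    fork <- dt$dag[dt$category == "fork"][[
      which(vapply(dt$dag[dt$category == "fork"],
                   function(d) has_edge(d, 3, 1) && has_edge(d, 3, 2),
                   logical(1)))]]
    rt <- randomization_test(model, fork, causal_query(1, 2), 3,
                             n_trials = 200, task = task,
                             seed = split_seed(seed, 13))
    add("fork_randomization_drop", rt$difference)
    obs <- sample_observations(dt$dag[[which(dt$label == "B>C,C>A")[1] %||% 2]],
                               task$n_obs, task$params,
                               seed = split_seed(seed, 14))
    msc <- marginal_shuffle_control(model, obs, task, n_shuffles = 50,
                                    seed = split_seed(seed, 15))
    add("marginal_shuffle_similarity", mean(msc$similarity[msc$shuffle > 0]))
    beh <- list(transitivity = tb, randomization = rt, shuffle = msc)
  }
  if (dynamics) {
    say("dynamics suite...")
    qs <- all_queries(task$n_nodes)
    attractors <- list()
    for (i in seq_len(nrow(qs))) {
      fps <- find_fixed_points(model, causal_query(qs$cause[i], qs$effect[i]),
                               task, seed = split_seed(seed, 20 + i))
      if (length(fps$points) >= 3)
        attractors[[length(attractors) + 1L]] <-
          build_line_attractor(fps, model$params)
    }
    add("n_line_attractors", length(attractors))
    if (length(attractors)) {
      interior <- unlist(lapply(attractors, function(a)
        vapply(interior_points(a), function(p) Re(p$top_eigenvalue), numeric(1))))
      add("mean_interior_top_eigenvalue", mean(interior))
      geom <- attractor_geometry(attractors)
      utils::write.csv(geom$pairs, file.path(out_dir, "attractor_geometry.csv"),
                       row.names = FALSE)
      add("same_vs_different_cause_distance_ratio",
          geom$summary$mean_distance[1] / geom$summary$mean_distance[2])
      dyn <- list(attractors = attractors, geometry = geom)
    }
  }
  summary <- dplyr::bind_rows(checks)
  jsonlite::write_json(stats::setNames(as.list(summary$value), summary$check),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = I(17))
  say("done: ", out_dir)
  invisible(list(model = model, evaluation = ev, behavior = beh,
                 dynamics = dyn, summary = summary))
}
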