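# One trained study-conditions model shared across the acceptance tests.
# Trained lazily on first use and memoized for the rest of the test run.

.model_cache <- new.env(parent = emptyenv())

study_task <- function() task_config()   # N = 3, K = 50, defaults

study_train_config <- function() {
  train_config(n_steps = 18000, seed = 65078, eval_every = 250,
               eval_trials = 600, target_accuracy = 0.95)
}

get_trained_model <- function() {
  if (is.null(.model_cache$model)) {
    message("training the shared study-conditions model (one-off)...")
    .model_cache$model <- train_rnn(study_task(), study_train_config(),
                                    quiet = TRUE)
  }
  .model_cache$model
}

# line attractors for all six queries, computed once from the shared model
get_attractors <- function() {
  if (is.null(.model_cache$attractors)) {
    model <- get_trained_model()
    qs <- all_queries(3)
    .model_cache$fps <- lapply(seq_len(nrow(qs)), function(i)
      find_fixed_points(model, causal_query(qs$cause[i], qs$effect[i]),
                        seed = 300 + i))
    .model_cache$attractors <- lapply(
      Filter(function(f) length(f$points) >= 3, .model_cache$fps),
      build_line_attractor, params = model$params)
  }
  .model_cache$attractors
}

get_fixed_point_sets <- function() {
  get_attractors()
  .model_cache$fps
}
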