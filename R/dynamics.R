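#' Tonic query-only input vector
#'
#' The M-vector presented between/after observations: observation channels
#' zero, the queried cause and effect one-hot at the task's query amplitude.
#'
#' @param query a `causal_query`.
#' @param task a `task_config`.
#' @return length-M numeric vector.
#' @export
query_input <- function(query, task) {
  n <- task$n_nodes
  u <- numeric(input_dim(task))
  u[n + query$cause] <- task$query_amplitude
  u[2L * n + query$effect] <- task$query_amplitude
  u
}

#' Speed of the RNN dynamics at a state
#'
#' The scalar \eqn{q(x) = \tfrac12 \lVert -x + \tanh(Wx + Bu) \rVert^2},
#' zero exactly at fixed points of the update map (for every `alpha`).
#'
#' @param x hidden state (length J).
#' @param u input vector (length M), typically a tonic [query_input()].
#' @param params an `rnn_params`.
#' @return nonnegative scalar.
#' @export
rnn_speed <- function(x, u, params) {
  g <- tanh(params$W %*% x + params$B %*% u) - x
  0.5 * sum(g^2)
}

# residual g(x) = tanh(Wx+Bu) - x and its Jacobian D W - I
speed_residual <- function(x, u, params) {
  h <- drop(params$W %*% x + params$B %*% u)
  th <- tanh(h)
  list(g = th - x, d = 1 - th^2)
}

speed_grad <- function(x, u, params) {
  r <- speed_residual(x, u, params)
  ## grad of 0.5||g||^2: (DW - I)^T g
  drop(crossprod(params$W, r$d * r$g)) - r$g
}

#' Find fixed points of the RNN under tonic query input
#'
#' Minimizes the speed function from many initial states subsampled from
#' simulated trajectories of the given query (plus isotropic jitter). The
#' minimization stops as soon as the speed drops below `tol` (slow-point
#' convention: descending to machine zero would slide every seed along the
#' slow manifold into the same exact attractor and hide the line
#' structure). Survivors are merged within `dedup_radius` (Euclidean),
#' keeping the lowest-speed representative, and each is linearized.
#'
#' @param model a `dag_rnn`.
#' @param query a `causal_query`.
#' @param task a `task_config` (defaults to the model's).
#' @param n_seeds number of initial states.
#' @param n_trials simulated trials from which seed states are drawn.
#' @param jitter isotropic Gaussian noise scale added to seed states.
#' @param tol keep candidates with speed q < tol.
#' @param dedup_radius merge radius in state space.
#' @param seed optional integer seed.
#' @return object of class `fixed_point_set`: list with `points` (list of
#'   `fixed_point`: fields `x_star`, `query`, `speed`, `jac_rec`, `jac_inp`,
#'   `values`, `right`, `left`, `top_eigenvalue`, `r`, `l`, `output`) and
#'   `summary` tibble (one row per point: `speed`, `top_eigenvalue_re`,
#'   `output`, `axis` filled later by [build_line_attractor()]).
#' @export
find_fixed_points <- function(model, query, task = NULL, n_seeds = 512,
                              n_trials = 100, jitter = 0.1, tol = 1e-8,
                              dedup_radius = 0.05, seed = NULL) {
  task <- task %||% model$task
  params <- model$params
  u <- query_input(query, task)
  with_seed(seed, {
    states <- sample_trajectory_states(model, query, task, n_trials)
    idx <- sample.int(nrow(states), n_seeds, replace = nrow(states) < n_seeds)
    seeds <- states[idx, , drop = FALSE] +
      matrix(stats::rnorm(n_seeds * params$J, 0, jitter), n_seeds)
    cands <- list()
    for (i in seq_len(n_seeds)) {
      x <- minimize_speed(seeds[i, ], u, params, tol)
      if (!is.null(x)) cands[[length(cands) + 1L]] <- x
    }
    if (!length(cands)) {
      warning("no fixed points found below tolerance for this query")
      return(structure(list(points = list(), summary = tibble::tibble(),
                            query = query), class = "fixed_point_set"))
    }
    xs <- do.call(rbind, cands)
    qs <- apply(xs, 1, function(x) rnn_speed(x, u, params))
    keep <- dedup_points(xs, qs, dedup_radius)
    pts <- lapply(keep, function(i) {
      lin <- linearize(xs[i, ], u, params)
      new_fixed_point(xs[i, ], query, qs[i], lin, params)
    })
    structure(list(points = pts, summary = fp_summary(pts), query = query),
              class = "fixed_point_set")
  })
}

# states visited during simulated trials of a query (rows = states)
sample_trajectory_states <- function(model, query, task, n_trials) {
  batch <- generate_trials(n_trials, task, fixed_query = query)
  f <- cpp_forward(model$params$W, model$params$B, matrix(model$params$C, 1),
                   model$params$alpha, batch$inputs,
                   matrix(0, model$params$J, n_trials))
  ## states: J x n_trials x T -> (n_trials*T) x J
  st <- f$states
  dm <- dim(st)
  t(matrix(st, dm[1], dm[2] * dm[3]))
}

# Minimize q from x0, stopping as soon as q < tol (slow-point convention:
# descending to machine zero would slide every seed along the slow manifold
# into the same exact attractor and lose the line structure). Returns NULL
# if the tolerance is not reached within the iteration budget.
minimize_speed <- function(x0, u, params, tol, chunk = 50, max_chunks = 80) {
  x <- x0
  q_prev <- rnn_speed(x, u, params)
  for (i in seq_len(max_chunks)) {
    if (q_prev < tol) return(x)
    o <- stats::optim(x, fn = function(x) rnn_speed(x, u, params),
                      gr = function(x) speed_grad(x, u, params),
                      method = "BFGS",
                      control = list(maxit = chunk, reltol = 1e-18))
    q <- o$value
    if (max(abs(o$par - x)) == 0) break   # converged without reaching tol
    x <- o$par
    # abandon seeds plateauing in a shallow non-zero valley of q
    if (q > tol && q > 0.5 * q_prev && i > 2) { q_prev <- q; break }
    q_prev <- q
  }
  if (rnn_speed(x, u, params) < tol) x else NULL
}

# indices of the lowest-speed representative of each cluster
dedup_points <- function(xs, qs, radius) {
  ord <- order(qs)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        min(sqrt(rowSums((xs[keep, , drop = FALSE] -
                          matrix(xs[i, ], length(keep), ncol(xs),
                                 byrow = TRUE))^2))) > radius)
      keep <- c(keep, i)
  }
  keep
}

new_fixed_point <- function(x_star, query, speed, lin, params) {
  structure(list(
    x_star = x_star, query = query, speed = speed,
    jac_rec = lin$jac_rec, jac_inp = lin$jac_inp,
    values = lin$values, right = lin$right, left = lin$left,
    top_eigenvalue = lin$values[1],
    r = lin$right[, 1], l = lin$left[1, ],
    output = stats::plogis(sum(params$C * x_star))
  ), class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point: speed %.2e, top eigenvalue %.4f%+.4fi, output %.3f>\n",
              x$speed, Re(x$top_eigenvalue), Im(x$top_eigenvalue), x$output))
  invisible(x)
}

fp_summary <- function(pts) {
  tibble::tibble(
    point = seq_along(pts),
    speed = vapply(pts, `[[`, numeric(1), "speed"),
    top_eigenvalue_re = vapply(pts, function(p) Re(p$top_eigenvalue), numeric(1)),
    top_eigenvalue_im = vapply(pts, function(p) Im(p$top_eigenvalue), numeric(1)),
    output = vapply(pts, `[[`, numeric(1), "output"))
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("<fixed_point_set: %d points for query %s->%s>\n",
              length(x$points), LETTERS[x$query$cause], LETTERS[x$query$effect]))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Linearize the RNN update around a state
#'
#' First-order expansion of the discrete update
#' \eqn{x' = (1-\alpha)x + \alpha\tanh(Wx + Bu)} gives
#' \deqn{J_{rec} = (1-\alpha) I + \alpha D W, \quad J_{inp} = \alpha D B}
#' with \eqn{D = \mathrm{diag}(1 - \tanh^2(Wx^* + Bu))}. Eigenvalues are
#' sorted by decreasing real part (ties by magnitude); left eigenvectors are
#' rows of the inverse of the right-eigenvector matrix, so biorthogonality
#' `L R = I` holds by construction, and the top left/right pair satisfies
#' `l . r = 1`.
#'
#' @param x_star state around which to linearize (length J).
#' @param u input held constant (length M).
#' @param params an `rnn_params`.
#' @return list with `jac_rec` (J x J), `jac_inp` (J x M), `values`
#'   (complex, sorted), `right` (J x J columns), `left` (J x J rows).
#' @export
linearize <- function(x_star, u, params) {
  h <- drop(params$W %*% x_star + params$B %*% u)
  d <- 1 - tanh(h)^2
  jac_rec <- (1 - params$alpha) * diag(params$J) + params$alpha * (d * params$W)
  jac_inp <- params$alpha * (d * params$B)
  es <- eigen(jac_rec)
  ord <- order(-Re(es$values), -Mod(es$values))
  values <- es$values[ord]
  right <- es$vectors[, ord, drop = FALSE]
  left <- tryCatch(solve(right), error = function(e) {
    warning("defective or near-defective spectrum: left eigenvectors via pseudo-inverse")
    ## least-squares pseudo-inverse keeps L R ~ I in the non-defective subspace
    sv <- svd(right)
    sv$v %*% diag(ifelse(sv$d > 1e-12, 1 / sv$d, 0)) %*% Conj(t(sv$u))
  })
  list(jac_rec = jac_rec, jac_inp = jac_inp, values = values,
       right = right, left = left)
}

#' Slow-eigenmode prediction of the response to one observation
#'
#' Near a fixed point with a simple real top eigenvalue \eqn{\lambda_1
#' \approx 1}, the long-horizon displacement of the state after a single
#' input \eqn{\hat w} is approximately \eqn{r\, \ell^\top J_{inp} \hat w}:
#' the input is projected onto the integrating mode by the left eigenvector
#' and re-expressed along the right eigenvector. The scalar
#' \eqn{\ell^\top J_{inp}\hat w} is the signed judgment update.
#'
#' @param fp a `fixed_point`.
#' @param w_hat length-M input vector (one observation pattern).
#' @return list with `displacement` (length-J vector along `r`) and
#'   `magnitude` (the signed scalar).
#' @export
slow_mode_prediction <- function(fp, w_hat) {
  lam <- fp$top_eigenvalue
  if (abs(Im(lam)) > 1e-10)
    stop("top eigenvalue is complex; slow-mode prediction unsupported")
  r <- Re(fp$r); l <- Re(fp$l)
  ## normalize so l . r = 1 (biorthogonal by construction, but be safe)
  s <- sum(l * r)
  if (abs(s) < 1e-12) stop("degenerate top eigenpair")
  l <- l / s
  mag <- sum(l * (fp$jac_inp %*% w_hat))
  list(displacement = r * mag, magnitude = mag)
}

#' Build a line attractor from a query's fixed points
#'
#' The judgment axis is the unit first principal component of the fixed
#' point locations, signed so that increasing projection increases the
#' sigmoid readout (the true end is positive); points are ordered by their
#' axis projection.
#'
#' @param fps a `fixed_point_set` (or list of `fixed_point`) with >= 3
#'   points for one query.
#' @param params the model's `rnn_params` (for the readout sign convention).
#' @return object of class `line_attractor`: list with `query`, `points`
#'   (sorted), `locations` (n x J matrix, sorted), `axis` (unit length-J),
#'   `centroid`, `projections` (sorted axis positions), `explained_variance`
#'   (fraction of location variance along the axis), `outputs`.
#' @export
build_line_attractor <- function(fps, params) {
  pts <- if (inherits(fps, "fixed_point_set")) fps$points else fps
  if (length(pts) < 3)
    stop("need at least 3 fixed points to fit a line attractor")
  query <- pts[[1]]$query
  X <- do.call(rbind, lapply(pts, `[[`, "x_star"))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = 1)
  axis <- drop(sv$v)
  ## sign: increasing projection must increase readout C . x
  if (sum(params$C * axis) < 0) axis <- -axis
  proj <- drop(Xc %*% axis)
  ord <- order(proj)
  ev <- if (sum(Xc^2) > 0) sv$d[1]^2 / sum(Xc^2) else 1
  structure(list(
    query = query, points = pts[ord], locations = X[ord, , drop = FALSE],
    axis = axis, centroid = ctr, projections = proj[ord],
    explained_variance = ev,
    outputs = vapply(pts, `[[`, numeric(1), "output")[ord]
  ), class = "line_attractor")
}

#' @export
print.line_attractor <- function(x, ...) {
  cat(sprintf(paste0("<line_attractor: query %s->%s, %d fixed points, ",
                     "%.1f%% variance on axis, outputs %.3f..%.3f>\n"),
              LETTERS[x$query$cause], LETTERS[x$query$effect], length(x$points),
              100 * x$explained_variance, min(x$outputs), max(x$outputs)))
  invisible(x)
}

#' Interior fixed points of a line attractor
#'
#' The middle `frac` of points by axis projection, excluding the
#' consolidating extremes where eigenstructure reorganizes.
#'
#' @param attr a `line_attractor`.
#' @param frac central fraction to keep (default 0.6).
#' @return list of `fixed_point`.
#' @export
interior_points <- function(attr, frac = 0.6) {
  p <- attr$projections
  lo <- stats::quantile(p, (1 - frac) / 2)
  hi <- stats::quantile(p, 1 - (1 - frac) / 2)
  attr$points[p >= lo & p <= hi]
}

#' All binary observation patterns on N nodes
#'
#' @param n_nodes number of nodes.
#' @return 2^N x N 0/1 matrix, rows ordered by binary code (all-zero first);
#'   row names like `"-"`, `"A"`, `"AB"`, ...
#' @export
observation_patterns <- function(n_nodes) {
  g <- as.matrix(expand.grid(rep(list(0:1), n_nodes)))[, n_nodes:1, drop = FALSE]
  g <- g[order(g %*% 2^((n_nodes - 1):0)), , drop = FALSE]
  colnames(g) <- node_labels(n_nodes)
  rownames(g) <- apply(g, 1, function(r)
    if (!sum(r)) "-" else paste(node_labels(n_nodes)[r == 1], collapse = ""))
  g
}

#' Map the effect of every observation pattern at every fixed point
#'
#' From each fixed point, presents one observation pattern for
#' `steps_per_obs` timesteps, then relaxes under query-only input for
#' `relax_steps`, recording the change in axis projection both instantly
#' (after the pulse) and after relaxation.
#'
#' @param attr a `line_attractor`.
#' @param model a `dag_rnn`.
#' @param task a `task_config`.
#' @param relax_steps relaxation horizon (timesteps).
#' @return tibble: `point` (index along the attractor), `start_projection`,
#'   `pattern`, `instant` and `relaxed` signed axis displacements.
#' @export
input_effect_map <- function(attr, model, task = NULL, relax_steps = 200) {
  task <- task %||% model$task
  params <- model$params
  uq <- query_input(attr$query, task)
  pats <- observation_patterns(task$n_nodes)
  rows <- list()
  for (i in seq_along(attr$points)) {
    x0 <- attr$points[[i]]$x_star
    p0 <- sum((x0 - attr$centroid) * attr$axis)
    for (pi in seq_len(nrow(pats))) {
      u_obs <- uq
      u_obs[seq_len(task$n_nodes)] <- pats[pi, ]
      inputs <- rbind(
        matrix(u_obs, task$steps_per_obs, length(uq), byrow = TRUE),
        matrix(uq, relax_steps, length(uq), byrow = TRUE))
      traj <- simulate_rnn(params, inputs, x0 = x0)
      pr <- drop((sweep(traj$states, 2, attr$centroid)) %*% attr$axis)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        point = i, start_projection = p0, pattern = rownames(pats)[pi],
        instant = pr[task$steps_per_obs] - p0,
        relaxed = pr[length(pr)] - p0)
    }
  }
  dplyr::bind_rows(rows)
}

#' Traverse a line attractor by repeated observations
#'
#' Repeatedly presents the same observation pattern (with query-only
#' relaxation between presentations) from a chosen fixed point and records
#' the axis projection after each presentation.
#'
#' @param model a `dag_rnn`.
#' @param attr a `line_attractor`.
#' @param start_point index of the starting fixed point along the attractor.
#' @param pattern character pattern name (e.g. `"A"`, `"AB"`, `"-"`) or a
#'   0/1 vector of node activities.
#' @param n_repeats number of presentations.
#' @param relax_steps relaxation steps between presentations.
#' @param task a `task_config`.
#' @return tibble: `presentation` (0 = start), `projection`, `output`.
#' @export
traverse_attractor <- function(model, attr, start_point = 1, pattern = "A",
                               n_repeats = 20, relax_steps = 20, task = NULL) {
  task <- task %||% model$task
  params <- model$params
  uq <- query_input(attr$query, task)
  pats <- observation_patterns(task$n_nodes)
  pv <- if (is.character(pattern)) {
    if (!pattern %in% rownames(pats)) stop("unknown pattern: ", pattern)
    pats[pattern, ]
  } else as.numeric(pattern)
  u_obs <- uq
  u_obs[seq_len(task$n_nodes)] <- pv
  x <- attr$points[[start_point]]$x_star
  proj <- function(x) sum((x - attr$centroid) * attr$axis)
  out <- numeric(n_repeats + 1)
  pos <- numeric(n_repeats + 1)
  pos[1] <- proj(x); out[1] <- stats::plogis(sum(params$C * x))
  one <- rbind(matrix(u_obs, task$steps_per_obs, length(uq), byrow = TRUE),
               matrix(uq, relax_steps, length(uq), byrow = TRUE))
  for (i in seq_len(n_repeats)) {
    traj <- simulate_rnn(params, one, x0 = x)
    x <- traj$states[nrow(traj$states), ]
    pos[i + 1] <- proj(x)
    out[i + 1] <- traj$outputs[length(traj$outputs)]
  }
  tibble::tibble(presentation = 0:n_repeats, projection = pos, output = out)
}

#' Geometry of line attractors across queries
#'
#' Pairwise Euclidean distances between attractor centroids, plus summary
#' statistics contrasting same-cause vs different-cause query pairs (and,
#' within different-cause pairs sharing structure, same-effect vs
#' different-effect).
#'
#' @param attractors list of `line_attractor`, one per ordered query.
#' @return object of class `attractor_geometry`: list with `distances`
#'   (named matrix), `pairs` tibble (`query1`, `query2`, `distance`,
#'   `same_cause`, `same_effect`) and `summary` tibble of group means.
#' @export
attractor_geometry <- function(attractors) {
  labs <- vapply(attractors, function(a)
    paste0(LETTERS[a$query$cause], ">", LETTERS[a$query$effect]), character(1))
  ctrs <- do.call(rbind, lapply(attractors, `[[`, "centroid"))
  D <- as.matrix(stats::dist(ctrs))
  dimnames(D) <- list(labs, labs)
  idx <- utils::combn(length(attractors), 2)
  pairs <- tibble::tibble(
    query1 = labs[idx[1, ]], query2 = labs[idx[2, ]],
    distance = D[t(idx)],
    same_cause = vapply(seq_len(ncol(idx)), function(k)
      attractors[[idx[1, k]]]$query$cause == attractors[[idx[2, k]]]$query$cause,
      logical(1)),
    same_effect = vapply(seq_len(ncol(idx)), function(k)
      attractors[[idx[1, k]]]$query$effect == attractors[[idx[2, k]]]$query$effect,
      logical(1)))
  summary <- tibble::tibble(
    group = c("same_cause", "different_cause", "same_effect", "different_effect"),
    mean_distance = c(
      mean(pairs$distance[pairs$same_cause]),
      mean(pairs$distance[!pairs$same_cause]),
      mean(pairs$distance[pairs$same_effect]),
      mean(pairs$distance[!pairs$same_effect & !pairs$same_cause])))
  structure(list(distances = D, pairs = pairs, summary = summary),
            class = "attractor_geometry")
}

#' @export
print.attractor_geometry <- function(x, ...) {
  cat("<attractor_geometry>\n")
  print(x$summary)
  invisible(x)
}

#' Project hidden-state trajectories onto common principal components
#'
#' Fits PCA on the pooled states of all supplied trajectories (one shared
#' reference basis) and returns each trajectory's projection plus the
#' variance-explained fractions.
#'
#' @param trajectories list of T x J state matrices (or `rnn_trajectory`
#'   objects).
#' @param n_components number of components.
#' @return object of class `pca_projection`: list with `loadings` (J x n),
#'   `center`, `variance_explained` (length n), `projected` (list of T x n
#'   matrices), `tidy` tibble (`trajectory`, `time`, `PC1`, ...).
#' @export
pca_projection <- function(trajectories, n_components = 3) {
  mats <- lapply(trajectories, function(tr)
    if (inherits(tr, "rnn_trajectory")) tr$states else as.matrix(tr))
  pooled <- do.call(rbind, mats)
  if (nrow(pooled) < n_components) stop("fewer samples than components")
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  projected <- lapply(mats, function(m)
    sweep(m, 2, pc$center) %*% pc$rotation[, seq_len(k), drop = FALSE])
  tidy <- dplyr::bind_rows(lapply(seq_along(projected), function(i) {
    d <- tibble::as_tibble(as.data.frame(projected[[i]]))
    d$trajectory <- i
    d$time <- seq_len(nrow(d))
    d
  }))
  structure(list(
    loadings = pc$rotation[, seq_len(k), drop = FALSE], center = pc$center,
    variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
    projected = projected, tidy = tidy), class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("<pca_projection: %d trajectories, variance explained %s>\n",
              length(x$projected),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " + ")))
  invisible(x)
}

#' Empirical decision axis from trial-averaged terminal states
#'
#' The difference between mean terminal hidden states over edge-present vs
#' edge-absent trials, normalized to unit length. With `per_query = TRUE`
#' the axis is computed separately for each ordered query.
#'
#' @param model a `dag_rnn`.
#' @param task a `task_config`.
#' @param n_trials number of trials.
#' @param seed optional integer seed.
#' @param per_query also return per-query axes.
#' @return list with `axis` (unit length-J), `raw_norm` (norm before
#'   normalization), and if requested `by_query` (tibble with list-column
#'   `axis`).
#' @export
decision_axis <- function(model, task = NULL, n_trials = 500, seed = NULL,
                          per_query = FALSE) {
  task <- task %||% model$task
  params <- model$params
  with_seed(seed, {
    batch <- generate_trials(n_trials, task)
    f <- cpp_forward(params$W, params$B, matrix(params$C, 1), params$alpha,
                     batch$inputs, matrix(0, params$J, n_trials))
    T_ <- dim(f$states)[3]
    term <- t(f$states[, , T_])          # n_trials x J
    lab <- batch$labels == 1
    dvec <- colMeans(term[lab, , drop = FALSE]) -
      colMeans(term[!lab, , drop = FALSE])
    res <- list(axis = dvec / sqrt(sum(dvec^2)), raw_norm = sqrt(sum(dvec^2)))
    if (per_query) {
      tr <- batch$trials
      by <- dplyr::group_by(tibble::tibble(cause = tr$cause, effect = tr$effect,
                                           label = lab, i = seq_len(n_trials)),
                            .data$cause, .data$effect)
      res$by_query <- dplyr::summarise(by, axis = {
        ii <- .data$i; ll <- .data$label
        d <- colMeans(term[ii[ll], , drop = FALSE]) -
          colMeans(term[ii[!ll], , drop = FALSE])
        list(d / sqrt(sum(d^2)))
      }, .groups = "drop")
    }
    res
  })
}
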