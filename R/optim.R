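# Population metaheuristics: particle swarm optimization and the parrot
# optimizer (four behaviors with Levy-flight steps), plus the mapping
# between optimizer coordinates and classifier hyperparameters.
#
# Minimization convention throughout: fitness is an error to be reduced.

#' Box bounds for an optimizer
#' @param lower,upper numeric vectors (recycled to a common dimension) with
#'   `lower < upper` elementwise.
#' @return a `bounds` object with `lower`, `upper`, `dim`.
#' @export
bounds <- function(lower, upper) {
  dim <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (!all(lower < upper))
    stop_seizr("bounds require lower < upper elementwise", "seizr_config")
  structure(list(lower = lower, upper = upper, dim = dim), class = "bounds")
}

clip_rows <- function(P, b) {
  P <- pmax(P, matrix(b$lower, nrow(P), b$dim, byrow = TRUE))
  pmin(P, matrix(b$upper, nrow(P), b$dim, byrow = TRUE))
}

eval_objective <- function(objective, P) {
  v <- apply(P, 1L, objective)
  bad <- !is.finite(v)
  if (any(bad)) {
    warning("objective returned non-finite value(s); treated as +Inf")
    v[bad] <- Inf
  }
  v
}

#' Initialize a particle swarm
#'
#' Positions uniform within bounds, velocities zero, personal bests at the
#' initial positions; if an objective is supplied the initial population is
#' evaluated and the global best set.
#'
#' @param b a [bounds].
#' @param n swarm size (default 9).
#' @param seed RNG seed.
#' @param objective optional function `position -> scalar`.
#' @param lambda inertia weight (default 0.9, the conventional starting
#'   value).
#' @param c1,c2 cognitive and social coefficients (default 2).
#' @param lambda_end final inertia weight; when `max_iter` is finite the
#'   inertia decays linearly from `lambda` to `lambda_end` across the run
#'   (the canonical schedule -- a fixed 0.9 with c1 = c2 = 2 oscillates
#'   rather than converging). Defaults to `lambda` (no decay) so a
#'   standalone step uses exactly the printed update.
#' @param max_iter planned iteration budget driving the inertia schedule;
#'   `Inf` (default) keeps the inertia fixed.
#' @return a `swarm_state`.
#' @export
pso_init <- function(b, n = 9L, seed = 1L, objective = NULL,
                     lambda = 0.9, c1 = 2, c2 = 2, lambda_end = lambda,
                     max_iter = Inf) {
  assert_that(inherits(b, "bounds"), "b must be a bounds object")
  assert_that(n >= 1L, "swarm size must be >= 1")
  P <- with_rng(seed, matrix(stats::runif(n * b$dim, rep(b$lower, each = n),
                                          rep(b$upper, each = n)), n, b$dim))
  vals <- if (is.null(objective)) rep(Inf, n) else eval_objective(objective, P)
  gi <- which.min(vals)
  structure(list(positions = P, velocities = matrix(0, n, b$dim),
                 pbest = P, pbest_values = vals,
                 gbest = P[gi, ], gbest_value = vals[gi],
                 t = 0L, lambda = lambda, lambda_end = lambda_end,
                 max_iter = max_iter, c1 = c1, c2 = c2, bounds = b,
                 evaluations = if (is.null(objective)) 0L else n,
                 seed = as.integer(seed), rng_stream = derive_seed(seed, "pso")),
            class = "swarm_state")
}

#' One particle-swarm iteration
#'
#' Per particle, with fresh uniform draws r1 and r2:
#' velocity <- lambda * velocity + c1*r1*(pbest - x) + c2*r2*(gbest - x);
#' position <- position + velocity. Velocities are clamped to 20% of each
#' dimension's range and positions clipped to the bounds; personal and
#' global bests are then updated. `r1`/`r2` can be fixed for testing.
#'
#' @param state a `swarm_state`.
#' @param objective function `position -> scalar`.
#' @param r1,r2 optional fixed random factors (scalar or n x dim matrix);
#'   by default drawn uniformly per particle per dimension.
#' @return the advanced `swarm_state`.
#' @export
pso_step <- function(state, objective, r1 = NULL, r2 = NULL) {
  n <- nrow(state$positions)
  d <- state$bounds$dim
  draws <- with_rng(state$rng_stream + state$t, {
    list(r1 = matrix(stats::runif(n * d), n, d),
         r2 = matrix(stats::runif(n * d), n, d))
  })
  R1 <- if (is.null(r1)) draws$r1 else matrix(r1, n, d)
  R2 <- if (is.null(r2)) draws$r2 else matrix(r2, n, d)
  G <- matrix(state$gbest, n, d, byrow = TRUE)
  lam <- if (is.finite(state$max_iter) && state$max_iter > 0)
    state$lambda - (state$lambda - state$lambda_end) *
      min(1, state$t / state$max_iter)
  else state$lambda
  V <- lam * state$velocities +
    state$c1 * R1 * (state$pbest - state$positions) +
    state$c2 * R2 * (G - state$positions)
  vmax <- 0.2 * (state$bounds$upper - state$bounds$lower)
  V <- pmin(pmax(V, matrix(-vmax, n, d, byrow = TRUE)), matrix(vmax, n, d, byrow = TRUE))
  P <- clip_rows(state$positions + V, state$bounds)
  vals <- eval_objective(objective, P)
  improved <- vals < state$pbest_values
  state$pbest[improved, ] <- P[improved, , drop = FALSE]
  state$pbest_values[improved] <- vals[improved]
  gi <- which.min(state$pbest_values)
  state$gbest <- state$pbest[gi, ]
  state$gbest_value <- state$pbest_values[gi]
  state$positions <- P
  state$velocities <- V
  state$t <- state$t + 1L
  state$evaluations <- state$evaluations + n
  state
}

optim_result <- function(best_position, best_value, history, evaluations) {
  structure(list(best_position = best_position, best_value = best_value,
                 history = history, evaluations = evaluations),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("<optim_result> best value %.6g after %d evaluations (%d iterations)\n",
              x$best_value, x$evaluations, length(x$history) - 1L))
  invisible(x)
}

#' Run particle swarm optimization
#'
#' @param objective function `position -> scalar` (minimized).
#' @param b a [bounds].
#' @param n swarm size (default 9).
#' @param max_iter iterations (default 100).
#' @param seed RNG seed.
#' @param lambda,lambda_end inertia schedule: linear decay from `lambda`
#'   (default 0.9) to `lambda_end` (default 0.4) across the run.
#' @param ... passed to [pso_init()] (`c1`, `c2`).
#' @param verbose emit a per-iteration log line.
#' @return an `optim_result` (history includes the initial best, so it has
#'   `max_iter + 1` entries and is non-increasing).
#' @export
pso_optimize <- function(objective, b, n = 9L, max_iter = 100L, seed = 1L,
                         verbose = FALSE, lambda = 0.9, lambda_end = 0.4, ...) {
  assert_that(max_iter >= 1L, "max_iter must be >= 1")
  state <- pso_init(b, n = n, seed = seed, objective = objective,
                    lambda = lambda, lambda_end = lambda_end,
                    max_iter = max_iter, ...)
  history <- state$gbest_value
  for (i in seq_len(max_iter)) {
    state <- pso_step(state, objective)
    history <- c(history, state$gbest_value)
    if (verbose)
      message(sprintf("pso iter %d best %.6g evals %d", i, state$gbest_value,
                      state$evaluations))
  }
  optim_result(state$gbest, state$gbest_value, history, state$evaluations)
}

#' Levy-flight step vector (Mantegna algorithm)
#'
#' Heavy-tailed steps `u / |v|^(1/beta)` with `u ~ N(0, sigma^2)`,
#' `v ~ N(0, 1)` and the Mantegna scale `sigma(beta)`.
#'
#' @param dim output dimension.
#' @param beta stability index in `(1, 2]` (default 1.5).
#' @param seed optional seed; if `NULL` the current RNG stream is used
#'   (callers inside [with_rng()]).
#' @return numeric vector of length `dim`.
#' @export
levy_flight <- function(dim, beta = 1.5, seed = NULL) {
  assert_that(dim >= 1L, "dim must be >= 1")
  if (!(beta > 1 && beta <= 2))
    stop_seizr("beta must lie in (1, 2]", "seizr_param")
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  draw <- function() {
    u <- stats::rnorm(dim, sd = sigma)
    v <- stats::rnorm(dim)
    u / abs(v)^(1 / beta)
  }
  if (is.null(seed)) draw() else with_rng(seed, draw())
}

#' Initialize a parrot-optimizer population
#'
#' Positions `Y_i = lb + rand(0,1) * (ub - lb)`; the population is
#' evaluated, and the best position and population mean recorded.
#'
#' @param b a [bounds].
#' @param n_agents population size, >= 2 (default 30).
#' @param max_iter planned iteration budget (enters the behavior
#'   equations through `t / Maxiter`).
#' @param seed RNG seed.
#' @param objective function `position -> scalar`.
#' @return a `parrot_state`.
#' @export
po_init <- function(b, n_agents = 30L, max_iter = 1000L, seed = 1L, objective) {
  assert_that(inherits(b, "bounds"), "b must be a bounds object")
  assert_that(n_agents >= 2L, "n_agents must be >= 2 (population mean)")
  P <- with_rng(seed, matrix(b$lower, n_agents, b$dim, byrow = TRUE) +
                  matrix(stats::runif(n_agents * b$dim), n_agents, b$dim) *
                  matrix(b$upper - b$lower, n_agents, b$dim, byrow = TRUE))
  vals <- eval_objective(objective, P)
  bi <- which.min(vals)
  structure(list(positions = P, values = vals,
                 best = P[bi, ], best_value = vals[bi],
                 mean = colMeans(P), t = 0L, max_iter = as.integer(max_iter),
                 bounds = b, evaluations = n_agents,
                 seed = as.integer(seed), rng_stream = derive_seed(seed, "po")),
            class = "parrot_state")
}

PO_BEHAVIORS <- c("foraging", "staying", "communicating", "fear")

# One behavior update for a single agent; rand_fn supplies each rand(0,1)
# occurrence, levy_fn the levy(dim) vector. Kept as printed: the
# communicating branch replaces the position rather than incrementing it.
po_candidate <- function(y, behavior, best, mu, t, max_iter, dim,
                         rand_fn, levy_fn, p_comm) {
  tf <- t / max_iter
  switch(behavior,
    foraging = (y - best) * levy_fn(dim) +
      rand_fn() * (1 - tf)^(2 * tf) * mu,
    staying = y + best * levy_fn(dim) + rand_fn() * rep(1, dim),
    communicating = {
      if (p_comm <= 0.5)
        0.2 * rand_fn() * (1 - tf) * (y - mu)
      else
        rep(0.2 * rand_fn() * exp(-t / (rand_fn() * max_iter)), dim)
    },
    fear = y + rand_fn() * cos(0.5 * pi * tf) * (best - y) -
      cos(rand_fn() * pi) * tf^(2 / max_iter) * (y - best))
}

#' One parrot-optimizer iteration
#'
#' Each agent draws one of the four behaviors (foraging, staying,
#' communicating, fear of strangers) uniformly at random and applies the
#' corresponding position update with fresh `rand(0,1)` draws per
#' occurrence; candidates are clipped to bounds and accepted greedily (only
#' if the objective improves). Behavior, random draws and the Levy source
#' are injectable for testing.
#'
#' @param state a `parrot_state`.
#' @param objective function `position -> scalar`.
#' @param behavior optional fixed behavior name (`"foraging"`, `"staying"`,
#'   `"communicating"` or `"fear"`) applied to every agent.
#' @param rand_fn optional replacement for the uniform `rand(0,1)` source.
#' @param levy_fn optional replacement for the `levy(dim)` source.
#' @param p_comm optional fixed value of the communicating-branch selector
#'   `P` (its own uniform draw by default).
#' @return the advanced `parrot_state`.
#' @export
po_step <- function(state, objective, behavior = NULL, rand_fn = NULL,
                    levy_fn = NULL, p_comm = NULL) {
  if (state$t >= state$max_iter)
    stop_seizr("parrot state already at max_iter", "seizr_config")
  n <- nrow(state$positions)
  d <- state$bounds$dim
  stream <- state$rng_stream + state$t
  cand <- with_rng(stream, {
    rf <- rand_fn %||% function() stats::runif(1)
    lf <- levy_fn %||% function(dim) levy_flight(dim)
    beh_idx <- if (is.null(behavior)) sample.int(4L, n, replace = TRUE) else
      rep(match(match.arg(behavior, PO_BEHAVIORS), PO_BEHAVIORS), n)
    out <- state$positions
    for (i in seq_len(n)) {
      pc <- p_comm %||% stats::runif(1)
      out[i, ] <- po_candidate(state$positions[i, ], PO_BEHAVIORS[beh_idx[i]],
                               state$best, state$mean, state$t, state$max_iter,
                               d, rf, lf, pc)
    }
    out
  })
  cand <- clip_rows(cand, state$bounds)
  vals <- eval_objective(objective, cand)
  improved <- vals < state$values
  state$positions[improved, ] <- cand[improved, , drop = FALSE]
  state$values[improved] <- vals[improved]
  bi <- which.min(state$values)
  state$best <- state$positions[bi, ]
  state$best_value <- state$values[bi]
  state$mean <- colMeans(state$positions)
  state$t <- state$t + 1L
  state$evaluations <- state$evaluations + n
  state
}

#' Run the parrot optimizer
#'
#' @param objective function `position -> scalar` (minimized).
#' @param b a [bounds]; the reference benchmark setting is dimension 30
#'   with bounds -100..100.
#' @param n_agents population size (default 30).
#' @param max_iter iterations (default 1000).
#' @param seed RNG seed.
#' @param verbose emit a per-iteration log line every 100 iterations.
#' @return an `optim_result` (history has `max_iter + 1` entries).
#' @export
po_optimize <- function(objective, b, n_agents = 30L, max_iter = 1000L,
                        seed = 1L, verbose = FALSE) {
  assert_that(max_iter >= 1L, "max_iter must be >= 1")
  state <- po_init(b, n_agents = n_agents, max_iter = max_iter, seed = seed,
                   objective = objective)
  history <- state$best_value
  for (i in seq_len(max_iter)) {
    state <- po_step(state, objective)
    history <- c(history, state$best_value)
    if (verbose && i %% 100L == 0L)
      message(sprintf("po iter %d best %.6g evals %d", i, state$best_value,
                      state$evaluations))
  }
  optim_result(state$best, state$best_value, history, state$evaluations)
}

#' Hyperparameter search space for the LSTM classifier
#'
#' Three tuned dimensions on the unit cube: learning rate (log-uniform on
#' `lr_range`), hidden units (rounded onto `hidden_range`), dropout (affine
#' onto `dropout_range`).
#'
#' @param lr_range learning-rate range (default `c(1e-5, 1e-2)`).
#' @param hidden_range integer hidden-unit range (default `c(16, 128)`).
#' @param dropout_range dropout range (default `c(0.1, 0.7)`).
#' @return a `search_space`; its `bounds` field is the unit cube.
#' @export
search_space <- function(lr_range = c(1e-5, 1e-2), hidden_range = c(16L, 128L),
                         dropout_range = c(0.1, 0.7)) {
  structure(list(lr_range = lr_range, hidden_range = as.integer(hidden_range),
                 dropout_range = dropout_range,
                 bounds = bounds(rep(0, 3), rep(1, 3)), dim = 3L),
            class = "search_space")
}

#' Decode an optimizer position into classifier hyperparameters
#'
#' Coordinates are clipped to the unit cube first; learning rate uses a
#' log-uniform transform, hidden units round onto the integer range,
#' dropout maps affinely.
#'
#' @param position numeric vector of length `space$dim`.
#' @param space a [search_space].
#' @return list with `learning_rate`, `hidden_units`, `dropout`.
#' @export
decode_position <- function(position, space) {
  assert_that(inherits(space, "search_space"), "space must be a search_space")
  if (length(position) != space$dim)
    stop_seizr(sprintf("position has length %d, expected %d", length(position),
                       space$dim), "seizr_param")
  u <- pmin(1, pmax(0, as.numeric(position)))
  lr <- exp(log(space$lr_range[1]) +
              u[1] * (log(space$lr_range[2]) - log(space$lr_range[1])))
  hidden <- as.integer(round(space$hidden_range[1] +
                               u[2] * (space$hidden_range[2] - space$hidden_range[1])))
  dropout <- space$dropout_range[1] +
    u[3] * (space$dropout_range[2] - space$dropout_range[1])
  list(learning_rate = lr, hidden_units = hidden, dropout = dropout)
}

#' Encode hyperparameters back onto the unit cube
#' @param config list with `learning_rate`, `hidden_units`, `dropout`.
#' @param space a [search_space].
#' @return numeric position of length `space$dim`.
#' @export
encode_config <- function(config, space) {
  c((log(config$learning_rate) - log(space$lr_range[1])) /
      (log(space$lr_range[2]) - log(space$lr_range[1])),
    (config$hidden_units - space$hidden_range[1]) /
      (space$hidden_range[2] - space$hidden_range[1]),
    (config$dropout - space$dropout_range[1]) /
      (space$dropout_range[2] - space$dropout_range[1]))
}

#' Write an optimizer history as a tab-separated table
#' @param result an `optim_result`.
#' @param path output file path.
#' @return invisibly, the history data frame.
#' @export
write_history <- function(result, path) {
  df <- data.frame(iteration = seq_along(result$history) - 1L,
                   best_value = result$history)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
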