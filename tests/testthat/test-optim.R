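sphere <- function(x) sum(x^2)

test_that("pso_init places the swarm inside bounds, deterministically", {
  b <- bounds(c(-5, -2), c(5, 2))
  st <- pso_init(b, n = 9L, seed = 3L, objective = sphere)
  expect_equal(dim(st$positions), c(9L, 2L))
  expect_true(all(st$positions >= -5 & st$positions <= 5))
  expect_true(all(st$positions[, 2] >= -2 & st$positions[, 2] <= 2))
  expect_true(all(st$velocities == 0))
  expect_identical(st$pbest, st$positions)
  expect_equal(st$gbest_value, min(st$pbest_values))
  expect_equal(st$evaluations, 9L)
  st2 <- pso_init(b, n = 9L, seed = 3L, objective = sphere)
  expect_identical(st$positions, st2$positions)
  expect_error(bounds(1, 1), class = "seizr_config")
})

test_that("pso_step reproduces the velocity/position update by hand", {
  b <- bounds(-5, 5)
  st <- pso_init(b, n = 1L, seed = 1L)
  st$positions[1, ] <- 1; st$velocities[1, ] <- 0
  st$pbest[1, ] <- 0; st$pbest_values <- 0
  st$gbest <- 0; st$gbest_value <- 0
  # v' = 0.9*0 + 2*0.5*(0-1) + 2*0.5*(0-1) = -2 ; x' = 1 - 2 = -1
  st2 <- pso_step(st, sphere, r1 = 0.5, r2 = 0.5)
  expect_equal(drop(st2$velocities), -2, tolerance = 1e-12)
  expect_equal(drop(st2$positions), -1, tolerance = 1e-12)

  # fixed point: at the shared best with zero velocity, nothing moves
  stf <- pso_init(b, n = 1L, seed = 2L)
  stf$positions[1, ] <- 0.5; stf$velocities[1, ] <- 0
  stf$pbest[1, ] <- 0.5; stf$pbest_values <- sphere(0.5)
  stf$gbest <- 0.5; stf$gbest_value <- sphere(0.5)
  stf2 <- pso_step(stf, sphere)
  expect_equal(drop(stf2$positions), 0.5)
  expect_equal(drop(stf2$velocities), 0)

  # r1 = r2 = 0 with lambda = 1 is pure inertia
  sti <- pso_init(b, n = 1L, seed = 4L, lambda = 1)
  sti$positions[1, ] <- 0; sti$velocities[1, ] <- 0.3
  sti$pbest[1, ] <- -2; sti$pbest_values <- 4
  sti$gbest <- 3; sti$gbest_value <- 9
  sti2 <- pso_step(sti, sphere, r1 = 0, r2 = 0)
  expect_equal(drop(sti2$positions) - drop(sti$positions), 0.3, tolerance = 1e-12)
})

test_that("pso_optimize bookkeeping: history, evaluations, determinism, bounds", {
  b <- bounds(c(-5, -5), c(5, 5))
  r1 <- pso_optimize(sphere, b, n = 9L, max_iter = 30L, seed = 6L)
  expect_length(r1$history, 31L)
  expect_true(all(diff(r1$history) <= 0))
  expect_equal(r1$evaluations, 9L * 31L)
  expect_equal(r1$best_value, tail(r1$history, 1))
  expect_true(all(r1$best_position >= -5 & r1$best_position <= 5))
  r2 <- pso_optimize(sphere, b, n = 9L, max_iter = 30L, seed = 6L)
  expect_identical(r1, r2)
})

test_that("non-finite objective values are treated as +Inf with a warning", {
  b <- bounds(-1, 1)
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  expect_warning(pso_optimize(bad, b, n = 5L, max_iter = 2L, seed = 1L),
                 "non-finite")
})

test_that("levy_flight is seeded, sized and heavy-tailed", {
  v <- levy_flight(7L, seed = 5L)
  expect_length(v, 7L)
  expect_identical(v, levy_flight(7L, seed = 5L))
  expect_error(levy_flight(3L, beta = 2.5), class = "seizr_param")
  big <- levy_flight(1e5, beta = 1.5, seed = 2L)
  k <- mean((big - mean(big))^4) / mean((big - mean(big))^2)^2
  expect_gt(k, 3)
})

test_that("parrot behavior equations match hand evaluation", {
  # foraging with Y = Y_best and t = 0: Y' = rand * Y_mean
  y <- c(3, 3)
  out <- seizr:::po_candidate(y, "foraging", best = y, mu = c(1, 2), t = 0,
                              max_iter = 100, dim = 2L,
                              rand_fn = function() 0.5,
                              levy_fn = function(d) rnorm(d), p_comm = 0.1)
  expect_equal(out, 0.5 * c(1, 2), tolerance = 1e-12)

  # staying with levy stubbed to zero and rand = 0: identity
  out <- seizr:::po_candidate(y, "staying", best = c(9, 9), mu = c(1, 1),
                              t = 5, max_iter = 100, dim = 2L,
                              rand_fn = function() 0,
                              levy_fn = function(d) rep(0, d), p_comm = 0.1)
  expect_equal(out, y, tolerance = 1e-12)

  # communicating, P = 0.4, rand = 0.5, t = 0: Y' = 0.1 * (Y - Y_mean)
  out <- seizr:::po_candidate(c(2, 2), "communicating", best = c(0, 0),
                              mu = c(1, 1), t = 0, max_iter = 100, dim = 2L,
                              rand_fn = function() 0.5,
                              levy_fn = function(d) rep(0, d), p_comm = 0.4)
  expect_equal(out, c(0.1, 0.1), tolerance = 1e-12)

  # fear at t = 0 with rand = 0: Y' = Y - cos(0)*0^(2/M)*(Y-best) = Y
  out <- seizr:::po_candidate(c(2, 2), "fear", best = c(0, 0), mu = c(1, 1),
                              t = 0, max_iter = 100, dim = 2L,
                              rand_fn = function() 0,
                              levy_fn = function(d) rep(0, d), p_comm = 0.1)
  expect_equal(out, c(2, 2), tolerance = 1e-12)
})

test_that("po_step applies greedy acceptance within bounds", {
  b <- bounds(rep(-10, 3), rep(10, 3))
  st <- po_init(b, n_agents = 8L, max_iter = 50L, seed = 9L, objective = sphere)
  expect_equal(st$mean, colMeans(st$positions))
  vals0 <- st$values
  st2 <- po_step(st, sphere)
  expect_true(all(st2$values <= vals0))
  expect_true(all(st2$positions >= -10 & st2$positions <= 10))
  expect_equal(st2$t, 1L)
  expect_equal(st2$evaluations, 8L + 8L)
  expect_equal(st2$best_value, min(st2$values))
  expect_error(po_init(b, n_agents = 1L, max_iter = 10L, seed = 1L,
                       objective = sphere), class = "seizr_invalid")
})

test_that("po_optimize converges on the sphere with monotone history", {
  b <- bounds(rep(-100, 5), rep(100, 5))
  r <- po_optimize(sphere, b, n_agents = 10L, max_iter = 100L, seed = 2L)
  expect_length(r$history, 101L)
  expect_true(all(diff(r$history) <= 0))
  expect_equal(r$evaluations, 10L * 101L)
  expect_lt(r$best_value, 1e-2)
  r2 <- po_optimize(sphere, b, n_agents = 10L, max_iter = 100L, seed = 2L)
  expect_identical(r, r2)
})

test_that("decode_position maps bounds, midpoint and round-trips", {
  sp <- search_space()
  lo <- decode_position(c(0, 0, 0), sp)
  expect_equal(lo$learning_rate, 1e-5)
  expect_equal(lo$hidden_units, 16L)
  expect_equal(lo$dropout, 0.1)
  hi <- decode_position(c(1, 1, 1), sp)
  expect_equal(hi$learning_rate, 1e-2)
  expect_equal(hi$hidden_units, 128L)
  expect_equal(hi$dropout, 0.7)
  mid <- decode_position(c(0.5, 0.5, 0.5), sp)
  expect_equal(mid$learning_rate, 10^-3.5, tolerance = 1e-12)

  # decode(encode(decode(x))) = decode(x), including out-of-bounds input
  for (x in list(c(0.3, 0.8, 0.1), c(-2, 0.5, 7))) {
    d1 <- decode_position(x, sp)
    d2 <- decode_position(encode_config(d1, sp), sp)
    expect_equal(d1, d2, tolerance = 1e-9)
  }
  expect_error(decode_position(c(0.5, 0.5), sp), class = "seizr_param")
})
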