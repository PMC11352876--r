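test_that("cell_forward matches hand evaluation with zero weights", {
  cfg <- lstm_config(hidden_units = 4L, seed = 1L)
  m <- seizr:::lstm_init(3L, cfg)
  m$W[] <- 0; m$Wy[] <- 0
  out <- cell_forward(rep(0, 3), rep(0, 4), rep(0, 4), m)
  expect_equal(out$gates$input, rep(0.5, 4))
  expect_equal(out$gates$forget, rep(0.5, 4))
  expect_equal(out$gates$output, rep(0.5, 4))
  expect_equal(out$gates$candidate, rep(0, 4))
  expect_equal(out$c, rep(0, 4))
  expect_equal(out$h, rep(0, 4))

  # with c = 1: c' = 0.5, h' = 0.5 * tanh(0.5)
  out1 <- cell_forward(rep(0, 3), rep(0, 4), rep(1, 4), m)
  expect_equal(out1$c, rep(0.5, 4))
  expect_equal(out1$h, rep(0.5 * tanh(0.5), 4), tolerance = 1e-12)
  expect_error(cell_forward(rep(0, 5), rep(0, 4), rep(0, 4), m),
               class = "seizr_shape")
})

test_that("hidden state is bounded by the tanh/sigmoid product", {
  cfg <- lstm_config(hidden_units = 6L, seed = 2L)
  m <- seizr:::lstm_init(3L, cfg)
  set.seed(3)
  m$W[] <- rnorm(length(m$W), sd = 3)
  h <- rep(0, 6); c <- rep(0, 6)
  for (t in 1:20) {
    st <- cell_forward(rnorm(3), h, c, m)
    h <- st$h; c <- st$c
    expect_true(all(abs(h) < 1))
  }
})

test_that("epochs = 0 returns the seeded initialization untouched", {
  ds <- make_separable_task(10L)
  cfg <- lstm_config(hidden_units = 8L, epochs = 0L, seed = 5L)
  fit <- lstm_train(ds, cfg)
  init <- seizr:::lstm_init(ds$n_features, cfg)
  expect_identical(fit$model$W, init$W)
  expect_identical(fit$model$Wy, init$Wy)
  expect_length(fit$report$epoch_loss, 0L)
})

test_that("training solves a separable task deterministically", {
  ds <- make_separable_task(50L)
  cfg <- lstm_config(hidden_units = 16L, learning_rate = 3e-3, dropout = 0.2,
                     gradient_threshold = 1, epochs = 30L, batch_size = 16L,
                     seed = 7L)
  fit <- lstm_train(ds, cfg)
  expect_gte(fit$report$train_accuracy, 0.95)
  fit2 <- lstm_train(ds, cfg)
  expect_identical(fit$model$W, fit2$model$W)
  expect_identical(fit$report$epoch_loss, fit2$report$epoch_loss)

  # held-out 30%
  idx <- c(1:35, 51:85)
  train <- sequence_dataset(ds$sequences[idx], ds$labels[idx])
  test_idx <- setdiff(seq_along(ds$sequences), idx)
  test <- sequence_dataset(ds$sequences[test_idx], ds$labels[test_idx])
  fit3 <- lstm_train(train, cfg)
  pred <- lstm_predict(fit3$model, test)
  expect_gte(mean(pred$labels == test$labels), 0.9)
  expect_equal(rowSums(pred$scores), rep(1, length(test_idx)), tolerance = 1e-9)
  pred2 <- lstm_predict(fit3$model, test)
  expect_identical(pred$scores, pred2$scores)
})

test_that("first-epoch loss starts near ln 2 on a balanced task", {
  ds <- make_separable_task(20L, sep = 1)
  cfg <- lstm_config(hidden_units = 12L, learning_rate = 1e-4, dropout = 0,
                     epochs = 1L, seed = 9L)
  fit <- lstm_train(ds, cfg)
  expect_lt(abs(fit$report$epoch_loss[1] - log(2)), 0.2 * log(2))
})

test_that("gradient norm never exceeds the clip threshold", {
  ds <- make_separable_task(20L)
  norms <- c()
  cfg <- lstm_config(hidden_units = 8L, learning_rate = 1e-3,
                     gradient_threshold = 0.01, epochs = 3L, seed = 4L)
  lstm_train(ds, cfg, grad_hook = function(gn) norms <<- c(norms, gn))
  expect_gt(length(norms), 0L)
  expect_true(all(norms <= 0.01 + 1e-9))
})

test_that("training validates its inputs", {
  seqs <- lapply(1:5, function(i) matrix(rnorm(12), 3))
  expect_error(lstm_train(sequence_dataset(seqs, rep("seizure", 5))),
               class = "seizr_invalid")
  expect_error(sequence_dataset(list(matrix(0, 2, 2), matrix(0, 3, 2)),
                                c("seizure", "non_seizure")),
               class = "seizr_invalid")
  expect_error(sequence_dataset(seqs, rep("positive", 5)),
               class = "seizr_invalid")
  ds <- make_separable_task(5L)
  m <- lstm_train(ds, lstm_config(hidden_units = 4L, epochs = 0L))$model
  wrong <- sequence_dataset(lapply(1:3, function(i) matrix(0, 6, 7)),
                            rep("seizure", 3))
  expect_error(lstm_predict(m, wrong), class = "seizr_shape")
})

test_that("cv_fitness is bounded, stratified and deterministic", {
  ds <- make_separable_task(15L)
  sp <- search_space()
  f1 <- cv_fitness(c(0.9, 0.2, 0.1), sp, ds, k_folds = 3L, seed = 2L,
                   epochs = 5L)
  expect_gte(f1, 0); expect_lte(f1, 1)
  f2 <- cv_fitness(c(0.9, 0.2, 0.1), sp, ds, k_folds = 3L, seed = 2L,
                   epochs = 5L)
  expect_identical(f1, f2)
  # class with fewer members than folds cannot be stratified
  small <- sequence_dataset(ds$sequences[c(1, 16, 17, 18)],
                            ds$labels[c(1, 16, 17, 18)])
  expect_error(cv_fitness(c(0.5, 0.5, 0.5), sp, small, k_folds = 2L, seed = 1L),
               class = "seizr_invalid")
})
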