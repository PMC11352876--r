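# Gated recurrent (LSTM) sequence classifier, implemented directly on
# matrix operations: batched forward pass, backpropagation through time,
# adaptive-moment (or plain SGD) updates, global gradient-norm clipping,
# and dropout on the hidden-to-readout path. Binary softmax readout with
# the seizure class positive; ties break to non-seizure.

CLASS_LEVELS <- c("non_seizure", "seizure")

#' LSTM training configuration
#'
#' Defaults follow the reference tuning framework: 100 hidden units,
#' learning rate 1e-4, dropout 0.5 and gradient-norm clip 0.01. Epochs and
#' batch size are desk-scale defaults (30 and 16).
#'
#' @param hidden_units recurrent state width.
#' @param learning_rate optimizer step size.
#' @param dropout drop probability on the hidden-to-readout path, `[0, 1)`.
#' @param gradient_threshold global gradient-norm clip value.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return an `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 100L, learning_rate = 1e-4, dropout = 0.5,
                        gradient_threshold = 0.01, epochs = 30L, batch_size = 16L,
                        optimizer = c("adam", "sgd"), seed = 1L) {
  assert_that(hidden_units >= 1L, "hidden_units must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  assert_that(gradient_threshold > 0, "gradient_threshold must be positive")
  assert_that(epochs >= 0L, "epochs must be >= 0")
  assert_that(batch_size >= 1L, "batch_size must be >= 1")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, dropout = dropout,
                 gradient_threshold = gradient_threshold,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = match.arg(optimizer), seed = as.integer(seed)),
            class = "lstm_config")
}

#' Bundle feature sequences and labels for the classifier
#'
#' @param sequences list of `T x F` numeric matrices, all sharing the same
#'   number of timesteps and features.
#' @param labels character vector (or factor) of `"seizure"` /
#'   `"non_seizure"`, one per sequence.
#' @param source_ids optional per-sequence origin strings.
#' @return a `sequence_dataset`.
#' @export
sequence_dataset <- function(sequences, labels, source_ids = NULL) {
  assert_that(length(sequences) >= 1L, "need at least one sequence")
  sequences <- lapply(sequences, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "double"; s
  })
  dims <- vapply(sequences, dim, integer(2))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "all sequences must share timestep and feature dimensions")
  labels <- as.character(labels)
  assert_that(length(labels) == length(sequences), "one label per sequence")
  assert_that(all(labels %in% CLASS_LEVELS),
              "labels must be 'seizure' or 'non_seizure'")
  structure(list(sequences = sequences, labels = labels,
                 source_ids = source_ids %||% sprintf("seq%04d", seq_along(sequences)),
                 n_timesteps = dims[1, 1], n_features = dims[2, 1]),
            class = "sequence_dataset")
}

# Weight layout: W is (F + H + 1) x 4H with column blocks
# [input | forget | output | candidate]; rows are [inputs, hidden, bias].
# Wy is (H + 1) x 2 for the softmax readout.
lstm_init <- function(input_dim, config) {
  H <- config$hidden_units
  with_rng(derive_seed(config$seed, "init"), {
    scale <- 0.08
    W <- matrix(stats::runif((input_dim + H + 1L) * 4L * H, -scale, scale),
                input_dim + H + 1L, 4L * H)
    W[input_dim + H + 1L, ] <- 0          # zero biases
    Wy <- matrix(stats::runif((H + 1L) * 2L, -scale, scale), H + 1L, 2L)
    Wy[H + 1L, ] <- 0
    structure(list(W = W, Wy = Wy, input_dim = as.integer(input_dim),
                   hidden_units = H, config = config),
              class = "lstm_model")
  })
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> %d features -> %d hidden units -> 2 classes (%d parameters)\n",
              x$input_dim, x$hidden_units, length(x$W) + length(x$Wy)))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' One LSTM cell update
#'
#' Standard gated update: `gates = sigmoid(affine)`, `candidate =
#' tanh(affine)`, `c' = forget * c + input * candidate`,
#' `h' = output * tanh(c')`.
#'
#' @param x_t input at this timestep: vector of length `input_dim` or a
#'   `B x input_dim` matrix.
#' @param h,c hidden and cell state: vectors of length `hidden_units` or
#'   `B x hidden_units` matrices.
#' @param model an `lstm_model`.
#' @return list with `h`, `c` (same shape as the inputs) and the gate
#'   activations `gates = list(input, forget, output, candidate)`.
#' @export
cell_forward <- function(x_t, h, c, model) {
  vec_in <- is.null(dim(x_t))
  X <- if (vec_in) matrix(x_t, 1L) else as.matrix(x_t)
  Hm <- if (is.null(dim(h))) matrix(h, 1L) else as.matrix(h)
  Cm <- if (is.null(dim(c))) matrix(c, 1L) else as.matrix(c)
  if (ncol(X) != model$input_dim || ncol(Hm) != model$hidden_units ||
      ncol(Cm) != model$hidden_units)
    stop_seizr("cell_forward: shape mismatch with model dimensions", "seizr_shape")
  H <- model$hidden_units
  Z <- cbind(X, Hm, 1) %*% model$W
  i <- sigmoid(Z[, 1:H, drop = FALSE])
  f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
  o <- sigmoid(Z[, (2 * H + 1):(3 * H), drop = FALSE])
  g <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
  c_new <- f * Cm + i * g
  h_new <- o * tanh(c_new)
  if (vec_in) {
    h_new <- drop(h_new); c_new <- drop(c_new)
    i <- drop(i); f <- drop(f); o <- drop(o); g <- drop(g)
  }
  list(h = h_new, c = c_new, gates = list(input = i, forget = f, output = o,
                                          candidate = g))
}

# Batched forward over a full sequence batch. X is a B x T x F array.
# Returns the readout cache needed by BPTT.
lstm_forward_batch <- function(model, X, mask = NULL) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- model$hidden_units
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B)
    step <- cell_forward(xt, h, c, model)
    cache[[t]] <- list(x = xt, h_prev = h, c_prev = c, i = step$gates$input,
                       f = step$gates$forget, o = step$gates$output,
                       g = step$gates$candidate, c = step$c)
    h <- step$h; c <- step$c
  }
  p <- model$config$dropout
  hd <- if (!is.null(mask)) h * mask / (1 - p) else h
  logits <- cbind(hd, 1) %*% model$Wy
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(cache = cache, h_final = h, hd = hd, logits = logits, probs = probs)
}

lstm_backward_batch <- function(model, fwd, Y, mask = NULL) {
  B <- nrow(Y); H <- model$hidden_units; Fdim <- model$input_dim
  p <- model$config$dropout
  dlogits <- (fwd$probs - Y) / B
  dWy <- t(cbind(fwd$hd, 1)) %*% dlogits
  dh <- dlogits %*% t(model$Wy[1:H, , drop = FALSE])
  if (!is.null(mask)) dh <- dh * mask / (1 - p)
  dW <- matrix(0, nrow(model$W), ncol(model$W))
  dc <- matrix(0, B, H)
  Wh <- model$W[(Fdim + 1):(Fdim + H), , drop = FALSE]
  for (t in rev(seq_along(fwd$cache))) {
    cc <- fwd$cache[[t]]
    tc <- tanh(cc$c)
    do <- dh * tc
    dct <- dc + dh * cc$o * (1 - tc^2)
    di <- dct * cc$g
    df <- dct * cc$c_prev
    dg <- dct * cc$i
    dc <- dct * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o), dg * (1 - cc$g^2))
    dW <- dW + t(cbind(cc$x, cc$h_prev, 1)) %*% dZ
    dh <- dZ %*% t(Wh)
  }
  list(dW = dW, dWy = dWy)
}

clip_gradients <- function(grads, threshold) {
  gn <- sqrt(sum(grads$dW^2) + sum(grads$dWy^2))
  if (gn > threshold) {
    s <- threshold / gn
    grads$dW <- grads$dW * s
    grads$dWy <- grads$dWy * s
    gn <- threshold
  }
  grads$norm <- gn
  grads
}

one_hot <- function(labels) {
  Y <- matrix(0, length(labels), 2L)
  Y[cbind(seq_along(labels), match(labels, CLASS_LEVELS))] <- 1
  Y
}

seq_array <- function(ds) {
  B <- length(ds$sequences)
  X <- array(0, c(B, ds$n_timesteps, ds$n_features))
  for (i in seq_len(B)) X[i, , ] <- ds$sequences[[i]]
  X
}

#' Train the LSTM classifier
#'
#' Minibatch cross-entropy training with backpropagation through time,
#' global gradient-norm clipping at `config$gradient_threshold`, dropout on
#' the hidden-to-readout path, and adaptive-moment (default) or plain SGD
#' updates. Fully deterministic for a fixed `config$seed`.
#'
#' @param ds a [sequence_dataset] containing both classes.
#' @param config an [lstm_config].
#' @param grad_hook optional function called with the post-clip gradient
#'   norm at every update (instrumentation for tests).
#' @return list with `model` (an `lstm_model`) and `report` (per-epoch mean
#'   loss, final training accuracy, update count, seed).
#' @export
lstm_train <- function(ds, config = lstm_config(), grad_hook = NULL) {
  assert_that(inherits(ds, "sequence_dataset"), "ds must be a sequence_dataset")
  if (length(unique(ds$labels)) < 2L)
    stop_seizr("training data must contain both classes", "seizr_invalid")
  model <- lstm_init(ds$n_features, config)
  X <- seq_array(ds)
  Yall <- one_hot(ds$labels)
  n <- length(ds$sequences)
  H <- config$hidden_units
  losses <- numeric(0)
  updates <- 0L
  if (config$epochs > 0L) {
    mW <- vW <- matrix(0, nrow(model$W), ncol(model$W))
    mWy <- vWy <- matrix(0, nrow(model$Wy), ncol(model$Wy))
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    with_rng(derive_seed(config$seed, "train"), {
      for (epoch in seq_len(config$epochs)) {
        ord <- sample.int(n)
        batch_losses <- numeric(0)
        for (start in seq(1L, n, by = config$batch_size)) {
          idx <- ord[start:min(start + config$batch_size - 1L, n)]
          B <- length(idx)
          Xb <- X[idx, , , drop = FALSE]
          Yb <- Yall[idx, , drop = FALSE]
          mask <- if (config$dropout > 0)
            matrix(stats::rbinom(B * H, 1L, 1 - config$dropout), B, H) else NULL
          fwd <- lstm_forward_batch(model, Xb, mask)
          loss <- -mean(log(pmax(rowSums(fwd$probs * Yb), 1e-300)))
          if (!is.finite(loss))
            stop_seizr(sprintf("non-finite training loss at epoch %d", epoch),
                       "seizr_numeric")
          batch_losses <- c(batch_losses, loss)
          grads <- lstm_backward_batch(model, fwd, Yb, mask)
          grads <- clip_gradients(grads, config$gradient_threshold)
          if (!is.null(grad_hook)) grad_hook(grads$norm)
          updates <- updates + 1L
          if (config$optimizer == "adam") {
            mW <- beta1 * mW + (1 - beta1) * grads$dW
            vW <- beta2 * vW + (1 - beta2) * grads$dW^2
            mWy <- beta1 * mWy + (1 - beta1) * grads$dWy
            vWy <- beta2 * vWy + (1 - beta2) * grads$dWy^2
            bc1 <- 1 - beta1^updates; bc2 <- 1 - beta2^updates
            model$W <- model$W - config$learning_rate * (mW / bc1) /
              (sqrt(vW / bc2) + adam_eps)
            model$Wy <- model$Wy - config$learning_rate * (mWy / bc1) /
              (sqrt(vWy / bc2) + adam_eps)
          } else {
            model$W <- model$W - config$learning_rate * grads$dW
            model$Wy <- model$Wy - config$learning_rate * grads$dWy
          }
        }
        losses <- c(losses, mean(batch_losses))
      }
    })
  }
  pred <- lstm_predict(model, ds)
  acc <- mean(pred$labels == ds$labels)
  list(model = model,
       report = list(epoch_loss = losses, train_accuracy = acc,
                     updates = updates, seed = config$seed))
}

#' Predict classes for feature sequences
#'
#' Deterministic inference (dropout disabled). Scores are softmax
#' probabilities summing to one; the predicted label is the higher-scoring
#' class, with the 0.5 tie breaking to non-seizure.
#'
#' @param model an `lstm_model`.
#' @param ds a [sequence_dataset] (labels may be placeholders).
#' @return list with `labels` (character) and `scores` (n x 2 matrix,
#'   columns `non_seizure`, `seizure`).
#' @export
lstm_predict <- function(model, ds) {
  assert_that(inherits(model, "lstm_model"), "model must be an lstm_model")
  assert_that(inherits(ds, "sequence_dataset"), "ds must be a sequence_dataset")
  if (ds$n_features != model$input_dim)
    stop_seizr(sprintf("feature width %d does not match model input %d",
                       ds$n_features, model$input_dim), "seizr_shape")
  X <- seq_array(ds)
  fwd <- lstm_forward_batch(model, X, mask = NULL)
  probs <- fwd$probs
  colnames(probs) <- CLASS_LEVELS
  labels <- ifelse(probs[, "seizure"] > 0.5, "seizure", "non_seizure")
  list(labels = labels, scores = probs)
}

stratified_folds <- function(labels, k, seed) {
  idx_by_class <- split(seq_along(labels), labels)
  if (any(vapply(idx_by_class, length, integer(1)) < k))
    stop_seizr(sprintf("cannot stratify %d folds: a class has fewer members than folds", k),
               "seizr_invalid")
  folds <- vector("list", k)
  with_rng(derive_seed(seed, "folds"), {
    for (cls in idx_by_class) {
      cls <- sample(cls)
      for (i in seq_along(cls)) {
        fi <- (i - 1L) %% k + 1L
        folds[[fi]] <- c(folds[[fi]], cls[i])
      }
    }
  })
  folds
}

#' Cross-validated fitness of a hyperparameter position
#'
#' Decodes `position` through `space`, runs stratified k-fold
#' cross-validation of the LSTM on `ds`, and returns `1 - mean validation
#' accuracy` (an error in `[0, 1]`, suitable for the minimizing
#' optimizers). Deterministic for a fixed `(position, seed)`.
#'
#' @param position optimizer coordinate vector.
#' @param space a [search_space].
#' @param ds a [sequence_dataset].
#' @param k_folds number of folds, >= 2.
#' @param seed RNG seed controlling folds and training.
#' @param epochs,batch_size training budget per fold.
#' @return scalar fitness in `[0, 1]`.
#' @export
cv_fitness <- function(position, space, ds, k_folds = 10L, seed = 1L,
                       epochs = 10L, batch_size = 16L) {
  assert_that(k_folds >= 2L, "k_folds must be >= 2")
  hp <- decode_position(position, space)
  folds <- stratified_folds(ds$labels, k_folds, seed)
  accs <- vapply(seq_len(k_folds), function(fi) {
    test_idx <- folds[[fi]]
    train_idx <- setdiff(seq_along(ds$sequences), test_idx)
    train_ds <- sequence_dataset(ds$sequences[train_idx], ds$labels[train_idx],
                                 ds$source_ids[train_idx])
    test_ds <- sequence_dataset(ds$sequences[test_idx], ds$labels[test_idx],
                                ds$source_ids[test_idx])
    cfg <- lstm_config(hidden_units = hp$hidden_units,
                       learning_rate = hp$learning_rate, dropout = hp$dropout,
                       epochs = epochs, batch_size = batch_size,
                       seed = derive_seed(seed, sprintf("fold%d", fi)))
    fit <- lstm_train(train_ds, cfg)
    pred <- lstm_predict(fit$model, test_ds)
    mean(pred$labels == test_ds$labels)
  }, numeric(1))
  1 - mean(accs)
}
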