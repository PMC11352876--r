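# Shared fixtures, all built in code.

# Write a Bonn-style directory tree with `n_files` short segments per set.
make_bonn_tree <- function(root, sets = c("D", "E"), n_files = 3L, n = 32L,
                           seed = 1L) {
  for (set in sets) {
    dir.create(file.path(root, set), recursive = TRUE, showWarnings = FALSE)
    set.seed(seed + match(set, LETTERS))
    for (i in seq_len(n_files))
      writeLines(as.character(sample(-100:100, n, replace = TRUE)),
                 file.path(root, set, sprintf("%s%03d.txt", set, i)))
  }
  root
}

# Two-class sequence data with the class means separated by `sep` pooled SDs.
make_separable_task <- function(n_per = 50L, t_len = 6L, n_feat = 4L,
                                sep = 5, seed = 11L) {
  set.seed(seed)
  seqs <- c(lapply(seq_len(n_per), function(i) matrix(rnorm(t_len * n_feat), t_len)),
            lapply(seq_len(n_per), function(i) matrix(rnorm(t_len * n_feat, mean = sep), t_len)))
  sequence_dataset(seqs, rep(c("non_seizure", "seizure"), each = n_per))
}

# Small, fast pipeline configuration for smoke tests.
tiny_run_config <- function(method = "ps_lstm", seed = 5L, ...) {
  run_config(method = method,
             data = synth_config(n_per_class = 10L, n_samples = 512L, seed = seed),
             win = 128L, population = 2L, iterations = 2L, cv_folds = 2L,
             epochs = 3L, seed = seed, ...)
}

# Independently coded brute-force fuzzy C-means (plain loops), sharing only
# the documented seeded initialization with the package implementation.
brute_force_fcm <- function(X, c, m, tol, max_iter, seed) {
  n <- nrow(X); p <- ncol(X)
  U <- seizr:::with_rng(seed, {
    u <- matrix(stats::runif(n * c), n, c)
    u / rowSums(u)
  })
  prev <- Inf
  for (iter in seq_len(max_iter)) {
    centers <- matrix(0, c, p)
    for (j in seq_len(c)) {
      w <- U[, j]^m
      for (col in seq_len(p)) centers[j, col] <- sum(w * X[, col]) / sum(w)
    }
    d2 <- matrix(0, n, c)
    for (i in seq_len(n)) for (j in seq_len(c))
      d2[i, j] <- sum((X[i, ] - centers[j, ])^2)
    for (i in seq_len(n)) {
      if (any(d2[i, ] < 1e-12)) {
        U[i, ] <- 0; U[i, which(d2[i, ] < 1e-12)[1]] <- 1
      } else {
        for (j in seq_len(c))
          U[i, j] <- 1 / sum((d2[i, j] / d2[i, ])^(1 / (m - 1)))
      }
    }
    obj <- 0
    for (i in seq_len(n)) for (j in seq_len(c))
      obj <- obj + U[i, j]^m * d2[i, j]
    if (is.finite(prev) && prev - obj < tol) break
    prev <- obj
  }
  list(centers = centers, memberships = U)
}

# Independent metric oracle: materializes the label vectors a confusion
# matrix summarizes and recomputes each metric from first principles
# (MCC as the Pearson correlation of the binary vectors, kappa via the
# agreement identity), avoiding the package's formulas.
oracle_metrics <- function(TP, FP, TN, FN) {
  truth <- c(rep(1, TP), rep(0, FP), rep(0, TN), rep(1, FN))
  pred <- c(rep(1, TP), rep(1, FP), rep(0, TN), rep(0, FN))
  acc <- mean(truth == pred)
  sens <- if (TP + FN == 0) 0 else TP / (TP + FN)
  spec <- if (TN + FP == 0) 0 else TN / (TN + FP)
  prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  mcc <- if (stats::sd(truth) == 0 || stats::sd(pred) == 0) 0 else
    stats::cor(truth, pred)
  pe <- mean(truth == 1) * mean(pred == 1) + mean(truth == 0) * mean(pred == 0)
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  csi <- if (TP + FP + FN == 0) 0 else TP / (TP + FP + FN)
  fm <- sqrt(prec * sens)
  100 * c(accuracy = acc, sensitivity = sens, specificity = spec,
          precision = prec, f1 = f1, mcc = mcc, kappa = kappa, csi = csi,
          fm_index = fm)
}

# Direct-DFT band power (independent of any package code path).
dft_band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  keep <- f >= f_lo & f <= f_hi & f <= fs / 2
  sum(Mod(X[keep])^2) / n
}
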