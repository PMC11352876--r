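# Windowed statistical features, fuzzy C-means clustering and
# membership-based feature selection.
#
# Features per window: mean, variance (Hjorth activity), standard
# deviation, skewness, kurtosis (population moments, non-excess) and
# Shannon entropy (bits) of a 16-bin amplitude histogram spanning the
# window's min-max range. FCM follows the canonical Bezdek alternating
# optimization.

FEATURE_NAMES <- c("mean", "variance", "standard_deviation", "skewness",
                   "kurtosis", "shannon_entropy")

#' Slice a record into fixed-width windows
#'
#' Produces windows of exactly `win` samples at step
#' `max(1, round(win * (1 - overlap_frac)))`; a trailing remainder shorter
#' than `win` is dropped.
#'
#' @param record an [eeg_record] (or bare numeric vector).
#' @param win window width in samples.
#' @param overlap_frac fractional overlap in `[0, 1)`.
#' @return list of numeric vectors, each of length `win`.
#' @export
window_segments <- function(record, win, overlap_frac = 0) {
  x <- if (inherits(record, "eeg_record")) record$samples else as.numeric(record)
  win <- as.integer(win)
  assert_that(overlap_frac >= 0 && overlap_frac < 1, "overlap_frac must be in [0, 1)")
  if (win > length(x))
    stop_seizr(sprintf("window (%d) exceeds record length (%d)", win, length(x)),
               "seizr_param")
  step <- max(1L, as.integer(round(win * (1 - overlap_frac))))
  starts <- seq(1L, length(x) - win + 1L, by = step)
  lapply(starts, function(s) x[s:(s + win - 1L)])
}

#' Statistical features of one window
#'
#' Population-moment definitions: variance = m2, skewness = m3 / m2^1.5,
#' kurtosis = m4 / m2^2 (non-excess). Shannon entropy is computed from a
#' 16-bin histogram over the window's own min-max range (amplitude
#' invariant); empty bins contribute zero. Zero-variance windows return
#' skewness = kurtosis = 0 by convention and entropy 0 (single occupied
#' bin).
#'
#' @param segment numeric vector, length >= 2.
#' @return named numeric vector of the six features.
#' @export
stat_features <- function(segment) {
  x <- as.numeric(segment)
  if (length(x) < 2L)
    stop_seizr("segment must contain at least 2 samples", "seizr_param")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  rng <- range(x)
  if (rng[2] > rng[1]) {
    breaks <- seq(rng[1], rng[2], length.out = 17L)
    counts <- tabulate(pmin(16L, pmax(1L, findInterval(x, breaks, rightmost.closed = TRUE))),
                       nbins = 16L)
    p <- counts / length(x)
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
  } else entropy <- 0
  c(mean = mu, variance = m2, standard_deviation = sqrt(m2),
    skewness = skew, kurtosis = kurt, shannon_entropy = entropy)
}

#' Feature matrix for a set of records
#'
#' Windows each record and stacks per-window feature vectors. Row order is
#' record-major then window-major; `record_id` and `window` columns of the
#' attribute frame give provenance.
#'
#' @param ds a [signal_dataset] (or list of [eeg_record]).
#' @param win window width in samples.
#' @param overlap_frac fractional overlap.
#' @return a `feature_matrix`: numeric matrix with feature columns plus
#'   attributes `labels` (per row), `record_id`, `window`, `n_windows`.
#' @export
feature_matrix <- function(ds, win = 512L, overlap_frac = 0) {
  records <- if (inherits(ds, "signal_dataset")) ds$records else ds
  rows <- list(); labs <- character(0); rid <- character(0); wid <- integer(0)
  for (rec in records) {
    segs <- window_segments(rec, win, overlap_frac)
    for (j in seq_along(segs)) {
      rows[[length(rows) + 1L]] <- stat_features(segs[[j]])
      labs <- c(labs, rec$label)
      rid <- c(rid, rec$source_id)
      wid <- c(wid, j)
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- FEATURE_NAMES
  structure(X, labels = labs, record_id = rid, window = wid,
            n_windows = length(window_segments(records[[1]], win, overlap_frac)),
            class = c("feature_matrix", "matrix", "array"))
}

#' Fuzzy C-means configuration
#'
#' @param c number of clusters (default 2: seizure / non-seizure structure).
#' @param m fuzziness exponent, > 1 (default 2).
#' @param tolerance convergence threshold on the objective decrease.
#' @param max_iter iteration cap.
#' @param seed RNG seed for the random membership initialization.
#' @return an `fcm_config`.
#' @export
fcm_config <- function(c = 2L, m = 2, tolerance = 1e-5, max_iter = 100L, seed = 1L) {
  assert_that(c >= 1L, "c must be >= 1")
  assert_that(m > 1, "fuzziness m must exceed 1")
  assert_that(tolerance > 0, "tolerance must be positive")
  structure(list(c = as.integer(c), m = m, tolerance = tolerance,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "fcm_config")
}

EPS_GUARD <- 1e-12

# Membership update for points X against fixed centers (Bezdek inverse
# squared-distance ratios with exponent 2/(m-1)); coincident points get
# full membership in the nearest coincident cluster.
fcm_memberships <- function(X, centers, m) {
  n <- nrow(X); k <- nrow(centers)
  d2 <- matrix(0, n, k)
  for (j in seq_len(k)) d2[, j] <- rowSums(sweep(X, 2, centers[j, ])^2)
  U <- matrix(0, n, k)
  zero <- d2 < EPS_GUARD
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    for (i in which(has_zero)) U[i, which(zero[i, ])[1]] <- 1
  }
  reg <- !has_zero
  if (any(reg)) {
    pw <- d2[reg, , drop = FALSE]^(-1 / (m - 1))
    U[reg, ] <- pw / rowSums(pw)
  }
  U
}

fcm_objective <- function(X, centers, U, m) {
  k <- nrow(centers)
  s <- 0
  for (j in seq_len(k))
    s <- s + sum(U[, j]^m * rowSums(sweep(X, 2, centers[j, ])^2))
  s
}

#' Fit fuzzy C-means
#'
#' Canonical alternating optimization: centers are membership^m-weighted
#' means; memberships come from inverse squared-distance ratios with
#' exponent `2/(m-1)`. Iterates until the objective decrease falls below
#' `tolerance` or `max_iter` is reached. Deterministic for a fixed seed.
#'
#' @param X numeric matrix (rows = samples); `nrow(X) >= c`.
#' @param config an [fcm_config].
#' @return an `fcm_result` with `centers` (c x p), `memberships` (n x c,
#'   row-stochastic), `objective_trajectory`, `iterations`, `config`.
#' @export
fcm_fit <- function(X, config = fcm_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  k <- config$c
  if (k > n)
    stop_seizr(sprintf("c (%d) exceeds number of rows (%d)", k, n), "seizr_config")
  if (k == 1L) {
    centers <- matrix(colMeans(X), 1L, ncol(X))
    colnames(centers) <- colnames(X)
    U <- matrix(1, n, 1L)
    obj <- fcm_objective(X, centers, U, config$m)
    return(structure(list(centers = centers, memberships = U,
                          objective_trajectory = obj, iterations = 0L,
                          config = config),
                     class = "fcm_result"))
  }
  U <- with_rng(config$seed, {
    u <- matrix(stats::runif(n * k), n, k)
    u / rowSums(u)
  })
  traj <- numeric(0)
  prev <- Inf
  iter <- 0L
  centers <- NULL
  repeat {
    iter <- iter + 1L
    Um <- U^config$m
    centers <- (t(Um) %*% X) / pmax(colSums(Um), EPS_GUARD)
    U <- fcm_memberships(X, centers, config$m)
    obj <- fcm_objective(X, centers, U, config$m)
    traj <- c(traj, obj)
    if (is.finite(prev) && prev - obj < config$tolerance) break
    if (iter >= config$max_iter) break
    prev <- obj
  }
  colnames(centers) <- colnames(X)
  structure(list(centers = centers, memberships = U,
                 objective_trajectory = traj, iterations = iter, config = config),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result> c=%d clusters, %d samples, %d iterations, objective %.6g\n",
              nrow(x$centers), nrow(x$memberships), x$iterations,
              utils::tail(x$objective_trajectory, 1)))
  invisible(x)
}

# Separation score per column: distance between cluster centers along the
# column divided by the pooled membership-weighted within-cluster spread.
feature_separation_scores <- function(result, X) {
  centers <- result$centers
  U <- result$memberships
  k <- nrow(centers)
  p <- ncol(X)
  scores <- numeric(p)
  for (jcol in seq_len(p)) {
    sep <- if (k >= 2) max(stats::dist(centers[, jcol, drop = FALSE])) else 0
    spread <- 0
    for (jc in seq_len(k)) {
      w <- U[, jc]
      spread <- spread + sum(w * (X[, jcol] - centers[jc, jcol])^2) / pmax(sum(w), EPS_GUARD)
    }
    scores[jcol] <- sep / (sqrt(spread / k) + EPS_GUARD)
  }
  names(scores) <- colnames(X)
  scores
}

#' Select features by cluster separation and append membership degrees
#'
#' Columns are ranked by a separation score (distance between cluster
#' centers along the column over the pooled membership-weighted
#' within-cluster spread); the top `k` columns are retained in their
#' original order, and each sample's cluster membership degrees are
#' appended as additional columns (`membership1..membershipc`).
#'
#' @param result an `fcm_result` fitted on `X`.
#' @param X the feature matrix the result was fitted on.
#' @param k number of original columns to keep, `1 <= k <= ncol(X)`.
#' @return matrix with `k + c` columns; attribute `selected` names the
#'   retained columns, attribute `scores` holds all column scores.
#' @export
select_features <- function(result, X, k) {
  assert_that(inherits(result, "fcm_result"), "result must be an fcm_result")
  X <- as.matrix(X)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > ncol(X))
    stop_seizr(sprintf("k must be in 1..%d", ncol(X)), "seizr_param")
  scores <- feature_separation_scores(result, X)
  keep <- sort(order(scores, decreasing = TRUE)[seq_len(k)])
  out <- cbind(X[, keep, drop = FALSE], result$memberships)
  colnames(out) <- c(colnames(X)[keep],
                     sprintf("membership%d", seq_len(ncol(result$memberships))))
  for (a in c("labels", "record_id", "window", "n_windows"))
    attr(out, a) <- attr(X, a)
  attr(out, "selected") <- colnames(X)[keep]
  attr(out, "scores") <- scores
  out
}

#' Membership degrees of new samples under fitted centers
#' @param result an `fcm_result`.
#' @param X numeric matrix of new samples (same columns as the fit).
#' @return n x c row-stochastic membership matrix.
#' @export
fcm_membership_for <- function(result, X) {
  fcm_memberships(as.matrix(X), result$centers, result$config$m)
}
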