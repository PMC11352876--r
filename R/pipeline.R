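# End-to-end orchestration of the three method variants:
#   fcm_ps_lstm : FCM feature refinement + PSO-tuned LSTM (10-fold CV)
#   ps_lstm     : PSO-tuned LSTM (10-fold CV)
#   po_lstm     : parrot-optimizer-tuned LSTM (5-fold CV)
# Stages: load/generate -> band-pass -> median -> RADWT reconstruct ->
# stratified 70/30 holdout -> (optional) augment the training side ->
# windowed statistical features (+ FCM selection for fcm_ps_lstm) ->
# hyperparameter search over CV fitness on the training side -> final
# train -> metrics on the held-out test side.
#
# Augmented variants never cross the split: the split is made on original
# records and only the training side is augmented, so the test set always
# consists of unaugmented segments and is identical between the
# before/after-augmentation arms of a comparison. The leak-prone
# augment-then-split ordering is available behind `paper_ordering = TRUE`.

METHODS <- c("fcm_ps_lstm", "ps_lstm", "po_lstm")

default_cv_folds <- function(method) if (method == "po_lstm") 5L else 10L

#' Pipeline run configuration
#'
#' @param method one of `"fcm_ps_lstm"`, `"ps_lstm"`, `"po_lstm"`.
#' @param data a [signal_dataset], a [synth_config], or a path to a
#'   Bonn-style directory tree.
#' @param bandpass a [filter_spec] or `NULL` to skip.
#' @param median_window odd running-median width or `NULL` to skip.
#' @param radwt a [radwt_params] or `NULL` to skip the wavelet
#'   analysis/synthesis stage.
#' @param augment an [augment_config] for the ARDA arm, or `NULL` (BDA).
#' @param win,overlap_frac feature windowing (defaults: 512 samples, no
#'   overlap, giving 8 windows per 4097-sample segment).
#' @param n_keep_features columns kept by FCM selection (fcm_ps_lstm only).
#' @param space a [search_space] for hyperparameter decoding.
#' @param population,iterations optimizer budget (desk-scale defaults 5 and
#'   10; the reference budgets are 9 x 100 for the swarm and 30 x 1000 for
#'   the parrot optimizer).
#' @param cv_folds cross-validation folds; defaults to 10 (5 for po_lstm).
#' @param train_fraction holdout training fraction in (0, 1); default 0.7.
#' @param epochs,batch_size LSTM training budget.
#' @param paper_ordering if `TRUE`, augment the full dataset before
#'   splitting (leak-prone; kept for comparison only).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a `run_config`.
#' @export
run_config <- function(method = "ps_lstm", data = synth_config(),
                       bandpass = filter_spec(), median_window = 5L,
                       radwt = radwt_params(), augment = NULL,
                       win = 512L, overlap_frac = 0, n_keep_features = 4L,
                       space = search_space(), population = 5L,
                       iterations = 10L, cv_folds = NULL,
                       train_fraction = 0.7, epochs = 10L, batch_size = 16L,
                       paper_ordering = FALSE, seed = 1L) {
  method <- match.arg(method, METHODS)
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  cv_folds <- as.integer(cv_folds %||% default_cv_folds(method))
  assert_that(cv_folds >= 2L, "cv_folds must be >= 2")
  structure(list(method = method, data = data, bandpass = bandpass,
                 median_window = median_window, radwt = radwt,
                 augment = augment, win = as.integer(win),
                 overlap_frac = overlap_frac,
                 n_keep_features = as.integer(n_keep_features), space = space,
                 population = as.integer(population),
                 iterations = as.integer(iterations), cv_folds = cv_folds,
                 train_fraction = train_fraction, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 paper_ordering = isTRUE(paper_ordering),
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_dataset <- function(data) {
  if (inherits(data, "signal_dataset")) data
  else if (inherits(data, "synth_config")) synth_dataset(data)
  else if (is.character(data)) load_dataset(data)
  else stop_seizr("data must be a signal_dataset, synth_config or directory path",
                  "seizr_config")
}

preprocess_record <- function(rec, config) {
  if (!is.null(config$bandpass)) rec <- bandpass_filter(rec, config$bandpass)
  if (!is.null(config$median_window)) rec <- median_filter(rec, config$median_window)
  if (!is.null(config$radwt)) rec <- radwt_inverse(radwt_forward(rec, config$radwt))
  rec
}

# Root of a (possibly augmented) source id: everything before "#aug".
source_root <- function(ids) sub("#aug[0-9]+$", "", ids)

stratified_split <- function(labels, train_fraction, seed) {
  idx_by_class <- split(seq_along(labels), labels)
  with_rng(derive_seed(seed, "split"), {
    train <- integer(0)
    for (cls in idx_by_class) {
      n_tr <- round(length(cls) * train_fraction)
      n_tr <- min(max(n_tr, 1L), length(cls) - 1L)
      train <- c(train, sample(cls, n_tr))
    }
    sort(train)
  })
}

# Fit the feature transform on the training records (standardization and,
# for fcm_ps_lstm, FCM column selection + membership augmentation), then
# apply it to any record list. Returns per-record T x F sequences.
fit_feature_transform <- function(train_records, config) {
  fm <- feature_matrix(train_records, win = config$win,
                       overlap_frac = config$overlap_frac)
  center <- colMeans(fm)
  sds <- apply(unclass(fm), 2L, stats::sd)
  sds[sds < EPS_GUARD] <- 1
  transform <- list(center = center, sds = sds, fcm = NULL, selected = NULL)
  if (config$method == "fcm_ps_lstm") {
    Z <- sweep(sweep(unclass(fm), 2L, center), 2L, sds, "/")
    colnames(Z) <- colnames(fm)
    fcm <- fcm_fit(Z, fcm_config(seed = derive_seed(config$seed, "fcm")))
    scores <- feature_separation_scores(fcm, Z)
    keep <- sort(order(scores, decreasing = TRUE)[seq_len(config$n_keep_features)])
    transform$fcm <- fcm
    transform$selected <- colnames(Z)[keep]
    transform$scores <- scores
  }
  transform
}

apply_feature_transform <- function(records, transform, config) {
  fm <- feature_matrix(records, win = config$win,
                       overlap_frac = config$overlap_frac)
  n_win <- attr(fm, "n_windows")
  Z <- sweep(sweep(unclass(fm), 2L, transform$center), 2L, transform$sds, "/")
  colnames(Z) <- colnames(fm)
  if (!is.null(transform$fcm)) {
    U <- fcm_membership_for(transform$fcm, Z)
    X <- cbind(Z[, transform$selected, drop = FALSE], U)
    colnames(X) <- c(transform$selected,
                     sprintf("membership%d", seq_len(ncol(U))))
  } else X <- Z
  labs <- vapply(records, `[[`, character(1), "label")
  ids <- vapply(records, `[[`, character(1), "source_id")
  seqs <- lapply(seq_along(records), function(i)
    X[((i - 1L) * n_win + 1L):(i * n_win), , drop = FALSE])
  sequence_dataset(seqs, labs, ids)
}

tune_hyperparameters <- function(train_ds, config) {
  objective <- function(pos)
    cv_fitness(pos, config$space, train_ds, k_folds = config$cv_folds,
               seed = derive_seed(config$seed, "cv"), epochs = config$epochs,
               batch_size = config$batch_size)
  b <- config$space$bounds
  if (config$method == "po_lstm")
    po_optimize(objective, b, n_agents = max(2L, config$population),
                max_iter = config$iterations,
                seed = derive_seed(config$seed, "tune"))
  else
    pso_optimize(objective, b, n = config$population,
                 max_iter = config$iterations,
                 seed = derive_seed(config$seed, "tune"))
}

#' Run one method variant end to end
#'
#' @param config a [run_config].
#' @return a `run_result`: best hyperparameters, optimizer history, the
#'   held-out-test `metrics_report` and confusion matrix, train/test source
#'   ids, augmentation provenance (if any) and the seed.
#' @export
run_method <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  ds <- resolve_dataset(config$data)
  records <- lapply(ds$records, preprocess_record, config = config)
  labels <- vapply(records, `[[`, character(1), "label")
  assert_that(all(labels %in% c("seizure", "non_seizure")),
              "pipeline records must be labeled seizure/non_seizure")
  provenance <- NULL
  if (!is.null(config$augment) && config$paper_ordering) {
    aug <- config$augment
    aug$seed <- derive_seed(config$seed, "augment")
    ads <- augment_dataset(signal_dataset(records), aug)
    provenance <- ads$provenance
    records <- ads$records
    labels <- vapply(records, `[[`, character(1), "label")
    warning("paper_ordering = TRUE: augmented variants may leak across the split")
  }
  train_idx <- stratified_split(labels, config$train_fraction, config$seed)
  test_idx <- setdiff(seq_along(records), train_idx)
  train_records <- records[train_idx]
  test_records <- records[test_idx]
  train_records_orig <- train_records
  if (!is.null(config$augment) && !config$paper_ordering) {
    aug <- config$augment
    aug$seed <- derive_seed(config$seed, "augment")
    ads <- augment_dataset(signal_dataset(train_records), aug)
    provenance <- ads$provenance
    train_records <- ads$records
  }
  # Standardization and FCM selection are fitted on the *original* training
  # records: augmented variants (amplitude-reduced by design) would
  # otherwise shift the feature statistics away from the unaugmented
  # test-time distribution.
  transform <- fit_feature_transform(train_records_orig, config)
  train_ds <- apply_feature_transform(train_records, transform, config)
  test_ds <- apply_feature_transform(test_records, transform, config)
  if (!config$paper_ordering) {
    leak <- intersect(source_root(train_ds$source_ids),
                      source_root(test_ds$source_ids))
    if (length(leak) > 0)
      stop_seizr(sprintf("leakage check failed: %d source(s) on both sides (e.g. %s)",
                         length(leak), leak[1]), "seizr_leakage")
  }
  tuned <- tune_hyperparameters(train_ds, config)
  hp <- decode_position(tuned$best_position, config$space)
  final_cfg <- lstm_config(hidden_units = hp$hidden_units,
                           learning_rate = hp$learning_rate,
                           dropout = hp$dropout, epochs = config$epochs,
                           batch_size = config$batch_size,
                           seed = derive_seed(config$seed, "final"))
  fit <- lstm_train(train_ds, final_cfg)
  pred <- lstm_predict(fit$model, test_ds)
  cm <- confusion(test_ds$labels, pred$labels)
  structure(list(method = config$method, best_hyperparameters = hp,
                 optimizer = tuned, cv_fitness_best = tuned$best_value,
                 train_report = fit$report, model = fit$model,
                 test_metrics = compute_metrics(cm), confusion = cm,
                 train_ids = train_ds$source_ids, test_ids = test_ds$source_ids,
                 provenance = provenance, transform = transform,
                 seed = config$seed, config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> method=%s seed=%d\n", x$method, x$seed))
  cat(sprintf("  tuned: lr=%.3g, hidden=%d, dropout=%.2f (cv error %.4f)\n",
              x$best_hyperparameters$learning_rate,
              x$best_hyperparameters$hidden_units,
              x$best_hyperparameters$dropout, x$cv_fitness_best))
  cat(sprintf("  test accuracy %.2f%% on %d held-out records\n",
              x$test_metrics[["accuracy"]], length(x$test_ids)))
  invisible(x)
}

#' Compare a method before and after random data augmentation
#'
#' Runs the configured method twice on identical seeds and splits: once
#' without augmentation (BDA) and once with (ARDA). The two runs share the
#' same held-out test records.
#'
#' @param config a [run_config] whose `augment` field is an
#'   [augment_config].
#' @return list with `bda` and `arda` run results, a two-row `table` (BDA /
#'   ARDA by the nine metrics) and `delta` (ARDA minus BDA).
#' @export
compare_bda_arda <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  assert_that(inherits(config$augment, "augment_config"),
              "config$augment must be an augment_config for a comparison")
  cfg_bda <- config
  cfg_bda$augment <- NULL
  bda <- run_method(cfg_bda)
  arda <- run_method(config)
  tab <- rbind(BDA = round(unclass(bda$test_metrics), 2),
               ARDA = round(unclass(arda$test_metrics), 2))
  list(bda = bda, arda = arda, table = as.data.frame(tab),
       delta = unclass(arda$test_metrics) - unclass(bda$test_metrics))
}
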