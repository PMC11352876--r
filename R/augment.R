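# Random data augmentation (RDA): label-preserving variants of EEG segments
# by amplitude scaling, circular time shift, width (duration) warping, and
# an amplitude+width combination. All transforms are length-preserving.

#' Augmentation configuration
#'
#' @param amp_range length-2 numeric, multiplicative amplitude factors drawn
#'   uniformly; default `c(0.5, 1)` (reduction-only, matching the intent of
#'   scaling seizure amplitudes down).
#' @param shift_frac maximum circular shift as a fraction of record length,
#'   in `[0, 0.5]`; default 0.1.
#' @param width_range length-2 numeric resampling (duration) factors;
#'   default `c(0.9, 1.1)`.
#' @param factor number of augmented copies per input record; default 2.
#' @param seed RNG seed.
#' @return an `augment_config`.
#' @export
augment_config <- function(amp_range = c(0.5, 1), shift_frac = 0.1,
                           width_range = c(0.9, 1.1), factor = 2L, seed = 1L) {
  assert_that(length(amp_range) == 2L && amp_range[1] > 0 && amp_range[1] <= amp_range[2],
              "amp_range must satisfy 0 < low <= high")
  assert_that(shift_frac >= 0 && shift_frac <= 0.5, "shift_frac must be in [0, 0.5]")
  assert_that(length(width_range) == 2L && width_range[1] > 0 &&
                width_range[1] <= width_range[2],
              "width_range must satisfy 0 < low <= high")
  assert_that(factor >= 0L, "factor must be >= 0")
  structure(list(amp_range = as.numeric(amp_range), shift_frac = shift_frac,
                 width_range = as.numeric(width_range), factor = as.integer(factor),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Amplitude scaling
#'
#' Multiplies every sample by `s`; label, length and sampling rate are
#' preserved. Exactly invertible by `1/s`.
#'
#' @param record an [eeg_record].
#' @param s positive scale factor.
#' @return the scaled [eeg_record].
#' @export
rda_amplitude <- function(record, s) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop_seizr("amplitude scale s must be a positive finite scalar", "seizr_param")
  out <- record
  out$samples <- record$samples * s
  out
}

#' Circular time shift
#'
#' Rotates the sample sequence by `k` positions (positive `k` delays the
#' signal). Circular shifting keeps the multiset of sample values -- and
#' hence all amplitude statistics -- unchanged.
#'
#' @param record an [eeg_record].
#' @param k integer sample offset, `|k| < length`.
#' @return the shifted [eeg_record].
#' @export
rda_shift <- function(record, k) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  n <- length(record$samples)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || abs(k) >= n)
    stop_seizr(sprintf("shift |k| must be below record length %d", n), "seizr_param")
  k <- as.integer(k) %% n
  out <- record
  if (k != 0L) out$samples <- c(record$samples[(n - k + 1):n], record$samples[1:(n - k)])
  out
}

# Band-limited (FFT) resampling of x to m samples.
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  keep <- min(n, m)
  h <- (keep - 1L) %/% 2L
  Y[1] <- X[1]
  if (h >= 1) {
    Y[2:(h + 1)] <- X[2:(h + 1)]
    Y[m:(m - h + 1)] <- X[n:(n - h + 1)]
  }
  if (keep %% 2L == 0L) {            # shared Nyquist bin, split evenly
    ny <- keep %/% 2L
    Y[ny + 1] <- X[ny + 1] / 2
    Y[m - ny + 1] <- Conj(X[ny + 1]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Width (duration) warping
#'
#' Band-limited resampling by factor `w` stretches (`w > 1`) or compresses
#' (`w < 1`) the signal in time, scaling every frequency by `1/w`. The
#' result is center-cropped (`w > 1`) or reflection-extended (`w < 1`) back
#' to the original length, so the transform is length-preserving.
#'
#' @param record an [eeg_record].
#' @param w positive warp factor.
#' @return the warped [eeg_record].
#' @export
rda_width <- function(record, w) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0)
    stop_seizr("width factor w must be a positive finite scalar", "seizr_param")
  x <- record$samples
  n <- length(x)
  m <- max(2L, as.integer(round(n * w)))
  y <- fft_resample(x, m)
  if (m >= n) {
    start <- (m - n) %/% 2L
    y <- y[(start + 1):(start + n)]
  } else {
    need <- n - m
    left <- need %/% 2L
    right <- need - left
    lpad <- if (left > 0) y[(left + 1):2] else numeric(0)
    rpad <- if (right > 0) y[(m - 1):(m - right)] else numeric(0)
    y <- c(lpad, y, rpad)
  }
  out <- record
  out$samples <- y
  out
}

#' Augment a dataset with random label-preserving variants
#'
#' For each input record, draws `factor` variants with a seeded RNG: the
#' transform is chosen uniformly among amplitude, shift, width and
#' amplitude+width combined; parameters are drawn uniformly from the
#' configured ranges. The output holds the originals followed by the
#' variants; per-record provenance records the source, transform and drawn
#' parameters.
#'
#' @param ds a [signal_dataset]; must be non-empty.
#' @param config an [augment_config].
#' @return an `augmented_dataset`: a [signal_dataset] plus a `provenance`
#'   data frame (source_id, transform, parameter, output_id).
#' @export
augment_dataset <- function(ds, config = augment_config()) {
  assert_that(inherits(ds, "signal_dataset"), "ds must be a signal_dataset")
  if (length(ds$records) == 0L)
    stop_seizr("cannot augment an empty dataset", "seizr_invalid")
  assert_that(inherits(config, "augment_config"), "config must be an augment_config")
  transforms <- c("amplitude", "shift", "width", "combined")
  variants <- list()
  prov <- list()
  with_rng(config$seed, {
    for (i in seq_along(ds$records)) {
      rec <- ds$records[[i]]
      n <- length(rec$samples)
      for (v in seq_len(config$factor)) {
        tr <- transforms[sample.int(4L, 1L)]
        out_id <- sprintf("%s#aug%d", rec$source_id, v)
        if (tr == "amplitude") {
          s <- stats::runif(1, config$amp_range[1], config$amp_range[2])
          new <- rda_amplitude(rec, s)
          par <- sprintf("s=%.6g", s)
        } else if (tr == "shift") {
          kmax <- max(1L, as.integer(floor(config$shift_frac * n)))
          k <- sample.int(2L * kmax + 1L, 1L) - kmax - 1L
          new <- rda_shift(rec, k)
          par <- sprintf("k=%d", k)
        } else if (tr == "width") {
          w <- stats::runif(1, config$width_range[1], config$width_range[2])
          new <- rda_width(rec, w)
          par <- sprintf("w=%.6g", w)
        } else {
          s <- stats::runif(1, config$amp_range[1], config$amp_range[2])
          w <- stats::runif(1, config$width_range[1], config$width_range[2])
          new <- rda_width(rda_amplitude(rec, s), w)
          par <- sprintf("s=%.6g;w=%.6g", s, w)
        }
        new$source_id <- out_id
        variants[[length(variants) + 1L]] <- new
        prov[[length(prov) + 1L]] <- data.frame(
          source_id = rec$source_id, transform = tr, parameter = par,
          output_id = out_id, label = rec$label, stringsAsFactors = FALSE)
      }
    }
  })
  out <- signal_dataset(c(ds$records, variants))
  out$provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(source_id = character(0), transform = character(0),
               parameter = character(0), output_id = character(0),
               label = character(0), stringsAsFactors = FALSE)
  class(out) <- c("augmented_dataset", class(out))
  out
}

#' Export augmentation provenance as a tab-separated file
#' @param ads an `augmented_dataset`.
#' @param path output file path.
#' @return invisibly, the provenance data frame.
#' @export
write_provenance <- function(ads, path) {
  assert_that(inherits(ads, "augmented_dataset"), "ads must be an augmented_dataset")
  utils::write.table(ads$provenance, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(ads$provenance)
}
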