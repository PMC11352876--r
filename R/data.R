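# Bonn-format EEG input and synthetic dataset generation.
#
# The Bonn database distributes each EEG segment as a plain ASCII file with
# one amplitude value (microvolts) per line, 4097 samples per segment,
# sampled at 173.61 Hz. Sets are stored one directory per set; set E holds
# ictal (seizure) segments and set D inter-ictal (non-seizure) segments.

BONN_FS <- 173.61
BONN_N_SAMPLES <- 4097L

LABELS <- c("seizure", "non_seizure", "unlabeled")

#' Construct an EEG record
#'
#' An `eeg_record` is the package's atomic data object: a single-channel,
#' fixed-rate amplitude sequence with a class label and an origin tag.
#'
#' @param samples numeric vector of amplitudes (microvolts); finite, length > 0.
#' @param fs sampling rate in Hz; positive scalar.
#' @param label one of `"seizure"`, `"non_seizure"`, `"unlabeled"`.
#' @param source_id origin string (file path or `"synthetic:<seed>:<index>"`).
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, label = "unlabeled", source_id = "<memory>") {
  samples <- as.numeric(samples)
  assert_that(length(samples) > 0L, "samples must be non-empty")
  assert_that(all(is.finite(samples)), "samples must all be finite")
  assert_that(is.numeric(fs) && length(fs) == 1L && fs > 0, "fs must be a positive scalar")
  label <- match.arg(label, LABELS)
  structure(list(samples = samples, fs = as.numeric(fs), label = label,
                 source_id = as.character(source_id)),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d samples @ %.2f Hz, label=%s, source=%s\n",
              length(x$samples), x$fs, x$label, x$source_id))
  invisible(x)
}

#' Construct a signal dataset
#'
#' @param records list of [eeg_record] objects sharing one sampling rate.
#' @return a `signal_dataset` with per-label `class_counts`.
#' @export
signal_dataset <- function(records = list()) {
  assert_that(all(vapply(records, inherits, logical(1), "eeg_record")),
              "records must all be eeg_record objects")
  if (length(records) > 1L) {
    fs <- vapply(records, `[[`, numeric(1), "fs")
    assert_that(max(fs) - min(fs) == 0, "all records must share one sampling rate")
  }
  labs <- vapply(records, `[[`, character(1), "label")
  counts <- vapply(LABELS, function(l) sum(labs == l), integer(1))
  structure(list(records = records, class_counts = counts),
            class = "signal_dataset")
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("<signal_dataset> %d records (seizure=%d, non_seizure=%d, unlabeled=%d)\n",
              length(x$records), x$class_counts[["seizure"]],
              x$class_counts[["non_seizure"]], x$class_counts[["unlabeled"]]))
  invisible(x)
}

#' @export
length.signal_dataset <- function(x) length(x$records)

infer_label_from_path <- function(path) {
  set <- basename(dirname(normalizePath(path, mustWork = FALSE)))
  if (toupper(set) == "E") "seizure" else if (toupper(set) == "D") "non_seizure" else "unlabeled"
}

#' Read one Bonn-format EEG segment
#'
#' Parses a plain ASCII file with one numeric amplitude per line (the Bonn
#' dialect: integers in the public files; floats are accepted). The label is
#' inferred from the containing directory: `E` maps to seizure, `D` to
#' non-seizure, anything else loads unlabeled.
#'
#' @param path file path.
#' @param fs sampling rate to stamp on the record; Bonn default 173.61 Hz.
#' @param label override the inferred label (optional).
#' @return an [eeg_record].
#' @export
read_bonn_segment <- function(path, fs = BONN_FS, label = NULL) {
  assert_that(file.exists(path), sprintf("file not found: %s", path), "seizr_not_found")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop_seizr(sprintf("format error: empty Bonn segment file '%s'", path), "seizr_format")
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop_seizr(sprintf("format error in '%s': non-numeric value '%s' at line %d",
                       path, lines[bad], bad), "seizr_format")
  }
  eeg_record(vals, fs = fs, label = label %||% infer_label_from_path(path),
             source_id = as.character(path))
}

#' Load a Bonn-style dataset from per-set directories
#'
#' @param root directory containing one sub-directory per set (e.g. `D`, `E`).
#' @param sets character vector of set names to load; default the two sets
#'   used for seizure/non-seizure classification.
#' @param fs sampling rate for all records.
#' @return a [signal_dataset].
#' @export
load_dataset <- function(root, sets = c("D", "E"), fs = BONN_FS) {
  records <- list()
  for (set in sets) {
    dir <- file.path(root, set)
    if (!dir.exists(dir))
      stop_seizr(sprintf("set directory not found: '%s' (set %s)", dir, set),
                 "seizr_not_found")
    files <- sort(list.files(dir, full.names = TRUE))
    files <- files[!dir.exists(files)]
    lab <- if (toupper(set) == "E") "seizure" else if (toupper(set) == "D") "non_seizure" else "unlabeled"
    for (f in files) records[[length(records) + 1L]] <- read_bonn_segment(f, fs = fs, label = lab)
  }
  signal_dataset(records)
}

#' Write a dataset as Bonn-style ASCII files plus a manifest
#'
#' Serializes each record to one value-per-line ASCII (full precision) in
#' `dir`, with a tab-separated `manifest.tsv` (file, source_id, label, fs).
#' `read_dataset()` restores it; parse/serialize round-trips are exact.
#'
#' @param ds a [signal_dataset].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(ds$records)
  files <- sprintf("rec%04d.txt", seq_len(n))
  for (i in seq_len(n))
    writeLines(format(ds$records[[i]]$samples, digits = 17, trim = TRUE, scientific = FALSE),
               file.path(dir, files[i]))
  man <- data.frame(file = files,
                    source_id = vapply(ds$records, `[[`, character(1), "source_id"),
                    label = vapply(ds$records, `[[`, character(1), "label"),
                    fs = vapply(ds$records, `[[`, numeric(1), "fs"),
                    stringsAsFactors = FALSE)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(man)
}

#' Read a dataset written by [write_dataset()]
#' @param dir directory holding the ASCII files and `manifest.tsv`.
#' @return a [signal_dataset].
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  assert_that(file.exists(man_path), sprintf("manifest not found in '%s'", dir),
              "seizr_not_found")
  man <- utils::read.table(man_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(man)), function(i) {
    rec <- read_bonn_segment(file.path(dir, man$file[i]), fs = man$fs[i], label = man$label[i])
    rec$source_id <- man$source_id[i]
    rec
  })
  signal_dataset(records)
}

#' Synthetic dataset configuration
#'
#' Describes the stated world the generator emulates: Bonn geometry (two
#' classes of 100 segments, 4097 samples at 173.61 Hz) with a seizure class
#' carrying high-amplitude spike-wave bursts and elevated 20-30 Hz (high
#' beta) band power, the band associated with anxiety.
#'
#' @param n_per_class segments per class (default 100, the Bonn set size).
#' @param n_samples segment length (default 4097).
#' @param fs sampling rate in Hz (default 173.61).
#' @param seizure_beta_gain multiplier (>= 1) for the seizure class 20-30 Hz
#'   band-limited component (default 4).
#' @param spike_rate spike-wave bursts per second in the seizure class
#'   (default 3, the classic ~3/s spike-wave rhythm).
#' @param noise_scale RMS of the pink-noise background in microvolts
#'   (default 30).
#' @param amp_jitter per-record overall amplitude variability: each record
#'   is scaled by a factor drawn uniformly from
#'   `(1 - amp_jitter, 1 + amp_jitter)`, emulating the large
#'   recording-to-recording amplitude spread of real EEG segments
#'   (default 0.4).
#' @param seed RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_per_class = 100L, n_samples = BONN_N_SAMPLES,
                         fs = BONN_FS, seizure_beta_gain = 4,
                         spike_rate = 3, noise_scale = 30, amp_jitter = 0.4,
                         seed = 1L) {
  assert_that(n_per_class >= 1L, "n_per_class must be >= 1")
  assert_that(n_samples >= 64L, "n_samples must be >= 64")
  assert_that(fs > 0, "fs must be positive")
  assert_that(seizure_beta_gain >= 1, "seizure_beta_gain must be >= 1")
  assert_that(spike_rate >= 0, "spike_rate must be >= 0")
  assert_that(noise_scale > 0, "noise_scale must be positive")
  assert_that(amp_jitter >= 0 && amp_jitter < 1, "amp_jitter must be in [0, 1)")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_samples = as.integer(n_samples), fs = fs,
                 seizure_beta_gain = seizure_beta_gain, spike_rate = spike_rate,
                 noise_scale = noise_scale, amp_jitter = amp_jitter,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f (pink) background: white Gaussian noise whose spectrum is shaped by
# 1/sqrt(f) (symmetric scaling keeps the signal real), normalized to the
# requested RMS.
pink_noise <- function(n, rms) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)
  f[1] <- 1
  X <- X / sqrt(f)
  X[1] <- 0 + 0i                    # remove DC
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y * rms / stats::sd(y)
}

# Band-limited Gaussian noise restricted to [f_lo, f_hi] Hz.
band_noise <- function(n, fs, f_lo, f_hi, rms) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)             # two-sided frequency axis
  X[f < f_lo | f > f_hi] <- 0 + 0i
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  (y - mean(y)) * rms / s
}

# Biphasic spike-wave kernel (sharp positive spike followed by a slower
# negative wave), unit peak amplitude.
spike_wave_kernel <- function(fs) {
  t <- seq(0, 0.25, by = 1 / fs)
  spike <- exp(-((t - 0.02) / 0.008)^2)
  wave <- -0.6 * exp(-((t - 0.12) / 0.045)^2)
  spike + wave
}

#' Generate a synthetic Bonn-mimicking dataset
#'
#' Non-seizure segments are pink-noise background plus a 10 Hz (alpha)
#' rhythm; seizure segments share the background and add spike-wave bursts
#' at `spike_rate` per second plus a 20-30 Hz band-limited component scaled
#' by `seizure_beta_gain`. Deterministic for a fixed seed; seizure records
#' come first, then non-seizure.
#'
#' @param config a [synth_config].
#' @return a [signal_dataset].
#' @export
synth_dataset <- function(config = synth_config()) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  with_rng(config$seed, {
    n <- config$n_samples
    fs <- config$fs
    t <- (seq_len(n) - 1) / fs
    kernel <- spike_wave_kernel(fs)
    make_one <- function(label, index) {
      bg <- pink_noise(n, rms = config$noise_scale)
      if (label == "non_seizure") {
        rhythm <- 0.8 * config$noise_scale *
          sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
        x <- bg + rhythm
      } else {
        n_spikes <- stats::rpois(1, config$spike_rate * n / fs)
        train <- numeric(n)
        if (n_spikes > 0) {
          pos <- sort(sample.int(n, min(n_spikes, n)))
          train[pos] <- 3 * config$noise_scale * stats::runif(length(pos), 0.8, 1.2)
        }
        bursts <- stats::convolve(train, rev(kernel), type = "open")[seq_len(n)]
        beta <- band_noise(n, fs, 20, 30,
                           rms = 0.5 * config$noise_scale * config$seizure_beta_gain)
        x <- bg + bursts + beta
      }
      if (config$amp_jitter > 0)
        x <- x * stats::runif(1, 1 - config$amp_jitter, 1 + config$amp_jitter)
      eeg_record(x, fs = fs, label = label,
                 source_id = sprintf("synthetic:%d:%s:%03d", config$seed, label, index))
    }
    recs <- c(lapply(seq_len(config$n_per_class), function(i) make_one("seizure", i)),
              lapply(seq_len(config$n_per_class), function(i) make_one("non_seizure", i)))
    signal_dataset(recs)
  })
}
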