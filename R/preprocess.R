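# Signal conditioning: zero-phase IIR band-pass filtering, running-median
# smoothing, and a rational-dilation wavelet transform (RADWT).
#
# The RADWT here is an iterated two-channel filter bank built in the DFT
# domain. At each scale the spectrum is split by a power-complementary
# (Meyer-style) lowpass/highpass pair |H|^2 + |G|^2 = 1 whose cutoff sits at
# fraction p/q of the current Nyquist; the lowpass branch is critically
# resampled in frequency (dropping only exactly-zero bins), so the scale
# dilation is the rational ratio q/p rather than dyadic. The construction is
# a tight frame: perfect reconstruction and exact energy conservation hold
# by Parseval's theorem.

#' Band-pass filter specification
#'
#' @param low_hz lower passband edge (Hz).
#' @param high_hz upper passband edge (Hz).
#' @param order Butterworth prototype order (the band-pass filter has
#'   `2*order` poles).
#' @return a `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 40, order = 4L) {
  assert_that(low_hz > 0 && high_hz > low_hz, "need 0 < low_hz < high_hz")
  assert_that(order >= 1L, "order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "filter_spec")
}

poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0i) - c(0i, coef * ri)
  coef
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog prototype -> lowpass-to-bandpass transform -> bilinear transform
#' with frequency prewarping; gain normalized to unity at the geometric
#' center frequency.
#'
#' @param spec a [filter_spec].
#' @param fs sampling rate (Hz); requires `high_hz < fs/2`.
#' @return list with numerator `b`, denominator `a` (length `2*order + 1`).
#' @export
butter_bandpass <- function(spec, fs) {
  assert_that(inherits(spec, "filter_spec"), "spec must be a filter_spec")
  if (spec$high_hz >= fs / 2)
    stop_seizr(sprintf("high_hz (%g) must be below Nyquist (%g)", spec$high_hz, fs / 2),
               "seizr_config")
  n <- spec$order
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped band edges
  w1 <- 2 * fs * tan(pi * spec$low_hz / fs)
  w2 <- 2 * fs * tan(pi * spec$high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass -> bandpass: each pole splits in two
  s <- p_proto * bw / 2
  p_bp <- c(s + sqrt(s^2 - w0^2), s - sqrt(s^2 - w0^2))
  # bilinear transform; n zeros at s=0 -> z=1, n zeros at infinity -> z=-1
  z_poles <- (2 * fs + p_bp) / (2 * fs - p_bp)
  z_zeros <- c(rep(1 + 0i, n), rep(-1 + 0i, n))
  b <- poly_from_roots(z_zeros)
  a <- Re(poly_from_roots(z_poles))
  # unity gain at the digital center frequency
  wc <- 2 * pi * sqrt(spec$low_hz * spec$high_hz) / fs
  zc <- exp(-1i * wc * (seq_along(a) - 1))
  g <- abs(sum(a * zc) / sum(b * zc))
  list(b = Re(b) * g, a = a)
}

#' Magnitude response of a digital filter
#' @param coefs list with `b` and `a` polynomial coefficients.
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @return numeric vector `|H(e^{j 2 pi f / fs})|`.
#' @export
filter_response <- function(coefs, f, fs) {
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs * (seq_along(coefs$a) - 1))
    abs(sum(coefs$b * z) / sum(coefs$a * z))
  }, numeric(1))
}

# Single-pass IIR filter (direct form) via stats::filter: convolution for
# the MA part, recursive for the AR part. Zero initial state.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Zero-phase band-pass filter an EEG record
#'
#' Forward-backward application (squared magnitude response, zero phase) of
#' the Butterworth design from [butter_bandpass()], with odd-reflection
#' padding at both ends to suppress edge transients. Length, label and
#' sampling rate are preserved.
#'
#' @param record an [eeg_record].
#' @param spec a [filter_spec]; default 0.5-40 Hz, order 4.
#' @return the filtered [eeg_record].
#' @export
bandpass_filter <- function(record, spec = filter_spec()) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  coefs <- butter_bandpass(spec, record$fs)
  x <- record$samples
  n <- length(x)
  npad <- min(n - 1L, 9L * (length(coefs$a) - 1L))
  if (npad > 0) {
    head_pad <- 2 * x[1] - x[(npad + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
    xp <- c(head_pad, x, tail_pad)
  } else xp <- x
  y <- iir_filter(coefs$b, coefs$a, xp)
  y <- rev(iir_filter(coefs$b, coefs$a, rev(y)))
  if (npad > 0) y <- y[(npad + 1):(npad + n)]
  out <- record
  out$samples <- y
  out
}

#' Running-median filter an EEG record
#'
#' Each output sample is the median of a centered window; edges are handled
#' by reflection padding so the length is preserved.
#'
#' @param record an [eeg_record].
#' @param window odd window width in samples (default 5).
#' @return the smoothed [eeg_record].
#' @export
median_filter <- function(record, window = 5L) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  window <- as.integer(window)
  if (window %% 2L == 0L)
    stop_seizr("median window must be odd", "seizr_config")
  assert_that(window >= 3L, "median window must be >= 3")
  x <- record$samples
  n <- length(x)
  assert_that(window <= n, "median window exceeds record length")
  h <- (window - 1L) %/% 2L
  xp <- c(x[h:1], x, x[n:(n - h + 1L)])   # symmetric (edge-including) pad
  y <- stats::runmed(xp, window, endrule = "keep")
  out <- record
  out$samples <- as.numeric(y[(h + 1):(h + n)])
  out
}

#' RADWT parameters
#'
#' @param p,q integer dilation fraction: the lowpass branch keeps fraction
#'   `p/q` of the spectrum per scale (dilation factor `q/p > 1`).
#' @param s redundancy parameter; only `s = 1` (full-rate detail bands) is
#'   implemented.
#' @param levels number of decomposition scales.
#' @return a `radwt_params`.
#' @export
radwt_params <- function(p = 2L, q = 3L, s = 1L, levels = 4L) {
  assert_that(p >= 1L, "p must be >= 1")
  assert_that(q > p, "q must exceed p (dilation q/p > 1)")
  assert_that(s == 1L, "only s = 1 (full-rate detail bands) is implemented")
  assert_that(levels >= 1L, "levels must be >= 1")
  structure(list(p = as.integer(p), q = as.integer(q), s = as.integer(s),
                 levels = as.integer(levels)),
            class = "radwt_params")
}

# Power-complementary lowpass/highpass pair on the DFT bins of a length-N
# signal; cutoff at fraction p/q of Nyquist with a raised-cosine-sqrt
# transition of total width 0.1*(p/q), centered on the cutoff. Returns H, G
# and the last bin index (1-based offset from DC) the lowpass can occupy.
radwt_filters <- function(N, p, q) {
  fc <- p / q
  tau <- 0.1 * fc
  k <- seq_len(N) - 1
  f <- pmin(k, N - k) / (N / 2)     # normalized |frequency| in [0, 1]
  H <- numeric(N)
  H[f <= fc - tau / 2] <- 1
  tr <- f > fc - tau / 2 & f < fc + tau / 2
  H[tr] <- cos(pi / 2 * (f[tr] - (fc - tau / 2)) / tau)
  G <- sqrt(pmax(0, 1 - H^2))
  kmax <- max(1L, ceiling((fc + tau / 2) * N / 2))
  list(H = H, G = G, kmax = as.integer(min(kmax, floor((N - 1) / 2))))
}

fft_u <- function(x) stats::fft(x) / sqrt(length(x))
ifft_u <- function(X) stats::fft(X, inverse = TRUE) / sqrt(length(X))

radwt_level_lengths <- function(n, p, q, levels) {
  lens <- integer(0)
  for (j in seq_len(levels)) {
    flt <- radwt_filters(n, p, q)
    m <- 2L * flt$kmax + 1L
    if (m < 16L || m >= n) return(lens)
    lens <- c(lens, m)
    n <- m
  }
  lens
}

#' Forward rational-dilation wavelet transform
#'
#' Decomposes a record into `levels` detail bands (level 1 = highest
#' frequencies) plus one approximation band. The transform is linear and a
#' tight frame: subband energies sum to the signal energy and
#' [radwt_inverse()] restores the input to near machine precision.
#'
#' @param record an [eeg_record].
#' @param params a [radwt_params].
#' @return a `subband_decomposition` with fields `subbands` (details then
#'   approximation), `params`, `original_length`, `input_lengths`, `fs`, and
#'   the record's `label`/`source_id` carried through.
#' @export
radwt_forward <- function(record, params = radwt_params()) {
  assert_that(inherits(record, "eeg_record"), "record must be an eeg_record")
  assert_that(inherits(params, "radwt_params"), "params must be radwt_params")
  x <- record$samples
  n0 <- length(x)
  feasible <- radwt_level_lengths(n0, params$p, params$q, params$levels)
  if (length(feasible) < params$levels)
    stop_seizr(sprintf(
      "record of length %d supports at most %d RADWT levels (requested %d)",
      n0, length(feasible), params$levels), "seizr_config")
  c_cur <- x
  details <- vector("list", params$levels)
  input_lengths <- integer(params$levels)
  for (j in seq_len(params$levels)) {
    N <- length(c_cur)
    input_lengths[j] <- N
    flt <- radwt_filters(N, params$p, params$q)
    C <- fft_u(c_cur)
    details[[j]] <- Re(ifft_u(flt$G * C))
    M <- 2L * flt$kmax + 1L
    Clow <- complex(length.out = M)
    L <- flt$H * C
    Clow[1] <- L[1]
    Clow[2:(flt$kmax + 1)] <- L[2:(flt$kmax + 1)]
    Clow[M:(flt$kmax + 2)] <- L[N:(N - flt$kmax + 1)]
    c_cur <- Re(ifft_u(Clow))
  }
  structure(list(subbands = c(details, list(c_cur)), params = params,
                 original_length = n0, input_lengths = input_lengths,
                 fs = record$fs, label = record$label, source_id = record$source_id),
            class = "subband_decomposition")
}

#' @export
print.subband_decomposition <- function(x, ...) {
  cat(sprintf("<subband_decomposition> %d detail bands + approximation (p/q = %d/%d), n = %d\n",
              x$params$levels, x$params$p, x$params$q, x$original_length))
  cat("  band lengths:", vapply(x$subbands, length, integer(1)), "\n")
  invisible(x)
}

#' Inverse rational-dilation wavelet transform
#'
#' Reconstructs the time-domain signal from a [radwt_forward()]
#' decomposition. Zeroing all but one subband before inversion yields that
#' band's additive contribution; the contributions sum to the original
#' signal.
#'
#' @param decomp a `subband_decomposition`.
#' @return an [eeg_record] of the original length.
#' @export
radwt_inverse <- function(decomp) {
  assert_that(inherits(decomp, "subband_decomposition"),
              "decomp must be a subband_decomposition")
  params <- decomp$params
  levels <- params$levels
  assert_that(length(decomp$subbands) == levels + 1L,
              "subband count must equal levels + 1", "seizr_consistency")
  c_cur <- decomp$subbands[[levels + 1L]]
  for (j in rev(seq_len(levels))) {
    N <- decomp$input_lengths[j]
    flt <- radwt_filters(N, params$p, params$q)
    M <- 2L * flt$kmax + 1L
    if (length(c_cur) != M)
      stop_seizr(sprintf("subband %d has length %d, expected %d", j + 1L,
                         length(c_cur), M), "seizr_consistency")
    d <- decomp$subbands[[j]]
    if (length(d) != N)
      stop_seizr(sprintf("detail band %d has length %d, expected %d", j,
                         length(d), N), "seizr_consistency")
    Clow <- fft_u(c_cur)
    L <- complex(length.out = N)
    L[1] <- Clow[1]
    L[2:(flt$kmax + 1)] <- Clow[2:(flt$kmax + 1)]
    L[N:(N - flt$kmax + 1)] <- Clow[M:(flt$kmax + 2)]
    C <- flt$H * L + flt$G * fft_u(d)
    c_cur <- Re(ifft_u(C))
  }
  eeg_record(c_cur, fs = decomp$fs, label = decomp$label,
             source_id = decomp$source_id)
}

#' Nominal frequency edges of each RADWT band
#'
#' @param decomp a `subband_decomposition`.
#' @return data frame with one row per subband (details then approximation)
#'   and columns `band`, `low_hz`, `high_hz`.
#' @export
radwt_band_edges <- function(decomp) {
  fs <- decomp$fs
  nyq <- fs / 2
  ratio <- vapply(seq_len(decomp$params$levels), function(j) {
    flt <- radwt_filters(decomp$input_lengths[j], decomp$params$p, decomp$params$q)
    (2 * flt$kmax + 1) / decomp$input_lengths[j]
  }, numeric(1))
  highs <- nyq * cumprod(c(1, ratio))[seq_len(decomp$params$levels)]
  fc <- decomp$params$p / decomp$params$q
  lows <- highs * fc
  data.frame(band = c(sprintf("detail%d", seq_len(decomp$params$levels)), "approx"),
             low_hz = c(lows, 0),
             high_hz = c(highs, lows[decomp$params$levels]))
}

#' Reconstruct the contribution of a single RADWT band
#'
#' @param decomp a `subband_decomposition`.
#' @param band index into `decomp$subbands` (1..levels for details,
#'   levels+1 for the approximation).
#' @return an [eeg_record] holding that band's additive component.
#' @export
radwt_band_signal <- function(decomp, band) {
  nb <- length(decomp$subbands)
  assert_that(band >= 1L && band <= nb, "band index out of range")
  d2 <- decomp
  for (i in seq_len(nb)) if (i != band)
    d2$subbands[[i]] <- numeric(length(decomp$subbands[[i]]))
  radwt_inverse(d2)
}

#' Serialize a subband decomposition to plain-text files
#' @param decomp a `subband_decomposition`.
#' @param dir output directory.
#' @return invisibly, the manifest data frame.
#' @export
write_decomposition <- function(decomp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nb <- length(decomp$subbands)
  files <- sprintf("band%02d.txt", seq_len(nb))
  for (i in seq_len(nb))
    writeLines(format(decomp$subbands[[i]], digits = 17, trim = TRUE),
               file.path(dir, files[i]))
  man <- data.frame(file = files, length = vapply(decomp$subbands, length, integer(1)),
                    p = decomp$params$p, q = decomp$params$q, s = decomp$params$s,
                    levels = decomp$params$levels,
                    original_length = decomp$original_length, fs = decomp$fs,
                    stringsAsFactors = FALSE)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(man)
}
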