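test_that("Butterworth design has the analytic band-pass response", {
  spec <- filter_spec(0.5, 40, 4)
  cf <- butter_bandpass(spec, 173.61)
  # -3 dB at both band edges, unity at the geometric center
  expect_equal(filter_response(cf, c(0.5, 40), 173.61),
               rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_equal(filter_response(cf, sqrt(0.5 * 40), 173.61), 1, tolerance = 1e-9)
  expect_error(butter_bandpass(filter_spec(0.5, 90), 173.61),
               class = "seizr_config")
})

test_that("zero-phase band-pass keeps in-band tones and rejects out-of-band", {
  fs <- 173.61
  t <- (0:4096) / fs
  spec <- filter_spec(0.5, 40, 4)
  cf <- butter_bandpass(spec, fs)
  mid <- 1000:3000                      # steady-state region
  # filtfilt applies |H|^2; the analytic response is the oracle
  for (f0 in c(10, 80)) {
    x <- sin(2 * pi * f0 * t)
    y <- bandpass_filter(eeg_record(x, fs), spec)$samples
    ratio <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
    expect_equal(ratio, filter_response(cf, f0, fs)^2, tolerance = 1e-3)
  }
  x10 <- bandpass_filter(eeg_record(sin(2 * pi * 10 * t), fs), spec)$samples
  expect_gte(sqrt(mean(x10[mid]^2)) / sqrt(mean(sin(2 * pi * 10 * t)[mid]^2)), 0.95)
  x80 <- bandpass_filter(eeg_record(sin(2 * pi * 80 * t), fs), spec)$samples
  expect_lte(sqrt(mean(x80[mid]^2)) / sqrt(mean(sin(2 * pi * 80 * t)[mid]^2)), 0.10)

  zero <- bandpass_filter(eeg_record(rep(0, 500), fs), spec)
  expect_equal(zero$samples, rep(0, 500))
  rec <- eeg_record(rnorm(300), fs, label = "seizure", source_id = "x")
  out <- bandpass_filter(rec, spec)
  expect_length(out$samples, 300)
  expect_equal(out$label, "seizure")
})

test_that("median filter matches a brute-force sliding median with reflection", {
  rec <- eeg_record(rep(4.2, 50), 100)
  expect_equal(median_filter(rec, 5)$samples, rep(4.2, 50))
  expect_equal(median_filter(eeg_record(c(0, 10, 0), 100), 3)$samples, c(0, 0, 0))
  expect_error(median_filter(rec, 4), class = "seizr_config")

  set.seed(42)
  x <- rnorm(101)
  for (w in c(3L, 5L, 9L)) {
    got <- median_filter(eeg_record(x, 100), w)$samples
    h <- (w - 1L) %/% 2L
    xp <- c(x[h:1], x, x[length(x):(length(x) - h + 1L)])
    want <- vapply(seq_along(x), function(i) median(xp[i:(i + w - 1L)]), numeric(1))
    expect_equal(got, want)
  }
})

test_that("RADWT is a tight frame: perfect reconstruction and energy", {
  set.seed(7)
  for (n in c(500L, 1024L, 4097L)) {
    x <- rnorm(n)
    dec <- radwt_forward(eeg_record(x, 173.61))
    expect_length(dec$subbands, 5L)
    xr <- radwt_inverse(dec)$samples
    expect_lt(max(abs(x - xr)), 1e-8)
    e <- sum(x^2)
    expect_lt(abs(e - sum(vapply(dec$subbands, function(b) sum(b^2), numeric(1)))) / e,
              1e-6)
  }
})

test_that("RADWT linearity, impulse energy, zero signal, band sums", {
  zero <- radwt_forward(eeg_record(rep(0, 512), 173.61))
  expect_true(all(vapply(zero$subbands, function(b) all(b == 0), logical(1))))

  imp <- rep(0, 512); imp[200] <- 1
  dec <- radwt_forward(eeg_record(imp, 173.61))
  expect_equal(sum(vapply(dec$subbands, function(b) sum(b^2), numeric(1))), 1,
               tolerance = 1e-6)

  # single-band contributions add up to the full reconstruction
  set.seed(3)
  x <- rnorm(512)
  dec <- radwt_forward(eeg_record(x, 173.61))
  parts <- vapply(seq_along(dec$subbands),
                  function(b) radwt_band_signal(dec, b)$samples,
                  numeric(512))
  expect_lt(max(abs(rowSums(parts) - x)), 1e-8)
})

test_that("a 25 Hz tone concentrates in its matching subband", {
  fs <- 173.61
  t <- (0:4096) / fs
  dec <- radwt_forward(eeg_record(sin(2 * pi * 25 * t), fs))
  en <- vapply(dec$subbands, function(b) sum(b^2), numeric(1))
  edges <- radwt_band_edges(dec)
  match_band <- which(edges$low_hz <= 25 & 25 <= edges$high_hz)[1]
  expect_gte(en[match_band] / sum(en), 0.80)
})

test_that("RADWT errors are informative", {
  short <- eeg_record(rnorm(64), 173.61)
  err <- tryCatch(radwt_forward(short, radwt_params(levels = 10L)),
                  seizr_config = function(e) conditionMessage(e))
  expect_match(err, "at most [0-9]+ RADWT levels")

  dec <- radwt_forward(eeg_record(rnorm(512), 173.61))
  dec$subbands[[2]] <- dec$subbands[[2]][-1]
  expect_error(radwt_inverse(dec), class = "seizr_consistency")
  expect_error(radwt_params(p = 3, q = 2), class = "seizr_invalid")
})
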