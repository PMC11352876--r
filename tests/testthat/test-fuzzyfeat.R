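test_that("window_segments geometry", {
  x <- eeg_record(rnorm(4097), 173.61)
  expect_length(window_segments(x, 4097L, 0), 1L)
  segs <- window_segments(x, 256L, 0.5)
  expect_length(segs, 31L)                       # floor((4097-256)/128)+1
  expect_true(all(vapply(segs, length, integer(1)) == 256L))
  # extreme overlap still makes progress (step clamped to >= 1)
  # step = max(1, round(256 * 0.01)) = 3 -> floor((300-256)/3) + 1 = 15
  expect_length(window_segments(eeg_record(rnorm(300), 100), 256L, 0.99), 15L)
  expect_error(window_segments(eeg_record(rnorm(100), 100), 101L),
               class = "seizr_param")
})

test_that("stat_features uses population moments and 16-bin entropy", {
  f <- stat_features(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 1.25)
  expect_equal(f[["standard_deviation"]], sqrt(1.25), tolerance = 1e-12)

  const <- stat_features(rep(3, 10))
  expect_equal(unname(const[c("variance", "skewness", "kurtosis",
                              "shannon_entropy")]), rep(0, 4))

  # 1600 samples filling 16 equal-count bins -> 4 bits
  x <- rep(seq(0.5, 15.5, by = 1), each = 100) + 0.0
  expect_equal(stat_features(x)[["shannon_entropy"]], 4)

  set.seed(8)
  y <- rnorm(500)
  f <- stat_features(y)
  d <- y - mean(y)
  expect_equal(f[["skewness"]], mean(d^3) / mean(d^2)^1.5)
  expect_equal(f[["kurtosis"]], mean(d^4) / mean(d^2)^2)
  expect_error(stat_features(1), class = "seizr_param")
})

test_that("FCM c = 1 closed form and membership normalization", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  r <- fcm_fit(X, fcm_config(c = 1L))
  expect_equal(drop(r$centers), colMeans(X))
  expect_true(all(r$memberships == 1))

  r2 <- fcm_fit(X, fcm_config(c = 3L, seed = 2L))
  expect_equal(rowSums(r2$memberships), rep(1, 20), tolerance = 1e-9)
  expect_true(all(r2$memberships >= 0 & r2$memberships <= 1))
  expect_error(fcm_fit(X, fcm_config(c = 21L)), class = "seizr_config")
  expect_error(fcm_config(m = 1), class = "seizr_invalid")
})

test_that("FCM matches an independently coded brute-force oracle", {
  set.seed(6)
  for (case in 1:3) {
    n <- c(30L, 40L, 50L)[case]
    X <- rbind(matrix(rnorm(n), n / 2, 2),
               matrix(rnorm(n, mean = 10), n / 2, 2))
    cfg <- fcm_config(c = 2L, m = 2, tolerance = 1e-10, max_iter = 200L,
                      seed = 20L + case)
    got <- fcm_fit(X, cfg)
    want <- brute_force_fcm(X, 2L, 2, 1e-10, 200L, 20L + case)
    expect_lt(max(abs(got$memberships - want$memberships)), 1e-6)
    expect_lt(max(abs(got$centers - want$centers)), 1e-6)
    # well-separated clouds: confident memberships
    expect_true(all(apply(got$memberships, 1, max) >= 0.9))
  }
})

test_that("FCM objective is non-increasing on random instances", {
  set.seed(7)
  for (i in 1:20) {
    X <- matrix(rnorm(25 * 4), 25, 4)
    r <- fcm_fit(X, fcm_config(c = sample(2:4, 1), seed = i))
    expect_true(all(diff(r$objective_trajectory) <= 1e-9))
  }
})

test_that("coincident points receive full membership in one cluster", {
  X <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  r <- fcm_fit(X, fcm_config(c = 2L, seed = 1L))
  expect_true(all(apply(r$memberships, 1, max) > 0.999))
})

test_that("select_features ranks separating columns first", {
  set.seed(9)
  sep <- c(rnorm(25, 0, 1), rnorm(25, 8, 1))
  noise <- rnorm(50)
  X <- cbind(signal = sep, noise = noise)
  r <- fcm_fit(X, fcm_config(c = 2L, seed = 3L))
  top1 <- select_features(r, X, 1L)
  expect_identical(attr(top1, "selected"), "signal")
  expect_equal(ncol(top1), 3L)                  # 1 kept + 2 memberships

  all_cols <- select_features(r, X, 2L)
  expect_identical(colnames(all_cols),
                   c("signal", "noise", "membership1", "membership2"))

  # constant column scores last (zero separation)
  Xc <- cbind(X, flat = rep(1, 50))
  rc <- fcm_fit(Xc, fcm_config(c = 2L, seed = 3L))
  scores <- attr(select_features(rc, Xc, 3L), "scores")
  expect_equal(which.min(scores), 3L, ignore_attr = TRUE)
  expect_error(select_features(r, X, 0L), class = "seizr_param")
})

test_that("membership degrees for new points are row-stochastic", {
  set.seed(10)
  X <- matrix(rnorm(40), 20, 2)
  r <- fcm_fit(X, fcm_config(c = 2L, seed = 4L))
  U <- fcm_membership_for(r, matrix(rnorm(10), 5, 2))
  expect_equal(rowSums(U), rep(1, 5), tolerance = 1e-9)
})
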