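test_that("a stationary recording selects the earliest window with score ~1", {
  t <- (0:2999) / 100
  raw <- raw_signal(sin(2 * pi * 2 * t), 100)
  sel <- select_stable_segment(raw)
  expect_equal(sel$report$window_start, 0)
  expect_lt(sel$report$stability_score, 1.05)
  expect_true(sel$report$accepted)
  expect_equal(length(sel$segment$samples), 1000L)
})

test_that("the selected window avoids an amplitude burst", {
  subj <- make_subject(31, "fundamental-rich")
  raw <- synth_signal(subj, 60, 100, seed = 5, artifact_rate = 0)
  x <- raw$samples
  burst <- 20 * 100 + seq_len(2 * 100)  # t = 20..22 s
  x[burst] <- x[burst] + 5 * sd(x) * rnorm(length(burst))
  raw$samples <- x
  sel <- select_stable_segment(raw)
  s0 <- sel$report$window_start
  expect_true(s0 + 10 <= 20 || s0 >= 22)

  # oracle: exhaustive scoring confirms every burst-overlapping window is worse
  xm <- x - mean(x)
  score_window <- function(start_s) {
    w <- xm[(start_s * 100 + 1):(start_s * 100 + 1000)]
    rms <- sapply(1:10, function(j) sqrt(mean(w[((j - 1) * 100 + 1):(j * 100)]^2)))
    max(rms) / median(rms)
  }
  starts <- 0:50
  scores <- sapply(starts, score_window)
  overlapping <- starts + 10 > 20 & starts < 22
  expect_false(overlapping[which.min(scores)])
  expect_true(all(scores[overlapping] > min(scores)))
  expect_equal(s0, starts[which.min(scores)])
})

test_that("segment preconditions are enforced", {
  expect_error(select_stable_segment(raw_signal(rnorm(500), 100)), "too short")
  expect_error(select_stable_segment(raw_signal(rnorm(500), 20)), "30 Hz|band")
})

test_that("segment selection is invariant to amplitude scaling", {
  subj <- make_subject(32, "am-suppressed")
  raw <- synth_signal(subj, 40, 100, seed = 9)
  a <- select_stable_segment(raw)
  raw$samples <- raw$samples * 37.5
  b <- select_stable_segment(raw)
  expect_equal(a$report$window_start, b$report$window_start)
  expect_equal(a$report$stability_score, b$report$stability_score, tolerance = 1e-9)
})

test_that("bandpass removes out-of-band tones and preserves in-band ones", {
  t <- (0:999) / 100
  seg <- segment(sin(2 * pi * 0.3 * t) + 0.5 * sin(2 * pi * 5 * t), 100)
  out <- bandpass(seg)  # default 0.6-15 Hz edges
  # 0.3 Hz component attenuated by >= 40 dB
  proj <- function(x, f) 2 * abs(mean(x * exp(-2i * pi * f * t)))
  expect_lt(proj(out$samples, 0.3) / proj(seg$samples, 0.3), 0.01)
  # 5 Hz amplitude preserved within 1%
  expect_equal(proj(out$samples, 5), 0.5, tolerance = 0.01)

  # a fully in-band tone passes unchanged within 1% RMS
  seg2 <- segment(sin(2 * pi * 2 * t), 100)
  out2 <- bandpass(seg2)
  expect_lt(sqrt(mean((out2$samples - seg2$samples)^2)) /
            sqrt(mean(seg2$samples^2)), 0.01)
})

test_that("filtered white noise keeps under 1% out-of-band power", {
  set.seed(41)
  seg <- segment(rnorm(6000), 100)
  out <- bandpass(seg)
  # plain periodogram of the output, integrated outside [0.6, 15]
  n <- length(out$samples)
  P <- Mod(fft(out$samples))^2 / n
  f <- (0:(n - 1)) / n * 100
  f <- pmin(f, 100 - f)
  oob <- sum(P[f < 0.6 | f > 15]) / sum(P)
  expect_lt(oob, 0.01)
})

test_that("bandpass is linear and nearly idempotent", {
  set.seed(5)
  t <- (0:999) / 100
  x <- rnorm(1000); y <- sin(2 * pi * 3 * t)
  bp <- function(v) bandpass(segment(v, 100))$samples
  lhs <- bp(2 * x - 3 * y)
  rhs <- 2 * bp(x) - 3 * bp(y)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # idempotence, on cardiac-band content (inputs with appreciable power in
  # the raised-cosine transition bands are re-attenuated on the second pass)
  xc <- sin(2 * pi * 1.1 * t) + 0.6 * sin(2 * pi * 7.3 * t) +
    0.3 * sin(2 * pi * 2.2 * t + 1) + 0.05 * rnorm(1000)
  once <- bp(xc)
  twice <- bp(once)
  expect_lt(sqrt(mean((twice - once)^2)) / sqrt(mean(once^2)), 0.01)
})

test_that("bandpass rejects impossible band edges", {
  seg <- segment(rnorm(1000), 100)
  expect_error(bandpass(seg, lo = 0), "lo")
  expect_error(bandpass(seg, lo = 1, hi = 60), "Nyquist")
})
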