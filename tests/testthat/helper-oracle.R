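# Independent brute-force oracle for peak counting and excess areas.
# Counts: explicit scan of the local-max-above-threshold predicate.
# Areas: numerical integration of the positive part of (power - theta) on a
# finely refined linear-interpolation grid; excursions are merged by
# construction, so this equals the sum of distinct above-threshold region
# areas counted once.

oracle_count <- function(power, theta) {
  n <- length(power)
  cnt <- 0L
  for (k in seq_len(n)) {
    left <- if (k == 1L) -Inf else power[k - 1L]
    right <- if (k == n) -Inf else power[k + 1L]
    if (power[k] > theta && power[k] > left && power[k] >= right)
      cnt <- cnt + 1L
  }
  cnt
}

oracle_area <- function(freqs, power, theta, refine = 1000L) {
  fg <- seq(freqs[1], freqs[length(freqs)],
            length.out = (length(freqs) - 1L) * refine + 1L)
  yg <- pmax(stats::approx(freqs, power, xout = fg)$y - theta, 0)
  sum(diff(fg) * (yg[-length(yg)] + yg[-1]) / 2)
}

oracle_peaks <- function(spec, fraction) {
  theta <- fraction * max(spec$power)
  list(count = oracle_count(spec$power, theta),
       total_area = oracle_area(spec$freqs, spec$power, theta))
}

# Random piecewise-linear test spectrum: a handful of smooth bumps plus a
# rough floor, all positive.
random_spectrum <- function(n_bins = NULL) {
  if (is.null(n_bins)) n_bins <- sample(30:80, 1)
  f <- 0.6 + 0.1 * (seq_len(n_bins) - 1L)
  p <- stats::runif(n_bins, 0, 0.15)
  for (b in seq_len(sample(2:6, 1))) {
    c0 <- stats::runif(1, min(f), max(f))
    w <- stats::runif(1, 0.15, 1.5)
    p <- p + stats::runif(1, 0.2, 1.5) * exp(-((f - c0) / w)^2)
  }
  spectrum_bcg(f, p, df = 0.1)
}

# A deterministic, metronomic single-tone subject for pipeline tests.
pure_tone_subject <- function(f0 = 1.0) {
  structure(list(
    subject_id = "tone", f0 = f0, jitter_max = 0.1,
    rsa_amp = 0, wobble_amp = 0,
    harmonics = data.frame(order = 1L, amplitude = 1, phase = 0),
    am_depth = 0, resp_freq = 0.25, resp_amp = 0, noise_sd = 0,
    session_variability = 0, profile_kind = "fundamental-rich"),
    class = "sim_subject")
}
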