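#' Analysis segment
#'
#' A `segment` is a duration-long slice of a [raw_signal()]: `samples`,
#' `rate` (Hz), `start_time` (s offset into the parent recording) and
#' `duration` (s).
#'
#' @param samples numeric amplitudes.
#' @param rate sampling rate in Hz.
#' @param start_time offset into the parent recording, seconds.
#' @param duration nominal duration in seconds.
#' @return An object of class `segment`.
#' @export
segment <- function(samples, rate, start_time = 0, duration = length(samples) / rate) {
  samples <- as.numeric(samples)
  if (abs(duration * rate - length(samples)) > 1 + 1e-6)
    stop("segment: duration x rate must equal length (within one sample)")
  structure(list(samples = samples, rate = rate,
                 start_time = start_time, duration = duration),
            class = "segment")
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> %.1f s @ %g Hz, starting at %.1f s\n",
              x$duration, x$rate, x$start_time))
  invisible(x)
}

#' Select the most stable analysis window of a recording
#'
#' Raw piezo-sensor traces contain body-movement transients and external
#' noise bursts alongside the cardiac vibration. This routine slides a
#' `duration`-long window across the recording in 1-s steps, scores each
#' window by the ratio of the maximum to the median RMS over its
#' non-overlapping 1-s subwindows (movement artifacts are amplitude
#' transients, so a clean window has a ratio near 1), and returns the
#' minimal-score window. Ties go to the earliest start. If even the best
#' window exceeds `threshold` it is still returned, flagged `accepted = FALSE`.
#'
#' @param raw a [raw_signal()].
#' @param duration window length, seconds (default 10).
#' @param threshold stability-ratio acceptance threshold (default 3).
#' @return A list with elements `segment` (a [segment()]) and `report`
#'   (`window_start`, `stability_score`, `accepted`).
#' @export
select_stable_segment <- function(raw, duration = 10, threshold = 3.0) {
  stopifnot(inherits(raw, "raw_signal"))
  rate <- raw$rate
  if (rate < 30) stop("select_stable_segment: rate < 30 Hz cannot resolve the 15 Hz band")
  n_win <- round(duration * rate)
  n <- length(raw$samples)
  if (n < n_win) stop("select_stable_segment: recording too short (",
                      sprintf("%.1f", n / rate), " s < ", duration, " s)")
  x <- raw$samples - mean(raw$samples)  # DC offset is sensor electronics, not motion
  step <- round(rate)                   # 1-s slide
  n_sub <- floor(duration)              # 1-s non-overlapping subwindows
  sub_len <- round(rate)
  starts <- seq(0L, n - n_win, by = step)
  scores <- vapply(starts, function(s0) {
    w <- x[(s0 + 1L):(s0 + n_win)]
    rms <- vapply(seq_len(n_sub), function(j) {
      seg <- w[((j - 1L) * sub_len + 1L):min(j * sub_len, n_win)]
      sqrt(mean(seg^2))
    }, numeric(1))
    med <- stats::median(rms)
    if (med <= 0) Inf else max(rms) / med
  }, numeric(1))
  # earliest window within numerical tolerance of the best score wins
  best <- which(scores <= min(scores) * (1 + 1e-9))[1]
  s0 <- starts[best]
  seg <- segment(raw$samples[(s0 + 1L):(s0 + n_win)], rate,
                 start_time = s0 / rate, duration = duration)
  report <- list(window_start = s0 / rate,
                 stability_score = scores[best],
                 accepted = scores[best] <= threshold)
  list(segment = seg, report = report)
}

#' Band-limit a segment to the cardiac vibration band
#'
#' Zero-phase frequency-domain filter: the segment is demeaned, transformed,
#' multiplied by a band mask with raised-cosine transitions of width 0.1 Hz
#' centered on the band edges, and inverse-transformed. The defaults cut
#' everything below 0.6 Hz (respiration, baseline drift) and above 15 Hz
#' (sensor/ambient noise), leaving the heartbeat harmonic comb. The mask is
#' exactly zero more than 0.05 Hz outside the band, so out-of-band
#' components are suppressed far beyond 40 dB; there is no phase distortion
#' and no filter-order choice.
#'
#' @param seg a [segment()] (or [raw_signal()], filtered in place).
#' @param lo,hi band edges in Hz; `0 < lo < hi < rate/2` required.
#' @return An object of the same class with filtered samples.
#' @export
bandpass <- function(seg, lo = 0.6, hi = 15) {
  rate <- seg$rate
  if (lo <= 0) stop("bandpass: lo must be > 0")
  if (hi >= rate / 2) stop("bandpass: hi must be below the Nyquist frequency")
  if (lo >= hi) stop("bandpass: need lo < hi")
  x <- seg$samples - mean(seg$samples)
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * rate
  f <- pmin(f, rate - f)               # two-sided frequency axis, folded
  gain <- band_mask(f, lo, hi, width = 0.1)
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  seg$samples <- y
  seg
}

# Raised-cosine band mask: 0 outside [lo-w/2, hi+w/2], 1 inside
# [lo+w/2, hi-w/2], half-cosine ramps centered on lo and hi.
band_mask <- function(f, lo, hi, width = 0.1) {
  h <- width / 2
  g <- numeric(length(f))
  g[f >= lo + h & f <= hi - h] <- 1
  ramp_lo <- f > lo - h & f < lo + h
  g[ramp_lo] <- 0.5 * (1 - cos(pi * (f[ramp_lo] - (lo - h)) / width))
  ramp_hi <- f > hi - h & f < hi + h
  g[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - (hi - h)) / width))
  g
}
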