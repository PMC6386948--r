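#' Discrete band-limited power spectrum
#'
#' Container for a one-sided power spectrum restricted to the cardiac band:
#' `freqs` (bin centers, Hz, uniformly spaced by `df`), `power` (non-negative
#' power density, 1/Hz once normalized), `df` (bin width, Hz) and a
#' `normalized` flag.
#'
#' @param freqs numeric vector of strictly increasing bin centers, Hz.
#' @param power numeric vector of non-negative power densities.
#' @param df bin width in Hz.
#' @param normalized logical; `TRUE` once the integral is 1.
#' @return An object of class `spectrum_bcg`.
#' @export
spectrum_bcg <- function(freqs, power, df, normalized = FALSE) {
  freqs <- as.numeric(freqs); power <- as.numeric(power)
  if (length(freqs) != length(power))
    stop("spectrum_bcg: freqs and power lengths differ")
  if (any(diff(freqs) <= 0)) stop("spectrum_bcg: freqs must be strictly increasing")
  if (any(power < 0)) stop("spectrum_bcg: negative power")
  structure(list(freqs = freqs, power = power, df = as.numeric(df),
                 normalized = isTRUE(normalized)),
            class = "spectrum_bcg")
}

#' @export
print.spectrum_bcg <- function(x, ...) {
  cat(sprintf("<spectrum_bcg> %d bins, %.2f-%.2f Hz, df = %g Hz%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$df,
              if (x$normalized) ", unit integral" else ""))
  invisible(x)
}

#' Power spectrum of an analysis segment
#'
#' Computes a single Hann-windowed periodogram of the full segment (one
#' transform, no Welch averaging: averaging 10-s data would destroy the
#' 0.1 Hz resolution the heartbeat harmonic peaks need). The one-sided
#' density is scaled so that the rectangle-rule integral over all bins
#' approximates the windowed signal variance; bins with centers outside
#' `[lo, hi]` are discarded. Frequency resolution is `df = 1/duration`.
#'
#' @param seg a [segment()] of duration >= 10 s, rate > 30 Hz.
#' @param lo,hi retained band in Hz (defaults 0.6 and 15).
#' @return A `spectrum_bcg` (not yet normalized).
#' @export
power_spectrum <- function(seg, lo = 0.6, hi = 15) {
  stopifnot(inherits(seg, "segment") || inherits(seg, "raw_signal"))
  x <- seg$samples
  rate <- seg$rate
  n <- length(x)
  if (n == 0L) stop("power_spectrum: empty segment")
  if (n / rate < 10 - 1e-9)
    stop("power_spectrum: segment shorter than 10 s (df would exceed 0.1 Hz)")
  if (rate <= 30) stop("power_spectrum: rate must exceed 30 Hz")
  if (all(x == 0)) warning("power_spectrum: all-zero segment")
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))  # periodic Hann
  X <- stats::fft(w * x)
  df <- rate / n
  k <- seq_len(floor((n - 1) / 2))                      # one-sided, no DC
  psd <- 2 * Mod(X[k + 1L])^2 / (rate * sum(w^2))
  freqs <- k * df
  keep <- freqs >= lo - 1e-9 & freqs <= hi + 1e-9
  spectrum_bcg(freqs[keep], psd[keep], df)
}

#' Smooth a spectrum with a conservative moving average
#'
#' Each bin's power is redistributed uniformly over a centered window of
#' `width_bins` bins (shrunk at the band edges), which for interior bins is
#' the ordinary centered moving average but conserves the total
#' `sum(power) * df` exactly. Raw periodogram local maxima are
#' noise-dominated; a 3-bin smooth suppresses spurious single-bin peaks
#' before peak counting. Width 1 disables smoothing.
#'
#' @param spec a `spectrum_bcg`.
#' @param width_bins odd positive integer window width (default 3).
#' @return A smoothed `spectrum_bcg`.
#' @export
smooth_spectrum <- function(spec, width_bins = 3L) {
  stopifnot(inherits(spec, "spectrum_bcg"))
  if (width_bins < 1 || width_bins %% 2 == 0)
    stop("smooth_spectrum: width_bins must be a positive odd integer")
  if (width_bins == 1L) return(spec)
  p <- spec$power
  n <- length(p)
  half <- (width_bins - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[j] <- out[j] + p[i] / length(j)
  }
  spec$power <- out
  spec
}

#' Normalize a spectrum to unit integral
#'
#' Divides the power density by its rectangle-rule integral
#' `sum(power) * df` so that the spectrum integrates to exactly 1 over the
#' retained band. This removes sensor gain and posture/coupling amplitude
#' effects: every downstream feature depends only on spectral shape.
#'
#' @param spec a `spectrum_bcg` with positive total power.
#' @return A `spectrum_bcg` with `normalized = TRUE`.
#' @export
normalize_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_bcg"))
  total <- sum(spec$power) * spec$df
  if (total <= 0) stop("normalize_spectrum: no signal power in band")
  spec$power <- spec$power / total
  spec$normalized <- TRUE
  spec
}

#' Export a spectrum as CSV (`freq_hz,power_density`)
#'
#' @param spec a `spectrum_bcg`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_bcg"))
  tab <- data.frame(freq_hz = spec$freqs, power_density = spec$power)
  utils::write.csv(format(tab, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
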