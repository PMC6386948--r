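#' Locate peak shapes above a fractional power standard
#'
#' The discriminant of this package is built from the "peak shapes" of the
#' normalized spectrum. Taking the global maximum power as the reference,
#' the threshold is `theta = fraction * max(power)` with `fraction` 1/2 or
#' 1/4. A bin is a peak iff its power strictly exceeds `theta` and it is a
#' local maximum (strictly above its left neighbor, at least its right
#' neighbor, so a flat-topped plateau is credited once, to its leftmost
#' bin; band-edge bins use the one-sided test, so the global maximum is
#' always countable). Each peak owns the maximal interval around it over
#' which the linearly interpolated power stays at or above `theta`; the
#' interval endpoints are the sub-bin interpolated crossings of `theta` (or
#' the band edge). The convex-upward cap cut off at the standard -- the
#' trapezoid integral of `power - theta` over the interval -- is the peak's
#' excess area. Peaks sharing one above-threshold excursion share the same
#' interval: the excursion's area is counted once, but every qualifying
#' local maximum still counts toward the peak number.
#'
#' @param spec a `spectrum_bcg` with at least 3 bins and positive maximum.
#' @param fraction power standard, 1/2 or 1/4.
#' @return An object of class `peak_set`: list with `fraction`, `threshold`,
#'   `peaks` (data frame `peak_freq`, `region_lo`, `region_hi`,
#'   `excess_area` per local maximum), `regions` (data frame of distinct
#'   merged regions `lo`, `hi`, `area`), `count`, `total_area`.
#' @export
find_peaks <- function(spec, fraction = 0.5) {
  stopifnot(inherits(spec, "spectrum_bcg"))
  p <- spec$power
  f <- spec$freqs
  n <- length(p)
  if (n < 3L) stop("find_peaks: need at least 3 bins")
  pmax_ <- max(p)
  if (pmax_ <= 0) stop("find_peaks: zero maximum power")
  theta <- fraction * pmax_

  left  <- c(-Inf, p[-n])   # virtual -Inf outside the band: edges one-sided
  right <- c(p[-1], -Inf)
  is_peak <- p > theta & p > left & p >= right
  idx <- which(is_peak)

  peaks <- lapply(idx, function(k) {
    # walk left to the first interpolated crossing of theta
    i <- k
    while (i > 1L && p[i - 1L] >= theta) i <- i - 1L
    lo <- if (i == 1L) f[1L] else
      f[i] - (f[i] - f[i - 1L]) * (p[i] - theta) / (p[i] - p[i - 1L])
    j <- k
    while (j < n && p[j + 1L] >= theta) j <- j + 1L
    hi <- if (j == n) f[n] else
      f[j] + (f[j + 1L] - f[j]) * (p[j] - theta) / (p[j] - p[j + 1L])
    area <- excess_area_interval(f, p, theta, i, j, lo, hi)
    c(peak_freq = f[k], region_lo = lo, region_hi = hi, excess_area = area)
  })
  peaks <- as.data.frame(do.call(rbind, peaks))
  if (nrow(peaks) == 0L)  # unreachable: the global max always qualifies
    peaks <- data.frame(peak_freq = numeric(0), region_lo = numeric(0),
                        region_hi = numeric(0), excess_area = numeric(0))

  # distinct excursions: peaks in one excursion carry identical [lo, hi]
  key <- !duplicated(paste(signif(peaks$region_lo, 12),
                           signif(peaks$region_hi, 12)))
  regions <- data.frame(lo = peaks$region_lo[key], hi = peaks$region_hi[key],
                        area = peaks$excess_area[key])
  structure(list(fraction = fraction, threshold = theta, peaks = peaks,
                 regions = regions, count = nrow(peaks),
                 total_area = sum(regions$area)),
            class = "peak_set")
}

# Trapezoid integral of (power - theta) between interpolated crossings.
# Bins i..j are all >= theta; lo/hi are the interval endpoints in Hz.
excess_area_interval <- function(f, p, theta, i, j, lo, hi) {
  xs <- c(lo, f[i:j], hi)
  ys <- c(if (i == 1L) p[1L] - theta else 0,
          p[i:j] - theta,
          if (j == length(f)) p[length(f)] - theta else 0)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> standard 1/%g: %d peak(s), total excess area %.4g\n",
              1 / x$fraction, x$count, x$total_area))
  invisible(x)
}

#' Extract the two spectral-shape discriminants
#'
#' Computes the package's 2-D descriptor of a spectrum:
#' \describe{
#'   \item{number of peak shapes}{the average of the peak counts at the 1/2
#'     and 1/4 power standards, `n_peaks = (n_half + n_quarter) / 2`;}
#'   \item{sharpness}{the summed excess areas at both standards, divided by
#'     the number of peak shapes, reciprocated:
#'     `sharpness = n_peaks / (area_half + area_quarter)`. The sharper
#'     (narrower) the peaks, the smaller the above-threshold caps and the
#'     larger the value.}
#' }
#'
#' @param spec a `spectrum_bcg` (normally unit-integral; features at fixed
#'   counts scale inversely with any residual amplitude scale, which
#'   normalization removes).
#' @return An object of class `peak_features`: list with `n_half`,
#'   `n_quarter`, `n_peaks`, `area_half`, `area_quarter`, `sharpness`.
#' @export
extract_features <- function(spec) {
  half <- find_peaks(spec, 0.5)
  quarter <- find_peaks(spec, 0.25)
  n_peaks <- (half$count + quarter$count) / 2
  total_area <- half$total_area + quarter$total_area
  if (total_area <= 0)
    stop("extract_features: zero total excess area")  # guarded; needs a flat spectrum
  structure(list(n_half = half$count, n_quarter = quarter$count,
                 n_peaks = n_peaks,
                 area_half = half$total_area, area_quarter = quarter$total_area,
                 sharpness = n_peaks / total_area),
            class = "peak_features")
}

#' @export
print.peak_features <- function(x, ...) {
  cat(sprintf(paste0("<peak_features> n_peaks = %.1f (1/2: %d, 1/4: %d), ",
                     "sharpness = %.4g\n"),
              x$n_peaks, x$n_half, x$n_quarter, x$sharpness))
  invisible(x)
}

#' @export
as.data.frame.peak_features <- function(x, ...) {
  data.frame(n_half = x$n_half, n_quarter = x$n_quarter, n_peaks = x$n_peaks,
             area_half = x$area_half, area_quarter = x$area_quarter,
             sharpness = x$sharpness)
}
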