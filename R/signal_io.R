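#' Raw vibration signal
#'
#' A `raw_signal` is a uniformly sampled single-channel vibration trace:
#' numeric `samples` (arbitrary sensor units), a sampling `rate` in Hz and an
#' optional free-text `meta` label (subject/session).
#'
#' @param samples numeric vector of finite amplitudes, length >= 1.
#' @param rate sampling frequency in Hz, > 0.
#' @param meta optional character label.
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(samples, rate, meta = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("raw_signal: need at least one sample")
  if (!all(is.finite(samples))) stop("raw_signal: all samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("raw_signal: rate must be a single positive number (Hz)")
  structure(list(samples = samples, rate = as.numeric(rate), meta = meta),
            class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  dur <- length(x$samples) / x$rate
  cat(sprintf("<raw_signal> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$rate, dur,
              if (is.null(x$meta)) "" else paste0(" [", x$meta, "]")))
  invisible(x)
}

#' Read a raw signal trace from delimited text
#'
#' Accepts one-column (`amplitude`) or two-column (`time_s,amplitude`) CSV,
#' with or without a header row. For two-column input the sampling rate is
#' inferred as the reciprocal of the median time step; timestamps must be
#' strictly increasing and uniform to within 1% of the median step. For
#' one-column input `rate_override` is required.
#'
#' @param path path to the CSV file.
#' @param rate_override optional sampling rate in Hz; overrides inference.
#' @param meta optional label stored on the returned signal.
#' @return A [raw_signal()].
#' @export
read_signal <- function(path, rate_override = NULL, meta = NULL) {
  if (!file.exists(path)) stop("read_signal: file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  tab <- utils::read.csv(path, header = has_header,
                         colClasses = "numeric", strip.white = TRUE)
  if (any(!vapply(tab, is.numeric, logical(1))) || anyNA(tab))
    stop("read_signal: non-numeric rows in ", path)
  if (ncol(tab) == 1L) {
    if (is.null(rate_override))
      stop("read_signal: 1-column input requires rate_override (Hz)")
    return(raw_signal(tab[[1]], rate_override, meta))
  }
  if (ncol(tab) != 2L)
    stop("read_signal: expected 1 or 2 columns, got ", ncol(tab))
  tt <- tab[[1]]
  if (any(diff(tt) <= 0))
    stop("read_signal: timestamps must be strictly increasing")
  step <- stats::median(diff(tt))
  if (any(abs(diff(tt) - step) > 0.01 * step))
    stop("read_signal: non-uniform sampling (timestamps deviate >1% from median step)")
  rate <- if (is.null(rate_override)) 1 / step else rate_override
  raw_signal(tab[[2]], rate, meta)
}

#' Write a raw signal as two-column CSV (`time_s,amplitude`)
#'
#' @param sig a [raw_signal()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path) {
  stopifnot(inherits(sig, "raw_signal"))
  n <- length(sig$samples)
  tab <- data.frame(time_s = (seq_len(n) - 1L) / sig$rate,
                    amplitude = sig$samples)
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write peak-shape feature records to CSV
#'
#' Writes a table with header `subject,session,n_peaks,sharpness`. Values
#' round-trip through [read_features()] to better than 12 significant digits.
#'
#' @param records a data frame with columns `subject`, `session`, `n_peaks`,
#'   `sharpness` (as produced by [features_record()]), or a list of such rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(records, path) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  if (is.null(records) || nrow(records) == 0L) {
    writeLines("subject,session,n_peaks,sharpness", path)
    return(invisible(path))
  }
  need <- c("subject", "session", "n_peaks", "sharpness")
  if (!all(need %in% names(records)))
    stop("write_features: records need columns ", paste(need, collapse = ", "))
  if (any(!nzchar(records$subject)))
    stop("write_features: empty subject label")
  key <- paste(records$subject, records$session, sep = "\r")
  if (anyDuplicated(key))
    stop("write_features: duplicate (subject, session) pair")
  out <- data.frame(
    subject = records$subject, session = records$session,
    n_peaks = formatC(records$n_peaks, digits = 15, format = "g"),
    sharpness = formatC(records$sharpness, digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path path to the CSV file.
#' @return A data frame with columns `subject`, `session`, `n_peaks`,
#'   `sharpness`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("read_features: file not found: ", path)
  tab <- utils::read.csv(path, header = TRUE,
                         colClasses = c("character", "character",
                                        "numeric", "numeric"))
  names(tab) <- c("subject", "session", "n_peaks", "sharpness")
  tab
}

#' Bundle a labeled feature record
#'
#' Convenience constructor for one row of a feature table.
#'
#' @param subject,session labels.
#' @param features a `peak_features` object from [extract_features()].
#' @return One-row data frame (`subject`, `session`, `n_peaks`, `sharpness`).
#' @export
features_record <- function(subject, session, features) {
  stopifnot(inherits(features, "peak_features"))
  data.frame(subject = as.character(subject), session = as.character(session),
             n_peaks = features$n_peaks, sharpness = features$sharpness,
             stringsAsFactors = FALSE)
}
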