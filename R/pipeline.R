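#' Full feature pipeline: raw trace to peak-shape descriptors
#'
#' Chains the analysis stages: select the most stable `duration`-second
#' window ([select_stable_segment()]), band-limit it to `[lo, hi]` Hz
#' ([bandpass()]), compute the Hann periodogram restricted to the band
#' ([power_spectrum()]), smooth ([smooth_spectrum()]), normalize to unit
#' integral ([normalize_spectrum()]) and extract the peak-shape features
#' ([extract_features()]).
#'
#' @param raw a [raw_signal()].
#' @param duration analysis window length, seconds (default 10).
#' @param lo,hi band edges in Hz (defaults 0.6 and 15).
#' @param stability_threshold acceptance threshold for the stability score.
#' @param smooth_bins odd moving-average width in bins; 1 disables.
#' @param keep_intermediates if `TRUE`, attach the segment, spectrum and
#'   stability report as attributes of the result.
#' @return A `peak_features` object (see [extract_features()]).
#' @export
signal_features <- function(raw, duration = 10, lo = 0.6, hi = 15,
                            stability_threshold = 3.0, smooth_bins = 3L,
                            keep_intermediates = FALSE) {
  sel <- select_stable_segment(raw, duration = duration,
                               threshold = stability_threshold)
  seg <- bandpass(sel$segment, lo = lo, hi = hi)
  spec <- power_spectrum(seg, lo = lo, hi = hi)
  spec <- smooth_spectrum(spec, smooth_bins)
  spec <- normalize_spectrum(spec)
  feats <- extract_features(spec)
  if (keep_intermediates) {
    attr(feats, "segment") <- seg
    attr(feats, "spectrum") <- spec
    attr(feats, "stability") <- sel$report
  }
  feats
}

#' Build an enrollment database from a labeled cohort
#'
#' Runs [signal_features()] on every recording of a [synth_cohort()] result
#' (or any list of recordings plus a truth table) and enrolls each into a
#' fresh [profile_db()].
#'
#' @param cohort a list with `recordings` and `truth` as returned by
#'   [synth_cohort()].
#' @param ... passed to [signal_features()].
#' @return A fitted [profile_db()].
#' @export
enroll_cohort <- function(cohort, ...) {
  db <- profile_db()
  for (i in seq_len(nrow(cohort$truth))) {
    rec <- cohort$recordings[[cohort$truth$recording[i]]]
    f <- signal_features(rec, ...)
    db <- enroll(db, cohort$truth$subject[i], cohort$truth$session[i], f)
  }
  db
}
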