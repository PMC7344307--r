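#' Cue-locked overlapping time-segment scheme
#'
#' Five overlapping windows of fixed 2-s length, shifted by `t0_s` relative
#' to cue onset: window `i` spans `[t0*(i-1), 2 + t0*(i-1)]` seconds after
#' the cue, `i = 1..5`. Typical shifts are 0.5 s (100-Hz calibration data
#' with a 4-s imagery period) and 0.25 s (3.5-4 s imagery periods).
#'
#' @param t0_s shift between consecutive windows, seconds.
#' @param segment_length_s window length, seconds (2 by default).
#' @param n_segments number of windows (5 by default).
#' @return An object of class `segment_scheme`.
#' @export
segment_scheme <- function(t0_s = 0.5, segment_length_s = 2, n_segments = 5) {
  if (t0_s < 0) stop("`t0_s` must be non-negative")
  if (segment_length_s <= 0) stop("`segment_length_s` must be positive")
  if (n_segments < 1L) stop("`n_segments` must be at least 1")
  structure(
    list(t0_s = as.numeric(t0_s),
         segment_length_s = as.numeric(segment_length_s),
         n_segments = as.integer(n_segments)),
    class = "segment_scheme"
  )
}

#' Band-pass filter specification
#'
#' Butterworth band-pass covering the mu/beta range that carries
#' sensorimotor ERD. Defaults: 3rd order, 8-30 Hz.
#'
#' @param order filter order.
#' @param low_hz,high_hz band edges, Hz.
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(order = 3, low_hz = 8, high_hz = 30) {
  if (order < 1L) stop("filter order must be >= 1")
  if (!(0 < low_hz && low_hz < high_hz)) {
    stop("band edges must satisfy 0 < low < high")
  }
  structure(
    list(order = as.integer(order), low_hz = as.numeric(low_hz),
         high_hz = as.numeric(high_hz), family = "butterworth"),
    class = "bandpass_spec"
  )
}

#' Sample intervals of the cue-locked windows
#'
#' Returns the five windows as half-open 0-based sample intervals
#' `[start, end)`: interval `i` starts at `round((cue_onset + t0*(i-1))*fs)`
#' and has length `round(segment_length * fs)` samples. R-level slicing of a
#' samples axis uses `(start + 1):end`.
#'
#' @param scheme a [segment_scheme()].
#' @param fs sampling rate, Hz.
#' @param cue_onset_s cue time from trial start, seconds.
#' @param n_samples optional trial length in samples; when given, any window
#'   running past it raises an error naming the offending window index.
#' @return A data frame with columns `segment`, `start_sample`, `end_sample`
#'   (0-based, half-open), `start_s`, `end_s` (seconds from trial start).
#' @examples
#' segment_bounds(segment_scheme(t0_s = 0.5), fs = 100, cue_onset_s = 2)
#' @export
segment_bounds <- function(scheme, fs, cue_onset_s, n_samples = NULL) {
  stopifnot(inherits(scheme, "segment_scheme"))
  i <- seq_len(scheme$n_segments)
  len <- round(scheme$segment_length_s * fs)
  start <- round((cue_onset_s + scheme$t0_s * (i - 1)) * fs)
  end <- start + len
  if (!is.null(n_samples)) {
    bad <- which(end > n_samples)
    if (length(bad) > 0L) {
      stop(sprintf(
        "time segment %d ([%g, %g) samples) exceeds the trial length of %d samples",
        bad[1L], start[bad[1L]], end[bad[1L]], n_samples))
    }
  }
  data.frame(segment = i, start_sample = start, end_sample = end,
             start_s = start / fs, end_s = end / fs)
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the filter forward and backward (`signal::filtfilt`), giving
#' zero phase distortion: group delay would misalign the short windows, and
#' the variance features downstream are invariant to the squared magnitude
#' response that forward-backward application produces.
#'
#' @param x numeric matrix `channels x samples` (a vector is treated as one
#'   channel).
#' @param spec a [bandpass_spec()].
#' @param fs sampling rate, Hz.
#' @return Filtered matrix of identical shape.
#' @export
bandpass <- function(x, spec, fs) {
  stopifnot(inherits(spec, "bandpass_spec"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (spec$high_hz >= fs / 2) {
    stop("band upper edge must lie below the Nyquist frequency fs/2")
  }
  if (ncol(x) < 3L * spec$order) {
    stop("segment too short to filter: need at least 3 x order samples")
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  out <- t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
  if (any(!is.finite(out))) stop("filter produced non-finite output")
  out
}

#' Decompose a trial set into filtered cue-locked segments
#'
#' Returns one `trialset` per window of the scheme, each holding every
#' trial's band-pass-filtered window, with labels and trial order
#' preserved. By default each full trial is filtered once (zero-phase) and
#' the windows are then sliced out, so 2-s windows carry no filter start-up
#' transient; `filter_mode = "segment"` instead slices first and filters
#' each short window on its own.
#'
#' @param ts a [trialset()].
#' @param scheme a [segment_scheme()].
#' @param spec a [bandpass_spec()].
#' @param filter_mode `"trial"` (filter whole trial, then slice; default)
#'   or `"segment"` (slice, then filter each window).
#' @return A list of `n_segments` [trialset()]s, each
#'   `n_trials x n_channels x round(segment_length * fs)`.
#' @export
decompose_trialset <- function(ts, scheme, spec,
                               filter_mode = c("trial", "segment")) {
  stopifnot(inherits(ts, "trialset"), inherits(scheme, "segment_scheme"),
            inherits(spec, "bandpass_spec"))
  filter_mode <- match.arg(filter_mode)
  bounds <- segment_bounds(scheme, ts$fs, ts$cue_onset_s,
                           n_samples = n_samples(ts))
  nt <- n_trials(ts)
  nc <- n_channels(ts)
  len <- bounds$end_sample[1L] - bounds$start_sample[1L]
  segs <- lapply(seq_len(scheme$n_segments), function(s) {
    array(0, c(nt, nc, len))
  })
  for (i in seq_len(nt)) {
    tr <- trial_matrix(ts, i)
    if (filter_mode == "trial") {
      trf <- bandpass(tr, spec, ts$fs)
      for (s in seq_len(scheme$n_segments)) {
        idx <- (bounds$start_sample[s] + 1L):bounds$end_sample[s]
        segs[[s]][i, , ] <- trf[, idx, drop = FALSE]
      }
    } else {
      for (s in seq_len(scheme$n_segments)) {
        idx <- (bounds$start_sample[s] + 1L):bounds$end_sample[s]
        segs[[s]][i, , ] <- bandpass(tr[, idx, drop = FALSE], spec, ts$fs)
      }
    }
  }
  lapply(segs, function(a) {
    trialset(a, ts$labels, ts$fs, cue_onset_s = 0,
             channel_names = ts$channel_names)
  })
}
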