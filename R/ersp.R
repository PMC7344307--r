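#' Event-related spectral perturbation of one channel
#'
#' ERSP is the trial-averaged squared spectral magnitude on a
#' time-frequency grid: `ERSP(f, t) = (1/N) * sum_i G_i(f, t)^2`, where
#' `G_i` is the short-time Fourier magnitude of trial `i`. The spectral
#' estimator is an STFT with a 0.5-s Hann window and 90 % overlap by
#' default (both configurable). No baseline normalization is applied in
#' the default `"absolute"` mode; `"relative"` divides each frequency row
#' by its mean pre-cue power, which renders ERD as values below 1. The
#' mode is recorded in the result.
#'
#' @param trials a [trialset()].
#' @param channel channel index or name.
#' @param f_range `(low, high)` Hz kept in the map (default 1-35 Hz).
#' @param t_range `(start, end)` seconds relative to cue onset kept in the
#'   map; default the full trial.
#' @param window_s STFT window length, seconds.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param class optional class label; when given, only that class's trials
#'   are averaged.
#' @param mode `"absolute"` (default) or `"relative"` (divide by mean
#'   pre-cue power per frequency).
#' @return An object of class `ersp_map`: `power` (`freqs x times`,
#'   non-negative), `freqs` (Hz), `times` (s relative to cue), `channel`,
#'   `mode`, `n_trials`.
#' @export
compute_ersp <- function(trials, channel = 1, f_range = c(1, 35),
                         t_range = NULL, window_s = 0.5, overlap = 0.9,
                         class = NULL, mode = c("absolute", "relative")) {
  stopifnot(inherits(trials, "trialset"))
  mode <- match.arg(mode)
  if (is.character(channel)) {
    channel <- match(channel, trials$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  idx <- seq_len(n_trials(trials))
  if (!is.null(class)) idx <- idx[trials$labels[idx] == class]
  if (length(idx) == 0L) stop("no trials to average")
  fs <- trials$fs
  if (max(f_range) >= fs / 2) stop("f_range must lie below fs/2")
  nwin <- round(window_s * fs)
  nov <- floor(overlap * nwin)
  acc <- NULL
  for (i in idx) {
    x <- trials$signals[i, channel, ]
    sg <- signal::specgram(x, n = nwin, Fs = fs,
                           window = signal::hanning(nwin), overlap = nov)
    g2 <- Mod(sg$S)^2
    acc <- if (is.null(acc)) g2 else acc + g2
  }
  power <- acc / length(idx)
  # specgram reports t as (1-based window start)/fs; convert to window
  # centers on the trial clock (sample 1 <-> 0 s), then cue-relative
  times <- as.numeric(sg$t) - 1 / fs + (nwin - 1) / (2 * fs) -
    trials$cue_onset_s
  freqs <- as.numeric(sg$f)
  if (mode == "relative") {
    base_cols <- which(times < 0)
    if (length(base_cols) == 0L) {
      stop("relative mode needs pre-cue samples for the baseline")
    }
    base <- rowMeans(power[, base_cols, drop = FALSE])
    if (any(base <= 0)) base[base <= 0] <- .Machine$double.eps
    power <- power / base
  }
  fkeep <- which(freqs >= f_range[1L] & freqs <= f_range[2L])
  tkeep <- seq_along(times)
  if (!is.null(t_range)) {
    if (t_range[1L] < -trials$cue_onset_s) {
      stop("t_range starts before the trial begins")
    }
    tkeep <- which(times >= t_range[1L] & times <= t_range[2L])
    if (length(tkeep) == 0L) stop("t_range contains no STFT windows")
  }
  structure(
    list(power = power[fkeep, tkeep, drop = FALSE],
         freqs = freqs[fkeep], times = times[tkeep],
         channel = trials$channel_names[channel], mode = mode,
         n_trials = length(idx)),
    class = "ersp_map"
  )
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf(
    "<ersp_map> channel %s: %d freqs (%g-%g Hz) x %d times (%.2f-%.2f s), %s, N = %d\n",
    x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$times), min(x$times), max(x$times), x$mode, x$n_trials))
  invisible(x)
}

#' Band-averaged ERSP per channel
#'
#' Averages the ERSP map over a frequency band and time window (e.g.
#' alpha band over the 4-s imagery period), returning one scalar per
#' channel — the quantity behind ERD topographies.
#'
#' @param trials a [trialset()].
#' @param f_band `(low, high)` Hz (default alpha, 8-13 Hz).
#' @param t_window `(start, end)` seconds relative to cue (default the
#'   4-s imagery period).
#' @param class optional class label to subset trials.
#' @param ... passed to [compute_ersp()].
#' @return Named numeric vector, one value per channel.
#' @export
band_topography <- function(trials, f_band = c(8, 13), t_window = c(0, 4),
                            class = NULL, ...) {
  stopifnot(inherits(trials, "trialset"))
  vapply(seq_len(n_channels(trials)), function(ch) {
    m <- compute_ersp(trials, channel = ch, f_range = f_band,
                      t_range = t_window, class = class, ...)
    mean(m$power)
  }, numeric(1)) |> stats::setNames(trials$channel_names)
}

#' Export an ERSP map as a CSV grid with a JSON sidecar
#'
#' Writes `power` as a 2-d CSV (rows = frequencies, columns = times) and a
#' `<path>.json` sidecar carrying `freqs`, `times`, `channel` and `mode`.
#'
#' @param map an [compute_ersp()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_ersp <- function(map, path) {
  stopifnot(inherits(map, "ersp_map"))
  utils::write.table(map$power, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(freqs = map$freqs, times = map$times, channel = map$channel,
         mode = map$mode, n_trials = map$n_trials),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
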