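#' ERD specification for one class
#'
#' Describes event-related desynchronization (ERD) for one imagery class:
#' on which channels, in which frequency band, during which time windows
#' (relative to cue onset), and how deeply the sensorimotor rhythm is
#' attenuated. Lateralized two-class problems use two specs with disjoint
#' channel sets (e.g. a C3 analogue for right-hand imagery and a C4
#' analogue for left-hand imagery).
#'
#' @param class_label 1 or 2.
#' @param channels integer indices of the channels carrying ERD.
#' @param band_hz length-2 numeric, `(low, high)` Hz of the attenuated rhythm.
#' @param windows_s list of `(start, end)` second pairs, relative to cue
#'   onset, where the attenuation is active.
#' @param depth fraction in `[0, 1)` by which the rhythm amplitude is
#'   reduced during active windows (`0` = no ERD, `0.8` = amplitude drops
#'   to 20 %).
#' @return An object of class `erd_spec`.
#' @export
erd_spec <- function(class_label, channels, band_hz = c(8, 12),
                     windows_s = list(c(0, 3)), depth = 0.8) {
  if (!class_label %in% c(1, 2)) stop("class_label must be 1 or 2")
  if (length(channels) < 1L || any(channels < 1L)) {
    stop("`channels` must be positive channel indices")
  }
  if (length(band_hz) != 2L || band_hz[1L] <= 0 || band_hz[2L] < band_hz[1L]) {
    stop("`band_hz` must be (low, high) with 0 < low <= high")
  }
  if (!is.list(windows_s)) windows_s <- list(windows_s)
  for (w in windows_s) {
    if (length(w) != 2L || w[2L] <= w[1L]) {
      stop("each ERD window must be (start, end) with end > start")
    }
  }
  if (depth < 0 || depth >= 1) stop("`depth` must lie in [0, 1)")
  structure(
    list(class_label = as.integer(class_label),
         channels = as.integer(channels),
         band_hz = as.numeric(band_hz),
         windows_s = lapply(windows_s, as.numeric),
         depth = as.numeric(depth)),
    class = "erd_spec"
  )
}

#' Synthetic motor-imagery EEG configuration
#'
#' Defaults emulate a calibration run of a two-class lateralized imagery
#' experiment at the competition recording scale: 100 trials per class
#' (200 total), 100 Hz sampling, a 7-s trial with the cue at 2 s followed
#' by a 4-s imagery period, an alpha-band (8-12 Hz) rhythm of 10 uV riding
#' on 2 uV white background noise, and deep (depth 0.8) ERD on one channel
#' per class during the first 3 s of imagery.
#'
#' @param n_trials_per_class trials per class.
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz.
#' @param trial_length_s trial length, seconds.
#' @param cue_onset_s cue time from trial start, seconds.
#' @param rhythm_amplitude rhythm amplitude, uV.
#' @param noise_sd background Gaussian noise standard deviation, uV.
#' @param erd_specs list of [erd_spec()]s (at most one per class).
#' @param mixing optional `n_channels x n_channels` matrix applied to each
#'   sample vector to induce spatial correlation; `NULL` keeps channels
#'   independent.
#' @param seed integer seed; generation is bitwise-reproducible given it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 100, n_channels = 8, fs = 100,
                         trial_length_s = 7, cue_onset_s = 2,
                         rhythm_amplitude = 10, noise_sd = 2,
                         erd_specs = list(
                           erd_spec(1, channels = 3),
                           erd_spec(2, channels = 6)
                         ),
                         mixing = NULL, seed = 1L) {
  cfg <- structure(
    list(n_trials_per_class = as.integer(n_trials_per_class),
         n_channels = as.integer(n_channels), fs = as.numeric(fs),
         trial_length_s = as.numeric(trial_length_s),
         cue_onset_s = as.numeric(cue_onset_s),
         rhythm_amplitude = as.numeric(rhythm_amplitude),
         noise_sd = as.numeric(noise_sd),
         erd_specs = erd_specs, mixing = mixing, seed = as.integer(seed)),
    class = "synth_config"
  )
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_trials_per_class < 1L) stop("need at least one trial per class")
  if (cfg$n_channels < 1L) stop("need at least one channel")
  imagery_len <- cfg$trial_length_s - cfg$cue_onset_s
  # the default five-segment scheme (t0 = 0.5 s, 2-s windows) spans 4 s
  if (imagery_len < 4) {
    stop("trial too short: need >= 4 s after cue onset to hold all five time segments")
  }
  for (spec in cfg$erd_specs) {
    if (!inherits(spec, "erd_spec")) stop("erd_specs must be erd_spec objects")
    if (max(spec$band_hz) >= cfg$fs / 2) {
      stop("ERD band must lie below the Nyquist frequency fs/2")
    }
    if (cfg$fs <= 2 * max(spec$band_hz)) {
      stop("fs must exceed twice the highest rhythm frequency")
    }
    if (any(spec$channels > cfg$n_channels)) {
      stop("erd_spec references channel beyond n_channels")
    }
    for (w in spec$windows_s) {
      if (w[1L] < 0 || cfg$cue_onset_s + w[2L] > cfg$trial_length_s) {
        stop(sprintf("ERD window (%g, %g) s falls outside the imagery period",
                     w[1L], w[2L]))
      }
    }
  }
  if (!is.null(cfg$mixing)) {
    if (!is.matrix(cfg$mixing) ||
        any(dim(cfg$mixing) != cfg$n_channels)) {
      stop("`mixing` must be an n_channels x n_channels matrix")
    }
  }
  invisible(cfg)
}

# Attenuation envelope over absolute trial time: 1 outside ERD windows,
# 1 - depth inside, with 100-ms raised-cosine ramps at window edges so the
# gating introduces no step discontinuity (steps would ring through the
# band-pass filter and dominate the variance features).
erd_envelope <- function(t_abs, windows_s, cue_onset_s, depth,
                         ramp_s = 0.1) {
  gate <- numeric(length(t_abs))
  for (w in windows_s) {
    a <- cue_onset_s + w[1L]
    b <- cue_onset_s + w[2L]
    r <- min(ramp_s, (b - a) / 2)
    g <- numeric(length(t_abs))
    core <- t_abs >= (a + r) & t_abs <= (b - r)
    up <- t_abs >= a & t_abs < (a + r)
    down <- t_abs > (b - r) & t_abs <= b
    g[core] <- 1
    g[up] <- 0.5 * (1 - cos(pi * (t_abs[up] - a) / r))
    g[down] <- 0.5 * (1 - cos(pi * (b - t_abs[down]) / r))
    gate <- pmax(gate, g)
  }
  1 - depth * gate
}

generate_signals <- function(cfg) {
  nt <- 2L * cfg$n_trials_per_class
  ns <- round(cfg$trial_length_s * cfg$fs)
  t_abs <- (seq_len(ns) - 1L) / cfg$fs
  labels <- rep(c(1L, 2L), each = cfg$n_trials_per_class)
  signals <- array(0, c(nt, cfg$n_channels, ns))
  spec_of <- list(NULL, NULL)
  for (spec in cfg$erd_specs) spec_of[[spec$class_label]] <- spec
  # all channels carry the rhythm; ERD gates it on class-specific channels
  band <- if (!is.null(spec_of[[1L]])) spec_of[[1L]]$band_hz
          else if (!is.null(spec_of[[2L]])) spec_of[[2L]]$band_hz
          else c(8, 12)
  for (i in seq_len(nt)) {
    spec <- spec_of[[labels[i]]]
    env <- NULL
    if (!is.null(spec) && spec$depth > 0) {
      env <- erd_envelope(t_abs, spec$windows_s, cfg$cue_onset_s, spec$depth)
    }
    tr <- matrix(0, cfg$n_channels, ns)
    for (ch in seq_len(cfg$n_channels)) {
      f <- stats::runif(1L, band[1L], band[2L])   # per-trial frequency jitter
      phi <- stats::runif(1L, 0, 2 * pi)          # per-trial random phase
      rhythm <- cfg$rhythm_amplitude * sin(2 * pi * f * t_abs + phi)
      if (!is.null(env) && ch %in% spec$channels) rhythm <- rhythm * env
      tr[ch, ] <- rhythm +
        stats::rnorm(ns, sd = cfg$noise_sd)
    }
    if (!is.null(cfg$mixing)) tr <- cfg$mixing %*% tr
    signals[i, , ] <- tr
  }
  list(signals = signals, labels = labels)
}

#' Generate a two-class motor-imagery trial set with controlled ERD
#'
#' Each trial is broadband Gaussian noise plus a band-limited sinusoidal
#' rhythm on every channel (random phase and in-band frequency jitter per
#' trial). On the ERD channels of the trial's class, the rhythm amplitude
#' is multiplied by `1 - depth` during the active windows, with 100-ms
#' cosine ramps at the window edges. Labels are balanced
#' (`n_trials_per_class` each) and generation is bitwise-deterministic
#' given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return A [trialset()] with `2 * n_trials_per_class` trials.
#' @examples
#' ts <- generate_mi_trialset(synth_config(n_trials_per_class = 5, seed = 7))
#' ts
#' @export
generate_mi_trialset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  withr::with_seed(config$seed, {
    g <- generate_signals(config)
    trialset(g$signals, g$labels, config$fs, config$cue_onset_s)
  })
}

#' Generate a label-permuted (null) trial set
#'
#' Signals are generated exactly as in [generate_mi_trialset()], after which
#' the labels are reassigned by an independent uniform random permutation of
#' the trials. Class counts are preserved but every label-signal association
#' is destroyed, so any downstream classifier should perform at chance.
#'
#' @param config a [synth_config()].
#' @return A [trialset()] whose labels carry no signal information.
#' @export
generate_null_trialset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  withr::with_seed(config$seed, {
    g <- generate_signals(config)
    perm <- sample.int(length(g$labels))
    trialset(g$signals, g$labels[perm], config$fs, config$cue_onset_s)
  })
}
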