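#' Epoched multichannel EEG trial set
#'
#' A `trialset` is the universal input of the package: a set of epoched,
#' labeled EEG trials sharing one sampling rate and one cue-onset time.
#' Signals are stored as a 3-d numeric array `trials x channels x samples`
#' (amplitudes in microvolts or amplifier units; the pipeline is
#' scale-robust), labels are integer class marks in `{1, 2}`, and
#' `cue_onset_s` gives the time of the imagery cue from trial start.
#'
#' @param signals numeric array, `n_trials x n_channels x n_samples`.
#' @param labels integer vector of length `n_trials` with values in `{1, 2}`.
#' @param fs sampling rate in Hz.
#' @param cue_onset_s cue-onset time in seconds from trial start.
#' @param channel_names optional character vector of channel names; defaults
#'   to `"ch1"`, `"ch2"`, ...
#' @return An object of class `trialset`.
#' @examples
#' x <- array(rnorm(4 * 2 * 100), c(4, 2, 100))
#' ts <- trialset(x, c(1, 1, 2, 2), fs = 100, cue_onset_s = 0)
#' ts
#' @export
trialset <- function(signals, labels, fs, cue_onset_s, channel_names = NULL) {
  if (!is.array(signals) || length(dim(signals)) != 3L) {
    stop("`signals` must be a 3-d array: trials x channels x samples")
  }
  storage.mode(signals) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != dim(signals)[1L]) {
    stop("length(labels) must equal the number of trials (dim(signals)[1])")
  }
  if (!all(labels %in% c(1L, 2L))) {
    stop("labels must take values in {1, 2}")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  if (!is.numeric(cue_onset_s) || length(cue_onset_s) != 1L || cue_onset_s < 0) {
    stop("`cue_onset_s` must be a non-negative scalar (seconds)")
  }
  nc <- dim(signals)[2L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("length(channel_names) must equal the number of channels")
  }
  structure(
    list(
      signals = signals,
      labels = labels,
      fs = as.numeric(fs),
      cue_onset_s = as.numeric(cue_onset_s),
      channel_names = as.character(channel_names)
    ),
    class = "trialset"
  )
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf(
    "<trialset> %d trials x %d channels x %d samples @ %g Hz (%.3g s)\n",
    d[1L], d[2L], d[3L], x$fs, d[3L] / x$fs
  ))
  cat(sprintf(
    "  cue onset: %g s; labels: %d x class 1, %d x class 2\n",
    x$cue_onset_s, sum(x$labels == 1L), sum(x$labels == 2L)
  ))
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$signals)

n_trials <- function(ts) dim(ts$signals)[1L]
n_channels <- function(ts) dim(ts$signals)[2L]
n_samples <- function(ts) dim(ts$signals)[3L]

#' Subset a trial set by trial index
#'
#' @param ts a [trialset()].
#' @param i integer vector of trial indices (may repeat or reorder).
#' @return A `trialset` holding the requested trials.
#' @export
subset_trials <- function(ts, i) {
  stopifnot(inherits(ts, "trialset"))
  i <- as.integer(i)
  if (any(i < 1L | i > n_trials(ts))) stop("trial index out of range")
  trialset(ts$signals[i, , , drop = FALSE], ts$labels[i],
           ts$fs, ts$cue_onset_s, ts$channel_names)
}

#' One trial as a channels x samples matrix
#'
#' @param ts a [trialset()].
#' @param i trial index.
#' @return Numeric matrix, `n_channels x n_samples`.
#' @export
trial_matrix <- function(ts, i) {
  m <- ts$signals[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # single-channel set
  m
}

#' Write a trial set to the package's plain-text container
#'
#' The container is a pair of files sharing one stem: `<path>` holds a JSON
#' header with the datasets `labels`, `fs`, `cue_onset_s`, `channel_names`
#' and the array geometry, and `<path>.signals.tsv` holds the signal array
#' flattened to one `(trial, channel)` row per line, samples as columns,
#' printed with `%.17g` so that doubles round-trip exactly.
#'
#' @param ts a [trialset()].
#' @param path output path for the JSON header; the signal matrix is written
#'   next to it as `<path>.signals.tsv`.
#' @return `path`, invisibly.
#' @seealso [read_trialset()]
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trialset"))
  d <- dim(ts$signals)
  header <- list(
    container = "tempocsp-trialset",
    version = 1L,
    n_trials = d[1L], n_channels = d[2L], n_samples = d[3L],
    labels = ts$labels,
    fs = ts$fs,
    cue_onset_s = ts$cue_onset_s,
    channel_names = ts$channel_names,
    signals_file = paste0(basename(path), ".signals.tsv")
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(header, path, auto_unbox = TRUE, digits = NA)
  # rows ordered trial-major: (t1,c1), (t1,c2), ..., (t2,c1), ...
  flat <- matrix(aperm(ts$signals, c(3L, 2L, 1L)), nrow = d[1L] * d[2L],
                 ncol = d[3L], byrow = TRUE)
  con <- file(paste0(path, ".signals.tsv"), "w")
  on.exit(close(con))
  writeLines(apply(flat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a trial set from the plain-text container
#'
#' @param path path to the JSON header written by [write_trialset()].
#' @return A [trialset()], bitwise-equal to the one written.
#' @export
read_trialset <- function(path) {
  if (!file.exists(path)) stop("no such container header: ", path)
  h <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(h$container, "tempocsp-trialset")) {
    stop("not a tempocsp trial-set container: ", path)
  }
  sig_path <- file.path(dirname(path), h$signals_file)
  if (!file.exists(sig_path)) stop("missing signal matrix file: ", sig_path)
  flat <- as.matrix(utils::read.table(sig_path, sep = "\t",
                                      colClasses = "numeric"))
  dimnames(flat) <- NULL
  d <- c(h$n_trials, h$n_channels, h$n_samples)
  if (nrow(flat) != d[1L] * d[2L] || ncol(flat) != d[3L]) {
    stop("signal matrix geometry does not match header")
  }
  signals <- aperm(array(t(flat), c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
  trialset(signals, h$labels, h$fs, h$cue_onset_s, h$channel_names)
}

#' Epoch a continuous recording at cue markers
#'
#' Competition-style motor-imagery recordings arrive as one continuous
#' multichannel signal plus marker arrays: the sample position of each cue
#' and its class code. This helper cuts fixed-length trials around the cues
#' and keeps only the two requested class codes (four-class sources are
#' reduced to a two-class problem, e.g. left vs right hand). Trials whose
#' class code is not in `class_codes`, or that would run past either end of
#' the recording, are dropped; the number excluded is reported via a message
#' and the `n_excluded` attribute.
#'
#' @param continuous numeric matrix, `channels x samples`.
#' @param cue_samples integer vector of cue positions (1-based sample index).
#' @param cue_codes class code of each cue (same length as `cue_samples`).
#' @param fs sampling rate in Hz.
#' @param class_codes length-2 vector: the codes mapped to labels 1 and 2.
#' @param pre_s seconds of signal kept before each cue.
#' @param post_s seconds kept after each cue (trial length is `pre_s + post_s`).
#' @param channel_names optional channel names.
#' @return A [trialset()] with `cue_onset_s = pre_s`.
#' @export
epoch_continuous <- function(continuous, cue_samples, cue_codes, fs,
                             class_codes, pre_s, post_s,
                             channel_names = NULL) {
  if (!is.matrix(continuous)) stop("`continuous` must be a channels x samples matrix")
  if (length(cue_samples) != length(cue_codes)) {
    stop("cue_samples and cue_codes must have equal length")
  }
  if (length(class_codes) != 2L) stop("`class_codes` must name exactly two classes")
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  len <- n_pre + n_post
  keep_code <- cue_codes %in% class_codes
  start <- cue_samples - n_pre
  in_range <- start >= 1L & (start + len - 1L) <= ncol(continuous)
  keep <- keep_code & in_range
  n_excl <- sum(!keep)
  if (n_excl > 0L) {
    message(sprintf("epoch_continuous: excluded %d cue(s) (unknown code or out of range)", n_excl))
  }
  if (!any(keep)) stop("no usable trials after exclusion")
  idx <- which(keep)
  signals <- array(0, c(length(idx), nrow(continuous), len))
  for (k in seq_along(idx)) {
    s0 <- start[idx[k]]
    signals[k, , ] <- continuous[, s0:(s0 + len - 1L)]
  }
  labels <- ifelse(cue_codes[idx] == class_codes[1L], 1L, 2L)
  out <- trialset(signals, labels, fs, cue_onset_s = pre_s,
                  channel_names = channel_names)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Load a trial set from disk
#'
#' Dispatches on the file content: the package's own plain-text container
#' (JSON header + TSV signal matrix, see [write_trialset()]) is read
#' directly. Continuous recordings with marker arrays are epoched via
#' [epoch_continuous()] when the JSON header declares
#' `"container": "tempocsp-continuous"` with fields `signals_file`
#' (channels x samples TSV), `cue_samples`, `cue_codes`, `fs`, and the
#' epoching parameters are supplied here.
#'
#' @param path path to a container header.
#' @param class_codes,pre_s,post_s epoching parameters for continuous
#'   containers; ignored for epoched containers.
#' @return A [trialset()].
#' @export
load_trialset <- function(path, class_codes = c(1L, 2L), pre_s = 2,
                          post_s = 5) {
  if (!file.exists(path)) stop("no such file: ", path)
  h <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) NULL)
  if (is.null(h) || is.null(h$container)) {
    stop("unknown trial-set format (expected a tempocsp JSON header): ", path)
  }
  if (identical(h$container, "tempocsp-trialset")) {
    return(read_trialset(path))
  }
  if (identical(h$container, "tempocsp-continuous")) {
    sig_path <- file.path(dirname(path), h$signals_file)
    cont <- as.matrix(utils::read.table(sig_path, sep = "\t",
                                        colClasses = "numeric"))
    dimnames(cont) <- NULL
    return(epoch_continuous(cont, as.integer(h$cue_samples),
                            as.integer(h$cue_codes), h$fs,
                            class_codes, pre_s, post_s,
                            channel_names = h$channel_names))
  }
  stop("unsupported container dialect: ", h$container)
}
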