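#' End-to-end pipeline configuration
#'
#' Bundles the segmentation scheme, band-pass filter, CSP and selector
#' settings, SVM hyperparameters and the cross-validation protocol.
#'
#' The default SVM is linear with `cost = 1` and training-split
#' standardization: the k = 4 log-variance features are near-linearly
#' separable, and a linear default removes an unreported tuning dimension;
#' kernel and cost are configurable.
#'
#' @param scheme a [segment_scheme()].
#' @param band a [bandpass_spec()].
#' @param m CSP filters per eigenvalue extreme (default 2).
#' @param k selected feature count (even; default 4, matching the `2m = 4`
#'   features of the fixed-window comparator).
#' @param selector `"muin"`, `"lasso"`, `"pca"`, `"swlda"`, or `"none"`
#'   (the plain-CSP comparator on a single fixed window).
#' @param svm list: `kernel` and `cost` for [e1071::svm()].
#' @param cv list: `n_repeats`, `n_folds`, `seed`.
#' @param filter_mode passed to [decompose_trialset()].
#' @param fixed_window_s `(start, end)` seconds relative to cue onset used
#'   when `selector = "none"` (default `c(0, 4)`, the 2-6-s window of a
#'   trial with the cue at 2 s).
#' @param normalize use normalized log-variance features (see
#'   [extract_features()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme = segment_scheme(t0_s = 0.5),
                            band = bandpass_spec(),
                            m = 2, k = 4, selector = "lasso",
                            svm = list(kernel = "linear", cost = 1),
                            cv = list(n_repeats = 10, n_folds = 10, seed = 1),
                            filter_mode = "trial",
                            fixed_window_s = c(0, 4),
                            normalize = FALSE) {
  if (!selector %in% c("muin", "lasso", "pca", "swlda", "none")) {
    stop("unknown selector: ", selector)
  }
  if (k %% 2L != 0L) stop("`k` must be even")
  if (cv$n_folds < 2L) stop("need at least 2 folds")
  structure(
    list(scheme = scheme, band = band, m = as.integer(m), k = as.integer(k),
         selector = selector, svm = svm, cv = cv,
         filter_mode = filter_mode,
         fixed_window_s = as.numeric(fixed_window_s),
         normalize = isTRUE(normalize)),
    class = "pipeline_config"
  )
}

# Segment decomposition appropriate to the configured method: the five
# overlapping windows for the selector pipelines, or the single fixed
# window for the plain-CSP comparator.
decompose_for_config <- function(ts, config) {
  if (config$selector == "none") {
    fw <- config$fixed_window_s
    shifted <- trialset(ts$signals, ts$labels, ts$fs,
                        cue_onset_s = ts$cue_onset_s + fw[1L],
                        channel_names = ts$channel_names)
    scheme1 <- segment_scheme(t0_s = 0, segment_length_s = fw[2L] - fw[1L],
                              n_segments = 1)
    decompose_trialset(shifted, scheme1, config$band,
                       filter_mode = config$filter_mode)
  } else {
    decompose_trialset(ts, config$scheme, config$band,
                       filter_mode = config$filter_mode)
  }
}

# Fit CSP models + feature table + selector + SVM on a subset of already
# segmented trials (indices into the segment trial axes).
fit_on_segments <- function(segs, idx, config) {
  labels <- segs[[1L]]$labels[idx]
  if (length(unique(labels)) < 2L) stop("training split lacks one class")
  models <- lapply(segs, function(seg) {
    tr1 <- lapply(which(labels == 1L), function(i) trial_matrix(seg, idx[i]))
    tr2 <- lapply(which(labels == 2L), function(i) trial_matrix(seg, idx[i]))
    fit_csp(tr1, tr2, m = config$m)
  })
  sub <- lapply(segs, function(seg) subset_trials(seg, idx))
  table <- build_feature_table(models, sub, normalize = config$normalize)
  if (config$selector == "none") {
    p <- ncol(table$values)
    selection <- selection_result("none", seq_len(p), diag(p),
                                  rep(NA_real_, p))
  } else {
    selection <- fit_selector(table, config$selector, k = config$k)
  }
  feats <- apply_selection(selection, table$values)
  svm_fit <- e1071::svm(feats, factor(labels, levels = c(1L, 2L)),
                        kernel = config$svm$kernel, cost = config$svm$cost,
                        scale = TRUE)
  list(models = models, selection = selection, svm_fit = svm_fit,
       labels = labels)
}

predict_on_segments <- function(fit, segs, idx, config) {
  sub <- lapply(segs, function(seg) subset_trials(seg, idx))
  table <- build_feature_table(fit$models, sub, normalize = config$normalize)
  feats <- apply_selection(fit$selection, table$values)
  as.integer(as.character(stats::predict(fit$svm_fit, feats)))
}

#' Train the full decoding pipeline
#'
#' Decomposes the training set into filtered cue-locked segments, fits one
#' CSP model per segment on the training trials only, builds the
#' concatenated feature table, fits the configured selector, and trains
#' the SVM on the selected (or projected) features.
#'
#' @param train a [trialset()] with both classes present.
#' @param config a [pipeline_config()].
#' @return An object of class `trained_pipeline`.
#' @export
train_pipeline <- function(train, config = pipeline_config()) {
  stopifnot(inherits(train, "trialset"), inherits(config, "pipeline_config"))
  if (min(table(train$labels)) < config$m + 1L) {
    stop("need at least m + 1 trials per class to train")
  }
  segs <- decompose_for_config(train, config)
  fit <- fit_on_segments(segs, seq_len(n_trials(train)), config)
  structure(
    list(models = fit$models, selection = fit$selection,
         svm_fit = fit$svm_fit, config = config,
         n_channels = n_channels(train), fs = train$fs,
         cue_onset_s = train$cue_onset_s),
    class = "trained_pipeline"
  )
}

#' Predict class labels for new trials
#'
#' @param object a [train_pipeline()] result.
#' @param trials a [trialset()] with matching channel count and sampling
#'   rate (labels, if any, are ignored).
#' @param ... unused.
#' @return Integer vector of predicted labels in `{1, 2}`, one per trial.
#' @export
predict.trained_pipeline <- function(object, trials, ...) {
  stopifnot(inherits(trials, "trialset"))
  if (n_channels(trials) != object$n_channels) {
    stop("channel count does not match the trained pipeline")
  }
  if (trials$fs != object$fs) stop("sampling rate does not match training")
  segs <- decompose_for_config(trials, object$config)
  predict_on_segments(object, segs, seq_len(n_trials(trials)), object$config)
}

# Stratified fold assignment: within each class, trials are shuffled and
# dealt round-robin into folds, so every training split keeps both classes.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of the pipeline
#'
#' Runs `n_repeats` independent stratified `n_folds`-fold partitions.
#' Within each fold the entire training path — CSP fitting, feature-table
#' construction, selector fitting, SVM training — sees only the 90 %
#' training split; the held-out trials are used once for evaluation, so
#' after one repeat every trial has appeared in the test set exactly once.
#' Band-pass filtering and window slicing are per-trial operations and are
#' precomputed once for the whole set (no information crosses trials).
#'
#' @param ts a [trialset()] with at least `n_folds` trials per class.
#' @param config a [pipeline_config()]; `config$cv` gives the protocol.
#' @return An object of class `cv_report`: `folds` (data frame with
#'   `rep`, `fold`, `n_test`, `n_correct`, `accuracy`), `selections`
#'   (per-fold [selection_result()]s), `partition` (per-repeat fold
#'   assignments), `mean_accuracy`, `sd_accuracy`, `seed`, `config`.
#' @export
cross_validate <- function(ts, config = pipeline_config()) {
  stopifnot(inherits(ts, "trialset"), inherits(config, "pipeline_config"))
  n_folds <- config$cv$n_folds
  n_repeats <- config$cv$n_repeats
  if (min(table(ts$labels)) < n_folds) {
    stop("need at least n_folds trials per class for stratified folds")
  }
  segs <- decompose_for_config(ts, config)
  nt <- n_trials(ts)
  withr::with_seed(config$cv$seed, {
    partition <- lapply(seq_len(n_repeats), function(r) {
      stratified_folds(ts$labels, n_folds)
    })
    rows <- list()
    selections <- list()
    for (r in seq_len(n_repeats)) {
      fold <- partition[[r]]
      for (fd in seq_len(n_folds)) {
        test_idx <- which(fold == fd)
        train_idx <- which(fold != fd)
        fit <- fit_on_segments(segs, train_idx, config)
        pred <- predict_on_segments(fit, segs, test_idx, config)
        truth <- ts$labels[test_idx]
        rows[[length(rows) + 1L]] <- data.frame(
          rep = r, fold = fd, n_test = length(test_idx),
          n_correct = sum(pred == truth),
          accuracy = mean(pred == truth)
        )
        selections[[length(selections) + 1L]] <- fit$selection
      }
    }
    folds <- do.call(rbind, rows)
    structure(
      list(folds = folds, selections = selections, partition = partition,
           mean_accuracy = mean(folds$accuracy),
           sd_accuracy = stats::sd(folds$accuracy),
           seed = config$cv$seed, config = config),
      class = "cv_report"
    )
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %s: %d x %d-fold CV, accuracy %.1f%% +/- %.1f%% (seed %d)\n",
    toupper(x$config$selector), x$config$cv$n_repeats, x$config$cv$n_folds,
    100 * x$mean_accuracy, 100 * x$sd_accuracy, x$seed
  ))
  invisible(x)
}

#' Paired comparison of decoding methods
#'
#' Two-sided paired t-tests on per-fold accuracy vectors between each
#' method and the comparator. All reports must share the identical fold
#' partition (run them with the same `cv$seed` on the same data), so the
#' per-fold accuracies are genuinely paired. Zero-variance differences
#' (identical accuracy vectors) are degenerate: `p = 1` is returned with
#' `degenerate = TRUE`.
#'
#' @param reports named list of [cross_validate()] reports.
#' @param comparator name of the baseline report (default the first).
#' @return Data frame with one row per non-comparator method: `method`,
#'   `comparator`, `mean_diff`, `t`, `p`, `degenerate`.
#' @export
compare_methods <- function(reports, comparator = names(reports)[1L]) {
  stopifnot(is.list(reports), length(reports) >= 2L,
            !is.null(names(reports)), comparator %in% names(reports))
  base <- reports[[comparator]]
  for (nm in names(reports)) {
    if (!identical(reports[[nm]]$partition, base$partition)) {
      stop("report '", nm, "' used a different fold partition; ",
           "rerun all methods with the same cv seed and data")
    }
  }
  others <- setdiff(names(reports), comparator)
  out <- lapply(others, function(nm) {
    a <- reports[[nm]]$folds$accuracy
    b <- base$folds$accuracy
    d <- a - b
    if (stats::sd(d) == 0) {
      warning("identical accuracy vectors for '", nm, "' vs '", comparator,
              "': paired t-test is degenerate, returning p = 1")
      data.frame(method = nm, comparator = comparator, mean_diff = mean(d),
                 t = NA_real_, p = 1, degenerate = TRUE)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(method = nm, comparator = comparator, mean_diff = mean(d),
                 t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
    }
  })
  do.call(rbind, out)
}

# Segment attribution of one fold's selection: selected columns' segments
# for the column selectors; for PCA each component is attributed to the
# segment of its largest-magnitude loading.
selection_segments <- function(selection, provenance) {
  if (length(selection$selected_columns) > 0L) {
    provenance$segment[selection$selected_columns]
  } else if (nrow(selection$transform) > 0L) {
    apply(selection$transform, 1L, function(row) {
      provenance$segment[which.max(abs(row))]
    })
  } else {
    integer(0)
  }
}

#' Time-window usage of the selected features
#'
#' Tallies, over all folds of one or more reports, which of the five time
#' windows the selected feature columns came from, and the fraction of
#' folds whose selection spans at least two distinct windows (the
#' cross-window combination ratio).
#'
#' @param reports a [cross_validate()] report or a list of them.
#' @param n_segments number of time windows (default 5).
#' @return A list: `counts` (named integer vector per window index) and
#'   `cross_window_ratio`.
#' @export
segment_usage <- function(reports, n_segments = 5) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  m2 <- 2L * reports[[1L]]$config$m
  provenance <- data.frame(
    segment = rep(seq_len(n_segments), each = m2),
    filter = rep(seq_len(m2), times = n_segments)
  )
  counts <- integer(n_segments)
  names(counts) <- as.character(seq_len(n_segments))
  n_folds_total <- 0L
  n_cross <- 0L
  for (rep in reports) {
    for (sel in rep$selections) {
      segs <- selection_segments(sel, provenance)
      if (length(segs) == 0L) next
      tab <- table(factor(segs, levels = seq_len(n_segments)))
      counts <- counts + as.integer(tab)
      n_folds_total <- n_folds_total + 1L
      if (length(unique(segs)) >= 2L) n_cross <- n_cross + 1L
    }
  }
  list(counts = counts,
       cross_window_ratio = if (n_folds_total > 0L) n_cross / n_folds_total
                            else NA_real_)
}
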