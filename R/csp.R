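#' Average trace-normalized spatial covariance of a class
#'
#' Each trial's spatial covariance `E %*% t(E)` is normalized by its trace
#' before averaging, so every trial contributes equally regardless of its
#' broadband power; the result is symmetric positive semi-definite with
#' unit trace.
#'
#' @param trials list of `channels x samples` matrices (or a [trialset()],
#'   in which case all its trials are used).
#' @return A `channels x channels` covariance matrix with unit trace.
#' @export
class_covariance <- function(trials) {
  if (inherits(trials, "trialset")) {
    trials <- lapply(seq_len(n_trials(trials)), function(i) trial_matrix(trials, i))
  }
  if (length(trials) < 1L) stop("need at least one trial")
  c1 <- nrow(trials[[1L]])
  acc <- matrix(0, c1, c1)
  for (i in seq_along(trials)) {
    E <- trials[[i]]
    S <- tcrossprod(E)
    tr <- sum(diag(S))
    if (tr <= 0) stop(sprintf("trial %d has zero energy (trace 0)", i))
    acc <- acc + S / tr
  }
  acc / length(trials)
}

#' Fit common spatial pattern filters for a two-class problem
#'
#' Whitens the composite covariance `C1 + C2` and eigendecomposes the
#' whitened class-1 covariance, yielding a projection matrix `W_full` whose
#' columns `w` jointly diagonalize both class covariances with
#' `t(w) %*% C1 %*% w + t(w) %*% C2 %*% w = 1`. Eigenvalues (the class-1
#' share of variance along each filter) lie in `[0, 1]`, sorted
#' descending. The `2m` retained filters pair the `m` largest with the `m`
#' smallest eigenvalues: within `W_2m`, column `j` pairs with column
#' `2m + 1 - j`, so each discriminative direction is kept together with its
#' opposite-class counterpart.
#'
#' Filter signs are fixed by scaling each column so its largest-magnitude
#' coefficient is positive (eigenvector signs are otherwise arbitrary).
#' Equal eigenvalues keep the eigensolver's stable order.
#'
#' @param class1_trials,class2_trials lists of `channels x samples` matrices
#'   (or [trialset()]s).
#' @param m filters kept per eigenvalue extreme (default 2, i.e. 4 filters).
#' @param shrinkage optional shrinkage weight `gamma` in `[0, 1]`: each
#'   class covariance is replaced by
#'   `(1 - gamma) * C + gamma * (trace(C)/c) * I` before whitening.
#'   Default 0; use a small positive value for rank-deficient data.
#' @return An object of class `csp_model` with elements `W_full` (`c x c`,
#'   filters in columns), `W_2m` (`c x 2m`), `eigenvalues` (length `c`,
#'   descending), `m`, and `pairing` (integer vector: `pairing[j]` is the
#'   partner column of column `j` within `W_2m`).
#' @export
fit_csp <- function(class1_trials, class2_trials, m = 2, shrinkage = 0) {
  C1 <- if (is.matrix(class1_trials)) class1_trials else class_covariance(class1_trials)
  C2 <- if (is.matrix(class2_trials)) class2_trials else class_covariance(class2_trials)
  cc <- nrow(C1)
  if (!all(dim(C1) == dim(C2))) stop("class covariances disagree in size")
  if (2 * m > cc) stop("2m cannot exceed the channel count")
  if (shrinkage > 0) {
    C1 <- (1 - shrinkage) * C1 + shrinkage * (sum(diag(C1)) / cc) * diag(cc)
    C2 <- (1 - shrinkage) * C2 + shrinkage * (sum(diag(C2)) / cc) * diag(cc)
  }
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  tol <- max(ec$values) * cc * .Machine$double.eps
  if (any(ec$values <= tol)) {
    stop("composite covariance is rank-deficient; ",
         "re-fit with a positive `shrinkage` (e.g. 0.05) to regularize")
  }
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)   # whitening: P Cc P' = I
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  e1 <- eigen(S1, symmetric = TRUE)                  # values descending
  W_full <- t(P) %*% e1$vectors                      # filters in columns
  # deterministic sign: largest-|coefficient| entry positive per filter
  for (j in seq_len(cc)) {
    peak <- which.max(abs(W_full[, j]))
    if (W_full[peak, j] < 0) W_full[, j] <- -W_full[, j]
  }
  lam <- pmin(pmax(e1$values, 0), 1)
  sel <- c(seq_len(m), seq.int(cc - m + 1L, cc))
  structure(
    list(W_full = W_full, W_2m = W_full[, sel, drop = FALSE],
         eigenvalues = lam, m = as.integer(m),
         pairing = rev(seq_len(2L * m))),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels, m = %d (%d filters kept)\n",
              nrow(x$W_full), x$m, ncol(x$W_2m)))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "), "\n")
  invisible(x)
}

#' Log-variance CSP features of one trial segment
#'
#' Projects the segment through the retained filters and returns
#' `log(var(w' E))` per filter. With `normalize = TRUE` the variances are
#' first divided by their sum across the `2m` filters (the conventional
#' normalized variant); the default keeps the raw log-variance.
#'
#' @param model a [fit_csp()] model.
#' @param trial_segment `channels x samples` matrix.
#' @param normalize divide variances by their sum before the log.
#' @return Numeric vector of length `2m`.
#' @export
extract_features <- function(model, trial_segment, normalize = FALSE) {
  stopifnot(inherits(model, "csp_model"))
  if (nrow(trial_segment) != nrow(model$W_full)) {
    stop("channel count does not match the fitted model")
  }
  proj <- crossprod(model$W_2m, trial_segment)   # 2m x samples
  v <- apply(proj, 1L, stats::var)
  if (any(v <= 0)) {
    stop(sprintf("zero-variance projection for filter %s: log undefined",
                 paste(which(v <= 0), collapse = ", ")))
  }
  if (normalize) v <- v / sum(v)
  log(v)
}

#' Concatenated spatio-temporal feature table
#'
#' Applies each segment's CSP model to every trial of that segment and
#' concatenates the per-segment feature vectors row-wise into an
#' `n_trials x (Ns * 2m)` matrix, in segment-major column order (all of
#' segment 1's filters, then segment 2's, ...). Column provenance
#' `(segment, filter)` is recorded so selections can be mapped back to
#' time windows.
#'
#' @param per_segment_models list of `Ns` [fit_csp()] models.
#' @param segmented_trialsets list of `Ns` [trialset()]s from
#'   [decompose_trialset()], trial-aligned across segments.
#' @param normalize passed to [extract_features()].
#' @return An object of class `feature_table`: list with `values`
#'   (`n_trials x Ns*2m` matrix), `provenance` (data frame `segment`,
#'   `filter` per column), `labels`, and `m`.
#' @export
build_feature_table <- function(per_segment_models, segmented_trialsets,
                                normalize = FALSE) {
  ns <- length(per_segment_models)
  if (length(segmented_trialsets) != ns) {
    stop("segment count mismatch between models and trial sets")
  }
  nt <- n_trials(segmented_trialsets[[1L]])
  for (s in seq_len(ns)) {
    if (n_trials(segmented_trialsets[[s]]) != nt) {
      stop("trial counts differ across segments")
    }
  }
  m2 <- ncol(per_segment_models[[1L]]$W_2m)
  values <- matrix(0, nt, ns * m2)
  for (s in seq_len(ns)) {
    cols <- (s - 1L) * m2 + seq_len(m2)
    for (i in seq_len(nt)) {
      values[i, cols] <- extract_features(
        per_segment_models[[s]],
        trial_matrix(segmented_trialsets[[s]], i),
        normalize = normalize
      )
    }
  }
  provenance <- data.frame(
    segment = rep(seq_len(ns), each = m2),
    filter = rep(seq_len(m2), times = ns)
  )
  colnames(values) <- sprintf("s%df%d", provenance$segment, provenance$filter)
  feature_table(values, provenance, segmented_trialsets[[1L]]$labels,
                m = per_segment_models[[1L]]$m)
}

#' Construct a feature table
#'
#' @param values `n_trials x n_columns` numeric matrix.
#' @param provenance data frame with one row per column: `segment`, `filter`.
#' @param labels per-trial class labels in `{1, 2}`.
#' @param m CSP filters per extreme (pairing uses `2m`).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, provenance, labels, m = 2) {
  stopifnot(is.matrix(values), nrow(provenance) == ncol(values),
            length(labels) == nrow(values))
  structure(list(values = values, provenance = provenance,
                 labels = as.integer(labels), m = as.integer(m)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trials x %d columns (%d segments x %d filters)\n",
              nrow(x$values), ncol(x$values),
              max(x$provenance$segment), 2L * x$m))
  invisible(x)
}

#' CSP pair partner of a feature column
#'
#' Within each segment the `2m` filters pair `j` with `2m + 1 - j`
#' (largest-eigenvalue filter with smallest, and so on). Given a column
#' index of the segment-major feature table, returns the column index of
#' its partner in the same segment.
#'
#' @param j column index (1-based), may be a vector.
#' @param m filters per extreme.
#' @return Partner column index (same shape as `j`).
#' @export
pair_partner <- function(j, m = 2) {
  m2 <- 2L * m
  seg0 <- (j - 1L) %/% m2
  filt <- (j - 1L) %% m2 + 1L
  seg0 * m2 + (m2 + 1L - filt)
}

#' Export a feature table as TSV with provenance header
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# segment\t", paste(table$provenance$segment, collapse = "\t")),
    paste0("# filter\t", paste(table$provenance$filter, collapse = "\t")),
    paste(c("label", colnames(table$values)), collapse = "\t")
  ), con)
  utils::write.table(
    cbind(label = table$labels, as.data.frame(table$values)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}
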