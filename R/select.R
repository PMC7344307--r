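#' Result of a feature-selection method
#'
#' Common return type of the four selectors. For the three column selectors
#' (MUIN, LASSO, SWLDA) `selected_columns` holds exactly `k` pair-closed
#' column indices and `transform` is the corresponding `k x p` 0/1
#' row-selector matrix; for PCA `selected_columns` is empty and `transform`
#' holds the top-`k` orthonormal principal axes. `center` is subtracted
#' from a feature row before applying `transform` (zero for selectors,
#' training column means for PCA).
#'
#' @param method one of `"muin"`, `"lasso"`, `"pca"`, `"swlda"`.
#' @param selected_columns integer vector (empty for PCA).
#' @param transform `k x p` matrix.
#' @param scores per-column diagnostic (MI bits, |beta| contribution
#'   degrees, eigenvalues, or partial-F p-values).
#' @param center length-`p` vector subtracted before `transform`.
#' @param meta method-specific list (final lambda, stepwise trace, ...).
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, selected_columns, transform, scores,
                             center = NULL, meta = list()) {
  if (is.null(center)) center <- numeric(ncol(transform))
  structure(
    list(method = method,
         selected_columns = as.integer(selected_columns),
         transform = transform, scores = scores, center = center,
         meta = meta),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method %s, k = %d\n",
              toupper(x$method), nrow(x$transform)))
  if (length(x$selected_columns) > 0L) {
    cat("  columns:", paste(x$selected_columns, collapse = ", "), "\n")
  } else {
    cat("  transform-based (no column subset)\n")
  }
  invisible(x)
}

#' Apply a fitted selection to a feature matrix
#'
#' @param result a [selection_result()].
#' @param values `n x p` feature matrix (same columns as at fit time).
#' @return `n x k` matrix of selected or projected features.
#' @export
apply_selection <- function(result, values) {
  stopifnot(inherits(result, "selection_result"))
  sweep(values, 2L, result$center) %*% t(result$transform)
}

row_selector_matrix <- function(cols, p) {
  tr <- matrix(0, length(cols), p)
  tr[cbind(seq_along(cols), cols)] <- 1
  tr
}

# Walk a ranking (best first) adding each not-yet-selected column together
# with its CSP pair partner until exactly k columns are held. Because the
# partner relation is an involution, the set grows two at a time, so with k
# even the walk lands on k exactly; collisions (a top column whose partner
# was already taken as someone's pair) simply advance the walk. Ties in the
# ranking must already be broken (lower column index first).
pair_complete_walk <- function(ranking, k, m) {
  sel <- integer(0)
  for (j in ranking) {
    if (j %in% sel) next
    sel <- c(sel, j, pair_partner(j, m))
    if (length(sel) >= k) break
  }
  if (length(sel) > k) sel <- sel[seq_len(k)]
  sel
}

rank_desc <- function(score) order(-score, seq_along(score))

#' Parzen-window mutual information between one feature and the class label
#'
#' Estimates `I(v; w) = H(w) - H(w | v)` in bits for a two-class label `w`.
#' Class-conditional densities `p(v | w)` are kernel estimates with a
#' Gaussian kernel whose bandwidth follows Silverman's rule per class,
#' `h = (4 / (3 n_w))^(1/5) * sigma_w` with `sigma_w` the class-`w`
#' standard deviation of the feature. Posteriors come from Bayes' rule
#' with empirical priors, and the conditional entropy is the empirical
#' average of `-sum_w p(w|v_i) log2 p(w|v_i)` over the training trials.
#' The estimate is clipped to `[0, H(w)]`.
#'
#' @param column numeric vector of per-trial feature values.
#' @param labels per-trial class labels in `{1, 2}`.
#' @return Mutual information in bits.
#' @export
mi_score <- function(column, labels) {
  labels <- as.integer(labels)
  classes <- c(1L, 2L)
  if (!all(classes %in% labels)) stop("both classes must be present")
  n <- length(column)
  stopifnot(length(labels) == n)
  prior <- c(mean(labels == 1L), mean(labels == 2L))
  dens <- matrix(0, n, 2L)
  for (w in 1:2) {
    idx <- which(labels == classes[w])
    s <- stats::sd(column[idx])
    if (!is.finite(s) || s <= 0) {
      stop(sprintf("feature is constant within class %d: Parzen bandwidth is zero", w))
    }
    h <- (4 / (3 * length(idx)))^(1 / 5) * s
    d <- outer(column, column[idx], "-")
    dens[, w] <- rowMeans(stats::dnorm(d, sd = h))
  }
  joint <- sweep(dens, 2L, prior, "*")
  post <- joint / rowSums(joint)
  plogp <- ifelse(post > 0, post * log2(post), 0)
  h_cond <- mean(-rowSums(plogp))
  h_prior <- -sum(prior * log2(prior))
  min(max(h_prior - h_cond, 0), h_prior)
}

#' Mutual-information (MUIN) feature selection
#'
#' Scores every column of the feature table with [mi_score()], ranks the
#' scores descending, and selects the top-ranked columns together with
#' their CSP pair partners until exactly `k` columns are held (ties broken
#' toward the lower column index; a top column whose partner is already
#' selected advances the ranking walk).
#'
#' @param table a [feature_table()].
#' @param k number of columns to select (even; default 4).
#' @return A [selection_result()] with MI scores in bits.
#' @export
select_muin <- function(table, k = 4) {
  stopifnot(inherits(table, "feature_table"))
  check_k(k, ncol(table$values))
  scores <- apply(table$values, 2L, mi_score, labels = table$labels)
  sel <- pair_complete_walk(rank_desc(scores), k, table$m)
  selection_result("muin", sel, row_selector_matrix(sel, ncol(table$values)),
                   scores)
}

check_k <- function(k, p) {
  if (k %% 2L != 0L) stop("`k` must be even (features are selected in pairs)")
  if (k > p) stop("`k` cannot exceed the number of feature columns")
}

#' Solve the LASSO by cyclic coordinate descent
#'
#' Minimizes `||y - X b||_2^2 + lambda * ||b||_1` after absorbing the
#' intercept by centering `y` and the columns of `X`. At `lambda = 0` the
#' solution is ordinary least squares; for
#' `lambda >= max_j |2 x_j' (y - mean(y))|` the solution is identically
#' zero.
#'
#' @param X `n x p` design matrix.
#' @param y length-`n` response.
#' @param lambda non-negative penalty on the l1 norm.
#' @param tol convergence tolerance on the largest coefficient update.
#' @param max_iter iteration cap.
#' @param beta_init optional warm-start coefficients (used when walking a
#'   penalty grid).
#' @return Numeric coefficient vector of length `p`.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-12, max_iter = 10000L,
                      beta_init = NULL) {
  stopifnot(lambda >= 0)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(Xc)
  xss <- colSums(Xc^2)
  if (any(xss == 0)) xss[xss == 0] <- .Machine$double.eps
  beta <- if (is.null(beta_init)) numeric(p) else beta_init
  r <- yc - drop(Xc %*% beta)
  g <- lambda / 2
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj <- beta[j]
      z <- sum(Xc[, j] * r) + xss[j] * bj
      # soft-threshold z at g
      bn <- if (z > g) (z - g) / xss[j]
            else if (z < -g) (z + g) / xss[j]
            else 0
      if (bn != bj) {
        r <- r - Xc[, j] * (bn - bj)
        beta[j] <- bn
        delta <- max(delta, abs(bn - bj))
      }
    }
    if (delta < tol * (1 + max(abs(beta)))) break
  }
  beta
}

#' LASSO-based feature selection
#'
#' Regresses the numeric class label on the feature table under an l1
#' penalty, reads each feature's contribution degree `CD_j = |beta_j|`,
#' and selects the top-`k` nonzero contributors completed with their CSP
#' pair partners. If fewer than `k` coefficients are nonzero at the current
#' penalty, `lambda` is decreased along the grid until at least `k` are
#' active; an exhausted grid is an error reporting the count reached.
#'
#' @param table a [feature_table()].
#' @param k number of columns to select (even; default 4).
#' @param lambda_grid decreasing penalty values; default geometric, 50
#'   points from `lambda_max` (the smallest penalty with all-zero solution)
#'   down to `1e-4 * lambda_max`.
#' @return A [selection_result()] with contribution degrees as scores and
#'   `meta$lambda` the penalty actually used.
#' @export
lasso_select <- function(table, k = 4, lambda_grid = NULL) {
  stopifnot(inherits(table, "feature_table"))
  check_k(k, ncol(table$values))
  X <- table$values
  y <- as.numeric(table$labels)
  if (is.null(lambda_grid)) {
    lam_max <- max(abs(2 * crossprod(X, y - mean(y))))
    lambda_grid <- exp(seq(log(lam_max), log(1e-4 * lam_max), length.out = 50L))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  beta <- NULL
  lambda_used <- NA_real_
  for (lam in lambda_grid) {
    beta <- lasso_fit(X, y, lam, beta_init = beta)
    lambda_used <- lam
    if (sum(beta != 0) >= k) break
  }
  nnz <- sum(beta != 0)
  if (nnz < k) {
    stop(sprintf(
      "lambda grid exhausted with only %d nonzero contribution degree(s); need %d",
      nnz, k))
  }
  cd <- abs(beta)
  ranking <- rank_desc(cd)
  ranking <- ranking[cd[ranking] > 0]
  sel <- pair_complete_walk(ranking, k, table$m)
  selection_result("lasso", sel, row_selector_matrix(sel, ncol(X)), cd,
                   meta = list(lambda = lambda_used, beta = beta,
                               n_nonzero = nnz))
}

#' PCA feature transform
#'
#' Column-centers the feature table and takes the top-`k` right singular
#' vectors as orthonormal projection axes (equivalently the leading
#' eigenvectors of the feature covariance). Unlike the three column
#' selectors, PCA is unsupervised and returns a dense transform rather
#' than a column subset, so the CSP pairing constraint does not apply.
#'
#' @param table a [feature_table()].
#' @param k number of components (must not exceed the table's rank).
#' @return A [selection_result()] with covariance eigenvalues as scores and
#'   `meta$captured_variance` the summed top-`k` eigenvalues.
#' @export
pca_transform <- function(table, k = 4) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  tol <- max(sv$d) * max(dim(Xc)) * .Machine$double.eps
  rk <- sum(sv$d > tol)
  if (k > rk) {
    stop(sprintf("k = %d exceeds the rank (%d) of the centered feature table",
                 k, rk))
  }
  eigvals <- sv$d^2 / (nrow(X) - 1L)
  transform <- t(sv$v[, seq_len(k), drop = FALSE])
  selection_result("pca", integer(0), transform, eigvals, center = ctr,
                   meta = list(captured_variance = sum(eigvals[seq_len(k)])))
}

# Residual sum of squares of the least-squares regression of y on an
# intercept plus the given columns.
rss_of <- function(X, y, cols) {
  d <- cbind(1, X[, cols, drop = FALSE])
  fit <- stats::lm.fit(d, y)
  sum(fit$residuals^2)
}

#' Stepwise linear discriminant (SWLDA) feature selection
#'
#' Stepwise regression of the numeric class label on the feature columns:
#' forward steps add the candidate with the smallest partial-F p-value when
#' that p-value is below `p_enter`; backward steps drop any included column
#' whose drop-one partial-F p-value exceeds `p_remove`. Iteration stops
#' when `k` columns are held or no legal move remains. Partial-F p-values
#' use 1 and `n - q - 1` degrees of freedom, `q` the size of the larger
#' model. The final set is then closed under CSP pairing (the stepwise
#' loop itself is pair-agnostic): columns are re-ranked by significance and
#' pairs are taken until exactly `k` columns are held, so the least
#' significant entries are dropped first if pairing would overflow `k`.
#'
#' @param table a [feature_table()].
#' @param labels optional label override (defaults to the table's labels).
#' @param k maximum number of selected columns (even; default 4).
#' @param p_enter forward entry threshold (default 0.1).
#' @param p_remove backward removal threshold (default 0.15).
#' @return A [selection_result()]; `meta$trace` records each step,
#'   `meta$termination` is `"reached_k"` or `"stalled"`, and an empty
#'   selection (nothing ever passed entry) is flagged via
#'   `meta$empty = TRUE` with a zero-row transform.
#' @export
swlda_select <- function(table, labels = NULL, k = 4, p_enter = 0.1,
                         p_remove = 0.15) {
  stopifnot(inherits(table, "feature_table"))
  check_k(k, ncol(table$values))
  X <- table$values
  y <- as.numeric(if (is.null(labels)) table$labels else labels)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= k + 1L) stop("need more trials than k + 1 for the partial F-tests")
  S <- integer(0)
  trace <- list()
  entry_p <- rep(NA_real_, p)
  forward_p <- function(S, j) {
    rss0 <- rss_of(X, y, S)
    rss1 <- rss_of(X, y, c(S, j))
    q <- length(S) + 1L
    df2 <- n - q - 1L
    if (rss1 <= 0 || df2 <= 0) return(0)
    f <- (rss0 - rss1) / (rss1 / df2)
    stats::pf(f, 1L, df2, lower.tail = FALSE)
  }
  drop_p <- function(S, j) {
    rss1 <- rss_of(X, y, S)
    rss0 <- rss_of(X, y, setdiff(S, j))
    q <- length(S)
    df2 <- n - q - 1L
    if (rss1 <= 0 || df2 <= 0) return(0)
    f <- (rss0 - rss1) / (rss1 / df2)
    stats::pf(f, 1L, df2, lower.tail = FALSE)
  }
  termination <- "stalled"
  seen <- character(0)
  repeat {
    moved <- FALSE
    if (length(S) < k) {
      cand <- setdiff(seq_len(p), S)
      pv <- vapply(cand, function(j) forward_p(S, j), numeric(1))
      best <- which.min(pv)   # ties: lower column index (cand is sorted)
      if (pv[best] < p_enter) {
        j <- cand[best]
        S <- c(S, j)
        entry_p[j] <- pv[best]
        trace[[length(trace) + 1L]] <- list(step = "enter", column = j,
                                            p = pv[best])
        moved <- TRUE
      }
    }
    if (length(S) > 0L) {
      pv <- vapply(S, function(j) drop_p(S, j), numeric(1))
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        j <- S[worst]
        S <- setdiff(S, j)
        trace[[length(trace) + 1L]] <- list(step = "remove", column = j,
                                            p = pv[worst])
        moved <- TRUE
      }
    }
    key <- paste(sort(S), collapse = ",")
    if (length(S) >= k) { termination <- "reached_k"; break }
    if (!moved) break
    if (key %in% seen) break   # enter/remove cycle guard
    seen <- c(seen, key)
  }
  # per-column diagnostic: drop-one p for included, add-one p for excluded
  scores <- vapply(seq_len(p), function(j) {
    if (j %in% S) drop_p(S, j) else forward_p(S, j)
  }, numeric(1))
  if (length(S) == 0L) {
    return(selection_result("swlda", integer(0), matrix(0, 0L, p), scores,
                            meta = list(empty = TRUE, trace = trace,
                                        termination = termination)))
  }
  # pair closure: most significant entries first, then remaining columns
  sig <- entry_p
  sig[is.na(sig)] <- Inf
  ranking <- c(S[order(sig[S], S)],
               setdiff(order(scores, seq_len(p)), S))
  sel <- pair_complete_walk(ranking, k, table$m)
  selection_result("swlda", sel, row_selector_matrix(sel, p), scores,
                   meta = list(empty = FALSE, trace = trace,
                               termination = termination,
                               stepwise_set = S))
}

#' Fit a feature selector by name
#'
#' @param table a [feature_table()].
#' @param method `"muin"`, `"lasso"`, `"pca"`, or `"swlda"`.
#' @param k number of columns/components.
#' @param ... passed to the specific selector.
#' @return A [selection_result()].
#' @export
fit_selector <- function(table, method, k = 4, ...) {
  switch(method,
    muin = select_muin(table, k = k, ...),
    lasso = lasso_select(table, k = k, ...),
    pca = pca_transform(table, k = k, ...),
    swlda = swlda_select(table, k = k, ...),
    stop("unknown selector: ", method)
  )
}
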