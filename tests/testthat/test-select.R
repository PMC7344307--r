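test_that("MI estimator tracks the quadrature oracle for separated Gaussians", {
  set.seed(20)
  n <- 200
  labels <- rep(c(1, 2), each = n)
  v <- c(rnorm(n, -5), rnorm(n, 5))
  truth <- gaussian_mixture_mi(-5, 5)  # ~ 1 bit
  expect_gt(truth, 0.999)
  expect_lt(abs(mi_score(v, labels) - truth), 0.1)

  # closer classes: oracle well below 1 bit, estimator still tracks it
  v2 <- c(rnorm(n, -1), rnorm(n, 1))
  truth2 <- gaussian_mixture_mi(-1, 1)
  expect_lt(abs(mi_score(v2, labels) - truth2), 0.1)
})

test_that("MI of label-independent features is near zero and bounded", {
  for (s in 1:5) {
    set.seed(s)
    labels <- rep(c(1, 2), each = 200)
    v <- rnorm(400)
    sc <- mi_score(v, labels)
    expect_gte(sc, 0)
    expect_lte(sc, 1)
    expect_lt(sc, 0.05)
  }
})

test_that("MI estimator rejects degenerate inputs", {
  labels <- rep(c(1, 2), each = 10)
  expect_error(mi_score(c(rep(1, 10), rnorm(10)), labels), "constant within class 1")
  expect_error(mi_score(rnorm(10), rep(1, 10)), "both classes")
})

test_that("MUIN selects top-ranked columns closed under CSP pairing", {
  set.seed(22)
  n <- 100
  labels <- rep(c(1L, 2L), each = n / 2)
  X <- matrix(rnorm(n * 20, sd = 0.5), n, 20)
  # class signal confined to segment-1 partners (columns 1 and 4)
  X[, 1] <- X[, 1] + ifelse(labels == 1, 2, -2)
  X[, 4] <- X[, 4] - ifelse(labels == 1, 2, -2)
  tab <- toy_table(X, labels)
  sel <- select_muin(tab, k = 4)
  expect_length(sel$selected_columns, 4)
  expect_true(all(c(1, 4) %in% sel$selected_columns))
  expect_setequal(pair_partner(sel$selected_columns), sel$selected_columns)

  # rerun equality
  expect_identical(select_muin(tab, k = 4), sel)

  # class relabeling leaves the selection invariant (MI is symmetric)
  tab_sw <- toy_table(X, 3L - labels)
  expect_setequal(select_muin(tab_sw, k = 4)$selected_columns,
                  sel$selected_columns)
})

test_that("degenerate duplicate columns still yield a deterministic pair-closed set", {
  set.seed(23)
  labels <- rep(c(1L, 2L), each = 30)
  base <- rnorm(60) + ifelse(labels == 1, 1, -1)
  X <- matrix(rep(base, 20), ncol = 20)
  tab <- toy_table(X, labels)
  sel <- select_muin(tab, k = 4)
  expect_length(sel$selected_columns, 4)
  expect_setequal(pair_partner(sel$selected_columns), sel$selected_columns)
  # tie-break toward the lowest column index: first pair is (1, 4)
  expect_equal(sort(sel$selected_columns), c(1, 2, 3, 4))
})

test_that("LASSO at lambda = 0 reproduces least squares", {
  set.seed(24)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- rep(c(1, 2), 25)[order(rnorm(50))]
  beta <- lasso_fit(X, y, lambda = 0)
  ls <- stats::lm.fit(cbind(1, scale(X, scale = FALSE)), y - mean(y))
  expect_equal(beta, unname(ls$coefficients[-1]), tolerance = 1e-8)
})

test_that("LASSO matches the soft-threshold closed form on orthonormal designs", {
  set.seed(25)
  n <- 50
  Q <- qr.Q(qr(matrix(rnorm(n * 20), n, 20)))
  # orthonormalize the centered design so the closed form applies exactly
  Qc <- qr.Q(qr(scale(Q, scale = FALSE)))
  y <- rnorm(n) + 1.5
  b <- drop(crossprod(Qc, y - mean(y)))
  lam_grid <- seq(0.01, 2 * max(abs(b)), length.out = 10)
  for (lam in lam_grid) {
    beta <- lasso_fit(Qc, y, lam)
    closed <- sign(b) * pmax(abs(b) - lam / 2, 0)
    expect_equal(beta, closed, tolerance = 1e-6)
  }
})

test_that("LASSO matches an independent solver on a general design", {
  skip_if_not_installed("glmnet")
  set.seed(26)
  n <- 80
  X <- matrix(rnorm(n * 12), n, 12)
  X[, 2] <- X[, 1] * 0.9 + rnorm(n, sd = 0.1)  # collinearity
  y <- as.numeric(rep(c(1, 2), n / 2))
  y <- y + 0.3 * X[, 1] - 0.2 * X[, 5]
  for (lam in c(5, 1, 0.1)) {
    mine <- lasso_fit(X, y, lam)
    # glmnet minimizes (1/2n)||y - b0 - Xb||^2 + lambda|b|_1
    g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam / (2 * n),
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14)
    expect_equal(mine, as.numeric(g$beta), tolerance = 1e-6)
  }
})

test_that("full-shrinkage bound zeroes the solution and triggers grid adjustment", {
  set.seed(27)
  labels <- rep(c(1L, 2L), each = 40)
  X <- matrix(rnorm(80 * 20), 80, 20)
  X[, 3] <- X[, 3] + ifelse(labels == 1, 1, -1)
  y <- as.numeric(labels)
  lam_max <- max(abs(2 * crossprod(X, y - mean(y))))
  expect_equal(lasso_fit(X, y, lam_max * 1.001), rep(0, 20))

  tab <- toy_table(X, labels)
  sel <- lasso_select(tab, k = 4)
  expect_length(sel$selected_columns, 4)
  expect_setequal(pair_partner(sel$selected_columns), sel$selected_columns)
  expect_true(3 %in% sel$selected_columns)
  expect_lt(sel$meta$lambda, lam_max)  # grid walked downward past lambda_max

  # relabeling flips the sign of beta but not the contribution degrees
  sel_sw <- lasso_select(toy_table(X, 3L - labels), k = 4)
  expect_setequal(sel_sw$selected_columns, sel$selected_columns)
})

test_that("an exhausted lambda grid is a descriptive failure", {
  labels <- rep(c(1L, 2L), each = 10)
  X <- matrix(1e-12 * rnorm(20 * 20), 20, 20)
  tab <- toy_table(X, labels)
  expect_error(lasso_select(tab, k = 4, lambda_grid = c(10, 5, 1)),
               "nonzero")
})

test_that("PCA returns orthonormal top axes with the right variance", {
  set.seed(28)
  X <- matrix(rnorm(50 * 20), 50, 20)
  tab <- toy_table(X, rep(c(1L, 2L), 25))
  sel <- pca_transform(tab, k = 4)
  expect_equal(sel$transform %*% t(sel$transform), diag(4), tolerance = 1e-10)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(sel$meta$captured_variance, sum(ev[1:4]), tolerance = 1e-8)
  expect_length(sel$selected_columns, 0)

  # variance concentrated in column 1 -> first axis is +/- e1
  X2 <- matrix(0, 30, 20); X2[, 1] <- rnorm(30, sd = 3)
  X2 <- X2 + matrix(rnorm(30 * 20, sd = 1e-4), 30, 20)
  sel2 <- pca_transform(toy_table(X2, rep(c(1L, 2L), 15)), k = 1)
  e1 <- abs(sel2$transform[1, ])
  expect_gt(e1[1], 0.9999)

  # complete basis reconstructs exactly
  Xs <- matrix(rnorm(10 * 20), 10, 20)  # rank 9 after centering
  tabs <- toy_table(Xs, rep(c(1L, 2L), 5))
  rk <- qr(scale(Xs, scale = FALSE))$rank
  selr <- pca_transform(tabs, k = rk)
  proj <- apply_selection(selr, Xs)
  recon <- proj %*% selr$transform + rep(1, 10) %o% colMeans(Xs)
  expect_equal(recon, Xs, tolerance = 1e-10)
  expect_error(pca_transform(tabs, k = rk + 1), "rank")
})

test_that("SWLDA enters a perfect predictor first and respects the cap", {
  set.seed(30)
  n <- 200
  labels <- rep(c(1L, 2L), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20)
  X[, 9] <- as.numeric(labels)  # perfect predictor
  tab <- toy_table(X, labels)
  sel <- swlda_select(tab, k = 4)
  expect_equal(sel$meta$trace[[1]]$step, "enter")
  expect_equal(sel$meta$trace[[1]]$column, 9)
  expect_length(sel$selected_columns, 4)
  expect_setequal(pair_partner(sel$selected_columns), sel$selected_columns)
  # every recorded entry satisfied the entry threshold
  for (st in sel$meta$trace) {
    if (st$step == "enter") expect_lt(st$p, 0.1)
  }
})

test_that("SWLDA on pure noise never exceeds the cap and can stall empty", {
  set.seed(31)
  labels <- rep(c(1L, 2L), each = 500)
  X <- matrix(rnorm(1000 * 20), 1000, 20)
  tab <- toy_table(X, labels)
  sel <- swlda_select(tab, k = 4)
  expect_lte(length(sel$meta$stepwise_set), 4)
  expect_lte(length(sel$selected_columns), 4)

  # impossible entry threshold -> empty selection, flagged
  sel0 <- swlda_select(tab, k = 4, p_enter = 1e-16)
  expect_true(sel0$meta$empty)
  expect_length(sel0$selected_columns, 0)
  expect_equal(nrow(sel0$transform), 0)
})

test_that("SWLDA entry order matches exhaustive partial-F enumeration", {
  set.seed(32)
  n <- 120
  z <- rnorm(n)
  labels <- ifelse(z + rnorm(n, sd = 0.8) > 0, 2L, 1L)
  if (length(unique(labels)) < 2) labels[1] <- 3L - labels[1]
  # three correlated candidates with decreasing label alignment
  X <- cbind(z + rnorm(n, sd = 0.5),
             z + rnorm(n, sd = 1.5),
             rnorm(n))
  y <- as.numeric(labels)
  # oracle: enumerate partial F p-values over all subsets by brute force
  rss <- function(cols) {
    d <- cbind(1, X[, cols, drop = FALSE])
    sum(stats::lm.fit(d, y)$residuals^2)
  }
  pval <- function(S, j) {
    q <- length(S) + 1
    f <- (rss(S) - rss(c(S, j))) / (rss(c(S, j)) / (n - q - 1))
    stats::pf(f, 1, n - q - 1, lower.tail = FALSE)
  }
  oracle_order <- integer(0)
  S <- integer(0)
  repeat {
    cand <- setdiff(1:3, S)
    if (length(cand) == 0) break
    ps <- vapply(cand, function(j) pval(S, j), numeric(1))
    if (min(ps) >= 0.1) break
    j <- cand[which.min(ps)]
    S <- c(S, j); oracle_order <- c(oracle_order, j)
  }
  tab <- feature_table(X, data.frame(segment = c(1, 1, 2), filter = c(1, 2, 1)),
                       labels, m = 1)
  sel <- swlda_select(tab, k = 2)
  entries <- vapply(Filter(function(s) s$step == "enter", sel$meta$trace),
                    function(s) as.numeric(s$column), numeric(1))
  expect_equal(entries[seq_along(oracle_order)][1], oracle_order[1])
  expect_equal(entries, oracle_order[seq_along(entries)])
})

test_that("selectors are deterministic functions of their inputs", {
  set.seed(33)
  labels <- rep(c(1L, 2L), each = 40)
  X <- matrix(rnorm(80 * 20), 80, 20)
  X[, 5] <- X[, 5] + ifelse(labels == 1, 1.5, -1.5)
  tab <- toy_table(X, labels)
  for (method in c("muin", "lasso", "pca", "swlda")) {
    a <- fit_selector(tab, method, k = 4)
    b <- fit_selector(tab, method, k = 4)
    expect_identical(a, b)
  }
  expect_error(fit_selector(tab, "muin", k = 3), "even")
  expect_error(fit_selector(tab, "mrmr"), "unknown")
})
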