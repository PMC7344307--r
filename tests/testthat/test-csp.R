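test_that("class covariance is trace-normalized and scale-invariant", {
  # all energy in channel 1
  E <- rbind(c(1, -1, 1, -1), c(0, 0, 0, 0))
  C <- class_covariance(list(E))
  expect_equal(C, diag(c(1, 0)))

  set.seed(4)
  trials <- lapply(1:6, function(i) matrix(rnorm(3 * 50), 3, 50))
  C1 <- class_covariance(trials)
  expect_equal(sum(diag(C1)), 1, tolerance = 1e-12)
  expect_equal(C1, t(C1))
  expect_true(all(eigen(C1, symmetric = TRUE)$values > -1e-12))

  C10 <- class_covariance(lapply(trials, function(E) 10 * E))
  expect_equal(C10, C1, tolerance = 1e-12)

  expect_error(class_covariance(list(matrix(0, 2, 4))), "trial 1")
})

test_that("fit_csp jointly diagonalizes and orders eigenvalues", {
  set.seed(8)
  A1 <- matrix(rnorm(16), 4); C1 <- crossprod(A1) / 20
  A2 <- matrix(rnorm(16), 4); C2 <- crossprod(A2) / 20
  mod <- fit_csp(C1, C2, m = 2)
  lam <- mod$eigenvalues
  expect_true(all(diff(lam) <= 1e-12))
  expect_true(all(lam >= 0 & lam <= 1))
  for (j in seq_len(ncol(mod$W_full))) {
    w <- mod$W_full[, j]
    expect_equal(drop(t(w) %*% C1 %*% w + t(w) %*% C2 %*% w), 1,
                 tolerance = 1e-10)
    expect_equal(drop(t(w) %*% C1 %*% w), lam[j], tolerance = 1e-10)
  }
  # off-diagonal joint diagonalization
  D1 <- t(mod$W_full) %*% C1 %*% mod$W_full
  expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-10)
})

test_that("symmetric classes give eigenvalues 1/2; pairing map is fixed", {
  C <- diag(c(0.5, 0.3, 0.2)) / 2
  mod <- fit_csp(C, C, m = 1)
  expect_equal(mod$eigenvalues, rep(0.5, 3), tolerance = 1e-12)

  set.seed(10)
  trials1 <- lapply(1:8, function(i) matrix(rnorm(10 * 80), 10, 80))
  trials2 <- lapply(1:8, function(i) matrix(rnorm(10 * 80), 10, 80))
  mod10 <- fit_csp(trials1, trials2, m = 2)
  expect_equal(ncol(mod10$W_2m), 4)
  expect_equal(mod10$pairing, c(4L, 3L, 2L, 1L))  # 1<->4, 2<->3
})

test_that("top filter matches brute-force variance-ratio maximization", {
  # class 1 energy on channel A, class 2 on channel B, slight mixing
  C1 <- matrix(c(1, 0.005, 0.005, 1e-4), 2)
  C2 <- matrix(c(1e-4, 0.003, 0.003, 1), 2)
  mod <- fit_csp(C1, C2, m = 1)
  oracle <- brute_force_csp_2ch(C1, C2, step_deg = 0.1)
  w_top <- mod$W_full[, 1]
  r_top <- drop(t(w_top) %*% C1 %*% w_top) /
    drop(t(w_top) %*% (C1 + C2) %*% w_top)
  expect_gte(r_top, 0.999 * oracle$ratio)
  expect_gte(r_top, 0.999)
  expect_lt(angle_dist_deg(angle_deg_of(w_top), oracle$angle_deg), 0.5)
})

test_that("class swap reverses the eigenvalue spectrum and filter set", {
  set.seed(12)
  A1 <- matrix(rnorm(25), 5); C1 <- crossprod(A1) / 30
  A2 <- matrix(rnorm(25), 5); C2 <- crossprod(A2) / 30
  a <- fit_csp(C1, C2, m = 2)
  b <- fit_csp(C2, C1, m = 2)
  expect_equal(b$eigenvalues, rev(1 - a$eigenvalues), tolerance = 1e-9)
  # column-reversed filter set (signs already canonical)
  expect_equal(b$W_2m, a$W_2m[, 4:1], tolerance = 1e-8)
  # scaling both class covariances by one scalar leaves the spectrum fixed
  s <- fit_csp(7 * C1, 7 * C2, m = 2)
  expect_equal(s$eigenvalues, a$eigenvalues, tolerance = 1e-9)
})

test_that("deep ERD with vanishing noise drives the top eigenvalue toward 1", {
  cfg <- synth_config(
    n_trials_per_class = 20, n_channels = 4, noise_sd = 1e-3,
    erd_specs = list(
      erd_spec(1, channels = 1, depth = 0.99, windows_s = list(c(0, 4))),
      erd_spec(2, channels = 2, depth = 0.99, windows_s = list(c(0, 4)))
    ),
    seed = 31
  )
  ts <- generate_mi_trialset(cfg)
  segs <- decompose_trialset(ts, segment_scheme(t0_s = 0.5), bandpass_spec())
  seg <- segs[[2]]  # fully inside the ERD interval
  tr1 <- lapply(which(seg$labels == 1), function(i) trial_matrix(seg, i))
  tr2 <- lapply(which(seg$labels == 2), function(i) trial_matrix(seg, i))
  mod <- fit_csp(tr1, tr2, m = 2)
  expect_gt(mod$eigenvalues[1], 0.97)
  expect_lt(mod$eigenvalues[length(mod$eigenvalues)], 0.03)
})

test_that("rank-deficient composite covariance asks for regularization", {
  C <- matrix(0, 3, 3); C[1, 1] <- 1  # rank 1
  expect_error(fit_csp(C / 2, C / 2, m = 1), "shrinkage|regulari")
  mod <- fit_csp(C / 2, C / 2, m = 1, shrinkage = 0.1)
  expect_true(all(is.finite(mod$W_full)))
})

test_that("log-variance features obey identity and scaling laws", {
  set.seed(14)
  E <- matrix(rnorm(2 * 200, sd = c(2, 0.5)), 2, 200)
  mod <- structure(
    list(W_full = diag(2), W_2m = diag(2), eigenvalues = c(0.5, 0.5),
         m = 1L, pairing = c(2L, 1L)),
    class = "csp_model")
  f <- extract_features(mod, E)
  expect_equal(f, log(apply(E, 1, var)), tolerance = 1e-12)
  f10 <- extract_features(mod, 10 * E)
  expect_equal(f10 - f, rep(2 * log(10), 2), tolerance = 1e-12)
  # normalized variant sums variances to one before the log
  fn <- extract_features(mod, E, normalize = TRUE)
  expect_equal(sum(exp(fn)), 1, tolerance = 1e-12)
  expect_error(extract_features(mod, matrix(0, 2, 50)), "filter")
})

test_that("feature table has segment-major provenance and permutes with trials", {
  cfg <- small_synth(n = 10, seed = 17)
  ts <- generate_mi_trialset(cfg)
  segs <- decompose_trialset(ts, segment_scheme(t0_s = 0.5), bandpass_spec())
  models <- lapply(segs, function(seg) {
    fit_csp(lapply(which(seg$labels == 1), function(i) trial_matrix(seg, i)),
            lapply(which(seg$labels == 2), function(i) trial_matrix(seg, i)),
            m = 2)
  })
  tab <- build_feature_table(models, segs)
  expect_equal(dim(tab$values), c(20, 20))
  expect_equal(tab$provenance$segment[7], 2)
  expect_equal(tab$provenance$filter[7], 3)
  expect_identical(tab$labels, ts$labels)

  perm <- sample(20)
  segs_p <- lapply(segs, function(s) subset_trials(s, perm))
  tab_p <- build_feature_table(models, segs_p)
  expect_equal(tab_p$values, tab$values[perm, ], tolerance = 1e-12)

  expect_error(build_feature_table(models[1:4], segs), "mismatch")
})

test_that("pair partner arithmetic is an involution within segments", {
  for (j in 1:20) {
    p <- pair_partner(j)
    expect_equal(pair_partner(p), j)
    expect_equal((j - 1) %/% 4, (p - 1) %/% 4)  # same segment
    expect_false(p == j)
  }
  expect_equal(pair_partner(c(1, 2, 3, 4)), c(4, 3, 2, 1))
  expect_equal(pair_partner(7), 6)
})

test_that("feature tables export with a provenance header", {
  tab <- toy_table(matrix(rnorm(40), 2, 20), c(1, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# segment\t1\t1\t1\t1\t2")
  expect_match(lines[2], "^# filter\t1\t2\t3\t4\t1")
  expect_equal(length(lines), 3 + 2)
})
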