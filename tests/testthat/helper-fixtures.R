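# Shared fixture builders and independent oracles for the test suite.

# A small, fast synthetic configuration with strong lateralized ERD:
# class 1 attenuates channel 3, class 2 channel 6, alpha band, first 3 s
# of the imagery period.
small_synth <- function(n = 15, seed = 42, depth = 0.8, noise_sd = 2,
                        rhythm_amplitude = 10, n_channels = 8) {
  ch1 <- min(3, n_channels)
  ch2 <- min(6, n_channels)
  if (ch2 == ch1) ch2 <- max(1, ch1 - 1)
  synth_config(
    n_trials_per_class = n, n_channels = n_channels,
    rhythm_amplitude = rhythm_amplitude, noise_sd = noise_sd,
    erd_specs = list(
      erd_spec(1, channels = ch1, depth = depth),
      erd_spec(2, channels = ch2, depth = depth)
    ),
    seed = seed
  )
}

# Band power of one trial channel over a sample window, computed directly
# from a Hann-windowed FFT: an oracle independent of the filtering and CSP
# code paths.
fft_band_power <- function(x, fs, band) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  X <- stats::fft(x * w)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= band[1] & f <= band[2]
  sum(Mod(X[keep])^2)
}

# Brute-force CSP oracle for 2 channels: scan unit vectors on an angular
# grid and maximize the class-1 share of the composite variance.
brute_force_csp_2ch <- function(C1, C2, step_deg = 0.1) {
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  ratio <- vapply(ang, function(a) {
    w <- c(cos(a), sin(a))
    v1 <- drop(t(w) %*% C1 %*% w)
    v2 <- drop(t(w) %*% C2 %*% w)
    v1 / (v1 + v2)
  }, numeric(1))
  best <- which.max(ratio)
  list(angle_deg = (ang[best] * 180 / pi), ratio = ratio[best])
}

angle_deg_of <- function(w) {
  a <- atan2(w[2], w[1]) * 180 / pi
  a <- a %% 180  # direction, not orientation
  a
}

# Acute angular distance between two filter directions in degrees.
angle_dist_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# Quadrature oracle: mutual information (bits) between a balanced binary
# class and a feature drawn from N(mu_w, sd^2) per class, integrating the
# true mixture densities.
gaussian_mixture_mi <- function(mu1, mu2, sd = 1, p1 = 0.5) {
  p2 <- 1 - p1
  h_prior <- -p1 * log2(p1) - p2 * log2(p2)
  integrand <- function(v) {
    d1 <- p1 * stats::dnorm(v, mu1, sd)
    d2 <- p2 * stats::dnorm(v, mu2, sd)
    tot <- d1 + d2
    w1 <- ifelse(tot > 0, d1 / tot, 0.5)
    w2 <- 1 - w1
    ent <- -(ifelse(w1 > 0, w1 * log2(w1), 0) +
             ifelse(w2 > 0, w2 * log2(w2), 0))
    tot * ent
  }
  lo <- min(mu1, mu2) - 10 * sd
  hi <- max(mu1, mu2) + 10 * sd
  h_cond <- stats::integrate(integrand, lo, hi, rel.tol = 1e-10)$value
  h_prior - h_cond
}

# A feature table with prescribed values and default 5-segment/m = 2
# provenance.
toy_table <- function(values, labels, m = 2) {
  ns <- ncol(values) / (2 * m)
  feature_table(values, data.frame(
    segment = rep(seq_len(ns), each = 2 * m),
    filter = rep(seq_len(2 * m), times = ns)
  ), labels, m = m)
}

# Exact two-sided binomial acceptance interval for chance-level accuracy:
# returns (lo, hi) bounds on the proportion correct at n predictions.
binomial_chance_interval <- function(n, level = 0.95) {
  alpha <- 1 - level
  lo <- stats::qbinom(alpha / 2, n, 0.5) / n
  hi <- stats::qbinom(1 - alpha / 2, n, 0.5) / n
  c(lo, hi)
}
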