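# Independent oracles used across the suite. Each is a direct, brute-force
# or closed-form computation kept deliberately separate from the package's
# own code paths.

# Monte-Carlo null: mean resultant length of N iid uniform phases
mc_null_plv_mean <- function(n_samples, n_draws = 10000) {
  mean(vapply(seq_len(n_draws), function(i) {
    Mod(mean(exp(1i * stats::runif(n_samples, -pi, pi))))
  }, numeric(1)))
}

# triple-loop PLV matrix, within-epoch averaging over valid samples
brute_plv_matrix <- function(sp, lp, retained, valid) {
  ns <- dim(sp)[2]; nl <- dim(lp)[2]
  out <- matrix(0, ns, nl)
  eps <- which(retained)
  for (i in seq_len(ns)) {
    for (k in seq_len(nl)) {
      acc <- 0
      for (e in eps) {
        d <- sp[e, i, valid] - lp[e, k, valid]
        acc <- acc + Mod(mean(exp(1i * d)))
      }
      out[i, k] <- acc / length(eps)
    }
  }
  out
}

# literal Benjamini-Hochberg step-up adjusted values
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, m * p[ord[j]] / j), numeric(1))
    adj_sorted[i] <- min(cand)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# textbook pooled-variance two-sample t
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2),
       d = (mean(a) - mean(b)) / sqrt(sp2))
}

# population Bessel-ratio PLV by numerical integration (independent of besselI)
bessel_ratio_integral <- function(kappa) {
  num <- integrate(function(th) cos(th) * exp(kappa * cos(th)), -pi, pi,
                   rel.tol = 1e-10)$value
  den <- integrate(function(th) exp(kappa * cos(th)), -pi, pi,
                   rel.tol = 1e-10)$value
  num / den
}

# analytic Granger statistic of the generator's unidirectional pair at lag 1
gc_analytic_forward <- function(drive, var_x = 1) log(1 + drive^2 * var_x)

# dominant frequency of a signal by discrete Fourier magnitude
fft_peak_hz <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x))[1:(floor(n / 2) + 1)]
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
  f[which.max(sp)]
}

# power-spectral centroid over positive frequencies
spectral_centroid_hz <- function(x, fs) {
  n <- length(x)
  sp <- Mod(fft(x))[2:(floor(n / 2) + 1)]^2
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1)[-1]
  sum(f * sp) / sum(sp)
}

# univariate AR(2) series for order-selection checks
ar2_series <- function(n, phi = c(0.5, -0.3)) {
  x <- numeric(n)
  e <- rnorm(n)
  for (t in 3:n) x[t] <- phi[1] * x[t - 1] + phi[2] * x[t - 2] + e[t]
  x
}

# small single-ROI phase-level cohort spec used in several tests
tiny_cohort_spec <- function(seed, roi_targets = default_roi_targets(),
                             epochs = 12, samples = 40) {
  cohort_spec(roi_targets = roi_targets, channels_per_roi = 1,
              epochs = epochs, samples_per_epoch = samples, seed = seed)
}
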