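# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: direct DFT sums, scalar loops, analog
# closed forms.

# energy of x in [f_lo, f_hi) Hz via the two-sided DFT
oracle_band_energy <- function(x, fs, f_lo, f_hi) {
  P <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  f <- pmin(f, fs - f)
  sum(P[f >= f_lo & f < f_hi])
}

# single-bin DFT magnitude (Goertzel-style direct sum) -> RMS of that tone
oracle_tone_rms <- function(x, fs, f_hz) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  c1 <- sum(x * exp(-2i * pi * f_hz * t))
  # amplitude of a real sinusoid at f: 2|c|/n; RMS = amplitude / sqrt(2)
  2 * Mod(c1) / n / sqrt(2)
}

# analytic-signal envelope restricted to a frequency band
oracle_band_envelope <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  ff <- pmin(f, fs - f)
  X[!(ff >= f_lo & ff <= f_hi)] <- 0
  xb <- Re(stats::fft(X, inverse = TRUE)) / n
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  env <- Mod(stats::fft(stats::fft(xb) * h, inverse = TRUE) / n)
  # 50 ms smoothing so intra-burst oscillation does not split events
  k <- max(1L, as.integer(round(0.05 * fs)))
  env <- stats::filter(env, rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  as.numeric(env)
}

# count upward crossings of a threshold (distinct envelope events)
oracle_count_events <- function(env, threshold) {
  above <- env > threshold
  sum(diff(c(FALSE, above)) == 1)
}

# scalar brute-force thresholding rules
oracle_hard_scalar <- function(c, t) if (abs(c) >= t) c else 0
oracle_soft_scalar <- function(c, t) {
  if (abs(c) >= t) sign(c) * (abs(c) - t) else 0
}

# double-loop frame-spectral noise power (means written as explicit sums)
oracle_noise_power <- function(power_matrix) {
  K <- nrow(power_matrix); L <- ncol(power_matrix)
  v <- numeric(L)
  for (l in seq_len(L)) {
    xbar <- 0
    for (k in seq_len(K)) xbar <- xbar + power_matrix[k, l]
    xbar <- xbar / K
    acc <- 0
    for (k in seq_len(K)) acc <- acc + (power_matrix[k, l] - xbar)^2
    v[l] <- acc / K
  }
  sum(v) / L
}

make_tone <- function(f_hz, fs, dur_s, amp = 1) {
  t <- seq_len(round(dur_s * fs)) - 1
  pcg_signal(amp * sin(2 * pi * f_hz * t / fs), fs)
}
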