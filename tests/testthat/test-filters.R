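fs <- 2000
cfg <- filter_bank_config(fs)

test_that("Butterworth low-pass meets DC, half-power, and slope contracts", {
  lp <- design_butterworth_lowpass(cfg)
  expect_equal(Mod(frequency_response(lp, 0)), 1, tolerance = 1e-9)
  expect_equal(Mod(frequency_response(lp, cfg$lp_cutoff_hz))^2, 0.5,
               tolerance = 1e-6)
  # digital response at 2*fc is at least as attenuated as the analog
  # order-4 prototype closed form 1/sqrt(1 + (f/fc)^8) (bilinear warping
  # compresses toward Nyquist)
  f2 <- min(2 * cfg$lp_cutoff_hz, fs / 2 - 1)
  expect_lte(Mod(frequency_response(lp, f2)), 1 / sqrt(1 + (f2 / 700)^8))
  expect_error(filter_bank_config(fs, lp_cutoff_hz = 1200), "fs/2")
})

test_that("twin-T notch kills the mains frequency and leaves the passband", {
  nt <- design_twin_t_notch(cfg)
  expect_lt(Mod(frequency_response(nt, cfg$notch_hz)), 1e-3)
  db <- function(g) 20 * log10(Mod(g))
  expect_lt(abs(db(frequency_response(nt, 0))), 0.1)
  # Nyquist gain via direct polynomial evaluation at z = -1
  h_nyq <- sum(nt$numerator * (-1)^(seq_along(nt$numerator) - 1)) /
    sum(nt$denominator * (-1)^(seq_along(nt$denominator) - 1))
  expect_lt(abs(20 * log10(abs(h_nyq))), 0.1)
})

test_that("notch attenuates a sustained 50 Hz tone by >= 40 dB in steady state", {
  tone <- make_tone(50, fs, 10)
  out <- apply_filter(design_twin_t_notch(cfg), tone)
  keep <- (2 * fs + 1):(10 * fs)  # discard 2 s transient
  atten_db <- 20 * log10(sqrt(mean(tone$samples[keep]^2)) /
                           sqrt(mean(out$samples[keep]^2)))
  expect_gte(atten_db, 40)
})

test_that("frequency_response matches an impulse-response FFT oracle", {
  lp <- design_butterworth_lowpass(cfg)
  nfft <- 4096
  imp <- pcg_signal(c(1, numeric(nfft - 1)), fs)
  h <- apply_filter(lp, imp)$samples
  H <- stats::fft(h)
  grid_hz <- (0:(nfft / 2 - 1)) * fs / nfft
  expect_equal(frequency_response(lp, grid_hz), H[seq_len(nfft / 2)],
               tolerance = 1e-6)
  # trivial anchors: identity and one-sample delay
  ident <- pcgdenoise:::new_digital_filter(1, 1, fs, "identity")
  expect_equal(Mod(frequency_response(ident, c(0, 123, 999))), rep(1, 3))
  delay <- pcgdenoise:::new_digital_filter(c(0, 1), 1, fs, "delay")
  g <- frequency_response(delay, c(100, 400))
  expect_equal(Mod(g), rep(1, 2), tolerance = 1e-12)
  expect_equal(Arg(g), -2 * pi * c(100, 400) / fs, tolerance = 1e-12)
  expect_error(frequency_response(lp, 1000), "Nyquist")
})

test_that("front end preserves in-band tones and removes mains interference", {
  t <- (seq_len(10 * fs) - 1) / fs
  x <- pcg_signal(sin(2 * pi * 50 * t) + sin(2 * pi * 100 * t), fs)
  y <- apply_front_end(x, cfg)
  keep <- (2 * fs + 1):(10 * fs)
  in50 <- oracle_tone_rms(x$samples[keep], fs, 50)
  in100 <- oracle_tone_rms(x$samples[keep], fs, 100)
  out50 <- oracle_tone_rms(y$samples[keep], fs, 50)
  out100 <- oracle_tone_rms(y$samples[keep], fs, 100)
  expect_gte(20 * log10(in50 / out50), 40)
  expect_lt(abs(20 * log10(in100 / out100)), 1)
  expect_equal(length(y$samples), length(x$samples))
  # zero in, zero out
  z <- apply_front_end(pcg_signal(numeric(100), fs), cfg)
  expect_equal(z$samples, numeric(100))
})

test_that("low-pass acts above cutoff: 900 Hz tone much weaker than 300 Hz", {
  lp <- design_butterworth_lowpass(cfg)
  g300 <- Mod(frequency_response(lp, 300))
  g900 <- Mod(frequency_response(lp, 900))
  expect_gte(20 * log10(g300 / g900), 8)
  # time-domain check agrees with the designed response
  y300 <- apply_filter(lp, make_tone(300, fs, 6))
  y900 <- apply_filter(lp, make_tone(900, fs, 6))
  keep <- (2 * fs + 1):(6 * fs)
  ratio_db <- 20 * log10(oracle_tone_rms(y300$samples[keep], fs, 300) /
                           oracle_tone_rms(y900$samples[keep], fs, 900))
  expect_gte(ratio_db, 8)
})

test_that("designed filters are stable and linear, and the cascade commutes", {
  lp <- design_butterworth_lowpass(cfg)
  nt <- design_twin_t_notch(cfg)
  for (flt in list(lp, nt)) {
    p <- pcgdenoise:::filter_poles(flt)
    expect_lt(max(Mod(p)), 1)
    imp <- apply_filter(flt, pcg_signal(c(1, numeric(5 * fs - 1)), fs))
    expect_lt(max(abs(utils::tail(imp$samples, fs))), 1e-9)
  }
  set.seed(17)
  x <- pcg_signal(rnorm(4000), fs); y <- pcg_signal(rnorm(4000), fs)
  lhs <- apply_filter(lp, pcg_signal(2 * x$samples - 3 * y$samples, fs))
  rhs <- 2 * apply_filter(lp, x)$samples - 3 * apply_filter(lp, y)$samples
  expect_equal(lhs$samples, rhs, tolerance = 1e-9)
  # steady-state commutation of the cascade order
  z <- make_tone(120, fs, 8)
  ab <- apply_filter(nt, apply_filter(lp, z))$samples
  ba <- apply_filter(lp, apply_filter(nt, z))$samples
  keep <- (3 * fs + 1):(8 * fs)
  expect_equal(ab[keep], ba[keep], tolerance = 1e-9)
})
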