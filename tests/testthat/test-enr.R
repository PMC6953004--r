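test_that("peak normalization scales exactly and rejects silence", {
  s <- pcg_signal(c(0.5, -0.25), 100)
  expect_equal(normalize_peak(s)$samples, c(1, -0.5))
  already <- pcg_signal(c(1, -0.3), 100)
  expect_equal(normalize_peak(already)$samples, already$samples)
  set.seed(51)
  x <- rnorm(100)
  for (a in c(0.01, 7)) {
    expect_equal(normalize_peak(pcg_signal(a * x, 100))$samples,
                 normalize_peak(pcg_signal(x, 100))$samples,
                 tolerance = 1e-12)
  }
  expect_error(normalize_peak(pcg_signal(numeric(5), 100)), "all-zero")
})

test_that("frame splitting partitions the signal and discards the remainder", {
  s <- pcg_signal(seq_len(30000) / 30000, 2000)
  fr <- split_frames(s, 5)
  expect_length(fr, 5L)
  expect_true(all(vapply(fr, function(f) length(f$samples), 1L) == 6000L))
  expect_equal(unlist(lapply(fr, `[[`, "samples")), s$samples)
  s2 <- pcg_signal(1:10 / 10, 100)
  expect_warning(fr2 <- split_frames(s2, 3), "discarding 1")
  expect_equal(unlist(lapply(fr2, `[[`, "samples")), s2$samples[1:9])
  expect_error(split_frames(s2, 0), ">= 1")
})

test_that("frame power spectra are two-sided |FFT|^2 with Parseval energy", {
  # unit impulse frame: flat unit power across all bins
  imp <- pcg_signal(c(1, numeric(15)), 100)
  sp <- frame_power_spectra(list(imp))
  expect_equal(dim(sp$power), c(16L, 1L))
  expect_equal(sp$power[, 1], rep(1, 16))
  zero <- frame_power_spectra(list(pcg_signal(numeric(8), 100)))
  expect_equal(zero$power[, 1], numeric(8))
  set.seed(61)
  frames <- lapply(1:4, function(i) pcg_signal(rnorm(128), 100))
  sp2 <- frame_power_spectra(frames)
  for (l in 1:4) {
    expect_equal(sum(sp2$power[, l]), 128 * sum(frames[[l]]$samples^2),
                 tolerance = 1e-9)
  }
  expect_error(frame_power_spectra(list(imp, pcg_signal(numeric(8), 100))),
               "ragged")
})

test_that("noise_power reproduces hand and double-loop oracle values", {
  flat <- structure(list(power = matrix(3, 10, 4), K = 10L, L = 4L, fs = 100),
                    class = "frame_spectra")
  npf <- noise_power(flat)
  expect_equal(npf$mean_power_per_frame, rep(3, 4))
  expect_equal(npf$variance_per_frame, rep(0, 4))
  expect_equal(npf$sigma_hat_sq, 0)
  hand <- structure(list(power = matrix(c(0, 2), 2, 1), K = 2L, L = 1L, fs = 100),
                    class = "frame_spectra")
  nph <- noise_power(hand)
  expect_equal(nph$mean_power_per_frame, 1)
  expect_equal(nph$variance_per_frame, 1)
  expect_equal(nph$sigma_hat_sq, 1)
  set.seed(62)
  for (rep in 1:5) {
    pm <- matrix(stats::rexp(64 * 5), 64, 5)
    sp <- structure(list(power = pm, K = 64L, L = 5L, fs = 100),
                    class = "frame_spectra")
    np <- noise_power(sp)
    expect_equal(np$sigma_hat_sq, oracle_noise_power(pm), tolerance = 1e-12)
    expect_equal(np$sigma_hat_sq, mean(np$variance_per_frame),
                 tolerance = 1e-12)
    # sqrt variant averages the per-frame standard deviations instead
    expect_equal(noise_power(sp, sqrt_variant = TRUE)$sigma_hat_sq,
                 mean(sqrt(np$variance_per_frame)), tolerance = 1e-12)
    # permutation invariance over frames
    perm <- sample(5)
    spp <- structure(list(power = pm[, perm], K = 64L, L = 5L, fs = 100),
                     class = "frame_spectra")
    expect_equal(noise_power(spp)$sigma_hat_sq, np$sigma_hat_sq,
                 tolerance = 1e-12)
  }
})

test_that("ENR identities: self-comparison and gain invariance give exactly 100%", {
  x <- generate_pcg(pcg_config(duration_s = 5, seed = 8))
  expect_equal(enr(x, x)$enr_percent, 100)
  for (a in c(0.1, 3)) {
    xs <- pcg_signal(a * x$samples, x$fs)
    expect_equal(enr(xs, x)$enr_percent, 100, tolerance = 1e-9)
    expect_equal(enr(x, xs)$enr_percent, 100, tolerance = 1e-9)
  }
  # one impulse per frame -> every frame spectrum is flat -> sigma_hat_sq = 0
  flat <- numeric(10000)
  flat[seq(1, 10000, by = 2000)] <- 1
  expect_error(enr(x, pcg_signal(flat, x$fs)), "undefined")
})

test_that("sigma_hat_sq grows with the level of added broadband noise", {
  # applied to raw (un-renormalized) spectra of a fixed reference signal
  clean <- generate_pcg(pcg_config(seed = 1))
  sig2 <- function(x) {
    noise_power(frame_power_spectra(split_frames(pcg_signal(x, 2000), 5)))$sigma_hat_sq
  }
  means <- vapply(c(0.2, 0.6, 1.8), function(rms) {
    mean(vapply(1:15, function(sd) {
      nz <- generate_noise(noise_spec("white", seed = 500 + sd), 30000, 2000)
      sig2(clean$samples + rms * nz$samples)
    }, 1))
  }, 1)
  expect_true(all(diff(means) > 0))
})

test_that("zero-padded FFT length option is accepted and scale-stable", {
  x <- generate_pcg(pcg_config(duration_s = 5, seed = 9))
  r <- enr(x, x, fft_length = 6000)
  expect_equal(r$enr_percent, 100)
  expect_length(r$test_estimate$mean_power_per_frame, 5L)
})
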