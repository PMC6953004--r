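#' Front-end filter bank configuration
#'
#' Digital emulation of the analog conditioning chain: a 4th-order
#' Butterworth low-pass (heart-sound band upper edge, default 700 Hz)
#' followed by a twin-T style notch at the mains frequency. The hardware
#' is causal, so the emulation filters causally by default.
#'
#' @param fs sampling rate in Hz.
#' @param lp_cutoff_hz low-pass -3 dB cutoff in Hz (default 700).
#' @param notch_hz notch centre frequency in Hz (default 50; set 60 for
#'   60 Hz mains).
#' @param notch_q notch quality factor, 3 dB bandwidth = `notch_hz /
#'   notch_q` (default 35, emulating a trimmed twin-T network).
#' @return A `filter_bank_config` list. The low-pass order is fixed at 4.
#' @export
filter_bank_config <- function(fs, lp_cutoff_hz = 700, notch_hz = 50,
                               notch_q = 35) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  if (!is.numeric(lp_cutoff_hz) || lp_cutoff_hz <= 0 || lp_cutoff_hz >= fs / 2)
    stop("`lp_cutoff_hz` must satisfy 0 < cutoff < fs/2", call. = FALSE)
  if (!is.numeric(notch_hz) || notch_hz <= 0 || notch_hz >= lp_cutoff_hz)
    stop("`notch_hz` must satisfy 0 < notch_hz < lp_cutoff_hz", call. = FALSE)
  if (!is.numeric(notch_q) || notch_q <= 0)
    stop("`notch_q` must be positive", call. = FALSE)
  structure(list(fs = fs, lp_cutoff_hz = lp_cutoff_hz, lp_order = 4L,
                 notch_hz = notch_hz, notch_q = notch_q),
            class = "filter_bank_config")
}

new_digital_filter <- function(b, a, fs, label) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  flt <- structure(list(numerator = b, denominator = a, fs = fs,
                        label = label),
                   class = "digital_filter")
  p <- filter_poles(flt)
  if (length(p) && max(Mod(p)) >= 1)
    stop(sprintf("designed filter '%s' is unstable (pole magnitude %.6f)",
                 label, max(Mod(p))), call. = FALSE)
  flt
}

filter_poles <- function(flt) {
  a <- flt$denominator
  if (length(a) < 2L) return(complex(0))
  polyroot(rev(a))
}

#' @export
print.digital_filter <- function(x, ...) {
  cat(sprintf("<digital_filter '%s' @ %g Hz, order %d>\n", x$label, x$fs,
              length(x$denominator) - 1L))
  cat("  b:", signif(x$numerator, 6), "\n")
  cat("  a:", signif(x$denominator, 6), "\n")
  invisible(x)
}

#' Design the 4th-order Butterworth low-pass
#'
#' Maximally flat digital low-pass obtained by bilinear transform with
#' frequency prewarping, so the half-power (-3.0103 dB) point lands
#' exactly on the configured cutoff. DC gain is unity.
#'
#' @param cfg a [filter_bank_config()].
#' @return A `digital_filter` (numerator/denominator coefficients plus
#'   sampling rate).
#' @export
design_butterworth_lowpass <- function(cfg) {
  if (!inherits(cfg, "filter_bank_config"))
    stop("`cfg` must be a filter_bank_config()", call. = FALSE)
  ba <- signal::butter(cfg$lp_order, cfg$lp_cutoff_hz / (cfg$fs / 2),
                       type = "low")
  new_digital_filter(ba$b, ba$a, cfg$fs,
                     sprintf("butterworth_lp_%gHz", cfg$lp_cutoff_hz))
}

#' Design the twin-T mains notch
#'
#' Digital emulation of a trimmed parallel-T (twin-T) RC notch: a
#' constrained second-order section with numerator zeros on the unit
#' circle at the notch frequency and poles pulled inside to set the 3 dB
#' bandwidth `notch_hz / notch_q`. Gain is exactly unity at DC and at the
#' Nyquist frequency.
#'
#' @param cfg a [filter_bank_config()].
#' @return A `digital_filter`.
#' @export
design_twin_t_notch <- function(cfg) {
  if (!inherits(cfg, "filter_bank_config"))
    stop("`cfg` must be a filter_bank_config()", call. = FALSE)
  if (cfg$notch_hz >= cfg$fs / 2)
    stop("`notch_hz` must be below fs/2", call. = FALSE)
  w0 <- 2 * pi * cfg$notch_hz / cfg$fs
  bw <- w0 / cfg$notch_q
  beta <- tan(bw / 2)
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  new_digital_filter(b, a, cfg$fs,
                     sprintf("twin_t_notch_%gHz_Q%g", cfg$notch_hz, cfg$notch_q))
}

#' Evaluate a digital filter's frequency response
#'
#' Evaluates the rational transfer function on the unit circle,
#' `H(e^{i 2 pi f / fs})`, at the requested frequencies.
#'
#' @param filter a `digital_filter`.
#' @param freqs_hz numeric vector of frequencies, all below `fs / 2`.
#' @return Complex vector of gains, one per frequency.
#' @export
frequency_response <- function(filter, freqs_hz) {
  if (!inherits(filter, "digital_filter"))
    stop("`filter` must be a digital_filter", call. = FALSE)
  if (any(freqs_hz >= filter$fs / 2))
    stop("all frequencies must be below the Nyquist rate fs/2", call. = FALSE)
  if (any(freqs_hz < 0))
    stop("frequencies must be nonnegative", call. = FALSE)
  vapply(freqs_hz, function(f) {
    z1 <- exp(-1i * 2 * pi * f / filter$fs)  # z^{-1}
    num <- sum(filter$numerator * z1^(seq_along(filter$numerator) - 1))
    den <- sum(filter$denominator * z1^(seq_along(filter$denominator) - 1))
    num / den
  }, complex(1))
}

#' Apply a digital filter causally to a signal
#'
#' @param flt a `digital_filter`.
#' @param signal_in a [pcg_signal()] with matching sampling rate.
#' @return Filtered [pcg_signal()], same length as the input.
#' @export
apply_filter <- function(flt, signal_in) {
  if (!inherits(flt, "digital_filter"))
    stop("`flt` must be a digital_filter", call. = FALSE)
  stop_if_not_signal(signal_in)
  if (signal_in$fs != flt$fs)
    stop(sprintf("sampling rate mismatch: signal %g Hz vs filter %g Hz",
                 signal_in$fs, flt$fs), call. = FALSE)
  y <- as.numeric(signal::filter(flt$numerator, flt$denominator,
                                 signal_in$samples))
  pcg_signal(y, signal_in$fs)
}

#' Apply the full front end: low-pass then notch
#'
#' Causal cascade matching the hardware order (Butterworth low-pass first,
#' then the mains notch). An optional zero-phase mode runs each filter
#' forward and backward for offline analysis.
#'
#' @param signal_in a [pcg_signal()].
#' @param cfg a [filter_bank_config()] with `fs` matching the signal.
#' @param zero_phase filter forward-backward instead of causally
#'   (default FALSE, as the hardware is causal).
#' @return Filtered [pcg_signal()], same length as the input.
#' @export
apply_front_end <- function(signal_in, cfg, zero_phase = FALSE) {
  stop_if_not_signal(signal_in)
  if (!inherits(cfg, "filter_bank_config"))
    stop("`cfg` must be a filter_bank_config()", call. = FALSE)
  if (signal_in$fs != cfg$fs)
    stop(sprintf("sampling rate mismatch: signal %g Hz vs config %g Hz",
                 signal_in$fs, cfg$fs), call. = FALSE)
  lp <- design_butterworth_lowpass(cfg)
  nt <- design_twin_t_notch(cfg)
  run <- function(flt, x) {
    if (zero_phase) {
      y <- as.numeric(signal::filtfilt(flt$numerator, flt$denominator,
                                       x$samples))
      pcg_signal(y, x$fs)
    } else apply_filter(flt, x)
  }
  run(nt, run(lp, signal_in))
}
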