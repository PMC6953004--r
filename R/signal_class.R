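#' Construct a sampled signal
#'
#' The universal currency of the pipeline: a finite real-valued waveform
#' together with its sampling rate. Amplitudes are dimensionless and
#' nominally lie in \[-1, 1\] (WAV full scale), but any finite values are
#' accepted.
#'
#' @param samples numeric vector of finite amplitudes, length >= 1.
#' @param fs sampling rate in Hz (positive scalar).
#' @return An object of class `pcg_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' s <- pcg_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), fs = 100)
#' length(s$samples)
#' @export
pcg_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("`samples` must contain at least one value", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive finite number (Hz)", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "pcg_signal")
}

#' @export
print.pcg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<pcg_signal: %d samples @ %g Hz (%.3f s), peak %.4g, RMS %.4g>\n",
              length(x$samples), x$fs, dur,
              max(abs(x$samples)), signal_rms(x$samples)))
  invisible(x)
}

#' @export
length.pcg_signal <- function(x) length(x$samples)

# internal: accept a pcg_signal or bare numeric (with fs supplied separately)
as_pcg_signal <- function(x, fs = NULL) {
  if (inherits(x, "pcg_signal")) return(x)
  if (is.null(fs))
    stop("a bare numeric vector needs an explicit `fs`", call. = FALSE)
  pcg_signal(x, fs)
}

signal_rms <- function(x) sqrt(mean(x^2))

stop_if_not_signal <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "pcg_signal"))
    stop(sprintf("`%s` must be a pcg_signal (see pcg_signal())", arg),
         call. = FALSE)
  invisible(x)
}
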