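# Orthonormal Daubechies scaling filter with 10 vanishing moments
# (20 taps), standard table values. Validated at load: sum(h) = sqrt(2)
# and sum(h^2) = 1 within 1e-10 (see db10_filters()).
DB10_SCALING <- c(
  2.66700579005555542e-02, 1.88176800077691497e-01,
  5.27201188931725628e-01, 6.88459039453603538e-01,
  2.81172343660577473e-01, -2.49846424327315381e-01,
  -1.95946274377377050e-01, 1.27369340335793252e-01,
  9.30573646035723484e-02, -7.13941471663970817e-02,
  -2.94575368218758134e-02, 3.32126740593410019e-02,
  3.60655356695616970e-03, -1.07331754833305745e-02,
  1.39535174705290106e-03, 1.99240529518505613e-03,
  -6.85856694959711619e-04, -1.16466855129285449e-04,
  9.35886703200695919e-05, -1.32642028945212443e-05)

# supported orthogonal wavelets: name -> scaling (lowpass synthesis) filter
wavelet_filter_table <- function() list(
  db10 = DB10_SCALING,
  haar = c(1, 1) / sqrt(2),
  db2 = c(0.48296291314469025, 0.83651630373746899,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.71484657055254153,
          0.63088076792959036, -0.02798376941698385,
          -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728))

# returns the synthesis pair (g0 lowpass, g1 highpass QMF) for a named
# wavelet, checking orthonormality of the table entry
db10_filters <- function(wavelet_name = "db10") {
  tab <- wavelet_filter_table()
  if (!wavelet_name %in% names(tab))
    stop(sprintf("unknown wavelet '%s'; supported: %s", wavelet_name,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  g0 <- tab[[wavelet_name]]
  if (abs(sum(g0) - sqrt(2)) > 1e-10 || abs(sum(g0^2) - 1) > 1e-10)
    stop("internal error: wavelet filter table failed orthonormality check",
         call. = FALSE)
  L <- length(g0)
  g1 <- (-1)^(seq_len(L) - 1) * rev(g0)
  list(g0 = g0, g1 = g1, length = L)
}

# MATLAB-style full convolution
conv_full <- function(u, v) stats::convolve(u, rev(v), type = "open")

# half-point symmetric extension lookup: maps arbitrary 0-based positions
# onto 1-based indices of x via reflection with period 2n
sym_index <- function(pos, n) {
  q <- pos %% (2L * n)
  ifelse(q < n, q, 2L * n - 1L - q) + 1L
}

# one analysis step, symmetric half-point extension; returns coefficient
# vectors of length ceiling((n + L - 1) / 2)
dwt_step_sym <- function(x, g0, g1) {
  n <- length(x); L <- length(g0)
  m <- ceiling((n + L - 1) / 2)
  i2 <- 2L * (seq_len(m) - 1L) - (L - 1L)  # leftmost tap position per coeff
  a <- numeric(m); d <- numeric(m)
  for (k in seq_len(L)) {
    xi <- x[sym_index(i2 + (k - 1L), n)]
    a <- a + g0[k] * xi
    d <- d + g1[k] * xi
  }
  list(a = a, d = d)
}

# inverse of dwt_step_sym; n is the pre-analysis length
idwt_step_sym <- function(a, d, g0, g1, n) {
  m <- length(a); L <- length(g0)
  ua <- numeric(2L * m - 1L); ud <- numeric(2L * m - 1L)
  ua[seq(1L, 2L * m - 1L, by = 2L)] <- a
  ud[seq(1L, 2L * m - 1L, by = 2L)] <- d
  y <- conv_full(ua, g0) + conv_full(ud, g1)
  y[L:(L + n - 1L)]
}

# one analysis step with periodization (circular); requires even n >= L,
# coefficient length n / 2; exactly energy conserving
dwt_step_per <- function(x, g0, g1) {
  n <- length(x); L <- length(g0)
  if (n %% 2L != 0L)
    stop("periodic boundary mode needs an even length at every level ",
         "(got ", n, ")", call. = FALSE)
  if (n < L)
    stop("periodic boundary mode needs length >= filter length (", L, ")",
         call. = FALSE)
  m <- n %/% 2L
  base <- 2L * (seq_len(m) - 1L)
  a <- numeric(m); d <- numeric(m)
  for (k in seq_len(L)) {
    xi <- x[(base + (k - 1L)) %% n + 1L]
    a <- a + g0[k] * xi
    d <- d + g1[k] * xi
  }
  list(a = a, d = d)
}

idwt_step_per <- function(a, d, g0, g1, n) {
  m <- length(a); L <- length(g0)
  y <- numeric(n)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_len(L)) {
    pos <- (base + (k - 1L)) %% n + 1L
    y[pos] <- y[pos] + g0[k] * a + g1[k] * d
  }
  y
}

#' Multilevel discrete wavelet decomposition
#'
#' Dyadic analysis of a signal into one approximation band plus `level`
#' detail bands. Detail band 1 is the finest (unit) scale, covering
#' `fs/4`-`fs/2`; the approximation covers `0`-`fs/2^(level+1)`. With the
#' default symmetric (half-point) extension each level's coefficient
#' length is `ceiling((n + L - 1) / 2)` for filter length `L`; with
#' periodic extension it is `n / 2` and the transform is exactly
#' orthonormal (energy conserving).
#'
#' @param signal a [pcg_signal()] of length at least `2^level`.
#' @param wavelet_name orthogonal wavelet identifier (default `"db10"`,
#'   the Daubechies wavelet with 10 vanishing moments, 20-tap filters).
#' @param level decomposition depth (default 4).
#' @param boundary `"symmetric"` (default) or `"periodic"` extension.
#' @return A `wavelet_decomposition` with fields `approximation`,
#'   `details` (list, finest first), `wavelet_name`, `level`,
#'   `boundary_mode`, `original_length`, `level_lengths`, `fs`.
#' @seealso [pcg_reconstruct()], [pcg_denoise()], [band_edges()]
#' @export
pcg_decompose <- function(signal, wavelet_name = "db10", level = 4L,
                          boundary = c("symmetric", "periodic")) {
  stop_if_not_signal(signal)
  boundary <- match.arg(boundary)
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("`level` must be >= 1", call. = FALSE)
  n <- length(signal$samples)
  if (n < 2^level)
    stop(sprintf("signal too short for level %d: need at least %d samples, got %d",
                 level, 2^level, n), call. = FALSE)
  filt <- db10_filters(wavelet_name)
  step <- if (boundary == "symmetric") dwt_step_sym else dwt_step_per
  x <- signal$samples
  details <- vector("list", level)
  level_lengths <- integer(level)
  for (j in seq_len(level)) {
    level_lengths[j] <- length(x)
    s <- step(x, filt$g0, filt$g1)
    details[[j]] <- s$d
    x <- s$a
  }
  structure(list(wavelet_name = wavelet_name, level = level,
                 approximation = x, details = details,
                 boundary_mode = boundary, original_length = n,
                 level_lengths = level_lengths, fs = signal$fs),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition '%s' level %d, %s extension, n = %d @ %g Hz>\n",
              x$wavelet_name, x$level, x$boundary_mode, x$original_length, x$fs))
  be <- band_edges(x$fs, x$level)
  cat(sprintf("  approximation: %d coeffs (%g-%g Hz)\n",
              length(x$approximation), be[1, 1], be[1, 2]))
  for (j in seq_len(x$level))
    cat(sprintf("  detail level %d: %d coeffs (%g-%g Hz)\n", j,
                length(x$details[[j]]),
                be[x$level + 2 - j, 1], be[x$level + 2 - j, 2]))
  invisible(x)
}

#' Inverse multilevel wavelet transform
#'
#' Reconstructs the time-domain signal from a decomposition. With
#' untouched coefficients the round trip `pcg_decompose` then
#' `pcg_reconstruct` reproduces the input to better than 1e-8 absolute.
#'
#' @param decomp a `wavelet_decomposition` from [pcg_decompose()].
#' @return A [pcg_signal()] of exactly `original_length` samples.
#' @export
pcg_reconstruct <- function(decomp) {
  if (!inherits(decomp, "wavelet_decomposition"))
    stop("`decomp` must come from pcg_decompose()", call. = FALSE)
  if (length(decomp$details) != decomp$level)
    stop("inconsistent decomposition: number of detail bands != level",
         call. = FALSE)
  filt <- db10_filters(decomp$wavelet_name)
  istep <- if (decomp$boundary_mode == "symmetric") idwt_step_sym else idwt_step_per
  x <- decomp$approximation
  for (j in rev(seq_len(decomp$level))) {
    d <- decomp$details[[j]]
    if (length(d) != length(x))
      stop(sprintf(paste0("inconsistent coefficient lengths at level %d: ",
                          "approximation %d vs detail %d"),
                   j, length(x), length(d)), call. = FALSE)
    x <- istep(x, d, filt$g0, filt$g1, decomp$level_lengths[j])
  }
  pcg_signal(x, decomp$fs)
}

#' Nominal dyadic band edges of a level-`level` decomposition
#'
#' Returns the `level + 1` nominal frequency bands: the approximation
#' `(0, fs / 2^(level+1))`, then detail bands from coarsest up to the
#' finest `(fs/4, fs/2)`. At `fs = 2000` and `level = 4` these are the
#' five bands 0-62.5, 62.5-125, 125-250, 250-500 and 500-1000 Hz.
#'
#' @param fs sampling rate in Hz.
#' @param level decomposition depth (>= 1).
#' @return A numeric matrix with columns `low_hz`, `high_hz`, one row per
#'   band ordered from the approximation upward.
#' @export
band_edges <- function(fs, level) {
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("`level` must be >= 1", call. = FALSE)
  highs <- fs / 2^seq(level + 1, 1)   # fs/2^(level+1) ... fs/2
  lows <- c(0, highs[-length(highs)])
  matrix(c(lows, highs), ncol = 2,
         dimnames = list(NULL, c("low_hz", "high_hz")))
}
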