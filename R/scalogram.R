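#' Generalized Morse wavelet filter bank (frequency domain)
#'
#' Peak-normalized generalized Morse wavelets with symmetry parameter `gamma`
#' and time-bandwidth product `P2` (so beta = P2 / gamma). Evaluated on the
#' FFT frequency grid for an analytic transform: the filter for center
#' frequency `fc` is `2 (f/fc)^beta exp((beta/gamma) (1 - (f/fc)^gamma))`
#' for f > 0 and zero elsewhere.
#'
#' @param n FFT length.
#' @param fs Sampling rate in Hz.
#' @param freqs Center frequencies in Hz (one column per frequency).
#' @param gamma,P2 Morse family parameters.
#' @return An `n x length(freqs)` matrix of filter gains.
#' @keywords internal
morse_filter_bank <- function(n, fs, freqs, gamma = 3, P2 = 60) {
  beta <- P2 / gamma
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs     # negative frequencies
  bank <- matrix(0, n, length(freqs))
  pos <- f > 0
  for (j in seq_along(freqs)) {
    r <- f[pos] / freqs[j]
    bank[pos, j] <- 2 * exp(beta * log(r) + (beta / gamma) * (1 - r^gamma))
  }
  bank
}

#' Continuous wavelet transform scalogram of a 5-s segment
#'
#' Computes the magnitude of the analytic CWT with generalized Morse wavelets
#' over 61 log-spaced center frequencies spanning 0.3-12 Hz, yielding a
#' 500 x 61 time-by-scale image for a 5-s segment at 100 Hz. The segment is
#' reflect-padded to twice its length before the FFT; the cone of influence
#' is not masked (the classifier consumes the full image).
#'
#' @param seg Numeric vector of `fs * 5` samples (500 at the default rate).
#' @param fs Sampling rate in Hz.
#' @param n_scales Number of scales (columns).
#' @param freq_range Length-2 numeric, frequency span of the scales in Hz.
#' @param gamma,P2 Morse wavelet parameters (symmetry and time-bandwidth).
#' @param normalize If `TRUE`, min-max normalize the image to [0, 1] (the
#'   form consumed by the CNN); if `FALSE`, raw magnitudes (linear in the
#'   input amplitude).
#' @return An object of class `scalogram`: list with `mag` (500 x 61
#'   non-negative matrix, time by scale) and `freqs` (increasing, Hz).
#' @export
cwt_scalogram <- function(seg, fs = 100, n_scales = 61,
                          freq_range = c(0.3, 12), gamma = 3, P2 = 60,
                          normalize = FALSE) {
  seg <- as.numeric(seg)
  n <- length(seg)
  if (n != round(5 * fs))
    stop(sprintf("segment must contain %d samples (5 s at %g Hz)",
                 round(5 * fs), fs))
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]),
                   length.out = n_scales))
  pad <- floor(n / 2)
  xp <- c(seg[pad:1], seg, seg[n:(n - pad + 1)])
  np <- length(xp)
  bank <- morse_filter_bank(np, fs, freqs, gamma, P2)
  X <- stats::fft(xp)
  W <- stats::mvfft(bank * X, inverse = TRUE) / np
  mag <- Mod(W[(pad + 1):(pad + n), , drop = FALSE])
  if (normalize) {
    rng <- range(mag)
    mag <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1])
           else mag * 0
  }
  structure(list(mag = mag, freqs = freqs), class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("scalogram: %d x %d (time x scale), %.2f-%.2f Hz\n",
              nrow(x$mag), ncol(x$mag), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Ridge frequency of a scalogram
#'
#' For each time instant, the frequency of the scale with maximal magnitude;
#' the ridge frequency is the median over time. Tracks the heart rate (HR/60
#' Hz) for a clean constant-rate pulse train.
#'
#' @param scg A [cwt_scalogram()] result.
#' @return Ridge frequency in Hz, or `NA` for an all-zero scalogram.
#' @export
ridge_frequency <- function(scg) {
  stopifnot(inherits(scg, "scalogram"))
  if (all(scg$mag == 0)) return(NA_real_)
  idx <- max.col(scg$mag, ties.method = "first")
  stats::median(scg$freqs[idx])
}

#' Scalogram image stack for a set of segments
#'
#' Applies [cwt_scalogram()] to each segment column and stacks the
#' (normalized) images into a 3-D array ready for the CNN.
#'
#' @param segs A `ppg_segments` object, or a samples matrix (segments in
#'   columns).
#' @param fs Sampling rate in Hz (taken from the object when available).
#' @param normalize Per-image min-max normalization flag (default `TRUE`:
#'   the CNN input convention).
#' @param ... Further arguments to [cwt_scalogram()].
#' @return A `500 x 61 x n_segments` numeric array with attribute `freqs`.
#' @export
scalogram_stack <- function(segs, fs = 100, normalize = TRUE, ...) {
  m <- if (inherits(segs, "ppg_segments")) segs$samples else as.matrix(segs)
  if (inherits(segs, "ppg_segments")) fs <- segs$fs
  n_seg <- ncol(m)
  first <- cwt_scalogram(m[, 1], fs = fs, normalize = normalize, ...)
  out <- array(0, dim = c(nrow(first$mag), ncol(first$mag), n_seg))
  out[, , 1] <- first$mag
  if (n_seg > 1) {
    for (i in 2:n_seg)
      out[, , i] <- cwt_scalogram(m[, i], fs = fs, normalize = normalize,
                                  ...)$mag
  }
  attr(out, "freqs") <- first$freqs
  out
}

#' Write a scalogram to CSV (time rows, scale columns)
#' @param scg A [cwt_scalogram()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scalogram_csv <- function(scg, path) {
  stopifnot(inherits(scg, "scalogram"))
  m <- scg$mag
  colnames(m) <- sprintf("f_%.4fHz", scg$freqs)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
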