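#' Dominant spectral frequency of a segment
#'
#' Location of the largest peak of the power spectrum over (0, fs/2], after
#' mean removal, Hann windowing and 4x zero-padding (frequency resolution
#' 0.05 Hz for a 5-s segment at 100 Hz).
#'
#' @param x Numeric vector of segment samples, or a `ppg_segments` object
#'   (then a vector of frequencies, one per segment, is returned).
#' @param fs Sampling rate in Hz.
#' @return Dominant frequency in Hz, or `NA` for an all-zero (flat) segment.
#' @export
dominant_frequency <- function(x, fs = 100) {
  if (inherits(x, "ppg_segments"))
    return(apply(x$samples, 2, dominant_frequency, fs = x$fs))
  x <- as.numeric(x)
  n <- length(x)
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  nfft <- 4 * n
  spec <- Mod(stats::fft(c(x * w, numeric(nfft - n))))^2
  k <- seq(2, floor(nfft / 2) + 1)   # positive frequencies only
  kmax <- k[which.max(spec[k])]
  (kmax - 1) * fs / nfft
}

#' Spectral signal-quality assessment of 5-s segments
#'
#' A segment is of good quality iff its dominant spectral frequency lies in
#' the 0.6-3 Hz band (equivalent to 3-15 beats in 5 s); otherwise it is
#' assessed poor and excluded from CNN detection. Band endpoints are
#' inclusive. A flat segment with no spectral peak is poor.
#'
#' @param x Numeric vector of segment samples, or a `ppg_segments` object
#'   (then the object's `quality` field is filled and the object returned).
#' @param band Length-2 numeric, quality band in Hz.
#' @param fs Sampling rate in Hz.
#' @return `"good"` or `"poor"` (vector for multiple segments), or the
#'   updated `ppg_segments` object.
#' @export
assess_quality <- function(x, band = c(0.6, 3), fs = 100) {
  if (inherits(x, "ppg_segments")) {
    x$quality <- assess_quality_freq(dominant_frequency(x), band)
    return(x)
  }
  assess_quality_freq(dominant_frequency(x, fs), band)
}

assess_quality_freq <- function(f, band = c(0.6, 3)) {
  ifelse(!is.na(f) & f >= band[1] & f <= band[2], "good", "poor")
}
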