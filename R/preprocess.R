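#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth filter applied forward-backward (zero phase), so the
#' timing of pulses is not shifted relative to episode annotations. The
#' signal is reflect-padded before filtering to suppress edge transients.
#'
#' @param ppg A [ppg_signal()].
#' @param low_hz,high_hz Cut-off frequencies in Hz; the detector band is
#'   0.5-40 Hz, the reference detector uses 0.5-6 Hz.
#' @param order Butterworth order (per direction).
#' @return A filtered [ppg_signal()].
#' @export
bandpass <- function(ppg, low_hz = 0.5, high_hz = 40, order = 4) {
  stopifnot(inherits(ppg, "ppg_signal"))
  nyq <- ppg$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("cutoffs must satisfy 0 < low_hz < high_hz < fs/2")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  x <- ppg$samples
  n <- length(x)
  pad <- min(n - 1, 3 * ppg$fs)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  ppg_signal(y[(pad + 1):(pad + n)], ppg$fs, ppg$annotations)
}

#' Baseline-wander removal with a single-tap NLMS filter
#'
#' Normalized least-mean-squares adaptive filter with the reference input
#' fixed at 1. With a constant reference the filter reduces to a single
#' adaptive weight tracking the slowly varying signal mean; the output is the
#' input minus that weight. The weight is initialized to the first sample to
#' shorten the startup transient.
#'
#' @param ppg A [ppg_signal()].
#' @param step NLMS step size mu, 0 < mu < 2.
#' @param reg Regularization added to the reference power in the
#'   normalization.
#' @return A [ppg_signal()] with slow baseline removed.
#' @export
remove_baseline_nlms <- function(ppg, step = 0.02, reg = 1e-6) {
  stopifnot(inherits(ppg, "ppg_signal"))
  if (!(step > 0 && step < 2)) stop("step must lie in (0, 2)")
  d <- ppg$samples
  n <- length(d)
  a <- step / (1 + reg)
  ## w[k+1] = (1 - a) w[k] + a d[k], w[1] = d[1]; output e[k] = d[k] - w[k]
  if (n == 1) {
    w <- d[1]
  } else {
    w_next <- stats::filter(a * d[-n], filter = 1 - a,
                            method = "recursive", init = d[1])
    w <- c(d[1], as.numeric(w_next))
  }
  ppg_signal(d - w, ppg$fs, ppg$annotations)
}

#' Split a PPG signal into non-overlapping 5-s segments
#'
#' Produces `floor(duration / win_s)` windows; a trailing remainder shorter
#' than one window is discarded. Labels and quality flags are unassigned
#' until [label_segments()] and [assess_quality()] are applied.
#'
#' @param ppg A [ppg_signal()].
#' @param win_s Window length in seconds (default 5).
#' @return An object of class `ppg_segments`: a list with `samples`
#'   (matrix, `win_s * fs` rows, one column per segment), `fs`, `win_s`,
#'   `index` (0-based), `start_s`, `label` (NA until assigned), `quality`
#'   (`"unassessed"`), and the carried `annotations`.
#' @export
segment_ppg <- function(ppg, win_s = 5) {
  stopifnot(inherits(ppg, "ppg_signal"))
  if (win_s <= 0) stop("win_s must be positive")
  win_n <- round(win_s * ppg$fs)
  n_seg <- floor(length(ppg$samples) / win_n)
  samples <- if (n_seg > 0)
    matrix(ppg$samples[seq_len(n_seg * win_n)], nrow = win_n)
  else matrix(numeric(0), nrow = win_n, ncol = 0)
  structure(list(samples = samples, fs = ppg$fs, win_s = win_s,
                 index = seq_len(n_seg) - 1L,
                 start_s = (seq_len(n_seg) - 1L) * win_s,
                 label = rep(NA_character_, n_seg),
                 quality = rep("unassessed", n_seg),
                 annotations = ppg$annotations),
            class = "ppg_segments")
}

#' @export
print.ppg_segments <- function(x, ...) {
  cat(sprintf("%d segments of %g s at %g Hz\n", length(x$index), x$win_s, x$fs))
  if (!all(is.na(x$label)))
    print(table(x$label, useNA = "ifany"))
  invisible(x)
}

#' @export
length.ppg_segments <- function(x) length(x$index)

#' Standard preprocessing chain
#'
#' Bandpass (0.5-40 Hz, zero phase), NLMS baseline removal, then
#' segmentation into non-overlapping windows.
#'
#' @param ppg A [ppg_signal()].
#' @param config A configuration list, see [default_config()].
#' @return A `ppg_segments` object.
#' @export
preprocess_ppg <- function(ppg, config = default_config()) {
  p <- config$preprocess
  ppg <- bandpass(ppg, p$band_low_hz, p$band_high_hz, p$filter_order)
  ppg <- remove_baseline_nlms(ppg, p$nlms_step, p$nlms_reg)
  segment_ppg(ppg, p$win_s)
}
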