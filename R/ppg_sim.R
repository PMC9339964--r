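#' PPG pulse waveform model
#'
#' Parameterizes a single photoplethysmographic pulse on normalized beat time
#' u in [0, 1) as a linear combination of a log-normal waveform (the fast
#' systolic wave) and two Gaussian waveforms (systolic shoulder and dicrotic
#' wave). The pulse is time-scaled with the RR interval, so it always fits
#' within its beat, and is peak-normalized to 1 when rendered.
#'
#' Defaults produce a physiological shape: upstroke to the systolic peak at
#' about 20% of the beat, a dicrotic wave near 60-65% of the beat with
#' amplitude about a quarter of the primary wave, and near-zero amplitude at
#' the beat boundaries so that concatenated pulses join continuously.
#'
#' @param lognormal Named numeric: `amp`, `meanlog` (log of normalized peak
#'   location), `sdlog` (shape).
#' @param gaussian1 Named numeric: `amp`, `center`, `width` (normalized time).
#' @param gaussian2 Named numeric: `amp`, `center`, `width`; the dicrotic
#'   component.
#' @return An object of class `pulse_model`.
#' @export
pulse_model <- function(lognormal = c(amp = 1, meanlog = log(0.25), sdlog = 0.35),
                        gaussian1 = c(amp = 0.45, center = 0.45, width = 0.12),
                        gaussian2 = c(amp = 0.25, center = 0.62, width = 0.09)) {
  m <- list(lognormal = lognormal, gaussian1 = gaussian1, gaussian2 = gaussian2)
  if (m$lognormal["sdlog"] <= 0 || m$gaussian1["width"] <= 0 ||
      m$gaussian2["width"] <= 0)
    stop("widths/shape parameters must be positive")
  if (all(c(m$lognormal["amp"], m$gaussian1["amp"], m$gaussian2["amp"]) == 0))
    stop("at least one pulse component must have non-zero amplitude")
  class(m) <- "pulse_model"
  m
}

pulse_shape <- function(model, u) {
  ln <- model$lognormal
  g1 <- model$gaussian1
  g2 <- model$gaussian2
  ## log-normal density shape, peak-normalized so `amp` is its peak height
  lw <- ifelse(u > 0, stats::dlnorm(u, ln[["meanlog"]], ln[["sdlog"]]), 0)
  pk <- stats::dlnorm(exp(ln[["meanlog"]] - ln[["sdlog"]]^2),
                      ln[["meanlog"]], ln[["sdlog"]])
  y <- ln[["amp"]] * lw / pk +
    g1[["amp"]] * exp(-(u - g1[["center"]])^2 / (2 * g1[["width"]]^2)) +
    g2[["amp"]] * exp(-(u - g2[["center"]])^2 / (2 * g2[["width"]]^2))
  y
}

#' Render one PPG pulse
#'
#' @param model A [pulse_model()].
#' @param rr Beat duration in seconds (> 0); the pulse support equals the RR
#'   interval.
#' @param fs Sampling rate in Hz.
#' @param n_samples Optional explicit sample count (used internally for
#'   drift-free placement); default `round(rr * fs)`.
#' @return Numeric vector of `round(rr * fs)` samples with maximum 1.
#' @export
render_pulse <- function(model, rr, fs = 100, n_samples = NULL) {
  stopifnot(inherits(model, "pulse_model"))
  if (rr <= 0) stop("rr must be positive")
  n <- if (is.null(n_samples)) round(rr * fs) else as.integer(n_samples)
  if (n < 1) stop("pulse would contain no samples at this rr and fs")
  u <- (seq_len(n) - 1) / n
  y <- pulse_shape(model, u)
  m <- max(y)
  if (m <= 0) stop("degenerate pulse model: rendered pulse is not positive")
  y / m
}

#' Uniformly sampled PPG signal
#'
#' @param samples Numeric vector of signal samples (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param annotations Data frame with columns `start_s`, `end_s`, `rhythm`
#'   describing arrhythmia episodes (half-open intervals in seconds from the
#'   start of the record), or an empty data frame.
#' @return An object of class `ppg_signal`.
#' @export
ppg_signal <- function(samples, fs = 100,
                       annotations = data.frame(start_s = numeric(0),
                                                end_s = numeric(0),
                                                rhythm = character(0),
                                                stringsAsFactors = FALSE)) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("PPG samples must be finite")
  if (fs <= 0) stop("fs must be positive")
  structure(list(samples = samples, fs = fs, annotations = annotations),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("PPG signal: %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (nrow(x$annotations) > 0) {
    for (i in seq_len(nrow(x$annotations)))
      cat(sprintf("  %s episode: %.2f-%.2f s\n", x$annotations$rhythm[i],
                  x$annotations$start_s[i], x$annotations$end_s[i]))
  }
  invisible(x)
}

#' @export
length.ppg_signal <- function(x) length(x$samples)

#' Duration of a PPG signal in seconds
#' @param ppg A [ppg_signal()].
#' @return Numeric scalar, `length(samples) / fs`.
#' @export
ppg_duration <- function(ppg) length(ppg$samples) / ppg$fs

#' Simulate a PPG signal from an RR series
#'
#' Places one rendered pulse per beat at the cumulative RR onsets so that a
#' connected signal is formed. Sample counts per beat are taken as
#' differences of the rounded cumulative beat times, so placement does not
#' drift. Episode annotations are carried over from the RR series in seconds.
#'
#' @param rr An [rr_series].
#' @param model A [pulse_model()].
#' @param fs Sampling rate in Hz (the detectors assume 100 Hz).
#' @param tachy_attenuation Amplitude factor applied to pulses inside a
#'   tachycardia episode (1 = none). Emulates the reduced pulsations seen in
#'   hemodynamically compromised ventricular tachycardia; off by default.
#' @return A [ppg_signal()] with annotations.
#' @export
simulate_ppg <- function(rr, model = pulse_model(), fs = 100,
                         tachy_attenuation = 1) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$intervals) == 0) stop("empty RR series")
  tcum <- c(0, cumsum(rr$intervals))
  bounds <- round(tcum * fs)
  total_n <- bounds[length(bounds)]
  samples <- numeric(total_n)
  for (i in seq_along(rr$intervals)) {
    n_i <- bounds[i + 1] - bounds[i]
    if (n_i < 1) next
    p <- render_pulse(model, rr$intervals[i], fs, n_samples = n_i)
    if (rr$labels[i] == "tachy" && tachy_attenuation != 1)
      p <- p * tachy_attenuation
    idx <- (bounds[i] + 1):(bounds[i + 1])
    samples[idx] <- samples[idx] + p
  }
  ppg_signal(samples, fs, annotations = rr_episode_annotation(rr))
}

#' Add stationary noise at a prescribed SNR
#'
#' Adds stationary colored noise (white Gaussian noise shaped by a first-order
#' low-pass with 6 dB/octave roll-off above `noise_lp_hz`) scaled so that the
#' signal-to-noise power ratio over the full record equals `snr_db` exactly.
#'
#' @param ppg A [ppg_signal()].
#' @param snr_db Target SNR in dB (`10*log10(P_signal / P_noise)`), or the
#'   string `"clean"` to return the input unchanged.
#' @param seed Optional integer seed for the noise realization.
#' @param noise_lp_hz Corner frequency of the shaping low-pass in Hz.
#' @return A [ppg_signal()] with the same length, rate and annotations.
#' @export
add_noise <- function(ppg, snr_db, seed = NULL, noise_lp_hz = 4) {
  stopifnot(inherits(ppg, "ppg_signal"))
  if (identical(snr_db, "clean")) return(ppg)
  snr_db <- as.numeric(snr_db)
  if (!is.finite(snr_db)) stop("snr_db must be finite or \"clean\"")
  if (!is.null(seed)) set.seed(seed)
  n <- length(ppg$samples)
  w <- stats::rnorm(n)
  bf <- signal::butter(1, noise_lp_hz / (ppg$fs / 2), type = "low")
  noise <- as.numeric(signal::filter(bf, w))
  p_sig <- mean(ppg$samples^2)
  p_noise <- mean(noise^2)
  noise <- noise * sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
  ppg_signal(ppg$samples + noise, ppg$fs, ppg$annotations)
}

#' Measured SNR between a clean and a noisy signal
#' @param clean,noisy [ppg_signal()] objects of equal length.
#' @return SNR in dB of the power of `clean` over the power of the residual.
#' @export
measure_snr <- function(clean, noisy) {
  stopifnot(length(clean$samples) == length(noisy$samples))
  10 * log10(mean(clean$samples^2) /
             mean((noisy$samples - clean$samples)^2))
}
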