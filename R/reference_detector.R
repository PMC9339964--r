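#' Pulse train with per-pulse quality
#'
#' @param times Pulse occurrence times in seconds, strictly increasing.
#' @param amplitudes Peak amplitudes of the detected pulses.
#' @param correlation Per-pulse maximum template correlation (NA before
#'   quality assessment).
#' @param accepted Logical per-pulse high-quality flag (NA before
#'   assessment).
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(times, amplitudes = rep(NA_real_, length(times)),
                        correlation = rep(NA_real_, length(times)),
                        accepted = rep(NA, length(times))) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("pulse times must be strictly increasing")
  structure(list(times = times, amplitudes = amplitudes,
                 correlation = correlation, accepted = accepted),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("pulse train: %d pulses", length(x$times)))
  if (!all(is.na(x$accepted)))
    cat(sprintf(", %d high-quality", sum(x$accepted, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
length.pulse_train <- function(x) length(x$times)

#' Threshold-based pulse detection
#'
#' Detects pulses on a 0.5-6 Hz bandpassed copy of the signal as local
#' maxima exceeding an adaptive amplitude threshold (a fraction of an
#' exponentially averaged recent peak amplitude), with a refractory period
#' preventing double detections.
#'
#' @param ppg A [ppg_signal()]; the function applies its own 0.5-6 Hz band.
#' @param config Configuration list; the `reference` block holds the band,
#'   refractory period (0.3 s), threshold fraction and averaging memory.
#' @return A [pulse_train()] (empty for a flat signal), with per-pulse
#'   quality unassessed.
#' @export
detect_pulses <- function(ppg, config = default_config()) {
  rc <- config$reference
  f <- bandpass(ppg, rc$band_low_hz, rc$band_high_hz,
                config$preprocess$filter_order)
  x <- f$samples
  n <- length(x)
  if (n < 3) return(pulse_train(numeric(0)))
  ## candidate local maxima with positive amplitude
  d <- diff(x)
  cand <- which(d[-(n - 1)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] > 0]
  if (length(cand) == 0) return(pulse_train(numeric(0)))

  refr <- rc$refractory_s * ppg$fs
  amp <- stats::quantile(x[cand], 0.9, names = FALSE)
  times <- integer(0)
  amps <- numeric(0)
  last <- -Inf
  for (i in cand) {
    if (i - last < refr) next
    if (x[i] > rc$amp_factor * amp) {
      times <- c(times, i)
      amps <- c(amps, x[i])
      last <- i
      amp <- rc$amp_memory * amp + (1 - rc$amp_memory) * x[i]
    }
  }
  pulse_train((times - 1) / ppg$fs, amplitudes = amps)
}

resample_to <- function(x, n_out) {
  if (length(x) < 2) return(rep(x[1], n_out))
  stats::approx(seq_along(x), x, n = n_out)$y
}

max_lag_correlation <- function(a, b, max_lag) {
  n <- length(a)
  best <- -1
  for (lag in -max_lag:max_lag) {
    ia <- max(1, 1 + lag):min(n, n + lag)
    ib <- ia - lag
    if (stats::sd(a[ia]) == 0 || stats::sd(b[ib]) == 0) next
    r <- stats::cor(a[ia], b[ib])
    if (r > best) best <- r
  }
  best
}

#' Template-correlation pulse quality
#'
#' Each pulse waveform (a window around the peak, resampled to the template
#' length) is correlated with a running-average template of recent accepted
#' pulses, maximizing the sample correlation coefficient over small lags. A
#' pulse is accepted iff the maximum coefficient strictly exceeds the
#' threshold `eta_c` = 0.6; the template is updated from accepted pulses
#' only. Until a template exists (the first pulse), pulses are provisionally
#' accepted.
#'
#' @param train A [pulse_train()] from [detect_pulses()].
#' @param ppg The same [ppg_signal()] the train was detected on.
#' @param config Configuration; `reference$template_len` (samples),
#'   `reference$template_n` (pulses averaged), `reference$max_lag`,
#'   `reference$eta_c`.
#' @return The [pulse_train()] with `correlation` and `accepted` filled.
#' @export
assess_pulse_quality <- function(train, ppg, config = default_config()) {
  stopifnot(inherits(train, "pulse_train"))
  if (length(train$times) == 0) return(train)
  rc <- config$reference
  f <- bandpass(ppg, rc$band_low_hz, rc$band_high_hz,
                config$preprocess$filter_order)
  x <- f$samples
  fs <- ppg$fs
  n_p <- length(train$times)
  s_idx <- round(train$times * fs) + 1

  ## full-beat window per pulse: from half the preceding inter-pulse
  ## interval to half the following one (covers upstroke, dicrotic wave and
  ## the surrounding baseline, which is what separates pulses from smooth
  ## artifacts)
  ipi <- diff(train$times)
  shapes <- matrix(0, rc$template_len, n_p)
  clipped <- logical(n_p)
  for (i in seq_len(n_p)) {
    wb <- if (i > 1) ipi[i - 1] else if (n_p > 1) ipi[i] else 0.8
    wa <- if (i < n_p) ipi[i] else wb
    wb <- min(max(wb, 0.24), 2.4); wa <- min(max(wa, 0.24), 2.4)
    lo <- s_idx[i] - round(0.5 * wb * fs)
    hi <- s_idx[i] + round(0.5 * wa * fs)
    clipped[i] <- lo < 1 || hi > length(x)
    lo <- max(1, lo); hi <- min(length(x), hi)
    shapes[, i] <- resample_to(x[lo:hi], rc$template_len)
  }

  corr <- numeric(n_p)
  accepted <- logical(n_p)
  kept <- matrix(0, rc$template_len, 0)
  for (i in seq_len(n_p)) {
    if (ncol(kept) == 0) {
      corr[i] <- 1
      accepted[i] <- TRUE
    } else {
      template <- rowMeans(kept)
      corr[i] <- max_lag_correlation(shapes[, i], template, rc$max_lag)
      accepted[i] <- corr[i] > rc$eta_c
    }
    if (accepted[i] && !clipped[i]) {
      # record-edge pulses with truncated windows never enter the template
      kept <- cbind(kept, shapes[, i])
      if (ncol(kept) > rc$template_n)
        kept <- kept[, (ncol(kept) - rc$template_n + 1):ncol(kept),
                     drop = FALSE]
    }
  }
  train$correlation <- corr
  train$accepted <- accepted
  train
}

#' Rate/duration episode detection on a pulse train
#'
#' Scans the instantaneous rate (60 / inter-pulse interval) of consecutive
#' high-quality beats: a bradycardia episode is a maximal run of at least
#' 3 beats with rate strictly below 40 bpm, a tachycardia episode a maximal
#' run of at least 3 beats with rate strictly above 120 bpm. An interval
#' qualifies only if both bounding pulses are accepted, so runs are broken
#' by rejected pulses and no episode contains one.
#'
#' @param train A quality-assessed [pulse_train()].
#' @param config Configuration; `reference$brady_bpm` (40),
#'   `reference$tachy_bpm` (120), `reference$min_beats` (3).
#' @return A data frame of episodes: `rhythm`, `start_s`, `end_s`,
#'   `n_beats`.
#' @export
detect_episodes <- function(train, config = default_config()) {
  stopifnot(inherits(train, "pulse_train"))
  rc <- config$reference
  empty <- data.frame(rhythm = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_beats = integer(0),
                      stringsAsFactors = FALSE)
  n_p <- length(train$times)
  if (n_p < rc$min_beats + 1) return(empty)
  acc <- train$accepted
  if (all(is.na(acc))) acc <- rep(TRUE, n_p)
  ipi <- diff(train$times)
  rate <- 60 / ipi
  valid <- acc[-n_p] & acc[-1]
  out <- empty
  for (rhythm in c("brady", "tachy")) {
    qual <- valid & if (rhythm == "brady") rate < rc$brady_bpm
                    else rate > rc$tachy_bpm
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values & r$lengths >= rc$min_beats)) {
      i0 <- starts[j]; i1 <- ends[j]
      out <- rbind(out, data.frame(rhythm = rhythm,
                                   start_s = train$times[i0],
                                   end_s = train$times[i1 + 1],
                                   n_beats = i1 - i0 + 1L,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start_s), , drop = FALSE]
}

#' Map detected episodes to per-segment labels
#'
#' Applies the same coverage rules used for ground-truth labelling (an
#' episode must cover at least 50% of a 5-s segment for bradycardia, 25% for
#' tachycardia), so that detector output and annotation are compared
#' symmetrically. Overlaps are computed in continuous time.
#'
#' @param episodes Data frame with `rhythm`, `start_s`, `end_s` (from
#'   [detect_episodes()] or an annotation file).
#' @param n_segments Number of 5-s segments of the record.
#' @param win_s Segment length in seconds.
#' @param config Configuration; `labeling` holds the overlap fractions.
#' @return Character vector of length `n_segments` with values `"brady"`,
#'   `"tachy"`, `"other"`.
#' @export
episodes_to_segments <- function(episodes, n_segments, win_s = 5,
                                 config = default_config()) {
  overlap_label(episodes, n_segments, win_s,
                config$labeling$brady_overlap, config$labeling$tachy_overlap,
                on_conflict = "largest")
}

#' Run the full pulse-based reference detector
#'
#' Pulse detection on the 0.5-6 Hz band, template-correlation quality,
#' rate/duration episode rules, and mapping to 5-s segment labels.
#'
#' @param ppg A [ppg_signal()].
#' @param n_segments Number of segments to label; defaults to
#'   `floor(duration / win_s)`.
#' @param config Configuration list.
#' @return List with `labels` (per segment), `episodes`, `train`.
#' @export
reference_detect <- function(ppg, n_segments = NULL,
                             config = default_config()) {
  win_s <- config$preprocess$win_s
  if (is.null(n_segments))
    n_segments <- floor(ppg_duration(ppg) / win_s)
  train <- detect_pulses(ppg, config)
  train <- assess_pulse_quality(train, ppg, config)
  episodes <- detect_episodes(train, config)
  labels <- episodes_to_segments(episodes, n_segments, win_s, config)
  list(labels = labels, episodes = episodes, train = train)
}
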