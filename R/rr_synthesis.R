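#' RR-interval series with rhythm labels
#'
#' Container for an ordered series of beat-to-beat (RR) intervals, a
#' per-interval rhythm label and, optionally, the beat range of a single
#' embedded arrhythmia episode.
#'
#' @param intervals Numeric vector of RR intervals in seconds; each must lie
#'   in (0, 10).
#' @param labels Character vector, same length as `intervals`, with values in
#'   `"sinus"`, `"brady"`, `"tachy"`.
#' @param episode_bounds Integer vector `c(start, end)` giving the 1-based
#'   first and last interval of the arrhythmia episode, or `NULL` when the
#'   series is pure sinus rhythm.
#'
#' @details Invariants enforced: all intervals positive and shorter than 10 s;
#'   exactly the intervals inside `episode_bounds` carry the arrhythmia label;
#'   every sinus-labelled interval corresponds to an instantaneous heart rate
#'   above 60 bpm.
#'
#' @return An object of class `rr_series` with fields `intervals`, `labels`
#'   and `episode_bounds`.
#' @export
rr_series <- function(intervals, labels, episode_bounds = NULL) {
  intervals <- as.numeric(intervals)
  labels <- as.character(labels)
  if (length(intervals) < 1L)
    stop("an rr_series needs at least one interval")
  if (length(labels) != length(intervals))
    stop("labels length must equal intervals length")
  if (!all(labels %in% c("sinus", "brady", "tachy")))
    stop("labels must be 'sinus', 'brady' or 'tachy'")
  if (any(!is.finite(intervals)) || any(intervals <= 0) || any(intervals >= 10))
    stop("all RR intervals must be finite and lie in (0, 10) s")
  if (!is.null(episode_bounds)) {
    episode_bounds <- as.integer(episode_bounds)
    if (length(episode_bounds) != 2L || episode_bounds[1] < 1L ||
        episode_bounds[2] > length(intervals) ||
        episode_bounds[1] > episode_bounds[2])
      stop("episode_bounds must be a valid (start, end) beat range")
    inside <- seq(episode_bounds[1], episode_bounds[2])
    if (length(unique(labels[inside])) != 1L || labels[inside][1] == "sinus")
      stop("intervals inside episode_bounds must all carry one arrhythmia label")
    if (any(labels[-inside] != "sinus"))
      stop("intervals outside episode_bounds must be labelled sinus")
  } else if (any(labels != "sinus")) {
    stop("arrhythmia labels require episode_bounds")
  }
  hr <- 60 / intervals
  if (any(labels == "sinus" & hr <= 60))
    stop("sinus intervals must have instantaneous heart rate above 60 bpm")
  structure(list(intervals = intervals, labels = labels,
                 episode_bounds = episode_bounds),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("RR series: %d beats, %.1f s total\n", n, sum(x$intervals)))
  if (!is.null(x$episode_bounds)) {
    eb <- x$episode_bounds
    rhythm <- x$labels[eb[1]]
    cat(sprintf("  %s episode: beats %d-%d (%d beats, median HR %.1f bpm)\n",
                rhythm, eb[1], eb[2], eb[2] - eb[1] + 1L,
                stats::median(60 / x$intervals[eb[1]:eb[2]])))
  } else {
    cat("  sinus rhythm throughout\n")
  }
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Episode time span of an RR series
#'
#' Converts the beat-index episode bounds of an [rr_series] to a time
#' interval in seconds from the start of the record: the episode spans from
#' the onset of its first beat to the end of its last RR interval.
#'
#' @param rr An [rr_series].
#' @return A data frame with columns `start_s`, `end_s`, `rhythm` (zero rows
#'   for a pure sinus series).
#' @export
rr_episode_annotation <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (is.null(rr$episode_bounds))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      rhythm = character(0), stringsAsFactors = FALSE))
  eb <- rr$episode_bounds
  tcum <- c(0, cumsum(rr$intervals))
  data.frame(start_s = tcum[eb[1]], end_s = tcum[eb[2] + 1L],
             rhythm = rr$labels[eb[1]], stringsAsFactors = FALSE)
}

## Truncated-Gaussian heart-rate draw: redraws out-of-band values so the
## marginal is the Gaussian conditioned on the band (no clumping at bounds).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) x[bad] <- pmin(pmax(x[bad], lower), upper)
  x
}

#' Generate a sinus-rhythm RR series
#'
#' Draws instantaneous heart rates from a Gaussian truncated below at 61 bpm,
#' optionally adds a slow sinusoidal respiratory-like modulation, and converts
#' to RR intervals (`rr = 60 / hr`). This is a synthetic stand-in for RR
#' subseries taken from normal-sinus-rhythm recordings; its hard constraint is
#' that every sinus beat is above 60 bpm.
#'
#' @param n_beats Number of beats (>= 1).
#' @param mean_hr Mean heart rate in bpm; must exceed 60.
#' @param hr_sd Between-beat heart-rate standard deviation in bpm.
#' @param seed Optional integer seed for reproducibility.
#' @param resp_amp Amplitude (bpm) of the respiratory modulation; 0 disables.
#' @param resp_freq Respiratory modulation frequency in Hz.
#' @return An [rr_series] with all intervals labelled `"sinus"`.
#' @export
generate_sinus_rr <- function(n_beats, mean_hr = 75, hr_sd = 3, seed = NULL,
                              resp_amp = 2, resp_freq = 0.25) {
  if (n_beats < 1) stop("n_beats must be at least 1")
  if (mean_hr <= 60)
    stop("mean_hr must exceed 60 bpm for sinus rhythm")
  if (!is.null(seed)) set.seed(seed)
  hr <- rtrunc_norm(n_beats, mean_hr, hr_sd, lower = 61)
  if (resp_amp > 0 && n_beats > 1) {
    ## modulate on the approximate beat time grid
    t_approx <- cumsum(rep(60 / mean_hr, n_beats))
    hr <- hr + resp_amp * sin(2 * pi * resp_freq * t_approx)
    hr <- pmax(hr, 61)
  }
  rr_series(60 / hr, rep("sinus", n_beats))
}

## Piecewise log-uniform episode-length draw reproducing a stated
## (min, median, max): half the mass log-uniform on [min, median],
## half on [median, max].
draw_episode_length <- function(lo, med, hi) {
  u <- stats::runif(1)
  if (u < 0.5) {
    round(exp(stats::runif(1, log(lo), log(med))))
  } else {
    round(exp(stats::runif(1, log(med), log(hi))))
  }
}

generate_arrhythmia_series <- function(rhythm, seed = NULL,
                                       episode_beats = "random",
                                       episode_hr = "random",
                                       episode_hr_sd = 1,
                                       mean_hr = 75, hr_sd = 3) {
  spec <- switch(rhythm,
    brady = list(len = c(8, 23, 51), hr_med = 36, hr_band = c(25, 40)),
    tachy = list(len = c(4, 14, 528), hr_med = 164, hr_band = c(120, 250)))
  if (!is.null(seed)) set.seed(seed)

  if (identical(episode_beats, "random")) {
    n_ep <- draw_episode_length(spec$len[1], spec$len[2], spec$len[3])
  } else {
    n_ep <- as.integer(episode_beats)
    if (n_ep < spec$len[1] || n_ep > spec$len[3])
      stop(sprintf("episode_beats must lie in [%d, %d] for %s",
                   spec$len[1], spec$len[3], rhythm))
  }
  if (identical(episode_hr, "random")) {
    hr_ep <- rtrunc_norm(1, spec$hr_med, 4, spec$hr_band[1], spec$hr_band[2])
  } else {
    hr_ep <- as.numeric(episode_hr)
    if (rhythm == "tachy" && hr_ep < 120)
      stop("tachycardia requires episode_hr of at least 120 bpm")
    if (rhythm == "brady" && (hr_ep < 25 || hr_ep > 40))
      stop("bradycardia requires episode_hr in [25, 40] bpm")
    if (hr_ep > spec$hr_band[2])
      stop(sprintf("episode_hr above the physiological ceiling (%g bpm)",
                   spec$hr_band[2]))
  }

  n_before <- sample(50:100, 1)
  n_after <- sample(1:100, 1)
  before <- generate_sinus_rr(n_before, mean_hr, hr_sd, seed = NULL)
  after <- generate_sinus_rr(n_after, mean_hr, hr_sd, seed = NULL)
  hr_beats <- rtrunc_norm(n_ep, hr_ep, episode_hr_sd,
                          spec$hr_band[1], spec$hr_band[2])
  episode <- 60 / hr_beats

  intervals <- c(before$intervals, episode, after$intervals)
  labels <- c(rep("sinus", n_before), rep(rhythm, n_ep),
              rep("sinus", n_after))
  rr_series(intervals, labels,
            episode_bounds = c(n_before + 1L, n_before + n_ep))
}

#' Generate an RR series with one bradycardia episode
#'
#' Concatenates sinus | bradycardia | sinus RR subseries: 50-100 sinus beats
#' before the episode and 1-100 after (counts drawn uniformly), with the
#' episode length and heart rate either fixed or drawn so that their sampling
#' distributions reproduce the training-set statistics (length min/median/max
#' 8/23/51 beats, median heart rate 36 bpm).
#'
#' @param seed Optional integer seed.
#' @param episode_beats Episode length in beats (8-51), or `"random"`.
#' @param episode_hr Episode heart rate in bpm (25-40), or `"random"`.
#' @param episode_hr_sd Within-episode beat-to-beat heart-rate SD in bpm.
#'   The within-episode variability of real episodes is not prescribed;
#'   it is exposed here as a parameter.
#' @param mean_hr,hr_sd Sinus-rhythm parameters passed to
#'   [generate_sinus_rr()].
#' @return An [rr_series] with `episode_bounds` marking the episode.
#' @export
generate_bradycardia_series <- function(seed = NULL, episode_beats = "random",
                                        episode_hr = "random",
                                        episode_hr_sd = 1,
                                        mean_hr = 75, hr_sd = 3) {
  generate_arrhythmia_series("brady", seed, episode_beats, episode_hr,
                             episode_hr_sd, mean_hr, hr_sd)
}

#' Generate an RR series with one ventricular-tachycardia episode
#'
#' As [generate_bradycardia_series()], but the embedded episode is
#' tachycardic: every episode beat is at least 120 bpm, and random draws
#' reproduce the training-set statistics (length min/median/max 4/14/528
#' beats, median heart rate 164 bpm).
#'
#' @inheritParams generate_bradycardia_series
#' @param episode_beats Episode length in beats (4-528), or `"random"`.
#' @param episode_hr Episode heart rate in bpm (>= 120), or `"random"`.
#' @return An [rr_series] with `episode_bounds` marking the episode.
#' @export
generate_tachycardia_series <- function(seed = NULL, episode_beats = "random",
                                        episode_hr = "random",
                                        episode_hr_sd = 1,
                                        mean_hr = 75, hr_sd = 3) {
  generate_arrhythmia_series("tachy", seed, episode_beats, episode_hr,
                             episode_hr_sd, mean_hr, hr_sd)
}

#' Write / read an RR series as CSV
#'
#' The CSV has two columns, `interval_s` and `label`; the episode bounds are
#' stored in a JSON sidecar at `<path>.json`.
#'
#' @param rr An [rr_series].
#' @param path CSV file path.
#' @return `write_rr_csv` returns `path` invisibly; `read_rr_csv` returns the
#'   reconstructed [rr_series].
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  utils::write.csv(data.frame(interval_s = rr$intervals, label = rr$labels),
                   path, row.names = FALSE, quote = FALSE)
  side <- list(episode_bounds = rr$episode_bounds)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("interval_s", "label") %in% names(df)))
    stop("RR CSV must have columns interval_s and label")
  eb <- NULL
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$episode_bounds) && length(side$episode_bounds) == 2)
      eb <- as.integer(side$episode_bounds)
  }
  rr_series(df$interval_s, df$label, episode_bounds = eb)
}
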