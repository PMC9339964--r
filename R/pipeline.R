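#' Simulate one annotated PPG record
#'
#' Convenience wrapper: generates an RR series with one embedded episode,
#' renders the PPG at 100 Hz and optionally adds stationary noise.
#'
#' @param rhythm `"brady"` or `"tachy"`.
#' @param seed Integer seed (drives both the RR series and the noise).
#' @param snr_db Noise level in dB, or `"clean"`.
#' @param config Configuration list.
#' @param ... Passed to the RR generator (e.g. `episode_beats`,
#'   `episode_hr`).
#' @return An annotated [ppg_signal()].
#' @export
simulate_record <- function(rhythm = c("brady", "tachy"), seed = 1,
                            snr_db = "clean", config = default_config(),
                            ...) {
  rhythm <- match.arg(rhythm)
  rr <- if (rhythm == "brady") generate_bradycardia_series(seed = seed, ...)
        else generate_tachycardia_series(seed = seed, ...)
  ppg <- simulate_ppg(rr, fs = config$fs)
  add_noise(ppg, snr_db, seed = seed + 1L, noise_lp_hz = config$noise$lp_hz)
}

#' Build a labelled scalogram dataset for one branch
#'
#' Simulates `n_series` annotated records, runs the standard preprocessing
#' (bandpass, baseline removal, 5-s segmentation), assigns ground-truth
#' segment labels from the episode annotations and computes normalized
#' scalograms. All segments enter the dataset (signal-quality exclusion
#' belongs to the detection pipeline, not to training data); negatives can
#' be subsampled to bound the dataset size.
#'
#' @param branch `"brady"` or `"tachy"`; the positive class.
#' @param n_series Number of simulated records of the branch's rhythm.
#' @param seed Integer seed; per-record seeds are derived from it.
#' @param snr_db Training-signal SNR in dB, or `"clean"`.
#' @param max_neg_per_pos Cap on retained negative segments per positive
#'   (`Inf` keeps all and preserves natural prevalence).
#' @param n_series_other Number of records of the *other* arrhythmia to
#'   include; their segments enter as negatives, so the branch learns to
#'   reject the opposite rhythm as well as sinus rhythm (the corpus a
#'   deployed detector faces contains both).
#' @param config Configuration list.
#' @param ... Passed to the RR generator.
#' @return List with `x` (scalogram array `500 x 61 x n`), `y` (1 =
#'   positive), `n_pos`, `n_neg`, `n_segments_total`.
#' @export
make_branch_dataset <- function(branch = c("brady", "tachy"), n_series,
                                seed = 1, snr_db = "clean",
                                max_neg_per_pos = Inf, n_series_other = 0,
                                config = default_config(), ...) {
  branch <- match.arg(branch)
  set.seed(seed)
  rhythms <- c(rep(branch, n_series),
               rep(setdiff(c("brady", "tachy"), branch), n_series_other))
  series_seeds <- sample.int(2^31 - 2, length(rhythms))
  noise_seeds <- sample.int(2^31 - 2, length(rhythms))

  cols <- list(); labs <- list()
  n_total <- 0L
  for (i in seq_along(rhythms)) {
    rr <- if (rhythms[i] == "brady")
      generate_bradycardia_series(seed = series_seeds[i], ...)
    else generate_tachycardia_series(seed = series_seeds[i], ...)
    ppg <- simulate_ppg(rr, fs = config$fs)
    ppg <- add_noise(ppg, snr_db, seed = noise_seeds[i],
                     noise_lp_hz = config$noise$lp_hz)
    segs <- preprocess_ppg(ppg, config)
    n_seg <- length(segs)
    if (n_seg == 0) next
    truth <- label_segments(ppg$annotations, n_seg, config$preprocess$win_s,
                            config)
    cols[[length(cols) + 1L]] <- segs$samples
    labs[[length(labs) + 1L]] <- truth
    n_total <- n_total + n_seg
  }
  samples <- do.call(cbind, cols)
  truth <- unlist(labs)
  y <- as.integer(truth == branch)

  pos <- which(y == 1L); neg <- which(y == 0L)
  if (is.finite(max_neg_per_pos) && length(neg) > max_neg_per_pos * length(pos))
    neg <- sort(sample(neg, round(max_neg_per_pos * length(pos))))
  sel <- sort(c(pos, neg))

  sc <- config$scalogram
  x <- scalogram_stack(samples[, sel, drop = FALSE], fs = config$fs,
                       normalize = sc$normalize, n_scales = sc$n_scales,
                       freq_range = sc$freq_range, gamma = sc$gamma,
                       P2 = sc$P2)
  list(x = x, y = y[sel], n_pos = length(pos), n_neg = length(neg),
       n_segments_total = n_total)
}

#' Segment-wise CNN detection on a PPG record
#'
#' Runs the full detection chain on one record: preprocessing, signal
#' quality assessment, scalograms of good-quality segments, branch CNN
#' probabilities and thresholded labels. Poor-quality segments are excluded
#' from detection and reported as `"other"` with probability `NA`; set
#' `apply_sqa = FALSE` to classify every segment regardless of quality.
#'
#' @param ppg A [ppg_signal()].
#' @param brady_model,tachy_model Fitted [ppg_cnn()] models (either may be
#'   `NULL` to skip that branch).
#' @param config Configuration list.
#' @param apply_sqa Exclude poor-quality segments from detection (the
#'   deployed pipeline behavior).
#' @return A data frame with one row per segment: `index` (0-based),
#'   `start_s`, `quality`, `truth` (from the record's annotations),
#'   `p_brady`, `brady`, `p_tachy`, `tachy` (per-branch probability and
#'   `"arrhythmia"`/`"other"` decision mapped to the rhythm name).
#' @export
detect_segments <- function(ppg, brady_model = NULL, tachy_model = NULL,
                            config = default_config(), apply_sqa = TRUE) {
  segs <- preprocess_ppg(ppg, config)
  n_seg <- length(segs)
  truth <- label_segments(ppg$annotations, n_seg, config$preprocess$win_s,
                          config)
  quality <- assess_quality(segs)$quality
  out <- data.frame(index = segs$index, start_s = segs$start_s,
                    quality = quality, truth = truth,
                    stringsAsFactors = FALSE)
  good <- if (apply_sqa) which(quality == "good") else seq_len(n_seg)
  sc <- config$scalogram
  x_good <- if (length(good) > 0)
    scalogram_stack(segs$samples[, good, drop = FALSE], fs = config$fs,
                    normalize = sc$normalize, n_scales = sc$n_scales,
                    freq_range = sc$freq_range, gamma = sc$gamma, P2 = sc$P2)
  for (branch in c("brady", "tachy")) {
    model <- if (branch == "brady") brady_model else tachy_model
    pcol <- paste0("p_", branch)
    out[[pcol]] <- NA_real_
    out[[branch]] <- "other"
    if (is.null(model)) next
    if (length(good) > 0) {
      p <- predict(model, x_good, type = "prob")
      out[[pcol]][good] <- p
      out[[branch]][good] <- ifelse(detect(p, model$threshold) ==
                                      "arrhythmia", branch, "other")
    }
  }
  out
}

#' Detection robustness versus training-signal SNR
#'
#' Trains the branch CNN on simulated datasets rendered at each requested
#' SNR (the same underlying RR series, with noise re-scaled), several
#' training sessions per SNR differing only in the training seed, and
#' evaluates every session on one fixed noise-free test set. Reports
#' per-session and mean sensitivity/specificity per SNR.
#'
#' @param snr_list Vector of SNRs in dB, e.g. `c("clean", 20, 10)`; order is
#'   preserved in the summary.
#' @param n_sessions Training sessions per SNR (>= 2).
#' @param seed Master seed; data, session and test seeds derive from it.
#' @param branch Branch to study.
#' @param n_series_train,n_series_test Simulated records for the training
#'   and test datasets.
#' @param max_neg_per_pos Negative-segment cap for the training data.
#' @param config Configuration list (use `default_config(cnn = list(...))`
#'   to scale epochs).
#' @return List with `sessions` (one row per SNR x session) and `summary`
#'   (mean sensitivity/specificity per SNR, in `snr_list` order).
#' @export
snr_experiment <- function(snr_list = c("clean", 20, 10), n_sessions = 5,
                           seed = 1, branch = "tachy", n_series_train = 40,
                           n_series_test = 15, max_neg_per_pos = 1,
                           config = default_config()) {
  if (n_sessions < 2) stop("n_sessions must be at least 2")
  set.seed(seed)
  data_seed <- sample.int(2^31 - 2, 1)
  test_seed <- sample.int(2^31 - 2, 1)
  session_seeds <- sample.int(2^31 - 2, n_sessions)

  test <- make_branch_dataset(branch, n_series_test, seed = test_seed,
                              snr_db = "clean", config = config)
  rows <- list()
  for (s in snr_list) {
    dat <- make_branch_dataset(branch, n_series_train, seed = data_seed,
                               snr_db = s, max_neg_per_pos = max_neg_per_pos,
                               config = config)
    for (j in seq_len(n_sessions)) {
      fit <- ppg_cnn(dat$x, dat$y, branch = branch, config = config,
                     seed = session_seeds[j])
      p <- predict(fit, test$x, type = "prob")
      pred <- ifelse(detect(p, fit$threshold) == "arrhythmia", branch,
                     "other")
      truth <- ifelse(test$y == 1L, branch, "other")
      ss <- sens_spec(pred, truth, branch)
      rows[[length(rows) + 1L]] <-
        data.frame(snr = as.character(s), session = j,
                   sensitivity = ss$sensitivity,
                   specificity = ss$specificity,
                   val_accuracy = fit$val_accuracy,
                   stringsAsFactors = FALSE)
    }
  }
  sessions <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(as.character(snr_list), function(s) {
    d <- sessions[sessions$snr == s, ]
    data.frame(snr = s, mean_sensitivity = mean(d$sensitivity),
               mean_specificity = mean(d$specificity),
               stringsAsFactors = FALSE)
  }))
  list(sessions = sessions, summary = summary)
}
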