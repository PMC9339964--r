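test_that("pulse counts match the beat count on clean constant-rate signals", {
  ppg <- const_hr_ppg(60, 60)
  tr <- detect_pulses(ppg)
  expect_lte(abs(length(tr$times) - 60), 1)
  expect_true(all(diff(tr$times) > 0))
})

test_that("a flat signal yields an empty pulse train", {
  tr <- detect_pulses(ppg_signal(numeric(3000)))
  expect_length(tr$times, 0)
  expect_identical(detect_episodes(tr),
                   detect_episodes(pulse_train(numeric(0))))
})

test_that("slow rhythms are detected with accurate inter-pulse intervals", {
  ppg <- const_hr_ppg(30, 60)
  tr <- detect_pulses(ppg)
  ipi <- diff(tr$times)
  expect_true(all(abs(ipi - 2.0) <= 0.05))
})

test_that("identical pulses correlate near-perfectly and are all accepted", {
  ppg <- const_hr_ppg(72, 40)
  tr <- assess_pulse_quality(detect_pulses(ppg), ppg)
  expect_true(all(tr$accepted))
  expect_true(all(tr$correlation > 0.95))
  expect_gt(stats::median(tr$correlation), 0.99)
})

test_that("a noise-corrupted beat rarely yields an accepted pulse", {
  ppg <- const_hr_ppg(72, 40)
  t0 <- round((19 * 60 / 72) * 100)
  clean_region <- 0L
  for (s in 1:10) {
    x <- ppg$samples
    set.seed(s)
    x[(t0 - 45):(t0 + 45)] <- stats::rnorm(91, sd = 0.6)
    noisy <- ppg_signal(x, ppg$fs)
    tr <- assess_pulse_quality(detect_pulses(noisy), noisy)
    bad <- which(tr$times > (t0 - 50) / 100 & tr$times < (t0 + 50) / 100)
    # success: the artifact is either not detected as a pulse at all, or
    # detected and rejected by the template correlation
    if (length(bad) == 0 || any(!tr$accepted[bad])) clean_region <- clean_region + 1L
    expect_gt(mean(tr$accepted), 0.8)   # the rest of the train survives
  }
  expect_gte(clean_region, 8L)
})

test_that("episode rules honor the strict rate bounds and 3-beat minimum", {
  mk_train <- function(rates) {
    times <- cumsum(c(0, 60 / rates))
    pulse_train(times, accepted = rep(TRUE, length(times)))
  }
  # rates [40, 35, 36, 38, 70]: one brady episode over the three sub-40 beats
  ep <- detect_episodes(mk_train(c(40, 35, 36, 38, 70)))
  expect_equal(nrow(ep), 1L)
  expect_identical(ep$rhythm, "brady")
  expect_equal(ep$n_beats, 3L)
  # exactly 40 bpm sustained: no episode (strict <)
  expect_equal(nrow(detect_episodes(mk_train(rep(40, 10)))), 0L)
  # exactly 120 bpm sustained: no episode (strict >)
  expect_equal(nrow(detect_episodes(mk_train(rep(120, 10)))), 0L)
  # two fast beats only: below the minimum run length
  expect_equal(nrow(detect_episodes(mk_train(c(80, 150, 150, 80)))), 0L)
  # three fast beats qualify
  ep2 <- detect_episodes(mk_train(c(80, 150, 150, 150, 80)))
  expect_equal(nrow(ep2), 1L)
  expect_identical(ep2$rhythm, "tachy")
})

test_that("runs are broken by rejected pulses and never contain one", {
  rates <- rep(35, 8)
  times <- cumsum(c(0, 60 / rates))
  acc <- rep(TRUE, 9); acc[5] <- FALSE
  ep <- detect_episodes(pulse_train(times, accepted = acc))
  # beats 1-4 and 5-9 give runs of 3 qualifying intervals each
  expect_true(all(ep$n_beats >= 3))
  for (i in seq_len(nrow(ep))) {
    inside <- which(times > ep$start_s[i] & times < ep$end_s[i])
    expect_true(all(acc[inside]))
  }
})

test_that("detected episodes map to segment labels by the overlap rules", {
  ep <- data.frame(rhythm = "brady", start_s = 50, end_s = 65,
                   stringsAsFactors = FALSE)
  lab <- episodes_to_segments(ep, 20)
  expect_identical(lab[11:13], rep("brady", 3))
  expect_identical(lab[c(10, 14)], c("other", "other"))
  # 40% brady coverage of a segment stays other (50% rule)
  ep2 <- data.frame(rhythm = "brady", start_s = 0, end_s = 2,
                    stringsAsFactors = FALSE)
  expect_identical(episodes_to_segments(ep2, 1), "other")
  # 30% tachy coverage qualifies (25% rule)
  ep3 <- data.frame(rhythm = "tachy", start_s = 0, end_s = 1.5,
                    stringsAsFactors = FALSE)
  expect_identical(episodes_to_segments(ep3, 1), "tachy")
  expect_identical(episodes_to_segments(ep3[0, ], 4), rep("other", 4))
})

test_that("the full reference detector recovers clean simulated episodes", {
  se_num <- se_den <- sp_num <- sp_den <- 0
  for (seed in 1:3) {
    rr <- generate_bradycardia_series(seed = seed)
    ppg <- simulate_ppg(rr)
    n_seg <- floor(ppg_duration(ppg) / 5)
    truth <- label_segments(ppg$annotations, n_seg)
    ref <- reference_detect(ppg)
    se_num <- se_num + sum(ref$labels == "brady" & truth == "brady")
    se_den <- se_den + sum(truth == "brady")
    sp_num <- sp_num + sum(ref$labels != "brady" & truth != "brady")
    sp_den <- sp_den + sum(truth != "brady")
  }
  expect_gte(se_num / se_den, 0.9)
  expect_gte(sp_num / sp_den, 0.95)
})
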