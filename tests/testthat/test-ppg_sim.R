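test_that("rendered pulses have the contracted length and normalization", {
  m <- pulse_model()
  p <- render_pulse(m, 1.0, 100)
  expect_length(p, 100)
  expect_equal(max(p), 1)
  expect_true(all(p >= 0))
  # 164 bpm beat: round(0.366 * 100) samples
  p2 <- render_pulse(m, 60 / 164, 100)
  expect_true(length(p2) %in% c(36L, 37L))
  expect_error(render_pulse(m, 0, 100), "positive")
  expect_error(render_pulse(m, -1, 100), "positive")
})

test_that("a pulse model with all zero amplitudes is rejected", {
  expect_error(pulse_model(lognormal = c(amp = 0, meanlog = log(0.25), sdlog = 0.35),
                           gaussian1 = c(amp = 0, center = 0.45, width = 0.12),
                           gaussian2 = c(amp = 0, center = 0.62, width = 0.09)),
               "non-zero")
  expect_error(pulse_model(gaussian1 = c(amp = 0.4, center = 0.45, width = -1)),
               "positive")
})

test_that("each beat contributes exactly one prominent pulse maximum", {
  rr <- generate_sinus_rr(40, mean_hr = 75, hr_sd = 2, seed = 3)
  ppg <- simulate_ppg(rr)
  x <- ppg$samples
  d <- diff(x)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  peaks <- peaks[x[peaks] > 0.5]
  expect_equal(length(peaks), length(rr$intervals))
})

test_that("constant-rate simulation has its spectral peak at the heart rate", {
  # 60 beats of exactly 1 s: fundamental at 1.0 Hz
  ppg <- const_hr_ppg(60, 60)
  n <- length(ppg$samples)
  spec <- Mod(stats::fft(ppg$samples - mean(ppg$samples)))^2
  k <- 2:(n %/% 2)
  f_peak <- (which.max(spec[k]) + 0) * ppg$fs / n
  expect_lt(abs(f_peak - 1.0), ppg$fs / n + 1e-9)
})

test_that("simulated duration matches the RR sum and annotations the episode", {
  rr <- generate_bradycardia_series(seed = 13, episode_beats = 23,
                                    episode_hr = 36)
  ppg <- simulate_ppg(rr)
  expect_lte(abs(length(ppg$samples) / ppg$fs - sum(rr$intervals)),
             length(rr$intervals) / ppg$fs)
  eb <- rr$episode_bounds
  tcum <- c(0, cumsum(rr$intervals))
  expect_equal(ppg$annotations$start_s, tcum[eb[1]])
  expect_equal(ppg$annotations$end_s, tcum[eb[2] + 1])
  expect_identical(ppg$annotations$rhythm, "brady")
  expect_error(simulate_ppg(structure(list(intervals = numeric(0)),
                                      class = "rr_series")), "empty")
})

test_that("added noise hits the requested SNR exactly and is seed-reproducible", {
  ppg <- const_hr_ppg(72, 30)
  noisy <- add_noise(ppg, 10, seed = 1)
  expect_lt(abs(measure_snr(ppg, noisy) - 10), 0.1)
  expect_length(noisy$samples, length(ppg$samples))
  # different seeds: different realizations, identical measured SNR
  noisy2 <- add_noise(ppg, 10, seed = 2)
  expect_false(isTRUE(all.equal(noisy$samples, noisy2$samples)))
  expect_lt(abs(measure_snr(ppg, noisy2) - 10), 0.1)
  # determinism
  expect_identical(add_noise(ppg, 10, seed = 1)$samples, noisy$samples)
  # clean sentinel is the identity
  expect_identical(add_noise(ppg, "clean"), ppg)
})

test_that("pulse joins are continuous", {
  rr <- generate_sinus_rr(30, mean_hr = 80, hr_sd = 4, seed = 8)
  ppg <- simulate_ppg(rr)
  expect_lt(max(abs(diff(ppg$samples))), 0.2)  # no step discontinuities
})
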