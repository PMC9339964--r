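test_that("zero-variance sinus rhythm yields exact intervals", {
  rr <- generate_sinus_rr(10, mean_hr = 75, hr_sd = 0, resp_amp = 0)
  expect_length(rr$intervals, 10)
  expect_equal(rr$intervals, rep(0.8, 10))
  expect_true(all(rr$labels == "sinus"))
})

test_that("sinus heart rates track the requested mean and stay above 60 bpm", {
  rr <- generate_sinus_rr(1000, mean_hr = 75, hr_sd = 3, seed = 1,
                          resp_amp = 0)
  hr <- 60 / rr$intervals
  expect_lt(abs(mean(hr) - 75), 0.5)
  expect_true(all(hr > 60))
  # with respiratory modulation the constraint still holds
  rr2 <- generate_sinus_rr(500, mean_hr = 63, hr_sd = 2, seed = 2)
  expect_true(all(60 / rr2$intervals > 60))
})

test_that("sub-60 bpm sinus rhythm is rejected", {
  expect_error(generate_sinus_rr(5, mean_hr = 50), "exceed 60")
  expect_error(generate_sinus_rr(5, mean_hr = 60), "exceed 60")
})

test_that("fixed-parameter bradycardia episode has the requested rate and bounds", {
  rr <- generate_bradycardia_series(seed = 7, episode_beats = 23,
                                    episode_hr = 36, episode_hr_sd = 0)
  eb <- rr$episode_bounds
  expect_equal(eb[2] - eb[1] + 1L, 23L)
  ep <- rr$intervals[eb[1]:eb[2]]
  expect_equal(ep, rep(60 / 36, 23), tolerance = 1e-12)
  expect_true(all(rr$labels[eb[1]:eb[2]] == "brady"))
  expect_true(all(rr$labels[-(eb[1]:eb[2])] == "sinus"))
})

test_that("surrounding sinus subseries have 50-100 beats before and 1-100 after", {
  for (seed in 1:20) {
    rr <- generate_bradycardia_series(seed = seed)
    eb <- rr$episode_bounds
    n_before <- eb[1] - 1L
    n_after <- length(rr$intervals) - eb[2]
    expect_gte(n_before, 50L); expect_lte(n_before, 100L)
    expect_gte(n_after, 1L); expect_lte(n_after, 100L)
    expect_equal(length(rr$intervals),
                 n_before + (eb[2] - eb[1] + 1L) + n_after)
  }
})

test_that("random episode statistics reproduce the stated length distribution", {
  len_b <- len_t <- hr_b <- hr_t <- numeric(200)
  for (i in 1:200) {
    b <- generate_bradycardia_series(seed = 1000 + i)
    t <- generate_tachycardia_series(seed = 3000 + i)
    len_b[i] <- diff(b$episode_bounds) + 1
    len_t[i] <- diff(t$episode_bounds) + 1
    hr_b[i] <- stats::median(60 / b$intervals[b$episode_bounds[1]:b$episode_bounds[2]])
    hr_t[i] <- stats::median(60 / t$intervals[t$episode_bounds[1]:t$episode_bounds[2]])
  }
  expect_true(all(len_b >= 8 & len_b <= 51))
  expect_true(all(len_t >= 4 & len_t <= 528))
  expect_lt(abs(stats::median(len_b) - 23), 3)
  expect_lt(abs(stats::median(hr_b) - 36), 2)
  expect_lt(abs(stats::median(hr_t) - 164), 8)
  expect_true(all(hr_t >= 120))
})

test_that("tachycardia below 120 bpm and out-of-band parameters are rejected", {
  expect_error(generate_tachycardia_series(seed = 1, episode_hr = 119),
               "120")
  expect_error(generate_bradycardia_series(seed = 1, episode_hr = 45),
               "\\[25, 40\\]")
  expect_error(generate_bradycardia_series(seed = 1, episode_beats = 5),
               "episode_beats")
})

test_that("tachycardia episode at 164 bpm gives ~0.366 s intervals", {
  rr <- generate_tachycardia_series(seed = 5, episode_beats = 20,
                                    episode_hr = 164, episode_hr_sd = 0)
  eb <- rr$episode_bounds
  expect_equal(rr$intervals[eb[1]], 60 / 164, tolerance = 1e-12)
})

test_that("generation is deterministic per seed and beat times increase", {
  a <- generate_bradycardia_series(seed = 42)
  b <- generate_bradycardia_series(seed = 42)
  expect_identical(a, b)
  expect_true(all(diff(cumsum(a$intervals)) > 0))
  c <- generate_tachycardia_series(seed = 42)
  d <- generate_tachycardia_series(seed = 42)
  expect_identical(c, d)
})

test_that("rr_series enforces its invariants", {
  expect_error(rr_series(c(1, -1), c("sinus", "sinus")), "\\(0, 10\\)")
  expect_error(rr_series(c(0.8, 0.8), c("sinus", "brady")), "episode_bounds")
  expect_error(rr_series(c(0.8, 1.5), c("sinus", "sinus")), "above 60")
  ok <- rr_series(c(0.8, 1.7, 0.8), c("sinus", "brady", "sinus"),
                  episode_bounds = c(2, 2))
  expect_s3_class(ok, "rr_series")
})

test_that("RR CSV round trip preserves the series", {
  rr <- generate_bradycardia_series(seed = 9)
  path <- tempfile(fileext = ".csv")
  write_rr_csv(rr, path)
  back <- read_rr_csv(path)
  expect_equal(back$intervals, rr$intervals, tolerance = 1e-12)
  expect_identical(back$labels, rr$labels)
  expect_identical(back$episode_bounds, rr$episode_bounds)
  unlink(c(path, paste0(path, ".json")))
})
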