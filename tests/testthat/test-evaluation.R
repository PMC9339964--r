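test_that("overlap rules label segments as specified", {
  ann <- function(s, e, r) data.frame(start_s = s, end_s = e, rhythm = r,
                                      stringsAsFactors = FALSE)
  # 2.5 s of 5 s brady -> brady; 2.0 s -> other
  expect_identical(label_segments(ann(0, 2.5, "brady"), 1), "brady")
  expect_identical(label_segments(ann(0, 2.0, "brady"), 1), "other")
  # 1.25 s tachy -> tachy; 1.0 s -> other
  expect_identical(label_segments(ann(0, 1.25, "tachy"), 1), "tachy")
  expect_identical(label_segments(ann(0, 1.0, "tachy"), 1), "other")
  # spans several segments
  lab <- label_segments(ann(5, 20, "brady"), 5)
  expect_identical(lab, c("other", "brady", "brady", "brady", "other"))
  # no annotations
  expect_identical(label_segments(ann(numeric(0), numeric(0), character(0)), 3),
                   rep("other", 3))
})

test_that("conflicting double labels are rejected", {
  ann <- data.frame(start_s = c(0, 2.5), end_s = c(2.5, 5),
                    rhythm = c("brady", "tachy"), stringsAsFactors = FALSE)
  expect_error(label_segments(ann, 1), "both")
  ov <- data.frame(start_s = c(0, 1), end_s = c(3, 4),
                   rhythm = c("brady", "brady"), stringsAsFactors = FALSE)
  expect_error(label_segments(ov, 1), "overlap")
})

test_that("sensitivity and specificity match direct counts", {
  truth <- c(rep("brady", 4), rep("other", 6))
  pred <- c("brady", "brady", "brady", "other",
            "brady", rep("other", 5))
  ss <- sens_spec(pred, truth, "brady")
  expect_equal(ss$sensitivity, 0.75)
  expect_equal(ss$specificity, 5 / 6)
  expect_equal(c(ss$tp, ss$fn, ss$fp, ss$tn), c(3, 1, 1, 5))
  # perfect and degenerate cases
  expect_equal(sens_spec(truth, truth, "brady")$sensitivity, 1)
  expect_equal(sens_spec(truth, truth, "brady")$specificity, 1)
  all_other <- rep("other", 10)
  expect_equal(sens_spec(all_other, truth, "brady")$sensitivity, 0)
  expect_equal(sens_spec(all_other, truth, "brady")$specificity, 1)
  expect_true(is.na(sens_spec(all_other, all_other, "brady")$sensitivity))
})

test_that("confidence intervals are proper and contain the point estimate", {
  ss <- sens_spec(c("brady", "brady", "other", "other"),
                  c("brady", "other", "brady", "other"), "brady")
  expect_true(ss$sensitivity_ci[1] <= ss$sensitivity &&
              ss$sensitivity <= ss$sensitivity_ci[2])
  expect_true(all(ss$specificity_ci >= 0 & ss$specificity_ci <= 1))
})

test_that("kappa equals 1 on identical labels and ~0 under independence", {
  a <- sample(c("brady", "other"), 400, replace = TRUE)
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  set.seed(99)
  b <- sample(c("brady", "other"), 5000, replace = TRUE, prob = c(0.3, 0.7))
  c <- sample(c("brady", "other"), 5000, replace = TRUE, prob = c(0.3, 0.7))
  expect_lt(abs(cohens_kappa(b, c)$kappa), 0.05)
})

test_that("kappa reproduces the hand-computed 2x2 value and its symmetries", {
  # contingency a=40, b=10, c=10, d=40: p_o = 0.8, p_e = 0.5, kappa = 0.6
  x <- c(rep("p", 40), rep("p", 10), rep("n", 10), rep("n", 40))
  y <- c(rep("p", 40), rep("n", 10), rep("p", 10), rep("n", 40))
  k <- cohens_kappa(x, y)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$p_observed, 0.8)
  expect_equal(k$p_expected, 0.5)
  expect_equal(cohens_kappa(y, x)$kappa, 0.6)       # symmetric
  x2 <- ifelse(x == "p", "A", "B")                  # renaming invariance
  y2 <- ifelse(y == "p", "A", "B")
  expect_equal(cohens_kappa(x2, y2)$kappa, 0.6)
  # degenerate marginals
  expect_true(is.na(cohens_kappa(rep("a", 5), rep("a", 5))$kappa))
  # bootstrap CI brackets the estimate
  ci <- cohens_kappa(x, y, n_boot = 200, seed = 1)$ci
  expect_true(ci[1] <= 0.6 && 0.6 <= ci[2])
})

test_that("ROC sweeps behave at the extremes and are monotone", {
  set.seed(4)
  truth <- rep(c(TRUE, FALSE), each = 50)
  p <- ifelse(truth, stats::runif(100, 0.6, 1), stats::runif(100, 0, 0.4))
  roc <- roc_sweep(p, truth)
  expect_equal(roc$sensitivity[roc$threshold == 0], 1)
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  # separable scores reach the (0, 1) corner
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  # threshold near 1: nothing flagged
  hi <- roc_sweep(p, truth, thresholds = 0.999)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
})
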