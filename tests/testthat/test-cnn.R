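test_that("architecture dimensions and parameter counts match the design", {
  b <- cnn_dims(13)
  expect_equal(b$conv1, c(488, 49, 32))
  expect_equal(b$pool1, c(244, 24, 32))
  expect_equal(b$conv2, c(232, 12, 32))
  expect_equal(b$pool2, c(116, 6, 32))
  expect_equal(b$flat, 22272)
  expect_equal(b$n_params,
               (13 * 13 * 32 + 32) + (13 * 13 * 32 * 32 + 32) +
               (22272 * 256 + 256) + (256 * 2 + 2))
  t <- cnn_dims(5)
  expect_equal(t$conv1, c(496, 57, 32))
  expect_equal(t$flat, 46848)
  expect_equal(t$n_params,
               (5 * 5 * 32 + 32) + (5 * 5 * 32 * 32 + 32) +
               (46848 * 256 + 256) + (256 * 2 + 2))
  # weight shapes agree with the audit
  p <- ppgarr:::init_cnn_params(13)
  expect_equal(dim(p$W1), c(169L, 32L))
  expect_equal(dim(p$W2), c(169 * 32, 32L))
  expect_equal(dim(p$Wd), c(22272L, 256L))
  expect_equal(dim(p$Wo), c(2L, 256L))
  expect_equal(sum(vapply(p, length, numeric(1))), b$n_params)
})

test_that("class balancing and the 70/30 split follow the stated rules", {
  x <- array(stats::runif(8 * 8 * 200), c(8, 8, 200))
  y <- c(rep(1, 40), rep(0, 160))
  d <- prepare_training_data(x, y, seed = 3)
  expect_equal(sum(d$train$y == 1) + sum(d$val$y == 1), 40)
  expect_equal(sum(d$train$y == 0) + sum(d$val$y == 0), 40)  # undersampled
  # 100 per class: 70 train / 30 validation each
  y2 <- rep(c(1, 0), each = 100)
  d2 <- prepare_training_data(array(0, c(4, 4, 200)), y2, seed = 1)
  expect_equal(length(d2$train$y), 140)
  expect_equal(length(d2$val$y), 60)
  expect_equal(sum(d2$train$y), 70)
  # determinism
  da <- prepare_training_data(x, y, seed = 11)
  db <- prepare_training_data(x, y, seed = 11)
  expect_identical(da$train$y, db$train$y)
  expect_identical(da$train$x, db$train$x)
  # absent class
  expect_error(prepare_training_data(x, rep(0, 200), seed = 1),
               "each class")
})

test_that("softmax outputs are proper probabilities and inference is deterministic", {
  p <- ppgarr:::init_cnn_params(5, c(40, 30))
  x <- array(stats::runif(40 * 30 * 4), c(40, 30, 4))
  pr <- ppgarr:::cnn_forward_cpp(p, x, 5)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(rowSums(pr), rep(1, 4))
  expect_identical(pr, ppgarr:::cnn_forward_cpp(p, x, 5))
})

test_that("thresholding is strict and monotone in the threshold", {
  expect_identical(detect(0.9, 0.5), "arrhythmia")
  expect_identical(detect(0.5, 0.5), "other")     # tie goes to other
  expect_identical(detect(c(0.2, 0.8), 0.5), c("other", "arrhythmia"))
  p <- stats::runif(50)
  n_det <- vapply(seq(0, 0.95, by = 0.05),
                  function(th) sum(detect(p, th) == "arrhythmia"),
                  numeric(1))
  expect_true(all(diff(n_det) <= 0))
})

test_that("threshold selection favors sensitivity and uses midpoints", {
  p <- c(0.1, 0.2, 0.8, 0.9, 0.95)
  y <- c(0, 0, 1, 1, 1)
  th <- choose_threshold(p, y, min_sensitivity = 0.98)
  expect_lt(th, 0.8)      # keeps all positives
  expect_gte(th, 0.2)     # as specific as possible
  expect_true(all(detect(p[y == 1], th) == "arrhythmia"))
})

test_that("the network can memorize a small random batch (capacity check)", {
  set.seed(10)
  x <- array(stats::runif(60 * 40 * 20), c(60, 40, 20))
  y <- rep(0:1, each = 10)
  cfg <- default_config(cnn = list(max_epochs = 30, patience = 30,
                                   dropout = 0, batch_size = 20,
                                   learning_rate = 0.001,
                                   min_sensitivity = 0.9))
  fit <- suppressWarnings(ppg_cnn(x, y, branch = "tachy", config = cfg,
                                  seed = 2))
  expect_equal(tail(fit$history$train_acc, 1), 1.0)
})

test_that("a zero learning rate leaves the weights unchanged", {
  set.seed(20)
  x <- array(stats::runif(40 * 30 * 24), c(40, 30, 24))
  y <- rep(0:1, 12)
  cfg0 <- default_config(cnn = list(max_epochs = 1, patience = 5,
                                    learning_rate = 0, min_sensitivity = 0.9))
  cfg3 <- default_config(cnn = list(max_epochs = 3, patience = 5,
                                    learning_rate = 0, min_sensitivity = 0.9))
  f1 <- suppressWarnings(ppg_cnn(x, y, branch = "tachy", config = cfg0,
                                 seed = 7))
  f3 <- suppressWarnings(ppg_cnn(x, y, branch = "tachy", config = cfg3,
                                 seed = 7))
  expect_equal(f1$params, f3$params)
  expect_warning(ppg_cnn(x, y, branch = "tachy", config = cfg0, seed = 7),
                 "did not converge")
})

test_that("prediction validates input shape and honors the saved threshold", {
  set.seed(30)
  x <- array(stats::runif(40 * 30 * 24), c(40, 30, 24))
  y <- rep(0:1, 12)
  cfg <- default_config(cnn = list(max_epochs = 2, patience = 2,
                                   min_sensitivity = 0.9))
  fit <- suppressWarnings(ppg_cnn(x, y, branch = "tachy", config = cfg,
                                  seed = 1))
  p <- predict(fit, x[, , 1:3])
  expect_length(p, 3)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict(fit, array(0, c(10, 10, 2))), "newdata must be")
  lab <- predict(fit, x[, , 1:3], type = "label")
  expect_identical(lab, detect(p, fit$threshold))
})

test_that("model save/load round trip preserves predictions", {
  set.seed(40)
  x <- array(stats::runif(40 * 30 * 16), c(40, 30, 16))
  y <- rep(0:1, 8)
  cfg <- default_config(cnn = list(max_epochs = 1, patience = 1,
                                   min_sensitivity = 0.9))
  fit <- suppressWarnings(ppg_cnn(x, y, branch = "tachy", config = cfg,
                                  seed = 4))
  path <- tempfile(fileext = ".json")
  save_ppg_cnn(fit, path)
  back <- load_ppg_cnn(path)
  expect_equal(predict(back, x[, , 1:4]), predict(fit, x[, , 1:4]))
  expect_equal(back$threshold, fit$threshold)
  unlink(path)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(50)
  k <- 5
  x <- array(stats::runif(40 * 30 * 3), c(40, 30, 3))
  y <- c(0L, 1L, 1L)
  params <- ppgarr:::init_cnn_params(k, c(40, 30))
  g <- ppgarr:::cnn_grad_cpp(params, x, y, k, 0, 1)
  loss_fn <- function(p) {
    pr <- ppgarr:::cnn_forward_cpp(p, x, k)
    -mean(log(pr[cbind(1:3, y + 1)]))
  }
  gmap <- c(W1 = "gW1", b1 = "gb1", W2 = "gW2", b2 = "gb2",
            Wd = "gWd", bd = "gbd", Wo = "gWo", bo = "gbo")
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      eps <- 1e-3
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      # single-precision forward: compare at mixed absolute/relative scale
      expect_lt(abs(g[[gmap[[nm]]]][i] - num), 0.08 * max(0.02, abs(num)))
    }
  }
})
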