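#' Layer dimensions of a branch CNN
#'
#' Shapes implied by the fixed architecture (two 32-kernel valid
#' convolutions with 2x2 average pooling) for a given conv kernel size and
#' input image size.
#'
#' @param kernel Conv kernel side (13 for the bradycardia branch, 5 for
#'   tachycardia).
#' @param input_dim Input image size, time by scale.
#' @return A list of layer shapes including `flat` (flattened feature count)
#'   and `n_params` (total trainable parameter count).
#' @export
cnn_dims <- function(kernel, input_dim = c(500, 61)) {
  H <- input_dim[1]; W <- input_dim[2]; k <- kernel
  H1 <- H - k + 1; W1 <- W - k + 1
  Hp1 <- H1 %/% 2; Wp1 <- W1 %/% 2
  H2 <- Hp1 - k + 1; W2 <- Wp1 - k + 1
  Hp2 <- H2 %/% 2; Wp2 <- W2 %/% 2
  flat <- Hp2 * Wp2 * 32
  n_params <- (k * k * 32 + 32) + (k * k * 32 * 32 + 32) +
    (flat * 256 + 256) + (256 * 2 + 2)
  list(conv1 = c(H1, W1, 32), pool1 = c(Hp1, Wp1, 32),
       conv2 = c(H2, W2, 32), pool2 = c(Hp2, Wp2, 32),
       flat = flat, dense = 256, output = 2, n_params = n_params)
}

init_cnn_params <- function(kernel, input_dim = c(500, 61)) {
  d <- cnn_dims(kernel, input_dim)
  k <- kernel
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                nr, nc)
  list(W1 = he(k * k, 32), b1 = numeric(32),
       W2 = he(k * k * 32, 32), b2 = numeric(32),
       Wd = he(d$flat, 256), bd = numeric(256),
       Wo = t(he(256, 2)), bo = numeric(2))   # 2 x 256, fan-in 256
}

#' Balance and split labelled scalograms for training
#'
#' Balances the two classes by undersampling the majority class at random,
#' then splits 70/30 into training and validation sets, stratified by class.
#'
#' @param x Scalogram stack, a `500 x 61 x n` array (see
#'   [scalogram_stack()]).
#' @param y Binary labels, 1 = arrhythmia, 0 = other (logical or numeric).
#' @param seed Optional integer seed making undersampling and split
#'   deterministic.
#' @param val_fraction Validation share of the balanced set.
#' @return List with `train` and `val`, each a list of `x` (array) and `y`.
#' @export
prepare_training_data <- function(x, y, seed = NULL, val_fraction = 0.3) {
  y <- as.integer(y)
  stopifnot(length(y) == dim(x)[3], all(y %in% c(0L, 1L)))
  if (!is.null(seed)) set.seed(seed)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 examples of each class")
  n_keep <- min(length(pos), length(neg))
  pos <- if (length(pos) > n_keep) sort(sample(pos, n_keep)) else pos
  neg <- if (length(neg) > n_keep) sort(sample(neg, n_keep)) else neg
  split1 <- function(idx) {
    n_tr <- floor((1 - val_fraction) * length(idx))
    tr <- sort(sample(idx, n_tr))
    list(train = tr, val = setdiff(idx, tr))
  }
  sp <- split1(pos); sn <- split1(neg)
  tr <- c(sp$train, sn$train); va <- c(sp$val, sn$val)
  list(train = list(x = x[, , tr, drop = FALSE], y = y[tr]),
       val = list(x = x[, , va, drop = FALSE], y = y[va]))
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  gmap <- c(W1 = "gW1", b1 = "gb1", W2 = "gW2", b2 = "gb2",
            Wd = "gWd", bd = "gbd", Wo = "gWo", bo = "gbo")
  for (nm in names(params)) {
    # in-place update: params/m/v are owned by this optimizer loop
    adam_step_cpp(params[[nm]], grads[[gmap[[nm]]]],
                  state$m[[nm]], state$v[[nm]],
                  lr, beta1, beta2, eps, c1, c2)
  }
  list(params = params, state = state)
}

cnn_probs <- function(params, x, kernel, batch = 64) {
  n <- dim(x)[3]
  out <- numeric(n)
  for (i0 in seq(1, n, by = batch)) {
    idx <- i0:min(i0 + batch - 1, n)
    out[idx] <- cnn_forward_cpp(params, x[, , idx, drop = FALSE],
                                kernel)[, 2]
  }
  out
}

#' Fit a branch CNN on scalogram images
#'
#' The fitting function of the detector: trains one binary branch
#' (bradycardia-vs-other or tachycardia-vs-other) on labelled scalogram
#' images with the Adam optimizer, mini-batches, dropout and early stopping
#' on validation accuracy, after balancing the classes by undersampling and
#' splitting 70/30 (see [prepare_training_data()]). The detection threshold
#' is then chosen on the validation set as the highest-specificity operating
#' point whose sensitivity still reaches `min_sensitivity` (sensitivity is
#' favored over specificity).
#'
#' @param x Scalogram stack (`500 x 61 x n` array), or `NULL` when `data` is
#'   given.
#' @param y Binary labels (1 = arrhythmia), or `NULL` when `data` is given.
#' @param branch `"brady"` or `"tachy"`; sets the conv kernel size (13 or 5).
#' @param data Optionally, an already prepared `list(train, val)` from
#'   [prepare_training_data()]; `x`/`y` are then ignored.
#' @param config Configuration list, see [default_config()]; the `cnn` block
#'   holds learning rate, batch size, dropout, epochs and patience.
#' @param seed Integer seed governing initialization, undersampling, batch
#'   shuffling and dropout. Results are stochastic across seeds.
#' @return An object of class `ppg_cnn`: list with `params` (weights at the
#'   best validation epoch), `branch`, `kernel`, `threshold`, `history`
#'   (per-epoch loss and accuracies), `dims`, `config` and `seed`.
#' @seealso [predict.ppg_cnn()], [detect()], [plot.ppg_cnn()]
#' @export
ppg_cnn <- function(x = NULL, y = NULL, branch = c("brady", "tachy"),
                    data = NULL, config = default_config(), seed = 1) {
  branch <- match.arg(branch)
  cc <- config$cnn
  kernel <- unname(cc$kernel[[branch]])
  set.seed(seed)
  if (is.null(data)) {
    if (is.null(x) || is.null(y)) stop("either x and y or data must be given")
    data <- prepare_training_data(x, y, seed = NULL,
                                  val_fraction = cc$val_fraction)
  }
  xtr <- data$train$x; ytr <- data$train$y
  xva <- data$val$x; yva <- data$val$y
  n_tr <- dim(xtr)[3]
  input_dim <- dim(xtr)[1:2]

  params <- init_cnn_params(kernel, input_dim)
  state <- adam_init(params)
  best <- list(acc = -Inf, params = lapply(params, function(p) p + 0),
               epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))
  wait <- 0L

  for (epoch in seq_len(cc$max_epochs)) {
    ord <- sample(n_tr)
    ep_loss <- 0; ep_acc <- 0; n_seen <- 0
    for (i0 in seq(1, n_tr, by = cc$batch_size)) {
      idx <- ord[i0:min(i0 + cc$batch_size - 1, n_tr)]
      drop_seed <- sample.int(.Machine$integer.max, 1)
      g <- cnn_grad_cpp(params, xtr[, , idx, drop = FALSE],
                        as.integer(ytr[idx]), kernel, cc$dropout, drop_seed)
      if (cc$learning_rate > 0) {
        up <- adam_update(params, g, state, cc$learning_rate)
        params <- up$params; state <- up$state
      }
      nb <- length(idx)
      ep_loss <- ep_loss + g$loss * nb
      ep_acc <- ep_acc + g$accuracy * nb
      n_seen <- n_seen + nb
    }
    p_val <- cnn_probs(params, xva, kernel)
    val_acc <- mean((p_val > 0.5) == (yva == 1L))
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss / n_seen,
                                train_acc = ep_acc / n_seen,
                                val_acc = val_acc))
    if (val_acc > best$acc + 1e-12) {
      # deep copy: the optimizer updates the live parameters in place
      best <- list(acc = val_acc,
                   params = lapply(params, function(p) p + 0),
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cc$patience) break
    }
    if (best$acc >= 1) break   # no further improvement is possible
  }

  if (best$acc <= 0.5 + 0.02)
    warning(sprintf(
      "branch '%s' did not converge: best validation accuracy %.3f",
      branch, best$acc))

  p_val_best <- cnn_probs(best$params, xva, kernel)
  threshold <- choose_threshold(p_val_best, yva,
                                min_sensitivity = cc$min_sensitivity)

  structure(list(params = best$params, branch = branch, kernel = kernel,
                 threshold = threshold, history = history,
                 best_epoch = best$epoch, val_accuracy = best$acc,
                 dims = cnn_dims(kernel, input_dim), input_dim = input_dim,
                 config = config, seed = seed),
            class = "ppg_cnn")
}

#' Choose a detection threshold favoring sensitivity
#'
#' Sweeps candidate thresholds on validation outputs and picks the operating
#' point with the highest specificity among those whose sensitivity still
#' reaches `min_sensitivity`; where several thresholds tie on specificity
#' (a separating gap), the most sensitive end of the tie is taken and the
#' threshold is centered in the gap to the next observed output, so it never
#' sits flush against the validation outputs. Detection uses the strict
#' rule `p > threshold`.
#'
#' @param p Validation probabilities of the arrhythmia class.
#' @param y Validation labels (1 = arrhythmia).
#' @param min_sensitivity Minimum sensitivity to preserve.
#' @return A threshold in [0, 1).
#' @export
choose_threshold <- function(p, y, min_sensitivity = 0.98) {
  y <- as.integer(y)
  cand <- sort(unique(c(0, p)))
  ## p > threshold: sensitivity non-increasing, specificity non-decreasing
  se <- vapply(cand, function(th) mean(p[y == 1L] > th), numeric(1))
  sp <- vapply(cand, function(th) mean(p[y == 0L] <= th), numeric(1))
  ok <- which(se >= min_sensitivity)
  if (length(ok) == 0) return(0)
  i <- min(ok[sp[ok] == max(sp[ok])])
  if (i < length(cand)) (cand[i] + cand[i + 1]) / 2 else cand[i]
}

#' Predict arrhythmia probabilities or labels for scalograms
#'
#' @param object A fitted [ppg_cnn()] model.
#' @param newdata A scalogram stack (`500 x 61 x n` array), a single
#'   `500 x 61` matrix, or a `scalogram` object. Dropout is disabled at
#'   inference.
#' @param type `"prob"` for the softmax probability of the arrhythmia class,
#'   `"label"` for thresholded labels.
#' @param threshold Detection threshold; defaults to the one chosen at fit
#'   time.
#' @param ... Unused.
#' @return Numeric probabilities in [0, 1], or a character vector of
#'   `"arrhythmia"` / `"other"`.
#' @export
predict.ppg_cnn <- function(object, newdata, type = c("prob", "label"),
                            threshold = object$threshold, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "scalogram")) newdata <- newdata$mag
  if (is.matrix(newdata))
    newdata <- array(newdata, dim = c(dim(newdata), 1))
  if (!(length(dim(newdata)) == 3 &&
        all(dim(newdata)[1:2] == object$input_dim)))
    stop(sprintf("newdata must be %d x %d x n",
                 object$input_dim[1], object$input_dim[2]))
  p <- cnn_probs(object$params, newdata, object$kernel)
  if (type == "prob") p else detect(p, threshold)
}

#' Threshold a detector output
#'
#' A segment is classified as arrhythmia iff its probability strictly
#' exceeds the threshold (an output exactly at the threshold is `"other"`).
#'
#' @param p Probabilities in [0, 1].
#' @param threshold Detection threshold in (0, 1) (0 is allowed and flags
#'   every segment with positive probability).
#' @return Character vector of `"arrhythmia"` / `"other"`.
#' @export
detect <- function(p, threshold) {
  stopifnot(all(p >= 0 & p <= 1), threshold >= 0, threshold < 1)
  ifelse(p > threshold, "arrhythmia", "other")
}

#' @export
print.ppg_cnn <- function(x, ...) {
  cat(sprintf("Branch CNN (%s): %dx%d kernels, %s trainable parameters\n",
              x$branch, x$kernel, x$kernel,
              format(x$dims$n_params, big.mark = ",")))
  cat(sprintf("  best validation accuracy %.3f (epoch %d of %d run)\n",
              x$val_accuracy, x$best_epoch, nrow(x$history)))
  cat(sprintf("  detection threshold %.3f (p > threshold)\n", x$threshold))
  invisible(x)
}

#' @export
summary.ppg_cnn <- function(object, ...) {
  cat(sprintf("Branch: %s (kernel %dx%d)\n", object$branch, object$kernel,
              object$kernel))
  d <- object$dims
  cat(sprintf("  conv1 -> %s, pool -> %s, conv2 -> %s, pool -> %s\n",
              paste(d$conv1, collapse = "x"), paste(d$pool1, collapse = "x"),
              paste(d$conv2, collapse = "x"), paste(d$pool2, collapse = "x")))
  cat(sprintf("  dense %d -> %d, softmax; %s parameters\n",
              d$flat, d$dense, format(d$n_params, big.mark = ",")))
  cat("Training history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Plot the training history of a branch CNN
#' @param x A fitted [ppg_cnn()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ppg_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "b",
                    pch = c(1, 19), lty = 1, xlab = "epoch",
                    ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"),
                   pch = c(1, 19), lty = 1, col = 1:2)
  invisible(x)
}

#' Save / load a fitted branch CNN as JSON
#'
#' Weights are serialized as plain JSON arrays, so checkpoints are
#' text-only and portable.
#'
#' @param object A [ppg_cnn()] model.
#' @param path Output file path.
#' @return `save_ppg_cnn` returns `path` invisibly; `load_ppg_cnn` the
#'   restored model.
#' @export
save_ppg_cnn <- function(object, path) {
  stopifnot(inherits(object, "ppg_cnn"))
  obj <- list(branch = object$branch, kernel = object$kernel,
              threshold = object$threshold, input_dim = object$input_dim,
              seed = object$seed, history = object$history,
              params = lapply(object$params, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = length(p), data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ppg_cnn
#' @export
load_ppg_cnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params, branch = obj$branch, kernel = obj$kernel,
                 threshold = obj$threshold,
                 history = as.data.frame(obj$history),
                 best_epoch = NA_integer_, val_accuracy = NA_real_,
                 dims = cnn_dims(obj$kernel, obj$input_dim),
                 input_dim = obj$input_dim, config = default_config(),
                 seed = obj$seed),
            class = "ppg_cnn")
}
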