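## Shared overlap-rule labelling: a segment [i*win, (i+1)*win) gets a rhythm
## iff episodes of that rhythm cover at least the rhythm's fraction of it.
overlap_label <- function(episodes, n_segments, win_s, brady_overlap,
                          tachy_overlap, on_conflict = c("error", "largest")) {
  on_conflict <- match.arg(on_conflict)
  labels <- rep("other", n_segments)
  if (n_segments == 0 || is.null(episodes) || nrow(episodes) == 0)
    return(labels)
  seg_lo <- (seq_len(n_segments) - 1) * win_s
  seg_hi <- seg_lo + win_s
  cover <- function(rhythm) {
    ep <- episodes[episodes$rhythm == rhythm, , drop = FALSE]
    tot <- numeric(n_segments)
    for (i in seq_len(nrow(ep)))
      tot <- tot + pmax(0, pmin(seg_hi, ep$end_s[i]) -
                           pmax(seg_lo, ep$start_s[i]))
    tot / win_s
  }
  is_b <- cover("brady") >= brady_overlap
  is_t <- cover("tachy") >= tachy_overlap
  both <- is_b & is_t
  if (any(both)) {
    if (on_conflict == "error")
      stop("a segment qualifies as both bradycardia and tachycardia")
    cb <- cover("brady")[both] / brady_overlap
    ct <- cover("tachy")[both] / tachy_overlap
    is_b[both] <- cb >= ct
    is_t[both] <- ct > cb
  }
  labels[is_t] <- "tachy"
  labels[is_b] <- "brady"
  labels
}

#' Ground-truth labelling of 5-s segments from episode annotations
#'
#' A segment is labelled bradycardia if episodes cover at least 50% of it,
#' tachycardia if at least 25% (tachycardia packs more beats into the same
#' time). Thresholds are inclusive; overlaps are computed in continuous
#' time. A segment qualifying as both rhythms raises an error.
#'
#' @param annotations Data frame with `start_s`, `end_s`, `rhythm`
#'   (`"brady"`/`"tachy"`), half-open intervals in seconds.
#' @param n_segments Number of 5-s segments.
#' @param win_s Segment length in seconds.
#' @param config Configuration; `labeling` holds the two overlap fractions.
#' @return Character vector of `"brady"`, `"tachy"`, `"other"`.
#' @export
label_segments <- function(annotations, n_segments, win_s = 5,
                           config = default_config()) {
  for (rhythm in c("brady", "tachy")) {
    ep <- annotations[annotations$rhythm == rhythm, , drop = FALSE]
    if (nrow(ep) > 1) {
      ep <- ep[order(ep$start_s), ]
      if (any(ep$start_s[-1] < ep$end_s[-nrow(ep)]))
        stop("episode annotations of one rhythm must not overlap")
    }
  }
  overlap_label(annotations, n_segments, win_s,
                config$labeling$brady_overlap, config$labeling$tachy_overlap,
                on_conflict = "error")
}

clopper_pearson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  a <- 1 - conf
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

#' Segment-wise sensitivity and specificity
#'
#' Sensitivity is the fraction of segments of the target rhythm that the
#' detector labelled with that rhythm; specificity the fraction of
#' non-target segments not labelled with it. Computed over all segments of
#' the record (poor-quality segments must enter with prediction `"other"`,
#' which counts against sensitivity). Exact Clopper-Pearson 95% confidence
#' intervals are attached.
#'
#' @param pred,truth Character vectors of per-segment labels, equal length.
#' @param rhythm Target rhythm, `"brady"` or `"tachy"` (any label value
#'   works: comparison is `== rhythm`).
#' @param conf Confidence level.
#' @return An object of class `sens_spec`: list with `sensitivity`,
#'   `specificity`, their CIs, and the confusion counts (`tp`, `fp`, `tn`,
#'   `fn`). Sensitivity is `NA` when the record has no positive segments.
#' @export
sens_spec <- function(pred, truth, rhythm, conf = 0.95) {
  stopifnot(length(pred) == length(truth))
  pp <- pred == rhythm
  tp_ <- truth == rhythm
  tp <- sum(pp & tp_); fn <- sum(!pp & tp_)
  fp <- sum(pp & !tp_); tn <- sum(!pp & !tp_)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(rhythm = rhythm,
                 sensitivity = se, sensitivity_ci = clopper_pearson(tp, tp + fn, conf),
                 specificity = sp, specificity_ci = clopper_pearson(tn, tn + fp, conf),
                 tp = tp, fp = fp, tn = tn, fn = fn, conf = conf),
            class = "sens_spec")
}

#' @export
print.sens_spec <- function(x, ...) {
  fmt <- function(v, ci) {
    if (is.na(v)) return("undefined (no such segments)")
    sprintf("%.1f%% [%.1f, %.1f]", 100 * v, 100 * ci[1], 100 * ci[2])
  }
  cat(sprintf("%s detection (n = %d segments)\n", x$rhythm,
              x$tp + x$fp + x$tn + x$fn))
  cat("  sensitivity:", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity:", fmt(x$specificity, x$specificity_ci), "\n")
  invisible(x)
}

#' Cohen's kappa between two detectors' segment labels
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` on the contingency
#' table of the two label sequences. Returns `NA` when chance agreement is 1
#' (both raters degenerate on one category). An optional bootstrap over
#' segments yields a percentile confidence interval.
#'
#' @param labels_a,labels_b Character vectors of per-segment labels, equal
#'   length.
#' @param n_boot Number of bootstrap resamples for the CI (0 = none).
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return List with `kappa`, `p_observed`, `p_expected` and, when
#'   requested, `ci`.
#' @export
cohens_kappa <- function(labels_a, labels_b, n_boot = 0, conf = 0.95,
                         seed = NULL) {
  stopifnot(length(labels_a) == length(labels_b))
  kap <- function(a, b) {
    lev <- sort(unique(c(a, b)))
    ta <- table(factor(a, lev), factor(b, lev))
    n <- sum(ta)
    po <- sum(diag(ta)) / n
    pe <- sum(rowSums(ta) * colSums(ta)) / n^2
    if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
    (po - pe) / (1 - pe)
  }
  k <- kap(labels_a, labels_b)
  out <- list(kappa = k)
  lev <- sort(unique(c(labels_a, labels_b)))
  ta <- table(factor(labels_a, lev), factor(labels_b, lev))
  out$p_observed <- sum(diag(ta)) / sum(ta)
  out$p_expected <- sum(rowSums(ta) * colSums(ta)) / sum(ta)^2
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(labels_a)
    ks <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      kap(labels_a[idx], labels_b[idx])
    }, numeric(1))
    a <- 1 - conf
    out$ci <- stats::quantile(ks, c(a / 2, 1 - a / 2), na.rm = TRUE,
                              names = FALSE)
  }
  out
}

#' ROC sweep over detection thresholds
#'
#' Applies the strict detection rule `p > threshold` at each threshold and
#' computes segment-wise sensitivity and specificity against the truth.
#'
#' @param probabilities Per-segment arrhythmia probabilities.
#' @param truth Logical or 0/1 vector: segment truly of the target rhythm.
#' @param thresholds Thresholds to sweep.
#' @return Data frame with `threshold`, `sensitivity`, `specificity`,
#'   `fpr` (= 1 - specificity); sensitivity is non-increasing in the
#'   threshold.
#' @export
roc_sweep <- function(probabilities, truth,
                      thresholds = seq(0, 0.99, by = 0.01)) {
  truth <- as.logical(truth)
  out <- lapply(thresholds, function(th) {
    pos <- probabilities > th
    data.frame(threshold = th,
               sensitivity = if (any(truth)) mean(pos[truth]) else NA_real_,
               specificity = if (any(!truth)) mean(!pos[!truth]) else NA_real_)
  })
  out <- do.call(rbind, out)
  out$fpr <- 1 - out$specificity
  out
}
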