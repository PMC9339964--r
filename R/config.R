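#' Default run configuration
#'
#' All tunables of the pipeline in one nested list. Defaults equal the
#' method's stated operating values where one exists: sampling rate 100 Hz,
#' detection band 0.5-40 Hz, reference-detector band 0.5-6 Hz, 5-s windows,
#' quality band 0.6-3 Hz, conv kernels 13x13 (bradycardia) / 5x5
#' (tachycardia) with 32 kernels per layer, 2x2 average pooling stride 2,
#' 256 dense units, dropout 0.5, Adam learning rate 0.01, 70/30
#' train/validation split, pulse-quality correlation threshold 0.6, episode
#' rules <40 bpm / >120 bpm for at least 3 beats, and segment-overlap
#' labelling rules 50% (bradycardia) / 25% (tachycardia).
#'
#' @param ... Named overrides replacing individual fields, e.g.
#'   `default_config(cnn = list(max_epochs = 10))` replaces only the fields
#'   given and keeps the rest.
#' @return A nested configuration list of class `ppgarr_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    fs = 100,
    preprocess = list(band_low_hz = 0.5, band_high_hz = 40, filter_order = 4,
                      nlms_step = 0.02, nlms_reg = 1e-6, win_s = 5),
    quality = list(band_hz = c(0.6, 3)),
    scalogram = list(n_scales = 61, freq_range = c(0.3, 12), gamma = 3,
                     P2 = 60, normalize = TRUE),
    cnn = list(kernel = c(brady = 13, tachy = 5), n_kernels = 32,
               dense_units = 256, dropout = 0.5, learning_rate = 0.01,
               batch_size = 32, max_epochs = 100, patience = 5,
               val_fraction = 0.3, min_sensitivity = 0.98),
    reference = list(band_low_hz = 0.5, band_high_hz = 6, eta_c = 0.6,
                     refractory_s = 0.3, amp_factor = 0.5, amp_memory = 0.8,
                     template_len = 100, template_n = 8, max_lag = 5,
                     brady_bpm = 40, tachy_bpm = 120, min_beats = 3),
    labeling = list(brady_overlap = 0.5, tachy_overlap = 0.25),
    noise = list(lp_hz = 4)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  validate_config(cfg)
  class(cfg) <- "ppgarr_config"
  cfg
}

validate_config <- function(cfg) {
  p <- cfg$preprocess
  if (!(p$band_low_hz > 0 && p$band_low_hz < p$band_high_hz &&
        p$band_high_hz < cfg$fs / 2))
    stop("preprocess: band cutoffs must satisfy 0 < low < high < fs/2")
  if (!(p$nlms_step > 0 && p$nlms_step < 2))
    stop("preprocess: nlms_step must lie in (0, 2)")
  if (cfg$cnn$dropout < 0 || cfg$cnn$dropout >= 1)
    stop("cnn: dropout must lie in [0, 1)")
  if (cfg$cnn$val_fraction <= 0 || cfg$cnn$val_fraction >= 1)
    stop("cnn: val_fraction must lie in (0, 1)")
  if (cfg$reference$eta_c <= 0 || cfg$reference$eta_c >= 1)
    stop("reference: eta_c must lie in (0, 1)")
  invisible(cfg)
}

#' Read / write a configuration as JSON
#' @param cfg A configuration list from [default_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   configuration list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, raw)
}
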