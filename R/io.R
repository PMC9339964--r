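#' Read a PPG record from CSV or WFDB
#'
#' CSV records hold one sample per row (column `value`, or the first
#' numeric column). WFDB records are read from a `.hea` header plus a
#' format-16 (16-bit little-endian) `.dat` signal file; when the record has
#' several signals the channel whose description matches `channel` is used.
#' Signals sampled at other rates are resampled to 100 Hz by linear
#' interpolation. Episode annotations are loaded from a JSON sidecar
#' `<path>.json` (fields `start_s`, `end_s`, `rhythm`) when present.
#'
#' @param path CSV file path, or WFDB record path without extension.
#' @param format `"csv"` or `"wfdb"`.
#' @param fs Sampling rate of a CSV record in Hz (WFDB records carry their
#'   own).
#' @param target_fs Rate the signal is resampled to.
#' @param channel Regular expression selecting the WFDB channel (default
#'   matches pulse/PLETH channels; falls back to the first channel).
#' @return A [ppg_signal()] at `target_fs`.
#' @export
read_ppg <- function(path, format = c("csv", "wfdb"), fs = 100,
                     target_fs = 100, channel = "PLETH|PPG|Pleth") {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path)
    col <- if ("value" %in% names(df)) "value" else names(df)[1]
    x <- as.numeric(df[[col]])
  } else {
    hea <- paste0(path, ".hea")
    if (!file.exists(hea)) stop("WFDB header not found: ", hea)
    rec <- read_wfdb_record(path, channel)
    x <- rec$samples
    fs <- rec$fs
  }
  if (fs != target_fs) {
    n_out <- round(length(x) * target_fs / fs)
    x <- stats::approx(seq_along(x), x, n = n_out)$y
  }
  ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    rhythm = character(0), stringsAsFactors = FALSE)
  side <- paste0(if (format == "csv") path else paste0(path, ".hea"), ".json")
  if (file.exists(side)) ann <- read_annotations(side)
  ppg_signal(x, target_fs, ann)
}

#' Write a PPG record as CSV
#'
#' One sample per row (column `value`); annotations go to a JSON sidecar
#' `<path>.json`.
#'
#' @param ppg A [ppg_signal()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(ppg, path) {
  stopifnot(inherits(ppg, "ppg_signal"))
  utils::write.csv(data.frame(value = ppg$samples), path, row.names = FALSE)
  if (nrow(ppg$annotations) > 0)
    write_annotations(ppg$annotations, paste0(path, ".json"))
  invisible(path)
}

## Minimal WFDB support: single-segment records, format 16 (16-bit two's
## complement, little endian), interleaved channels.
read_wfdb_record <- function(path, channel = "PLETH|PPG|Pleth") {
  hea <- readLines(paste0(path, ".hea"), warn = FALSE)
  hea <- hea[!grepl("^#", hea) & nzchar(trimws(hea))]
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(strsplit(top[3], "/")[[1]][1]) else 250
  sig_lines <- hea[1 + seq_len(n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- as.integer(strsplit(f[2], "x|:|\\+")[[1]][1])
    gain <- if (length(f) >= 3) as.numeric(strsplit(f[3], "[(/]")[[1]][1]) else 200
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], fmt = fmt, gain = ifelse(is.na(gain) | gain == 0, 200, gain),
         baseline = {
           b <- regmatches(f[3], regexec("\\(([-0-9]+)\\)", f[3]))[[1]]
           if (length(b) == 2) as.numeric(b[2]) else 0
         },
         desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  if (any(vapply(sigs, function(s) s$fmt, numeric(1)) != 16))
    stop("only WFDB format 16 is supported")
  dat_path <- file.path(dirname(paste0(path, ".hea")), sigs[[1]]$file)
  raw <- readBin(dat_path, "integer", n = file.info(dat_path)$size / 2,
                 size = 2, signed = TRUE, endian = "little")
  n_samp <- length(raw) %/% n_sig
  m <- matrix(raw[seq_len(n_samp * n_sig)], nrow = n_sig)
  ch <- grep(channel, vapply(sigs, function(s) s$desc, character(1)))
  ch <- if (length(ch) > 0) ch[1] else 1L
  samples <- (m[ch, ] - sigs[[ch]]$baseline) / sigs[[ch]]$gain
  list(samples = samples, fs = fs)
}

#' Write a PPG record in WFDB format
#'
#' Single-channel, format 16 (16-bit little endian). Annotations are written
#' to `<record>.hea.json`.
#'
#' @param ppg A [ppg_signal()].
#' @param path Record path without extension.
#' @param gain Analogue-to-digital gain (units per physical unit); chosen
#'   automatically to use the 16-bit range when `NULL`.
#' @return `path`, invisibly.
#' @export
write_ppg_wfdb <- function(ppg, path, gain = NULL) {
  stopifnot(inherits(ppg, "ppg_signal"))
  rng <- max(abs(ppg$samples), 1e-9)
  if (is.null(gain)) gain <- floor(30000 / rng)
  dig <- as.integer(round(ppg$samples * gain))
  rec <- basename(path)
  hea <- c(sprintf("%s 1 %g %d", rec, ppg$fs, length(dig)),
           sprintf("%s.dat 16 %g(0)/au 16 0 %d 0 0 PLETH", rec, gain,
                   dig[1]))
  writeLines(hea, paste0(path, ".hea"))
  writeBin(dig, paste0(path, ".dat"), size = 2, endian = "little")
  if (nrow(ppg$annotations) > 0)
    write_annotations(ppg$annotations, paste0(path, ".hea.json"))
  invisible(path)
}

#' Read / write episode annotations as JSON intervals
#'
#' Annotations are a list of objects with `start_s`, `end_s` (half-open
#' interval, seconds from record start) and lowercase `rhythm`.
#'
#' @param annotations Data frame with `start_s`, `end_s`, `rhythm`.
#' @param path JSON file path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   the annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(df) == 0 || is.null(dim(df)))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      rhythm = character(0), stringsAsFactors = FALSE))
  data.frame(start_s = as.numeric(df$start_s), end_s = as.numeric(df$end_s),
             rhythm = as.character(df$rhythm), stringsAsFactors = FALSE)
}
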