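#' Read an EEG recording from disk
#'
#' Two dialects are supported: EDF (16-bit European Data Format; channel
#' labels, sampling rate and physical units are taken from the header) and
#' CSV (one column per channel, with a JSON sidecar `<path>.json` carrying
#' `rate`, `channels`, `condition`, `subject_id`). Samples are returned in
#' microvolts; EDF physical dimensions of uV, mV and V are rescaled, any
#' other unit is an error — never a silent rescale.
#'
#' @param path file path (`.edf` or `.csv`/`.tsv`).
#' @param dialect `"auto"` (by extension), `"edf"` or `"csv"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, dialect = c("auto", "edf", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (dialect == "edf") return(read_edf(path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort(sprintf("CSV sidecar not found: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$rate)) abort("sidecar lacks `rate`.")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "numeric")
  samples <- as.matrix(dat)
  storage.mode(samples) <- "double"
  eeg_recording(samples, rate = meta$rate,
                channels = meta$channels %||% colnames(samples),
                condition = meta$condition %||% NA_character_,
                subject_id = meta$subject_id %||% NA_character_)
}

#' Write an EEG recording to disk
#'
#' Inverse of [read_recording()]: CSV with JSON sidecar, or 16-bit EDF.
#' The CSV dialect round-trips samples bit-exactly; EDF quantises to the
#' 16-bit range of each channel.
#'
#' @param rec an [eeg_recording()].
#' @param path output path (`.edf` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(write_edf(rec, path))
  # 17 significant digits guarantee bit-exact double round-trips through text
  con <- file(path, "w")
  writeLines(paste(rec$channels, collapse = ","), con)
  body <- do.call(paste, c(lapply(seq_len(ncol(rec$samples)), function(j) {
    sprintf("%.17g", rec$samples[, j])
  }), sep = ","))
  writeLines(body, con)
  close(con)
  jsonlite::write_json(
    list(rate = rec$rate, channels = rec$channels,
         condition = rec$condition, subject_id = rec$subject_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

edf_unit_scale <- function(unit) {
  u <- trimws(unit)
  scale <- c("uV" = 1, "µV" = 1, "mV" = 1000, "V" = 1e6)
  if (!u %in% names(scale)) {
    abort(sprintf("unknown EDF physical dimension '%s'; refusing to rescale silently.", u))
  }
  scale[[u]]
}

#' Minimal EDF reader
#'
#' Reads a plain (continuous) EDF file: 256-byte fixed header, per-signal
#' header blocks, and int16 little-endian data records scaled from digital to
#' physical range per channel. Annotation channels are not supported. All
#' signals must share one sampling rate.
#'
#' @param path path to an `.edf` file.
#' @return An [eeg_recording()] in microvolts.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar) rawToChar(readBin(con, "raw", nchar))
  num <- function(nchar) as.numeric(trimws(rd(nchar)))
  rd(8) # version
  rd(80); rd(80) # patient, recording id
  rd(8); rd(8) # start date/time
  header_bytes <- num(8)
  rd(44) # reserved
  n_records <- num(8)
  record_seconds <- num(8)
  ns <- num(4)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "") # transducer
  units <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin_ <- vapply(seq_len(ns), function(i) num(8), 0)
  pmax_ <- vapply(seq_len(ns), function(i) num(8), 0)
  dmin_ <- vapply(seq_len(ns), function(i) num(8), 0)
  dmax_ <- vapply(seq_len(ns), function(i) num(8), 0)
  vapply(seq_len(ns), function(i) rd(80), "") # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) num(8), 0)
  vapply(seq_len(ns), function(i) rd(32), "") # reserved
  stopifnot(seek(con) == header_bytes)
  if (length(unique(nsamp / record_seconds)) != 1) {
    abort("EDF signals with differing sampling rates are not supported.")
  }
  rate <- nsamp[1] / record_seconds
  chans <- matrix(0, nrow = n_records * nsamp[1], ncol = ns)
  for (r in seq_len(n_records)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[j], size = 2, endian = "little")
      gain <- (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
      phys <- (dig - dmin_[j]) * gain + pmin_[j]
      phys <- phys * edf_unit_scale(units[j])
      chans[((r - 1) * nsamp[j] + 1):(r * nsamp[j]), j] <- phys
    }
  }
  eeg_recording(chans, rate = rate, channels = labels)
}

#' Minimal EDF writer
#'
#' Writes a continuous EDF file with one data record per second, physical
#' dimension uV, digital range -32768..32767 spanning each channel's physical
#' range. Trailing samples that do not fill a whole record are dropped.
#'
#' @param rec an [eeg_recording()]; `rec$rate` must be a whole number.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate != round(rec$rate)) abort("EDF writer requires an integer sampling rate.")
  ns <- ncol(rec$samples)
  nsamp <- as.integer(rec$rate)
  n_records <- floor(nrow(rec$samples) / nsamp)
  if (n_records < 1) abort("recording shorter than one 1 s EDF record.")
  x <- rec$samples[seq_len(n_records * nsamp), , drop = FALSE]
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, width) {
    s <- sprintf("%-*s", width, substr(as.character(s), 1, width))
    writeBin(charToRaw(s), con)
  }
  header_bytes <- 256 + 256 * ns
  put("0", 8)
  put("X X X X", 80); put(sprintf("Startdate X X X X cond_%s", rec$condition), 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(header_bytes, 8)
  put("", 44)
  put(n_records, 8)
  put("1", 8) # 1 s records
  put(ns, 4)
  for (lab in rec$channels) put(lab, 16)
  for (j in seq_len(ns)) put("", 80)
  for (j in seq_len(ns)) put("uV", 8)
  for (j in seq_len(ns)) put(format(pmin_[j], digits = 6), 8)
  for (j in seq_len(ns)) put(format(pmax_[j], digits = 6), 8)
  for (j in seq_len(ns)) put("-32768", 8)
  for (j in seq_len(ns)) put("32767", 8)
  for (j in seq_len(ns)) put("", 80)
  for (j in seq_len(ns)) put(nsamp, 8)
  for (j in seq_len(ns)) put("", 32)
  for (r in seq_len(n_records)) {
    for (j in seq_len(ns)) {
      seg <- x[((r - 1) * nsamp + 1):(r * nsamp), j]
      dig <- round((seg - pmin_[j]) / (pmax_[j] - pmin_[j]) * 65535 - 32768)
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Resample a recording (polyphase)
#'
#' Rational-ratio polyphase resampling of every channel (via
#' [signal::resample()]), e.g. from a 2048 Hz acquisition rate down to the
#' 128 Hz analysis rate.
#'
#' @param rec an [eeg_recording()].
#' @param new_rate target sampling rate (Hz); `new_rate / rate` must be a
#'   rational number with small terms.
#' @return A resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, new_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (new_rate == rec$rate) return(rec)
  fr <- MASS_fractions(new_rate / rec$rate)
  out <- apply(rec$samples, 2, function(ch) {
    if (fr[1] == 1) {
      # integer decimation: FIR anti-alias filtering in stages of at most 8x
      q <- fr[2]
      while (q > 1) {
        step_q <- if (q %% 8 == 0) 8 else if (q %% 4 == 0) 4 else if (q %% 2 == 0) 2 else q
        ch <- signal::decimate(ch, step_q, ftype = "fir")
        q <- q / step_q
      }
      ch
    } else {
      signal::resample(ch, fr[1], fr[2])
    }
  })
  eeg_recording(out, rate = new_rate, channels = rec$channels,
                condition = rec$condition, subject_id = rec$subject_id)
}

# small rational approximation p/q of a ratio
MASS_fractions <- function(r, max_q = 4096) {
  for (q in seq_len(max_q)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  abort("resampling ratio is not a small rational number.")
}

#' Write a segmentation as BED-like TSV
#'
#' Columns: `channel`, `start_s`, `end_s`, `kind`, `area_uVs`, `truncated`.
#' Times are seconds from recording start, half-open intervals
#' `[start_s, end_s)`.
#'
#' @param segments a `segment_set`, or a tibble of several (with a `channel`
#'   column).
#' @param path output path.
#' @param channel channel label used when `segments` lacks one.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path, channel = "ch1") {
  df <- as_tibble(segments)
  if (!"channel" %in% names(df)) df$channel <- channel
  out <- df |>
    dplyr::transmute(channel = .data$channel, start_s = .data$start_time,
                     end_s = .data$end_time, kind = .data$kind,
                     area_uVs = .data$area, truncated = .data$truncated)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tidy metrics CSV
#'
#' Long format: `subject`, `condition`, `channel`, `metric`, `value`.
#'
#' @param metrics wide per-channel metric tibble (as from [cohort_metrics()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  id_cols <- intersect(c("subject", "condition", "channel"), names(metrics))
  long <- metrics |>
    tidyr::pivot_longer(-dplyr::all_of(id_cols), names_to = "metric",
                        values_to = "value")
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
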