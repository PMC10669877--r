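#' EEG recording container
#'
#' A light container for a multichannel EEG recording: a numeric sample matrix
#' (rows = time points, columns = channels, amplitudes in microvolts), a
#' sampling rate in Hz, channel labels, and optional condition / subject
#' metadata. All downstream functions ([compute_asd()], [hvp_pipeline()],
#' [comparator_metrics()], ...) consume either a single numeric channel vector
#' or one of these objects.
#'
#' @param samples numeric vector (single channel) or matrix with one column per
#'   channel, amplitudes in microvolts.
#' @param rate sampling rate in Hz (samples per second); must be positive.
#' @param channels character vector of channel labels; defaults to the matrix
#'   column names or `ch1 ... chk`.
#' @param condition free-form state label (e.g. `"EC"`, `"EO"`, `"rest"`).
#' @param subject_id opaque subject identifier.
#'
#' @return An object of class `eeg_recording` with fields `samples` (matrix),
#'   `rate`, `channels`, `condition`, `subject_id` and derived `duration`
#'   (seconds).
#' @examples
#' rec <- eeg_recording(matrix(rnorm(256), ncol = 2), rate = 128)
#' rec$duration # 1 second
#' @export
eeg_recording <- function(samples, rate, channels = NULL, condition = NA_character_,
                          subject_id = NA_character_) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric vector or matrix (time x channels).")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  if (is.null(channels)) {
    channels <- colnames(samples) %||% paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channels) != ncol(samples)) {
    abort("`channels` must have one label per sample column.")
  }
  colnames(samples) <- channels
  structure(
    list(
      samples = samples,
      rate = rate,
      channels = channels,
      condition = condition,
      subject_id = subject_id,
      duration = nrow(samples) / rate
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) x %.1f s @ %g Hz%s%s\n",
    length(x$channels), x$duration, x$rate,
    if (!is.na(x$condition)) paste0(", condition=", x$condition) else "",
    if (!is.na(x$subject_id)) paste0(", subject=", x$subject_id) else ""
  ))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn eeg_recording long-format tibble (`time`, `channel`, `amplitude`).
#' @param x an `eeg_recording`.
#' @param ... unused.
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble(
    time = rep((seq_len(nrow(x$samples)) - 1) / x$rate, times = ncol(x$samples)),
    channel = rep(x$channels, each = nrow(x$samples)),
    amplitude = as.vector(x$samples)
  )
}

#' Extract one channel from a recording
#'
#' @param rec an [eeg_recording()].
#' @param channel channel label or index.
#' @return numeric vector of samples (microvolts).
#' @export
channel_samples <- function(rec, channel = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(channel) && !channel %in% rec$channels) {
    abort(sprintf("channel '%s' not present (have: %s)", channel,
                  paste(rec$channels, collapse = ", ")))
  }
  as.numeric(rec$samples[, channel])
}

#' Electrode subsets used for reduced-montage analysis
#'
#' Named frontal/temporal subsets of the 14-channel saline headset montage:
#' `F8` (six fronto-lateral channels), `F4_1`, `F4_2` (four frontal channels
#' each) and `T4` (four temporal channels). `ALL` means every channel present.
#'
#' @param name one of `"ALL"`, `"F8"`, `"F4_1"`, `"F4_2"`, `"T4"`, or a
#'   character vector of explicit channel labels (returned as-is).
#' @param available optional character vector of available channels; when
#'   given, `"ALL"` resolves to it and membership is checked.
#' @return character vector of channel labels.
#' @examples
#' electrode_subset("T4")
#' @export
electrode_subset <- function(name, available = NULL) {
  subsets <- list(
    F8   = c("AF3", "AF4", "F7", "F8", "FC5", "FC6"),
    F4_1 = c("F3", "F4", "F7", "F8"),
    F4_2 = c("AF3", "AF4", "F7", "F8"),
    T4   = c("T7", "T8", "FC5", "FC6")
  )
  if (length(name) == 1L && name %in% c("ALL", names(subsets))) {
    labels <- if (name == "ALL") available %||% "ALL" else subsets[[name]]
  } else {
    labels <- name
  }
  if (!is.null(available) && !identical(labels, "ALL")) {
    missing <- setdiff(labels, available)
    if (length(missing) > 0) {
      abort(sprintf("channels not available: %s", paste(missing, collapse = ", ")))
    }
  }
  labels
}
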