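#' Moving-window analysis parameters
#'
#' Parameters of the moving-window amplitude-SD analysis: the window length
#' `m` in seconds, the fractional overlap between successive windows, and the
#' rank percentile used for the variability threshold.
#'
#' Defaults follow the recommended operating point for multi-minute resting
#' recordings: 10 s windows, 50% overlap, 25th-percentile ("quartile")
#' threshold. For short (5 min) anesthesia blocks a 3 s window is conventional;
#' set `window_seconds = 3`.
#'
#' @param window_seconds window length m in seconds (> 0).
#' @param overlap fraction of a window shared with its successor, in \[0, 1).
#' @param percentile threshold rank percentile p, in (0, 100).
#' @return A `window_params` list with `window_seconds`, `overlap`,
#'   `percentile` and derived `step_seconds = window_seconds * (1 - overlap)`.
#' @examples
#' window_params() # 10 s, 50% overlap, quartile threshold
#' window_params(3, 0.5, 25) # anesthesia-block setting
#' @export
window_params <- function(window_seconds = 10, overlap = 0.5, percentile = 25) {
  if (window_seconds <= 0) abort("`window_seconds` must be > 0.")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must lie in [0, 1).")
  if (percentile <= 0 || percentile >= 100) abort("`percentile` must lie in (0, 100).")
  structure(
    list(
      window_seconds = window_seconds,
      overlap = overlap,
      percentile = percentile,
      step_seconds = window_seconds * (1 - overlap)
    ),
    class = "window_params"
  )
}

as_window_params <- function(params) {
  if (inherits(params, "window_params")) return(params)
  do.call(window_params, as.list(params))
}

#' Moving-window amplitude standard deviation (A_SD)
#'
#' Slides a window of `m` seconds along a single EEG channel, advancing by
#' `m * (1 - overlap)` seconds, and computes within each window the standard
#' deviation of the amplitude about the window mean, using the population
#' denominator `m * s` (the number of samples in the window), not the n-1
#' sample estimator. Trailing samples that do not fill a complete window are
#' dropped.
#'
#' @param x numeric vector of single-channel samples (microvolts), or an
#'   [eeg_recording()] together with `channel`.
#' @param rate sampling rate in Hz (ignored when `x` is a recording).
#' @param params a [window_params()] object (or list coercible to one).
#' @param channel channel label/index when `x` is a recording.
#' @return An `asd_trace` object: tibble with columns `window` (index),
#'   `start_time` (s), `asd` (microvolts), and attributes `step_seconds`,
#'   `window_seconds`, `rate`.
#' @examples
#' tr <- compute_asd(rnorm(1280, sd = 10), rate = 128, window_params(2, 0.5))
#' tr
#' @export
compute_asd <- function(x, rate = NULL, params = window_params(), channel = 1L) {
  if (inherits(x, "eeg_recording")) {
    rate <- x$rate
    x <- channel_samples(x, channel)
  }
  if (is.null(rate)) abort("`rate` must be supplied for a plain sample vector.")
  params <- as_window_params(params)
  bad <- which(!is.finite(x))
  if (length(bad) > 0) {
    abort(sprintf("non-finite sample at index %d.", bad[[1]]))
  }
  w <- round(params$window_seconds * rate)
  if (w < 2) abort("window must span at least 2 samples (window_seconds * rate >= 2).")
  if (length(x) < w) {
    abort(sprintf("signal too short: %d samples < one window of %d samples.",
                  length(x), w))
  }
  step <- max(1L, round(params$step_seconds * rate))
  starts <- seq.int(1L, length(x) - w + 1L, by = step)
  # population SD per window via cumulative sums (O(n))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  s1 <- cs[starts + w] - cs[starts]
  s2 <- cs2[starts + w] - cs2[starts]
  v <- pmax(0, s2 / w - (s1 / w)^2)
  trace <- tibble(
    window = seq_along(starts),
    start_time = (starts - 1) / rate,
    asd = sqrt(v)
  )
  structure(trace,
    class = c("asd_trace", class(trace)),
    step_seconds = step / rate,
    window_seconds = params$window_seconds,
    rate = rate
  )
}

#' Build an A_SD trace from bare values
#'
#' Constructs an `asd_trace` directly from a vector of windowed SD values and
#' a window spacing, for use when the windowed values come from elsewhere
#' (e.g. the per-window harmonic amplitudes of [hr_duration()]).
#'
#' @param values non-negative numeric vector of windowed values.
#' @param step_seconds spacing between successive window starts (s).
#' @param window_seconds window length m (s); defaults to `step_seconds`.
#' @param rate optional sampling rate (Hz), metadata only.
#' @return An `asd_trace` (see [compute_asd()]).
#' @examples
#' segment_trace(asd_trace(c(1, 5, 5, 1, 5, 1), step_seconds = 5), 2)
#' @export
asd_trace <- function(values, step_seconds, window_seconds = NULL, rate = NULL) {
  trace <- tibble::new_tibble(
    list(
      window = seq_along(values),
      start_time = (seq_along(values) - 1) * step_seconds,
      asd = as.numeric(values)
    ),
    nrow = length(values)
  )
  structure(trace,
    class = c("asd_trace", class(trace)),
    step_seconds = step_seconds,
    window_seconds = window_seconds %||% step_seconds,
    rate = rate
  )
}

#' Rank-percentile variability threshold
#'
#' The threshold T is the i-th value of the rank-ordered (ascending) A_SD
#' values, with the nearest-rank index `i = ceiling(p * n / 100)` clamped to
#' `[1, n]`. At the default p = 25 this is the "quartile cutoff"; p = 10 and
#' p = 50 are the other operating points commonly explored.
#'
#' @param asd an `asd_trace` from [compute_asd()], or a bare numeric vector of
#'   A_SD values.
#' @param percentile rank percentile p in (0, 100).
#' @return An `asd_threshold` list: `value` (microvolts), `percentile`,
#'   `source_rank_index`, `n`, `source_condition`.
#' @param source_condition optional label of the recording condition the
#'   threshold is anchored to.
#' @examples
#' compute_threshold(c(8, 3, 5, 1, 7, 2, 6, 4), percentile = 25) # T = 2
#' @export
compute_threshold <- function(asd, percentile = 25, source_condition = NA_character_) {
  values <- if (inherits(asd, "asd_trace")) asd$asd else as.numeric(asd)
  n <- length(values)
  if (n < 4) abort("need at least 4 A_SD values for a rank threshold (n >= 4).")
  if (percentile <= 0 || percentile >= 100) abort("`percentile` must lie in (0, 100).")
  i <- min(n, max(1L, as.integer(ceiling(percentile * n / 100))))
  structure(
    list(
      value = sort(values)[i],
      percentile = percentile,
      source_rank_index = i,
      n = n,
      source_condition = source_condition
    ),
    class = "asd_threshold"
  )
}

#' @export
print.asd_threshold <- function(x, ...) {
  cat(sprintf("<asd_threshold> T = %.4g uV (p%g, rank %d of %d%s)\n",
              x$value, x$percentile, x$source_rank_index, x$n,
              if (!is.na(x$source_condition)) paste0(", anchored to ", x$source_condition) else ""))
  invisible(x)
}

#' Segment an A_SD trace into high/low variability periods
#'
#' Maximal runs of consecutive windows whose A_SD is strictly above the
#' threshold T become high variability periods (HVPs); runs at or below T
#' become low variability periods (LVPs). A value exactly equal to T counts as
#' low, preserving the strictly-supra-threshold HVP definition. Segment
#' boundaries are placed at window start times, so a run of k windows has
#' duration `k * step_seconds` — the time between threshold crossings on the
#' window grid. HVP area is the run's summed A_SD times `step_seconds`
#' (microvolt-seconds). The first and last segments abut the recording
#' boundary and are flagged `truncated`.
#'
#' @param asd an `asd_trace` from [compute_asd()].
#' @param threshold an `asd_threshold`, or a single number (microvolts).
#' @return A `segment_set`: tibble with columns `segment`, `kind`
#'   (`"HVP"`/`"LVP"`), `start_time`, `end_time`, `duration`, `n_windows`,
#'   `area` (NA for LVPs), `truncated`; attributes carry the threshold and
#'   window parameters.
#' @examples
#' tr <- asd_trace(c(1, 5, 5, 1, 5, 1), step_seconds = 5)
#' segment_trace(tr, 2)
#' @export
segment_trace <- function(asd, threshold) {
  if (!inherits(asd, "asd_trace")) abort("`asd` must be an `asd_trace`.")
  if (nrow(asd) == 0) abort("empty A_SD trace.")
  if (inherits(threshold, "asd_threshold")) {
    tval <- threshold$value
  } else {
    tval <- as.numeric(threshold)
    threshold <- structure(list(value = tval, percentile = NA_real_,
                                source_rank_index = NA_integer_, n = nrow(asd),
                                source_condition = NA_character_),
                           class = "asd_threshold")
  }
  if (!is.finite(tval) || tval < 0) abort("threshold must be finite and >= 0.")
  step <- attr(asd, "step_seconds")
  supra <- asd$asd > tval
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts_idx <- ends - r$lengths + 1L
  seg_start <- asd$start_time[starts_idx]
  seg_end <- seg_start + r$lengths * step
  cs <- cumsum(c(0, asd$asd))
  area <- (cs[ends + 1L] - cs[starts_idx]) * step
  area[!r$values] <- NA_real_
  nseg <- length(r$lengths)
  truncated <- rep(FALSE, nseg)
  truncated[c(1L, nseg)] <- TRUE
  segs <- tibble::new_tibble(
    list(
      segment = seq_len(nseg),
      kind = ifelse(r$values, "HVP", "LVP"),
      start_time = seg_start,
      end_time = seg_end,
      duration = r$lengths * step,
      n_windows = r$lengths,
      area = area,
      truncated = truncated
    ),
    nrow = nseg
  )
  structure(segs,
    class = c("segment_set", class(segs)),
    threshold = threshold,
    step_seconds = step,
    window_seconds = attr(asd, "window_seconds"),
    n_trace_windows = nrow(asd)
  )
}

#' Summarise a segmentation into HVP metrics
#'
#' Computes the five summary metrics of a high/low-variability segmentation:
#' mean HVP duration (HVP-D, s), mean HVP area (HVP-A, microvolt-seconds),
#' mean LVP duration (LVP-D, s), HVP rate (HVP-R, events per minute of
#' recording) and the HVP-D / LVP-D duration ratio. A recording with no
#' supra-threshold window (the deep-anesthesia case) yields
#' `hvp_d = hvp_a = hvp_r = 0`.
#'
#' @param segments a `segment_set` from [segment_trace()].
#' @param recording_duration total recording length in seconds, used for the
#'   per-minute rate. Defaults to the segmented (windowed) time span.
#' @param include_truncated include boundary-truncated segments in the means
#'   (default TRUE).
#' @param duration `"crossing"` (default) measures run durations as
#'   `run_length * step_seconds` (time between threshold crossings);
#'   `"literal"` multiplies run lengths by the full window length m instead,
#'   reproducing the overlap-blind textbook formula for audit.
#' @return One-row tibble: `hvp_d`, `hvp_a`, `lvp_d`, `hvp_r`, `ratio`,
#'   `n_hvp`, `n_lvp`. `ratio` is `NA` when no LVP exists.
#' @export
hvp_summary <- function(segments, recording_duration = NULL,
                        include_truncated = TRUE,
                        duration = c("crossing", "literal")) {
  if (!inherits(segments, "segment_set")) abort("`segments` must be a `segment_set`.")
  duration <- match.arg(duration)
  segs <- segments
  if (!include_truncated) segs <- segs[!segs$truncated, , drop = FALSE]
  if (is.null(recording_duration)) {
    recording_duration <- attr(segments, "n_trace_windows") * attr(segments, "step_seconds")
  }
  dur <- if (duration == "literal") {
    segs$n_windows * attr(segments, "window_seconds")
  } else {
    segs$duration
  }
  hvp <- segs$kind == "HVP"
  n_hvp <- sum(hvp)
  n_lvp <- sum(!hvp)
  tibble(
    hvp_d = if (n_hvp > 0) mean(dur[hvp]) else 0,
    hvp_a = if (n_hvp > 0) mean(segs$area[hvp]) else 0,
    lvp_d = if (n_lvp > 0) mean(dur[!hvp]) else 0,
    hvp_r = n_hvp * 60 / recording_duration,
    ratio = {
      lv <- if (n_lvp > 0) mean(dur[!hvp]) else 0
      hv <- if (n_hvp > 0) mean(dur[hvp]) else 0
      if (lv > 0) hv / lv else NA_real_
    },
    n_hvp = n_hvp,
    n_lvp = n_lvp
  )
}

#' Full single-channel HVP pipeline
#'
#' Convenience wrapper: A_SD trace, percentile threshold (optionally anchored
#' to an externally supplied threshold), segmentation and summary for one
#' channel of a recording.
#'
#' @inheritParams compute_asd
#' @param threshold optional fixed `asd_threshold` (or microvolt value) from a
#'   baseline condition; when NULL the trace's own percentile threshold is used.
#' @param ... passed to [hvp_summary()] (`include_truncated`, `duration`).
#' @return One-row tibble of HVP metrics (see [hvp_summary()]); the
#'   `segment_set` and threshold are attached as attributes `segments` and
#'   `threshold`.
#' @examples
#' rec <- synth_recording(synth_config(duration = 120, seed = 1))$recording
#' hvp_pipeline(rec, params = window_params(10, 0.5, 25))
#' @export
hvp_pipeline <- function(x, rate = NULL, params = window_params(), channel = 1L,
                         threshold = NULL, ...) {
  params <- as_window_params(params)
  if (inherits(x, "eeg_recording")) {
    rate <- x$rate
    dur <- x$duration
    x <- channel_samples(x, channel)
  } else {
    dur <- length(x) / rate
  }
  asd <- compute_asd(x, rate, params)
  thr <- threshold %||% compute_threshold(asd, params$percentile)
  segs <- segment_trace(asd, thr)
  out <- hvp_summary(segs, recording_duration = dur, ...)
  attr(out, "segments") <- segs
  attr(out, "threshold") <- attr(segs, "threshold")
  out
}
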