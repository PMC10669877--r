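#' Baseline-anchored HVP metrics across conditions
#'
#' When comparing conditions (e.g. eyes-closed rest against eyes-open tasks,
#' or rest against anesthesia blocks), the variability threshold must be the
#' same absolute microvolt value in every condition, otherwise each condition
#' is segmented against its own amplitude scale and the comparison is
#' meaningless. Per channel, the rank-percentile threshold is computed from
#' the baseline recording and applied unchanged to every target condition.
#'
#' @param baseline an [eeg_recording()] providing the anchoring condition
#'   (conventionally resting eyes-closed, or the pre-anesthesia rest block).
#' @param targets a list of [eeg_recording()]s sharing the baseline's channel
#'   set and rate; the baseline itself is always included in the output.
#' @param params a [window_params()].
#' @param channels channels to process (default: all shared channels).
#' @param ... passed to [hvp_summary()].
#' @return Tibble with one row per condition x channel: `condition`,
#'   `channel`, `threshold_uV`, and the [hvp_summary()] metric columns.
#'   Channel-averaged rows per condition are available via
#'   [average_channels()].
#' @examples
#' coh <- synth_condition_pair(seed = 1)
#' anchored_pipeline(coh$EC, list(coh$EO), window_params())
#' @export
anchored_pipeline <- function(baseline, targets, params = window_params(),
                              channels = NULL, ...) {
  stopifnot(inherits(baseline, "eeg_recording"))
  if (inherits(targets, "eeg_recording")) targets <- list(targets)
  params <- as_window_params(params)
  for (tg in targets) {
    if (!setequal(tg$channels, baseline$channels) || tg$rate != baseline$rate) {
      asym <- c(setdiff(baseline$channels, tg$channels),
                setdiff(tg$channels, baseline$channels))
      abort(sprintf(
        "target condition '%s' does not match baseline montage/rate (asymmetric channels: %s)",
        tg$condition, if (length(asym)) paste(asym, collapse = ", ") else "rate differs"))
    }
  }
  channels <- channels %||% baseline$channels
  recs <- c(list(baseline), targets)
  purrr::map_dfr(recs, function(rec) {
    purrr::map_dfr(channels, function(ch) {
      thr <- compute_threshold(
        compute_asd(baseline, params = params, channel = ch),
        params$percentile,
        source_condition = baseline$condition
      )
      m <- hvp_pipeline(rec, params = params, channel = ch, threshold = thr, ...)
      dplyr::bind_cols(
        tibble(condition = rec$condition, channel = ch, threshold_uV = thr$value),
        m
      )
    })
  })
}

#' Average per-channel metrics within subject
#'
#' Collapses a per-channel metric table to one row per subject/condition by
#' unweighted averaging over channels (optionally restricted to a named
#' electrode subset).
#'
#' @param metrics tibble with a `channel` column and numeric metric columns
#'   (as from [anchored_pipeline()] or [cohort_metrics()]).
#' @param subset electrode subset name or label vector (see
#'   [electrode_subset()]); default `"ALL"`.
#' @return Tibble with the `channel` column dropped and metrics averaged
#'   within the remaining grouping columns (any of `subject`, `condition`).
#' @export
average_channels <- function(metrics, subset = "ALL") {
  keep <- electrode_subset(subset, available = unique(metrics$channel))
  if (!identical(keep, "ALL")) metrics <- dplyr::filter(metrics, .data$channel %in% keep)
  group_cols <- intersect(c("subject", "subject_id", "condition"), names(metrics))
  metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::select(-dplyr::any_of(c("channel", "threshold_uV")))
}

#' Two-stage group summary of HVP metrics
#'
#' Group means are computed by first averaging each metric across channels
#' within each subject and then taking the mean and standard error of those
#' subject averages across subjects.
#'
#' @param metrics tibble with columns `subject` (or `subject_id`), optionally
#'   `condition` and `channel`, plus numeric metric columns.
#' @param metric_cols metric columns to summarise (default: all numeric
#'   columns except bookkeeping counts).
#' @return Tibble with one row per condition x metric: `condition` (if
#'   present), `metric`, `mean`, `sem`, `n_subjects`. `sem` is `NA` for a
#'   single subject.
#' @examples
#' df <- tibble::tibble(subject = rep(1:2, each = 2), channel = rep(c("a", "b"), 2),
#'                      hvp_d = c(3, 5, 5, 7))
#' aggregate_metrics(df) # subject means 4 and 6 -> group mean 5, SEM 1
#' @export
aggregate_metrics <- function(metrics, metric_cols = NULL) {
  if (nrow(metrics) == 0) abort("empty metrics table.")
  if (!"subject" %in% names(metrics) && "subject_id" %in% names(metrics)) {
    metrics <- dplyr::rename(metrics, subject = "subject_id")
  }
  if (!"subject" %in% names(metrics)) abort("metrics must have a `subject` column.")
  per_subject <- if ("channel" %in% names(metrics)) {
    average_channels(metrics)
  } else {
    metrics
  }
  metric_cols <- metric_cols %||%
    setdiff(names(per_subject)[vapply(per_subject, is.numeric, logical(1))],
            c("subject", "n_hvp", "n_lvp"))
  group_cols <- intersect("condition", names(per_subject))
  per_subject |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "metric")))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = if (dplyr::n() > 1) sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))) else NA_real_,
      n_subjects = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-channel HVP metrics for a labelled cohort
#'
#' Runs the baseline-anchored pipeline for every subject of a cohort tibble
#' (as produced by [synth_cohort()] or assembled from [read_recording()]
#' calls) and returns a tidy per-subject, per-condition, per-channel metric
#' table.
#'
#' @param cohort tibble with columns `subject`, `condition`, `recording`
#'   (list-column of [eeg_recording()]s).
#' @param baseline_condition condition label anchoring the threshold; `NULL`
#'   thresholds each condition on itself.
#' @param params a [window_params()].
#' @param ... passed to [hvp_summary()].
#' @return Tibble: `subject`, `condition`, `channel`, `threshold_uV`, metrics.
#' @export
cohort_metrics <- function(cohort, baseline_condition = NULL,
                           params = window_params(), ...) {
  stopifnot(all(c("subject", "condition", "recording") %in% names(cohort)))
  params <- as_window_params(params)
  cohort |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(rows, key) {
      recs <- rows$recording
      names(recs) <- rows$condition
      out <- if (is.null(baseline_condition)) {
        purrr::map_dfr(recs, function(rec) {
          purrr::map_dfr(rec$channels, function(ch) {
            m <- hvp_pipeline(rec, params = params, channel = ch, ...)
            thr <- attr(m, "threshold")
            dplyr::bind_cols(tibble(condition = rec$condition, channel = ch,
                                    threshold_uV = thr$value), m)
          })
        })
      } else {
        if (!baseline_condition %in% names(recs)) {
          abort(sprintf("subject %s lacks baseline condition '%s'",
                        key$subject, baseline_condition))
        }
        anchored_pipeline(recs[[baseline_condition]],
                          recs[names(recs) != baseline_condition],
                          params = params, ...)
      }
      dplyr::bind_cols(tibble(subject = key$subject), out)
    }) |>
    dplyr::bind_rows()
}
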