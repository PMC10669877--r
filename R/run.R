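#' Run a full analysis pipeline from a configuration
#'
#' Orchestrates the end-to-end analysis: load (or synthesise) recordings,
#' compute baseline-anchored HVP metrics per channel, write segment and
#' metric tables, condition comparisons, an optional classification report,
#' and a manifest recording every parameter needed to reproduce the run.
#' Deterministic under `config$seed`.
#'
#' @param config a named list (or YAML file path, read with
#'   `yaml::read_yaml()`) with entries:
#'   \describe{
#'     \item{inputs}{named list condition -> recording path; or `simulate`
#'       (list of [synth_cohort()] arguments) for a synthetic cohort.}
#'     \item{baseline}{condition label anchoring the threshold (optional).}
#'     \item{window}{list of [window_params()] arguments.}
#'     \item{classify}{optional list: `pair` (two condition labels),
#'       `feature_set`, `electrodes`.}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed.}
#'   }
#' @return Invisibly, a list with the output paths and the in-memory metric
#'   tables (`metrics`, `comparisons`, `classification`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("yaml package required for YAML configs.")
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% abort("config lacks `out_dir`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(window_params, config$window %||% list())
  seed <- config$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cohort <- stage("load", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% seed
      if (!is.null(args$base)) args$base <- do.call(synth_config, args$base)
      do.call(synth_cohort, args)
    } else {
      if (is.null(config$inputs)) abort("config needs `inputs` or `simulate`.")
      purrr::imap_dfr(config$inputs, function(path, cond) {
        if (!file.exists(path)) abort(sprintf("input path does not exist: %s", path))
        rec <- read_recording(path)
        rec$condition <- cond
        tibble(subject = rec$subject_id %||% "S01", condition = cond,
               recording = list(rec))
      })
    }
  })

  metrics <- stage("hvp_metrics", {
    cohort_metrics(cohort, baseline_condition = config$baseline, params = params)
  })
  metrics_path <- file.path(out_dir, "metrics.csv")
  write_metrics_csv(metrics, metrics_path)

  segments_path <- file.path(out_dir, "segments.tsv")
  stage("segments", {
    seg_tables <- purrr::pmap_dfr(
      cohort[c("subject", "condition", "recording")],
      function(subject, condition, recording) {
        purrr::map_dfr(recording$channels, function(ch) {
          m <- hvp_pipeline(recording, params = params, channel = ch)
          segs <- as_tibble(attr(m, "segments"))
          dplyr::bind_cols(tibble(subject = subject, condition = condition,
                                  channel = ch), segs)
        })
      })
    write_segments_tsv(seg_tables, segments_path)
  })

  per_subject <- average_channels(metrics)
  comparisons <- NULL
  comparisons_path <- NULL
  if (length(unique(per_subject$condition)) >= 2 &&
      all(table(per_subject$condition) >= 3)) {
    comparisons <- stage("comparisons", compare_conditions(per_subject))
    comparisons_path <- file.path(out_dir, "comparisons.csv")
    utils::write.csv(comparisons, comparisons_path, row.names = FALSE)
  }

  classification <- NULL
  classification_path <- NULL
  if (!is.null(config$classify)) {
    classification <- stage("classify", {
      pair <- config$classify$pair
      feats <- build_features(
        dplyr::filter(metrics, .data$condition %in% pair),
        feature_set = config$classify$feature_set %||% "hvp",
        channel_subset = config$classify$electrodes %||% "ALL"
      )
      train_eval(feats, seed = seed)
    })
    classification_path <- file.path(out_dir, "classification.json")
    jsonlite::write_json(
      list(summary = classification$summary,
           per_repeat = classification$per_repeat,
           config = classification$config,
           positive_class = classification$positive_class),
      classification_path, auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    window_seconds = params$window_seconds,
    overlap = params$overlap,
    percentile = params$percentile,
    step_seconds = params$step_seconds,
    baseline = config$baseline,
    seed = seed,
    thresholds_uV = metrics |>
      dplyr::distinct(.data$subject, .data$condition, .data$channel, .data$threshold_uV),
    classifier = if (!is.null(classification)) classification$config,
    outputs = list(metrics = metrics_path, segments = segments_path,
                   comparisons = comparisons_path,
                   classification = classification_path)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(metrics = metrics, comparisons = comparisons,
                 classification = classification,
                 manifest = file.path(out_dir, "manifest.json"),
                 out_dir = out_dir))
}
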