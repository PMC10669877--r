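#' Assemble a per-subject feature table
#'
#' Builds the classification feature table: one row per (subject, condition)
#' pair, columns = channel-averaged metrics restricted to a named feature set
#' and electrode subset. Channel averaging happens after the subset
#' restriction.
#'
#' Feature sets: `"hvp"` = the three numbered HVP metrics (mean HVP duration,
#' mean HVP area, mean LVP duration); `"other"` = sample entropy +
#' harmonic-regression duration; `"spectral"` = five relative band powers +
#' theta/beta ratio; `"all"` = all eleven.
#'
#' @param metrics tibble with columns `subject`, `condition`, `channel` and
#'   numeric metric columns (HVP metrics from [cohort_metrics()] joined with
#'   [comparator_metrics()] outputs as needed).
#' @param feature_set `"hvp"`, `"other"`, `"spectral"`, `"all"`, or an
#'   explicit character vector of metric columns.
#' @param channel_subset electrode subset name (see [electrode_subset()]) or
#'   label vector.
#' @return Tibble: `subject`, `condition`, then one column per feature; no
#'   missing values (an error names the offending subject/field otherwise).
#' @export
build_features <- function(metrics, feature_set = "hvp", channel_subset = "ALL") {
  sets <- list(
    hvp = c("hvp_d", "hvp_a", "lvp_d"),
    other = c("sample_entropy", "hr_duration"),
    spectral = c("delta", "theta", "alpha", "beta", "gamma", "theta_beta_ratio")
  )
  sets$all <- unlist(sets, use.names = FALSE)
  cols <- if (length(feature_set) == 1L && feature_set %in% names(sets)) {
    sets[[feature_set]]
  } else {
    feature_set
  }
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols) > 0) {
    abort(sprintf("metrics table lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  raw <- metrics |>
    dplyr::select(dplyr::all_of(c("subject", "condition", "channel", cols)))
  bad <- raw |>
    tidyr::pivot_longer(dplyr::all_of(cols)) |>
    dplyr::filter(!is.finite(.data$value))
  if (nrow(bad) > 0) {
    abort(sprintf("missing/non-finite feature: subject %s, field %s (channel %s)",
                  bad$subject[1], bad$name[1], bad$channel[1]))
  }
  average_channels(raw, subset = channel_subset)
}

#' Gradient-boosted discrimination of two conditions
#'
#' The discrimination protocol: repeated 75/25 train/test splits, a boosted
#' decision-tree ensemble (logistic objective, maximum depth 3, 50 boosting
#' rounds) per split, and held-out accuracy, sensitivity, specificity,
#' recall, precision and F1 averaged over repeats. Splits are made at the
#' subject level by default, keeping both of a subject's condition rows in
#' the same partition so no subject leaks between train and test; set
#' `split_unit = "row"` for the leakier row-level split for audit.
#'
#' The positive class is the second condition label alphabetically.
#'
#' @param features feature table from [build_features()] with exactly two
#'   condition labels.
#' @param train_fraction fraction of split units used for training (0.75).
#' @param max_depth,nrounds booster tree depth (3) and boosting rounds (50).
#' @param n_repeats number of independent splits (10).
#' @param split_unit `"subject"` (default) or `"row"`.
#' @param eta booster learning rate (library default 0.3).
#' @param seed integer seed; fixes the whole sequence of splits.
#' @return An `hvp_classifier` list: `per_repeat` tibble (one row per repeat
#'   with all scores), `summary` (mean over repeats), `config`,
#'   `positive_class`. `glance()` returns the one-row summary.
#' @export
train_eval <- function(features, train_fraction = 0.75, max_depth = 3,
                       nrounds = 50, n_repeats = 10,
                       split_unit = c("subject", "row"), eta = 0.3, seed = 1L) {
  split_unit <- match.arg(split_unit)
  conds <- sort(unique(features$condition))
  if (length(conds) != 2) abort("feature table must contain exactly two conditions.")
  positive <- conds[2]
  feat_cols <- setdiff(names(features), c("subject", "condition"))
  xmat <- as.matrix(features[feat_cols])
  y <- as.integer(features$condition == positive)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  per_repeat <- purrr::map_dfr(seq_len(n_repeats), function(rep_i) {
    for (attempt in 1:100) {
      if (split_unit == "subject") {
        subs <- unique(features$subject)
        train_subs <- sample(subs, size = round(train_fraction * length(subs)))
        train_idx <- features$subject %in% train_subs
      } else {
        train_idx <- seq_len(nrow(features)) %in%
          sample(nrow(features), size = round(train_fraction * nrow(features)))
      }
      if (length(unique(y[train_idx])) == 2 && length(unique(y[!train_idx])) == 2) break
      if (attempt == 100) abort("could not draw a split containing both classes.")
      inform(sprintf("repeat %d: split missing a class in one partition; redrawing.", rep_i))
    }
    dtrain <- xgboost::xgb.DMatrix(xmat[train_idx, , drop = FALSE],
                                   label = y[train_idx], nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, tree_method = "exact", nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
    prob <- predict(booster, xgboost::xgb.DMatrix(xmat[!train_idx, , drop = FALSE],
                                                  nthread = 1))
    pred <- as.integer(prob > 0.5)
    truth <- y[!train_idx]
    tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
    fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    tibble(
      repeat_id = rep_i,
      n_test = length(truth),
      accuracy = (tp + tn) / length(truth),
      sensitivity = recall,
      specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
      recall = recall,
      precision = precision,
      f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    )
  })
  structure(
    list(
      per_repeat = per_repeat,
      summary = dplyr::summarise(per_repeat, dplyr::across(
        c("accuracy", "sensitivity", "specificity", "recall", "precision", "f1"),
        mean)),
      config = list(train_fraction = train_fraction, max_depth = max_depth,
                    nrounds = nrounds, n_repeats = n_repeats, eta = eta,
                    split_unit = split_unit, seed = seed,
                    features = feat_cols),
      positive_class = positive
    ),
    class = "hvp_classifier"
  )
}

#' @export
print.hvp_classifier <- function(x, ...) {
  cat(sprintf("<hvp_classifier> positive class '%s', %d repeats, features: %s\n",
              x$positive_class, x$config$n_repeats,
              paste(x$config$features, collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' @describeIn train_eval per-repeat scores as a tibble.
#' @param x an `hvp_classifier`.
#' @param ... unused.
#' @export
tidy.hvp_classifier <- function(x, ...) x$per_repeat

#' @describeIn train_eval one-row tibble of mean scores over repeats.
#' @export
glance.hvp_classifier <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble(n_repeats = x$config$n_repeats,
                          positive_class = x$positive_class))
}
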