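#' Paired comparison of a metric between two conditions
#'
#' Two-sided paired t-test of a metric between two conditions across
#' subjects. The reported mean difference is condition2 - condition1 (second
#' column-label minus first), the same sign convention used in the
#' comparison CSV output.
#'
#' @param df tibble with columns `subject`, `condition`, `value` (or name the
#'   value column via `metric`).
#' @param conditions length-2 character vector ordering the contrast; default
#'   sorted unique conditions.
#' @param metric name of the value column (default `"value"`).
#' @return One-row tibble: `condition_1`, `condition_2`, `metric`,
#'   `mean_difference`, `p_value`, `sig_05`, `sig_001`, `n`. Identical paired
#'   vectors give difference 0 and p = 1.
#' @examples
#' df <- tibble::tibble(subject = rep(1:10, 2),
#'                      condition = rep(c("EC", "EO"), each = 10),
#'                      value = c(rnorm(10), rnorm(10) + 2))
#' paired_compare(df)
#' @export
paired_compare <- function(df, conditions = NULL, metric = "value") {
  conditions <- conditions %||% sort(unique(df$condition))
  if (length(conditions) != 2) abort("`conditions` must name exactly two conditions.")
  wide <- df |>
    dplyr::select(dplyr::all_of(c("subject", "condition", metric))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(metric))
  if (!all(conditions %in% names(wide))) {
    abort(sprintf("conditions not found: %s",
                  paste(setdiff(conditions, names(wide)), collapse = ", ")))
  }
  x1 <- wide[[conditions[1]]]; x2 <- wide[[conditions[2]]]
  if (anyNA(x1) || anyNA(x2)) abort("unpaired data: some subjects lack one condition.")
  if (length(x1) < 3) abort("need at least 3 paired subjects.")
  d <- x2 - x1
  p <- if (sd(d) == 0) {
    1 # constant differences carry no evidence against equality beyond the shift
  } else {
    t.test(x2, x1, paired = TRUE)$p.value
  }
  if (sd(d) == 0 && mean(d) != 0) {
    # a constant nonzero shift with zero variance: t statistic degenerate;
    # report p = 0 would overclaim, keep the t.test convention unavailable
    p <- NA_real_
  }
  tibble(
    condition_1 = conditions[1], condition_2 = conditions[2], metric = metric,
    mean_difference = mean(d), p_value = p,
    sig_05 = isTRUE(p < 0.05), sig_001 = isTRUE(p < 0.001), n = length(d)
  )
}

#' Tukey HSD comparisons across condition groups
#'
#' One-way ANOVA followed by Tukey's honest significant difference for all
#' pairwise condition contrasts. Differences are condition2 - condition1 with
#' conditions in alphabetical order, matching [paired_compare()].
#'
#' @param df tibble with columns `condition` and `value` (or `metric` naming
#'   the value column).
#' @param metric name of the value column.
#' @return Tibble with one row per pair: `condition_1`, `condition_2`,
#'   `metric`, `mean_difference`, `p_value` (Tukey-adjusted), `conf_low`,
#'   `conf_high`, `sig_05`, `sig_001`.
#' @export
tukey_hsd <- function(df, metric = "value") {
  groups <- unique(df$condition)
  if (length(groups) < 2) abort("need at least 2 condition groups.")
  counts <- table(df$condition)
  if (any(counts < 3)) abort("need at least 3 observations per group.")
  dat <- data.frame(value = df[[metric]], condition = factor(df$condition))
  fit <- aov(value ~ condition, data = dat)
  tk <- TukeyHSD(fit)$condition
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble(
    condition_1 = vapply(pairs, `[`, "", 2),
    condition_2 = vapply(pairs, `[`, "", 1),
    metric = metric,
    mean_difference = tk[, "diff"],
    p_value = tk[, "p adj"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    sig_05 = tk[, "p adj"] < 0.05,
    sig_001 = tk[, "p adj"] < 0.001
  )
}

#' Condition comparison table for every metric
#'
#' Runs [paired_compare()] (within-subject pairs) and [tukey_hsd()] (group
#' contrasts) for each metric column of a per-subject metric table and stacks
#' the results, labelled by test.
#'
#' @param per_subject tibble with `subject`, `condition` and numeric metric
#'   columns (e.g. from [average_channels()]).
#' @param metrics metric columns; default all numeric except bookkeeping.
#' @return Tibble of comparison rows with a `test` column (`"paired_t"` /
#'   `"tukey_hsd"`).
#' @export
compare_conditions <- function(per_subject, metrics = NULL) {
  metrics <- metrics %||%
    setdiff(names(per_subject)[vapply(per_subject, is.numeric, logical(1))],
            c("subject", "n_hvp", "n_lvp"))
  conds <- sort(unique(per_subject$condition))
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  purrr::map_dfr(metrics, function(mc) {
    long <- per_subject |>
      dplyr::select(dplyr::all_of(c("subject", "condition", mc))) |>
      dplyr::rename(value = dplyr::all_of(mc)) |>
      dplyr::filter(is.finite(.data$value))
    paired <- purrr::map_dfr(pairs, function(pr) {
      sub <- dplyr::filter(long, .data$condition %in% pr)
      out <- tryCatch(paired_compare(sub, conditions = pr),
                      error = function(e) NULL)
      out
    })
    tk <- if (length(conds) >= 2 && all(table(long$condition) >= 3)) {
      tukey_hsd(long)
    } else {
      NULL
    }
    dplyr::bind_rows(
      if (nrow(paired) > 0) dplyr::mutate(paired, metric = mc, test = "paired_t"),
      if (!is.null(tk)) dplyr::mutate(tk, metric = mc, test = "tukey_hsd")
    )
  })
}
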