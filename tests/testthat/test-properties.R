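test_that("segmentation equals exhaustive run enumeration on random short traces", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(4:20, 1)
    vals <- round(runif(n, 0, 10), 2)
    thr <- compute_threshold(vals, sample(c(10, 25, 50), 1))
    ss <- segment_trace(asd_trace(vals, 1), thr)
    oracle <- enumerate_runs(vals, thr$value, 1)
    expect_equal(nrow(ss), length(oracle))
    expect_equal(ss$kind, vapply(oracle, `[[`, "", "kind"))
    expect_equal(ss$start_time, vapply(oracle, `[[`, 0, "start"))
    expect_equal(ss$n_windows, vapply(oracle, `[[`, 0, "n"), ignore_attr = TRUE)
    expect_equal(ss$area, vapply(oracle, `[[`, 0, "area"))
  }
})

test_that("supra-threshold count follows percentile coverage on distinct values", {
  set.seed(8)
  for (p in c(10, 25, 50)) {
    for (n in c(7, 24, 101)) {
      vals <- sample(seq_len(n)) / 3 # distinct
      thr <- compute_threshold(vals, p)
      expect_equal(sum(vals > thr$value), n - ceiling(p * n / 100))
    }
  }
})

test_that("metrics are equivariant to amplitude scaling and invariant to offsets", {
  set.seed(9)
  x <- as.numeric(synth_recording(synth_config(duration = 120, seed = 3))$recording$samples)
  params <- window_params(10, 0.5, 25)
  base <- hvp_pipeline(x, 128, params)
  for (c_scale in c(0.25, 3, 1000)) {
    sc <- hvp_pipeline(c_scale * x, 128, params)
    expect_equal(sc$hvp_d, base$hvp_d)
    expect_equal(sc$lvp_d, base$lvp_d)
    expect_equal(sc$hvp_r, base$hvp_r)
    expect_equal(sc$ratio, base$ratio)
    expect_equal(sc$hvp_a, c_scale * base$hvp_a, tolerance = 1e-12)
  }
  for (k in c(-50, 13.7, 2000)) {
    sh <- hvp_pipeline(x + k, 128, params)
    expect_equal(as.data.frame(sh), as.data.frame(base), tolerance = 1e-9)
  }
})

test_that("raising the percentile never increases total supra-threshold time", {
  set.seed(10)
  for (i in 1:20) {
    vals <- runif(sample(8:60, 1), 0, 20)
    tr <- asd_trace(vals, 5)
    total_hvp <- vapply(c(10, 25, 40, 50, 75), function(p) {
      ss <- segment_trace(tr, compute_threshold(vals, p))
      sum(ss$duration[ss$kind == "HVP"])
    }, numeric(1))
    expect_true(all(diff(total_hvp) <= 0))
  }
})

test_that("segments alternate and account for the full windowed time", {
  set.seed(11)
  for (i in 1:50) {
    vals <- runif(sample(4:40, 1))
    step <- runif(1, 0.5, 10)
    ss <- segment_trace(asd_trace(vals, step), compute_threshold(vals, 25))
    expect_true(all(ss$kind[-1] != ss$kind[-nrow(ss)]))
    expect_equal(sum(ss$duration), length(vals) * step)
    expect_equal(sum(ss$n_windows), length(vals))
  }
})

test_that("two-stage aggregation equals a brute-force recomputation", {
  # two subjects with subject means 4 and 6 -> group mean 5, SEM 1
  df <- tibble::tibble(
    subject = rep(c("a", "b"), each = 2),
    channel = rep(c("c1", "c2"), 2),
    hvp_d = c(3, 5, 5, 7)
  )
  agg <- aggregate_metrics(df)
  expect_equal(agg$mean, 5)
  expect_equal(agg$sem, 1)
  expect_equal(agg$n_subjects, 2L)

  # single subject, single channel: mean passes through, SEM undefined
  agg1 <- aggregate_metrics(df[1, ])
  expect_equal(agg1$mean, 3)
  expect_true(is.na(agg1$sem))

  # 10 subjects x 3 channels, random values: match direct two-stage arithmetic
  set.seed(12)
  big <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:10), each = 3),
    channel = rep(c("c1", "c2", "c3"), 10),
    hvp_d = rnorm(30, 20, 5)
  )
  agg_big <- aggregate_metrics(big)
  subj_means <- tapply(big$hvp_d, big$subject, mean)
  expect_equal(agg_big$mean, mean(subj_means))
  expect_equal(agg_big$sem, sd(subj_means) / sqrt(10))
  expect_error(aggregate_metrics(big[0, ]), "empty")
})

test_that("anchoring a threshold in absolute microvolts behaves as expected", {
  pair <- synth_condition_pair(seed = 21, duration = 120)
  params <- window_params(10, 0.5, 25)

  # identical baseline and target: anchored metrics equal self-thresholded ones
  self_m <- hvp_pipeline(pair$EC, params = params)
  anch <- anchored_pipeline(pair$EC, list(), params)
  expect_equal(anch$hvp_d, self_m$hvp_d)
  expect_equal(anch$hvp_a, self_m$hvp_a)

  # baseline at twice the target's scale: fixed uV threshold cuts off more of
  # the smaller signal
  big <- pair$EC
  small <- eeg_recording(big$samples / 2, big$rate, big$channels, condition = "half")
  res <- anchored_pipeline(big, list(small), params)
  supra_frac <- function(cond) {
    r <- res[res$condition == cond, ]
    r$hvp_d * r$n_hvp
  }
  expect_lt(supra_frac("half"), supra_frac("EC"))

  # channel mismatch errors with the asymmetric labels
  odd <- eeg_recording(big$samples, big$rate, paste0("X", seq_along(big$channels)),
                       condition = "odd")
  expect_error(anchored_pipeline(big, list(odd), params), "X1")
})
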