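test_that("moving-window SD uses the population denominator and drops partial windows", {
  # constant signal: zero variance everywhere
  tr <- compute_asd(rep(5, 1280), rate = 128, window_params(2, 0.5))
  expect_true(all(tr$asd == 0))

  # {-1, +1, -1, +1}: mean 0, population SD exactly 1
  tr <- compute_asd(c(-1, 1, -1, 1), rate = 1, window_params(4, 0))
  expect_equal(tr$asd, 1)

  # sample (n-1) denominator would give sqrt(4/3) here; assert we do not
  expect_false(isTRUE(all.equal(tr$asd, sd(c(-1, 1, -1, 1)))))

  # 60 s white noise, m = 10 s, 50% overlap: 11 windows matching brute force
  set.seed(42)
  x <- rnorm(60 * 128, sd = 10)
  tr <- compute_asd(x, 128, window_params(10, 0.5))
  expect_equal(nrow(tr), 11)
  expect_equal(tr$asd, brute_window_sd(x, 128, 10, 0.5), tolerance = 1e-10)
  expect_equal(tr$start_time, seq(0, 50, by = 5))

  # trailing samples that do not fill a window are dropped
  tr2 <- compute_asd(c(x, rnorm(3 * 128, sd = 10)), 128, window_params(10, 0.5))
  expect_equal(nrow(tr2), 11)
  expect_equal(tr2$asd, tr$asd)
})

test_that("degenerate inputs to compute_asd error informatively", {
  expect_error(compute_asd(rnorm(100), 128, window_params(10, 0.5)), "too short")
  x <- rnorm(2560)
  x[1300] <- NA
  expect_error(compute_asd(x, 128, window_params(10, 0.5)), "1300")
})

test_that("rank threshold is the nearest-rank order statistic, clamped", {
  # permutation of 1..8 at p = 25: i = ceil(2) = 2 -> T = 2
  expect_equal(compute_threshold(c(8, 3, 5, 1, 7, 2, 6, 4), 25)$value, 2)
  expect_equal(compute_threshold(c(8, 3, 5, 1, 7, 2, 6, 4), 25)$source_rank_index, 2L)
  # constant list: any percentile returns the constant
  expect_equal(compute_threshold(rep(3.3, 10), 25)$value, 3.3)
  expect_equal(compute_threshold(rep(3.3, 10), 99.9)$value, 3.3)
  # 1..100 at p = 50 -> T = 50
  expect_equal(compute_threshold(sample(1:100), 50)$value, 50)
  # clamping at tiny p
  expect_equal(compute_threshold(1:4, 0.1)$source_rank_index, 1L)
  expect_error(compute_threshold(1:3, 25), "at least 4")
})

test_that("segmentation matches the hand-enumerated example", {
  tr <- asd_trace(c(1, 5, 5, 1, 5, 1), step_seconds = 5)
  ss <- segment_trace(tr, 2)
  hvp <- ss[ss$kind == "HVP", ]
  lvp <- ss[ss$kind == "LVP", ]
  expect_equal(hvp$duration, c(10, 5))
  expect_equal(hvp$area, c(50, 25))
  expect_equal(lvp$duration, c(5, 5, 5))
  # alternation and time accounting
  expect_true(all(ss$kind[-1] != ss$kind[-nrow(ss)]))
  expect_equal(sum(ss$duration), 6 * 5)
  # half-open adjacency
  expect_equal(ss$start_time[-1], ss$end_time[-nrow(ss)])
})

test_that("all-supra and all-tie traces produce single truncated segments", {
  tr <- asd_trace(c(5, 6, 7, 8), step_seconds = 2)
  ss <- segment_trace(tr, 1)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$kind, "HVP")
  expect_true(ss$truncated)
  expect_equal(ss$duration, 8)

  # values exactly at the threshold are low-variability (strict supra rule)
  ss2 <- segment_trace(asd_trace(rep(4, 6), step_seconds = 2), 4)
  expect_equal(ss2$kind, "LVP")
  expect_equal(nrow(ss2), 1)
  expect_error(segment_trace(asd_trace(numeric(0), 1), 1), "empty")
})

test_that("summary metrics match hand arithmetic and handle empty-HVP traces", {
  tr <- asd_trace(c(1, 5, 5, 1, 5, 1), step_seconds = 5)
  m <- hvp_summary(segment_trace(tr, 2), recording_duration = 35)
  expect_equal(m$hvp_d, 7.5)
  expect_equal(m$lvp_d, 5)
  expect_equal(m$hvp_a, 37.5)
  expect_equal(m$ratio, 1.5)
  expect_equal(m$hvp_r, 2 * 60 / 35)
  expect_equal(m$n_hvp, 2L)

  # the deep-anesthesia case: nothing above threshold
  m0 <- hvp_summary(segment_trace(tr, 10), recording_duration = 35)
  expect_equal(m0$hvp_d, 0)
  expect_equal(m0$hvp_a, 0)
  expect_equal(m0$hvp_r, 0)
  expect_equal(m0$n_hvp, 0L)

  # no LVP: ratio undefined
  m1 <- hvp_summary(segment_trace(tr, 0.5), recording_duration = 35)
  expect_true(is.na(m1$ratio))
})

test_that("literal duration mode multiplies run lengths by the window length", {
  vals <- c(1, 5, 5, 1, 5, 1)
  tr <- asd_trace(vals, step_seconds = 5, window_seconds = 10)
  m_cross <- hvp_summary(segment_trace(tr, 2), recording_duration = 40)
  m_lit <- hvp_summary(segment_trace(tr, 2), recording_duration = 40,
                       duration = "literal")
  expect_equal(m_lit$hvp_d, 2 * m_cross$hvp_d) # step = m/2 at 50% overlap
  expect_equal(m_lit$lvp_d, 2 * m_cross$lvp_d)
  expect_equal(m_lit$hvp_a, m_cross$hvp_a) # area untouched by duration mode
})

test_that("truncated boundary segments can be excluded from the means", {
  tr <- asd_trace(c(5, 1, 5, 5, 1, 5), step_seconds = 5)
  ss <- segment_trace(tr, 2)
  expect_equal(ss$truncated, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  m_all <- hvp_summary(ss)
  m_int <- hvp_summary(ss, include_truncated = FALSE)
  expect_equal(m_all$n_hvp, 3L)
  expect_equal(m_int$n_hvp, 1L)
  expect_equal(m_int$hvp_d, 10)
})
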