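test_that("sample entropy matches exhaustive template counting and limits", {
  # constant signal: all templates match at every length
  expect_equal(sample_entropy(rep(5, 200)), 0)

  # 30-sample fixed sequence against the brute-force pair-enumeration oracle
  set.seed(31)
  x30 <- round(rnorm(30), 2)
  expect_equal(sample_entropy(x30), brute_sampen(x30))
  x30b <- cumsum(rnorm(30))
  expect_equal(sample_entropy(x30b, m = 3, r_frac = 0.3),
               brute_sampen(x30b, m = 3, r_frac = 0.3))

  # strictly periodic signal: near 0
  per <- rep(c(0, 3, 1, -2, 4), 60)
  expect_lt(sample_entropy(per), 0.05)

  # with a vanishing tolerance no two templates of a strictly increasing
  # series match: infinite-entropy sentinel rather than an error
  expect_equal(sample_entropy(1:30, r_frac = 1e-9), Inf)
})

test_that("sample entropy and LZ complexity are invariant to affine transforms", {
  set.seed(32)
  x <- rnorm(300)
  for (fun in list(sample_entropy, function(v) as.numeric(lempel_ziv(v)))) {
    expect_equal(fun(5 * x - 7), fun(x))
  }
})

test_that("LZ76 phrase counting matches hand parses", {
  # all-zeros: single phrase
  z <- lempel_ziv(rep(0L, 64))
  expect_equal(attr(z, "phrases"), 1L)

  # hand-parsed binary string 0001101001000101 -> phrases 0|001|10|100|1000|(101)
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(attr(lempel_ziv(s), "phrases"), 5L)

  # alternating string: two phrases regardless of length
  for (n in c(16, 64, 256)) {
    alt <- rep(c(0L, 1L), n / 2)
    expect_lte(attr(lempel_ziv(alt), "phrases"), 3L)
  }

  # median binarization: numeric input equals explicit binary input
  set.seed(33)
  x <- rnorm(128)
  expect_equal(as.numeric(lempel_ziv(x)),
               as.numeric(lempel_ziv(as.integer(x > median(x)))))
  expect_error(lempel_ziv(rnorm(8)), "too short")
})

test_that("waveform complexity counts shape clusters", {
  shape <- sin(2 * pi * (1:64) / 64)
  # one repeated waveform: a single cluster
  wc <- waveform_complexity(rep(shape, 10), segment_len = 64)
  expect_equal(as.numeric(wc), 1 / 10)
  expect_equal(attr(wc, "clusters"), 1L)

  # two interleaved shapes: exactly two clusters
  shape2 <- sin(4 * pi * (1:64) / 64)
  x2 <- unlist(lapply(1:5, function(i) c(shape, shape2)))
  wc2 <- waveform_complexity(x2, segment_len = 64)
  expect_equal(attr(wc2, "clusters"), 2L)
  expect_equal(as.numeric(wc2), 2 / 10)

  # independent white-noise segments: near-maximal diversity
  set.seed(34)
  wn <- rnorm(64 * 20)
  expect_gt(as.numeric(waveform_complexity(wn, segment_len = 64)), 0.8)
  expect_error(waveform_complexity(rnorm(70), segment_len = 64), "2 complete segments")
})

test_that("harmonic regression recovers a pure sinusoid and ties give zero duration", {
  tt <- seq(0, 20, by = 1 / 128)
  x <- 20 * sin(2 * pi * 10 * tt + 0.4)
  hr <- hr_duration(x, 128, window_params(2, 0.5))
  expect_true(all(abs(hr$fits$a - 20) / 20 < 0.01))
  expect_true(all(abs(hr$fits$b - 2 * pi * 10) / (2 * pi * 10) < 0.01))
  expect_true(all(hr$fits$converged))
  # constant-amplitude harmonic signal: all |a| equal, tie rule -> no high runs
  expect_equal(hr$hr_duration, 0)

  # white noise: fitted sinusoid amplitude well below the signal SD
  set.seed(35)
  wn <- rnorm(20 * 128, sd = 10)
  hrn <- hr_duration(wn, 128, window_params(2, 0.5))
  expect_true(all(hrn$fits$a < 10))
})

test_that("harmonic |a| segmentation shares the A_SD run machinery", {
  # the [1,5,5,1,5,1] example pushed through the same threshold/segment path
  amp <- asd_trace(c(1, 5, 5, 1, 5, 1), step_seconds = 5)
  thr <- compute_threshold(amp, 25)
  ss <- segment_trace(amp, thr)
  hvp <- ss[ss$kind == "HVP", ]
  expect_equal(mean(hvp$duration), 7.5)
})

test_that("relative band powers are a partition of total power", {
  tt <- seq(0, 30, by = 1 / 128)
  # pure 10 Hz: essentially all alpha
  bp <- band_powers(sin(2 * pi * 10 * tt), 128)
  expect_gt(bp$alpha, 0.99)
  expect_equal(bp$delta + bp$theta + bp$alpha + bp$beta + bp$gamma, 1)

  # equal-power 6 Hz + 20 Hz tones: theta/beta ratio ~ 1
  bp2 <- band_powers(sin(2 * pi * 6 * tt) + sin(2 * pi * 20 * tt), 128)
  expect_equal(bp2$theta_beta_ratio, 1, tolerance = 0.02)

  # seeded pink noise matches a direct periodogram integration
  set.seed(36)
  pn <- as.numeric(synth_recording(synth_config(duration = 120, sd_ratio = 1,
                                                oscillations = list(),
                                                seed = 36))$recording$samples)
  bp3 <- band_powers(pn, 128, segment_seconds = 16)
  per <- Mod(fft(pn - mean(pn)))[1:(length(pn) / 2 + 1)]^2
  freq <- (0:(length(pn) / 2)) * 128 / length(pn)
  intg <- function(lo, hi, inc = FALSE) {
    sum(per[freq >= lo & (if (inc) freq <= hi else freq < hi)])
  }
  oracle <- c(intg(0.5, 4), intg(4, 8), intg(8, 12), intg(12, 30),
              intg(30, 45, TRUE)) / intg(0.5, 45, TRUE)
  expect_equal(unlist(bp3[1:5]), oracle, tolerance = 0.02, ignore_attr = TRUE)

  # sum-to-one on arbitrary input
  set.seed(37)
  bp4 <- band_powers(cumsum(rnorm(2000)), 128)
  expect_equal(sum(unlist(bp4[1:5])), 1)

  expect_warning(band_powers(rnorm(600), rate = 64), "Nyquist")
})

test_that("metric correlations report r, p and degenerate columns", {
  set.seed(38)
  feats <- tibble::tibble(hvp_d = rnorm(50), other = rnorm(50),
                          self = NA_real_, flat = 1)
  feats$self <- feats$hvp_d
  res <- metric_correlations(feats, comparators = c("self", "other", "flat"))
  expect_equal(res$r[res$metric_pair == "hvp_d vs self"], 1)
  # independent metrics at n = 50: |r| small
  expect_lt(abs(res$r[res$metric_pair == "hvp_d vs other"]), 0.3)
  expect_true(is.na(res$r[res$metric_pair == "hvp_d vs flat"]))
  expect_error(metric_correlations(feats[1:4, ]), "at least 5")
})
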