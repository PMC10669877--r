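#' Sample entropy
#'
#' Negative log of the conditional probability that two subsequences matching
#' for `m` points (Chebyshev distance at most `r_frac * sd(x)`) also match for
#' `m + 1` points, self-matches excluded. Larger values indicate a less
#' predictable signal; a constant or strictly periodic signal scores (near) 0.
#'
#' @param x numeric signal vector (>= 100 samples recommended).
#' @param m embedding (template) length; default 2.
#' @param r_frac tolerance as a fraction of the signal SD; default 0.2.
#' @return Sample entropy (dimensionless). When no template pair matches even
#'   at length `m`, there is no conditional probability to estimate and `Inf`
#'   is returned (infinite-entropy sentinel), never an error.
#' @examples
#' sample_entropy(sin(seq(0, 20 * pi, length.out = 500))) # near 0
#' @export
sample_entropy <- function(x, m = 2L, r_frac = 0.2) {
  x <- as.numeric(x)
  if (length(x) < m + 2) abort("signal too short for sample entropy.")
  tol <- r_frac * sd(x)
  if (!is.finite(tol)) abort("signal SD is not finite.")
  counts <- sampen_counts(x, as.integer(m), tol)
  a <- counts[[1]]; b <- counts[[2]]
  if (b == 0) return(Inf)
  if (a == 0) return(Inf)
  -log(a / b)
}

#' Lempel-Ziv (LZ76) complexity
#'
#' Binarizes the signal at its median (strictly above -> 1) and counts the
#' phrases of an exhaustive-history LZ76 parse, normalised by `n / log2(n)`.
#' A trailing phrase still reproducible from the preceding content does not
#' add to the count, so a constant signal has phrase count 1.
#'
#' @param x numeric signal vector (length >= 16) or a 0/1 integer vector
#'   (used as the binary sequence directly).
#' @return Normalised complexity `c(n) * log2(n) / n`; the raw phrase count is
#'   attached as attribute `phrases`.
#' @examples
#' lempel_ziv(rnorm(256)) # near 1 for white noise
#' @export
lempel_ziv <- function(x) {
  if (length(x) < 16) abort("signal too short for LZ76 complexity (need >= 16).")
  s <- if (all(x %in% c(0, 1))) as.integer(x) else as.integer(x > median(x))
  cn <- lz76_phrases(s)
  n <- length(s)
  structure(cn * log2(n) / n, phrases = cn)
}

#' Waveform complexity (segment-clustering variant)
#'
#' Quantifies the diversity of waveform shapes: the signal is cut into
#' non-overlapping segments of `segment_len` samples, each is amplitude
#' normalised (z-scored), and segments are greedily clustered — a segment
#' joins the first cluster whose representative (founding) segment correlates
#' with it at or above `similarity_threshold`, otherwise it founds a new
#' cluster. Complexity is the cluster count divided by the segment count: a
#' signal tiling one repeated shape scores `1 / n_segments`, fully diverse
#' segments score near 1.
#'
#' @param x numeric signal vector.
#' @param segment_len segment length in samples (default 64, i.e. 0.5 s at
#'   128 Hz).
#' @param similarity_threshold Pearson correlation at or above which two
#'   segments count as the same shape (default 0.8).
#' @return Complexity in (0, 1]; cluster count attached as attribute
#'   `clusters`.
#' @export
waveform_complexity <- function(x, segment_len = 64L, similarity_threshold = 0.8) {
  n_seg <- floor(length(x) / segment_len)
  if (n_seg < 2) abort("need at least 2 complete segments for waveform complexity.")
  segs <- matrix(x[seq_len(n_seg * segment_len)], nrow = segment_len)
  norm <- apply(segs, 2, function(s) {
    s <- s - mean(s)
    v <- sqrt(mean(s^2))
    if (v > 0) s / v else s # flat segment stays all-zero
  })
  reps <- list()
  n_clusters <- 0L
  for (j in seq_len(n_seg)) {
    seg <- norm[, j]
    assigned <- FALSE
    for (r in reps) {
      flat_r <- all(r == 0); flat_s <- all(seg == 0)
      sim <- if (flat_r || flat_s) {
        if (flat_r && flat_s) 1 else -Inf
      } else {
        sum(r * seg) / segment_len # correlation of z-scored segments
      }
      if (sim >= similarity_threshold) {
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      n_clusters <- n_clusters + 1L
      reps[[n_clusters]] <- seg
    }
  }
  structure(n_clusters / n_seg, clusters = n_clusters)
}

#' Harmonic-regression duration
#'
#' Fits `a * sin(b * t + c)` by nonlinear least squares in each moving window
#' (same window length and 50% overlap as the variability analysis), with `b`
#' initialised at the window's dominant FFT frequency, `a` at the window RMS
#' times sqrt(2) and `c` at 0. The per-window fitted amplitude magnitude |a|
#' is then thresholded at its own 25th percentile and segmented exactly like
#' an A_SD trace; the mean supra-threshold run duration is returned. For a
#' stationary pure sinusoid every |a| is (numerically) equal, equality counts
#' as sub-threshold, and the duration is 0.
#'
#' @param x numeric signal vector (microvolts).
#' @param rate sampling rate (Hz).
#' @param params a [window_params()]; `percentile` is applied to the |a|
#'   sequence.
#' @return A list: `hr_duration` (s), `fits` (tibble with per-window
#'   `window`, `start_time`, `a`, `b`, `c`, `rss`, `converged`), `segments`
#'   (the `segment_set` over |a|).
#' @examples
#' x <- 20 * sin(2 * pi * 10 * seq(0, 20, by = 1 / 128))
#' fit <- hr_duration(x, 128, window_params(2, 0.5))
#' fit$hr_duration # 0: constant-amplitude harmonic signal has no high runs
#' @export
hr_duration <- function(x, rate, params = window_params()) {
  params <- as_window_params(params)
  w <- round(params$window_seconds * rate)
  if (length(x) < w) abort("signal shorter than one window.")
  step <- max(1L, round(params$step_seconds * rate))
  starts <- seq.int(1L, length(x) - w + 1L, by = step)
  tt <- (seq_len(w) - 1) / rate
  fits <- purrr::map_dfr(seq_along(starts), function(i) {
    y <- x[starts[i]:(starts[i] + w - 1L)]
    y <- y - mean(y)
    spec <- Mod(fft(y))[2:floor(w / 2)]
    f0 <- which.max(spec) / (w / rate) # dominant frequency, Hz
    a0 <- sqrt(2) * sqrt(mean(y^2))
    start_par <- list(a = a0, b = 2 * pi * f0, c = 0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * sin(b * tt + c),
                        start = start_par,
                        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      tibble(window = i, start_time = (starts[i] - 1) / rate,
             a = a0, b = 2 * pi * f0, c = 0,
             rss = sum(y^2), converged = FALSE)
    } else {
      cf <- coef(fit)
      tibble(window = i, start_time = (starts[i] - 1) / rate,
             a = abs(cf[["a"]]), b = cf[["b"]], c = cf[["c"]],
             rss = sum(stats::resid(fit)^2), converged = TRUE)
    }
  })
  if (mean(fits$converged) < 0.5) {
    warn("more than 50% of harmonic-regression windows failed to converge; initial values used for |a|.")
  }
  # report amplitudes at the fit tolerance so sub-tolerance numerical jitter
  # between identical windows cannot fabricate threshold crossings
  fits$a <- signif(fits$a, 8)
  amp_trace <- asd_trace(fits$a, step_seconds = step / rate,
                         window_seconds = params$window_seconds, rate = rate)
  thr <- compute_threshold(amp_trace, params$percentile)
  segs <- segment_trace(amp_trace, thr)
  hvp <- segs$kind == "HVP"
  list(
    hr_duration = if (any(hvp)) mean(segs$duration[hvp]) else 0,
    fits = fits,
    segments = segs
  )
}

#' Relative spectral band powers
#'
#' Welch power spectrum (Hann windows, 4 s segments, 50% overlap) integrated
#' over the conventional bands delta 0.5-4, theta 4-8, alpha 8-12, beta
#' 12-30, gamma 30-45 Hz, each expressed relative to the total power over
#' 0.5-45 Hz, plus the theta/beta ratio. Band edges are half-open `[lo, hi)`
#' except gamma which includes its upper edge.
#'
#' @param x numeric signal vector (>= 4 s of data).
#' @param rate sampling rate (Hz). Below 90 Hz the gamma band is truncated at
#'   the Nyquist frequency with a warning.
#' @param segment_seconds Welch segment length (default 4 s).
#' @return One-row tibble: `delta`, `theta`, `alpha`, `beta`, `gamma`
#'   (relative powers summing to 1) and `theta_beta_ratio`.
#' @examples
#' band_powers(sin(2 * pi * 10 * seq(0, 30, by = 1 / 128)), 128) # alpha ~ 1
#' @export
band_powers <- function(x, rate, segment_seconds = 4) {
  if (length(x) < 4 * rate) abort("need at least 4 s of signal for band powers.")
  ps <- welch_psd(x, rate, segment_seconds)
  gamma_hi <- 45
  if (rate < 90) {
    gamma_hi <- rate / 2
    warn(sprintf("sampling rate %g Hz: gamma band truncated at Nyquist (%g Hz).",
                 rate, gamma_hi))
  }
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                beta = c(12, 30), gamma = c(30, gamma_hi))
  band_power <- function(lo, hi, closed_hi = FALSE) {
    sel <- ps$freq >= lo & (if (closed_hi) ps$freq <= hi else ps$freq < hi)
    sum(ps$psd[sel]) * ps$df
  }
  p <- purrr::imap_dbl(bands, function(b, nm) {
    band_power(b[1], b[2], closed_hi = (nm == "gamma"))
  })
  total <- sum(p)
  rel <- p / total
  dplyr::bind_cols(as_tibble(as.list(rel)),
                   tibble(theta_beta_ratio = rel[["theta"]] / rel[["beta"]]))
}

# Welch PSD: mean of Hann-windowed one-sided periodograms over 50%-overlapping
# segments; density scaling 1 / (fs * sum(w^2)).
welch_psd <- function(x, rate, segment_seconds = 4) {
  nper <- min(length(x), round(segment_seconds * rate))
  step <- max(1L, floor(nper / 2))
  starts <- seq.int(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1)) # Hann
  scale <- 1 / (rate * sum(w^2))
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))[seq_len(nfreq)]^2 * scale
    # one-sided: double everything except DC (and Nyquist when nper even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nper %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nfreq) - 1) * rate / nper,
       psd = acc / length(starts),
       df = rate / nper)
}

#' All comparator metrics for one channel
#'
#' Convenience wrapper computing sample entropy, Lempel-Ziv complexity,
#' waveform complexity, harmonic-regression duration and relative band powers
#' for a single channel.
#'
#' @inheritParams hr_duration
#' @param segment_len waveform-complexity segment length in samples.
#' @return One-row tibble: `sample_entropy`, `lempel_ziv`,
#'   `waveform_complexity`, `hr_duration`, `delta` ... `gamma`,
#'   `theta_beta_ratio`.
#' @export
comparator_metrics <- function(x, rate, params = window_params(),
                               segment_len = round(rate / 2)) {
  dplyr::bind_cols(
    tibble(
      sample_entropy = sample_entropy(x),
      lempel_ziv = as.numeric(lempel_ziv(x)),
      waveform_complexity = as.numeric(waveform_complexity(x, segment_len)),
      hr_duration = hr_duration(x, rate, params)$hr_duration
    ),
    band_powers(x, rate)
  )
}

#' Pearson correlations between HVP duration and comparator metrics
#'
#' Computes Pearson's r and the two-sided p-value between a reference metric
#' (mean HVP duration by default) and each comparator, across subjects, on
#' subject-level channel-averaged values.
#'
#' @param features tibble with one row per subject and numeric metric columns.
#' @param target reference metric column (default `"hvp_d"`).
#' @param comparators comparator columns; default: every other numeric column.
#' @return Tibble: `metric_pair`, `r`, `p_value`, `n`. A zero-variance metric
#'   yields `r = NA`.
#' @export
metric_correlations <- function(features, target = "hvp_d", comparators = NULL) {
  if (nrow(features) < 5) abort("need at least 5 subjects for metric correlations.")
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  comparators <- comparators %||% setdiff(num_cols, c(target, "subject"))
  purrr::map_dfr(comparators, function(cm) {
    xs <- features[[target]]; ys <- features[[cm]]
    ok <- is.finite(xs) & is.finite(ys)
    if (sd(xs[ok]) == 0 || sd(ys[ok]) == 0) {
      return(tibble(metric_pair = paste(target, "vs", cm),
                    r = NA_real_, p_value = NA_real_, n = sum(ok)))
    }
    ct <- cor.test(xs[ok], ys[ok], method = "pearson")
    tibble(metric_pair = paste(target, "vs", cm),
           r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
  })
}
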