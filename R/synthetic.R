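#' Synthetic nonstationary EEG configuration
#'
#' Describes a synthetic single- or multi-channel EEG-like signal: a
#' 1/f-coloured background plus band-limited oscillations, multiplied by a
#' piecewise amplitude envelope that alternates between high- and
#' low-variability epochs with random (gamma- or exponential-distributed)
#' durations. The envelope is the controllable ground truth that the
#' variability segmentation is meant to recover.
#'
#' The default envelope spends three times as long in the high state as in
#' the low state (`low_mean = high_mean / 3`). This matches the default
#' quartile threshold: the 25th-percentile A_SD of a 75%/25% high/low
#' envelope falls on the epoch transition ramps, so threshold crossings line
#' up with the programmed epoch boundaries.
#'
#' @param rate sampling rate, Hz.
#' @param duration recording length, seconds.
#' @param spectral_slope exponent of the 1/f^slope background power spectrum.
#' @param background_rms background RMS amplitude in the low state, microvolts.
#' @param oscillations list of `c(center_hz, bandwidth_hz, rms_uv)` vectors.
#' @param high_mean,low_mean mean high-/low-epoch durations, seconds
#'   (`low_mean` defaults to `high_mean / 3`).
#' @param sd_ratio amplitude-SD ratio of high to low epochs (> 1, or exactly
#'   1 for a stationary control).
#' @param epoch_dist `"gamma"` (shape 4, avoids degenerate ultra-short
#'   epochs) or `"exponential"`.
#' @param ramp_seconds raised-cosine transition length between epochs.
#' @param n_channels number of (independently drawn) channels.
#' @param condition_label condition tag carried into the recording.
#' @param expected_window_seconds the analysis window length the signal is
#'   destined for; epochs shorter than twice this are flagged at generation
#'   time as unresolvable by design.
#' @param seed integer seed; fully determines the output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(rate = 128, duration = 180, spectral_slope = 1,
                         background_rms = 15,
                         oscillations = list(c(10, 2, 15)),
                         high_mean = 30, low_mean = high_mean / 3,
                         sd_ratio = 2, epoch_dist = c("gamma", "exponential"),
                         ramp_seconds = 0.5, n_channels = 1,
                         condition_label = "synthetic",
                         expected_window_seconds = 10, seed = 1L) {
  epoch_dist <- match.arg(epoch_dist)
  stopifnot(rate > 0, duration > 0, high_mean > 0, low_mean > 0, sd_ratio >= 1)
  structure(
    list(rate = rate, duration = duration, spectral_slope = spectral_slope,
         background_rms = background_rms, oscillations = oscillations,
         high_mean = high_mean, low_mean = low_mean, sd_ratio = sd_ratio,
         epoch_dist = epoch_dist, ramp_seconds = ramp_seconds,
         n_channels = n_channels, condition_label = condition_label,
         expected_window_seconds = expected_window_seconds,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# 1/f^slope coloured noise via FFT amplitude shaping, unit RMS.
# Flat below f_floor to mimic the high-pass-limited bandwidth of real
# recordings; DC removed.
colored_noise <- function(n, rate, slope, f_floor = 0.5) {
  white <- rnorm(n)
  spec <- fft(white)
  freq <- c(0, seq_len(n - 1)) * rate / n
  freq <- pmin(freq, rate - freq) # fold to physical frequency
  gain <- pmax(freq, f_floor)^(-slope / 2)
  gain[1] <- 0
  x <- Re(fft(spec * gain, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Narrow-band oscillation: white noise FFT-masked by a Gaussian around the
# center frequency, unit RMS.
band_oscillation <- function(n, rate, center, bandwidth) {
  white <- rnorm(n)
  spec <- fft(white)
  freq <- c(0, seq_len(n - 1)) * rate / n
  freq <- pmin(freq, rate - freq)
  gain <- exp(-0.5 * ((freq - center) / (bandwidth / 2))^2)
  gain[1] <- 0
  x <- Re(fft(spec * gain, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Alternating high/low epoch boundaries tiling [0, duration]; starts low.
draw_epochs <- function(duration, high_mean, low_mean, epoch_dist) {
  draw <- function(mean_d) {
    d <- if (epoch_dist == "gamma") rgamma(1, shape = 4, scale = mean_d / 4)
         else rexp(1, rate = 1 / mean_d)
    max(d, 0.25) # keep epochs physically sensible
  }
  t <- 0; kind <- "low"
  starts <- c(); ends <- c(); kinds <- c()
  while (t < duration) {
    d <- draw(if (kind == "high") high_mean else low_mean)
    starts <- c(starts, t); ends <- c(ends, min(t + d, duration)); kinds <- c(kinds, kind)
    t <- t + d
    kind <- if (kind == "high") "low" else "high"
  }
  tibble(start = starts, end = ends, kind = kinds)
}

# Smooth multiplicative envelope: low = 1, high = sd_ratio, raised-cosine
# ramps of ramp_seconds centred on each boundary.
epoch_envelope <- function(epochs, n, rate, sd_ratio, ramp_seconds) {
  tt <- (seq_len(n) - 1) / rate
  env <- rep(1, n)
  for (i in seq_len(nrow(epochs))) {
    if (epochs$kind[i] == "high") {
      env[tt >= epochs$start[i] & tt < epochs$end[i]] <- sd_ratio
    }
  }
  half <- ramp_seconds / 2
  bounds <- epochs$start[-1]
  for (b in bounds) {
    sel <- tt >= (b - half) & tt < (b + half)
    if (!any(sel)) next
    lo <- env[max(1, which(sel)[1] - 1)]
    hi <- env[min(n, tail(which(sel), 1) + 1)]
    phase <- (tt[sel] - (b - half)) / ramp_seconds
    env[sel] <- lo + (hi - lo) * (1 - cos(pi * phase)) / 2
  }
  env
}

#' Generate a synthetic EEG recording
#'
#' Draws the coloured-noise background and oscillations, multiplies by the
#' programmed variance envelope, and returns both the recording and its
#' ground truth (the epoch boundaries and programmed parameters). The output
#' is fully determined by `config$seed`.
#'
#' @param config a [synth_config()].
#' @return List with `recording` (an [eeg_recording()]) and `ground_truth`
#'   (list: `epochs` tibble with per-channel epoch boundaries, `high_mean`,
#'   `sd_ratio`).
#' @examples
#' out <- synth_recording(synth_config(duration = 60, seed = 42))
#' out$ground_truth$epochs
#' @export
synth_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$high_mean < 2 * config$expected_window_seconds) {
    # epochs short relative to the analysis window cannot be resolved by the
    # moving-window segmentation, by construction
    warn(sprintf(
      "mean high-epoch duration (%.3g s) is below twice the intended %g s analysis window; recovered durations will be window-limited.",
      config$high_mean, config$expected_window_seconds))
  }
  n <- round(config$duration * config$rate)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  chans <- vector("list", config$n_channels)
  epoch_list <- vector("list", config$n_channels)
  for (k in seq_len(config$n_channels)) {
    base <- config$background_rms * colored_noise(n, config$rate, config$spectral_slope)
    for (osc in config$oscillations) {
      base <- base + osc[3] * band_oscillation(n, config$rate, osc[1], osc[2])
    }
    epochs <- draw_epochs(config$duration, config$high_mean, config$low_mean,
                          config$epoch_dist)
    env <- epoch_envelope(epochs, n, config$rate, config$sd_ratio,
                          config$ramp_seconds)
    chans[[k]] <- base * env
    epoch_list[[k]] <- dplyr::bind_cols(tibble(channel = paste0("ch", k)), epochs)
  }
  rec <- eeg_recording(do.call(cbind, chans), rate = config$rate,
                       condition = config$condition_label)
  list(
    recording = rec,
    ground_truth = list(
      epochs = dplyr::bind_rows(epoch_list),
      high_mean = config$high_mean,
      low_mean = config$low_mean,
      sd_ratio = config$sd_ratio
    )
  )
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_subjects` subjects, each recorded under every named condition.
#' Per-subject lognormal random effects (SD `subject_sd` on the log scale)
#' scale the envelope epoch means, so subjects differ in their characteristic
#' epoch durations while conditions differ systematically.
#'
#' @param n_subjects number of subjects.
#' @param condition_specs named list: condition label -> list of
#'   [synth_config()] argument overrides (e.g.
#'   `list(EC = list(high_mean = 15), EO = list(high_mean = 30))`).
#' @param base a [synth_config()] supplying all non-overridden parameters.
#' @param subject_sd SD of the lognormal subject effect on epoch means.
#' @param seed integer master seed.
#' @return Tibble: `subject`, `condition`, `recording` (list-column),
#'   `ground_truth` (list-column).
#' @examples
#' coh <- synth_cohort(2, list(EC = list(high_mean = 15),
#'                             EO = list(high_mean = 30)),
#'                     base = synth_config(duration = 60), seed = 7)
#' @export
synth_cohort <- function(n_subjects, condition_specs, base = synth_config(),
                         subject_sd = 0.15, seed = 1L) {
  if (length(condition_specs) < 2) abort("need at least 2 conditions.")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  effects <- exp(rnorm(n_subjects, 0, subject_sd))
  sub_seeds <- sample.int(2^30, n_subjects * length(condition_specs))
  dim(sub_seeds) <- c(n_subjects, length(condition_specs))
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    purrr::imap_dfr(condition_specs, function(delta, label) {
      cfg_args <- utils::modifyList(unclass(base), delta)
      cfg_args <- cfg_args[names(cfg_args) %in% names(formals(synth_config))]
      cfg <- do.call(synth_config, cfg_args)
      cfg$high_mean <- cfg$high_mean * effects[i]
      cfg$low_mean <- cfg$low_mean * effects[i]
      cfg$condition_label <- label
      cfg$seed <- sub_seeds[i, match(label, names(condition_specs))]
      out <- synth_recording(cfg)
      out$recording$subject_id <- sprintf("S%02d", i)
      tibble(subject = sprintf("S%02d", i), condition = label,
             recording = list(out$recording), ground_truth = list(out$ground_truth))
    })
  })
}

#' Synthetic eyes-closed / eyes-open style condition pair
#'
#' One subject's worth of a two-condition contrast: the `EC`-like baseline has
#' stronger alpha and shorter high-variability epochs; the `EO`-like condition
#' has weaker alpha and high epochs twice as long.
#'
#' @param seed integer seed.
#' @param duration seconds per condition.
#' @param n_channels channels per recording.
#' @return Named list of two [eeg_recording()]s (`EC`, `EO`).
#' @export
synth_condition_pair <- function(seed = 1L, duration = 180, n_channels = 1) {
  ec <- synth_recording(synth_config(
    duration = duration, high_mean = 20, sd_ratio = 2,
    oscillations = list(c(10, 2, 30)), n_channels = n_channels,
    condition_label = "EC", seed = seed))$recording
  eo <- synth_recording(synth_config(
    duration = duration, high_mean = 40, sd_ratio = 2,
    oscillations = list(c(10, 2, 12)), n_channels = n_channels,
    condition_label = "EO", seed = seed + 1L))$recording
  list(EC = ec, EO = eo)
}

#' Synthetic anesthesia session
#'
#' Four 5-minute blocks mimicking an anesthesia induction/recovery sequence:
#' `rest` (structured envelope), `low` (damped amplitude, sparser and shorter
#' high epochs), `deep` and `recovery` (variance structure abolished,
#' amplitude strongly damped — under a rest-anchored threshold no window
#' exceeds T, so HVPs vanish and do not reappear). Analyse with a 3 s window
#' and the threshold anchored on the `rest` block.
#'
#' @param seed integer seed.
#' @param block_seconds block length (default 300 s).
#' @return Named list of [eeg_recording()]s: `rest`, `low`, `deep`,
#'   `recovery`, in administration order.
#' @export
synth_anesthesia_session <- function(seed = 1L, block_seconds = 300) {
  base <- function(label, high_mean, low_mean, sd_ratio, amp, sd) {
    synth_recording(synth_config(
      duration = block_seconds, high_mean = high_mean, low_mean = low_mean,
      sd_ratio = sd_ratio, background_rms = 15 * amp,
      oscillations = list(c(10, 2, 15 * amp)),
      condition_label = label, expected_window_seconds = 3, seed = sd))$recording
  }
  list(
    rest = base("rest", high_mean = 9, low_mean = 3, sd_ratio = 4, amp = 1, sd = seed),
    low = base("low", high_mean = 3, low_mean = 27, sd_ratio = 4, amp = 0.8, sd = seed + 1L),
    deep = base("deep", high_mean = 9, low_mean = 3, sd_ratio = 1, amp = 0.35, sd = seed + 2L),
    recovery = base("recovery", high_mean = 9, low_mean = 3, sd_ratio = 1, amp = 0.5, sd = seed + 3L)
  )
}
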