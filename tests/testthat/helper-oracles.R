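# Independent brute-force oracles used across tests.

# Exhaustive run enumeration: walk the supra/sub flag sequence element by
# element and emit alternating segments. Independent of segment_trace's rle
# implementation.
enumerate_runs <- function(values, threshold, step) {
  supra <- values > threshold
  segs <- list()
  run_start <- 1
  for (i in seq_along(supra)[-1]) {
    if (supra[i] != supra[i - 1]) {
      segs[[length(segs) + 1]] <- list(
        kind = if (supra[run_start]) "HVP" else "LVP",
        start = (run_start - 1) * step,
        n = i - run_start,
        area = if (supra[run_start]) sum(values[run_start:(i - 1)]) * step else NA_real_
      )
      run_start <- i
    }
  }
  segs[[length(segs) + 1]] <- list(
    kind = if (supra[run_start]) "HVP" else "LVP",
    start = (run_start - 1) * step,
    n = length(supra) - run_start + 1,
    area = if (supra[run_start]) sum(values[run_start:length(supra)]) * step else NA_real_
  )
  segs
}

# Direct two-pass per-window SD with population denominator.
brute_window_sd <- function(x, rate, window_seconds, overlap) {
  w <- round(window_seconds * rate)
  step <- round(window_seconds * (1 - overlap) * rate)
  starts <- seq(1, length(x) - w + 1, by = step)
  vapply(starts, function(s) {
    win <- x[s:(s + w - 1)]
    sqrt(mean((win - mean(win))^2))
  }, numeric(1))
}

# Exhaustive template-counting sample entropy (Chebyshev, self-matches
# excluded, first n - m templates).
brute_sampen <- function(x, m = 2, r_frac = 0.2) {
  tol <- r_frac * sd(x)
  n <- length(x)
  nt <- n - m
  a <- 0; b <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= tol) {
        b <- b + 1
        if (abs(x[i + m] - x[j + m]) <= tol) a <- a + 1
      }
    }
  }
  if (b == 0 || a == 0) return(Inf)
  -log(a / b)
}

# small deterministic EC/EO-style feature cohort for classifier tests
make_separable_features <- function(n = 14, gap = 5, noise = 0) {
  tibble::tibble(
    subject = rep(sprintf("S%02d", seq_len(n)), 2),
    condition = rep(c("A", "B"), each = n),
    f1 = rep(c(0, gap), each = n) + stats::rnorm(2 * n, 0, noise),
    f2 = rep(c(gap, 0), each = n) + stats::rnorm(2 * n, 0, noise)
  )
}
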