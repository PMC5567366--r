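# shared oracles and fixture builders (everything generated in code)

# O(n^2) direct-evaluation oracle for the normalized cross-correlation:
# per-lag Pearson correlation of the overlapping segments.
brute_xcorr <- function(x, y, max_lag, min_overlap = 1) {
  sr <- x$sample_rate
  xs <- x$samples; ys <- y$samples
  nx <- length(xs); ny <- length(ys)
  L <- round(max_lag * sr)
  best <- list(r = -Inf, lag = NA)
  for (l in (-L):L) {
    # positive lag = y delayed: pair x[i] with y[i + l]
    i1 <- max(1, 1 - l); i2 <- min(nx, ny - l)
    m <- i2 - i1 + 1
    if (m < max(2, round(min_overlap * sr))) next
    r <- suppressWarnings(stats::cor(xs[i1:i2], ys[(i1 + l):(i2 + l)]))
    if (!is.na(r) && r > best$r) best <- list(r = r, lag = l / sr)
  }
  best
}

# short constant-interval train for fast unit tests
quick_train <- function(interval = 1 / 14.73, duration = 4, sr = 2000,
                        pulse_duration = 0.068, taper = 0.1) {
  synthesize_train(pulse_train_spec(
    constant_intervals(interval, duration), duration, sr,
    pulse_duration, taper_fraction = taper))
}

# sum-of-sines harmonic comb with optional notched harmonics
tone_comb <- function(f0, harmonics, duration = 7, sr = 2000, amps = NULL) {
  t <- (0:(duration * sr - 1)) / sr
  if (is.null(amps)) amps <- rep(1, length(harmonics))
  x <- numeric(length(t))
  for (i in seq_along(harmonics))
    x <- x + amps[i] * sin(2 * pi * harmonics[i] * f0 * t)
  waveform(x, sr)
}
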