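#' Single-sided power spectrum of a full record
#'
#' Hann-windowed, zero-padded magnitude-squared FFT of the whole
#' waveform. Zero padding by a factor of 4 (default) plus the 3-point
#' parabolic peak interpolation used by [estimate_fundamental()] resolves
#' harmonic peak frequencies well below the raw Rayleigh resolution: a
#' 7 s record at 2 kHz has ~0.14 Hz raw bins, not enough on its own to
#' separate 14.73 Hz from 14.7 Hz.
#'
#' @param w A [waveform()] with at least 16 samples.
#' @param zero_pad_factor Integer >= 1; the FFT length is
#'   `zero_pad_factor * length(w$samples)`, so the bin spacing is
#'   `sample_rate / (zero_pad_factor * length)`.
#' @return An object of class `call_spectrum` with fields `frequencies`
#'   (Hz, strictly increasing from 0), `power` (linear, single-sided),
#'   `sample_rate`, `nfft` and `window`.
#' @export
power_spectrum <- function(w, zero_pad_factor = 4) {
  stopifnot_waveform(w)
  n <- length(w$samples)
  if (n < 16) stop("waveform too short for a spectrum (need >= 16 samples)")
  if (!is.numeric(zero_pad_factor) || zero_pad_factor < 1)
    stop("zero_pad_factor must be >= 1")
  zp <- as.integer(zero_pad_factor)
  h <- hann_window(n)
  nfft <- zp * n
  X <- stats::fft(c(w$samples * h, numeric(nfft - n)))
  k <- 0:(nfft %/% 2)
  structure(
    list(frequencies = k * w$sample_rate / nfft,
         power = Mod(X[k + 1])^2,
         sample_rate = w$sample_rate, nfft = nfft, n = n, window = "hann"),
    class = "call_spectrum"
  )
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' @export
print.call_spectrum <- function(x, ...) {
  cat(sprintf("<call_spectrum> %d bins, 0-%g Hz, resolution %.4g Hz\n",
              length(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' @export
plot.call_spectrum <- function(x, xlim = NULL, ...) {
  db <- 10 * log10(x$power / max(x$power) + 1e-300)
  graphics::plot(x$frequencies, db, type = "l", xlim = xlim,
                 xlab = "frequency (Hz)", ylab = "power (dB re max)", ...)
  invisible(x)
}

#' Short-time Fourier spectrogram
#'
#' Hann-windowed frames on a uniform grid with per-frame zero padding;
#' frame times refer to window centers.
#'
#' @param w A [waveform()].
#' @param window_s Window length in seconds; `window_s * sample_rate`
#'   must be >= 16 and no longer than the record.
#' @param overlap_fraction Fractional overlap of consecutive windows in
#'   [0, 1).
#' @param zero_pad_factor Per-frame zero-padding factor (>= 1).
#' @return An object of class `call_spectrogram` with fields `times`
#'   (window centers, s), `frequencies` (Hz) and `power`
#'   (frequency x time matrix, linear).
#' @export
spectrogram <- function(w, window_s = 2, overlap_fraction = 0.5,
                        zero_pad_factor = 4) {
  stopifnot_waveform(w)
  n <- length(w$samples)
  win <- round(window_s * w$sample_rate)
  if (win < 16) stop("window too short: need window_s * sample_rate >= 16")
  if (win > n) stop("window longer than the record")
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  hop <- max(1L, round(win * (1 - overlap_fraction)))
  starts <- seq(1L, n - win + 1L, by = hop)
  h <- hann_window(win)
  nfft <- as.integer(zero_pad_factor) * win
  if (zero_pad_factor < 1) stop("zero_pad_factor must be >= 1")
  k <- 0:(nfft %/% 2)
  P <- vapply(starts, function(s0) {
    X <- stats::fft(c(w$samples[s0:(s0 + win - 1L)] * h, numeric(nfft - win)))
    Mod(X[k + 1])^2
  }, numeric(length(k)))
  structure(
    list(times = w$start_time + (starts - 1 + (win - 1) / 2) / w$sample_rate,
         frequencies = k * w$sample_rate / nfft,
         power = P, sample_rate = w$sample_rate,
         window_s = window_s, overlap_fraction = overlap_fraction),
    class = "call_spectrogram"
  )
}

#' @export
print.call_spectrogram <- function(x, ...) {
  cat(sprintf("<call_spectrogram> %d frames x %d bins, %.3g-%.3g s, 0-%g Hz\n",
              length(x$times), length(x$frequencies),
              min(x$times), max(x$times), max(x$frequencies)))
  invisible(x)
}

#' @export
plot.call_spectrogram <- function(x, flim = NULL, ...) {
  db <- 10 * log10(t(x$power) / max(x$power) + 1e-300)
  graphics::image(x$times, x$frequencies, db, ylim = flim,
                  xlab = "time (s)", ylab = "frequency (Hz)", ...)
  invisible(x)
}

## 3-point parabolic interpolation of a spectral peak on a log-power scale.
## i is the index of the bin maximum; returns list(freq, power).
interp_peak <- function(freqs, power, i) {
  df <- freqs[2] - freqs[1]
  if (i <= 1L || i >= length(power)) {
    return(list(freq = freqs[i], power = power[i]))
  }
  y <- log(power[(i - 1):(i + 1)] + 1e-300)
  denom <- y[1] - 2 * y[2] + y[3]
  d <- if (abs(denom) < 1e-12) 0 else 0.5 * (y[1] - y[3]) / denom
  d <- max(min(d, 0.5), -0.5)
  list(freq = freqs[i] + d * df,
       power = exp(y[2] - 0.25 * (y[1] - y[3]) * d))
}

## indices (within `sel`) of strict local maxima of power over the full grid
local_maxima <- function(power, sel) {
  n <- length(power)
  sel[vapply(sel, function(i) {
    left <- if (i > 1L) power[i - 1L] else -Inf
    right <- if (i < n) power[i + 1L] else -Inf
    power[i] > left && power[i] >= right
  }, logical(1))]
}

#' Estimate the fundamental frequency from a spectrum
#'
#' Finds the largest in-band local maximum and refines its frequency by
#' 3-point parabolic interpolation around the bin maximum (on log
#' power). The returned value carries a `prominence_db` attribute - the
#' peak height above the in-band median power - and a logical
#' `prominent` attribute comparing it with `prominence_db` (default
#' 6 dB); low-prominence results (e.g. from noise-only records) are
#' thereby flagged rather than suppressed.
#'
#' @param s A `call_spectrum` from [power_spectrum()].
#' @param band Search band `c(low, high)` in Hz, within the spectrum
#'   range.
#' @param prominence_db Threshold for the `prominent` flag.
#' @return Fundamental frequency in Hz with attributes `prominence_db`
#'   and `prominent`. Errors if the band holds no local maximum.
#' @export
estimate_fundamental <- function(s, band = c(5, 25), prominence_db = 6) {
  if (!inherits(s, "call_spectrum")) stop("s must be a call_spectrum")
  if (!is.numeric(band) || length(band) != 2L || band[1] >= band[2])
    stop("band must be c(low, high) with low < high")
  if (band[1] < min(s$frequencies) || band[2] > max(s$frequencies))
    stop("band outside spectrum range")
  sel <- which(s$frequencies >= band[1] & s$frequencies <= band[2])
  if (length(sel) < 3L) stop("band too narrow for this spectrum resolution")
  lm <- local_maxima(s$power, sel)
  if (!length(lm)) stop("no local maximum in band")
  i <- lm[which.max(s$power[lm])]
  pk <- interp_peak(s$frequencies, s$power, i)
  prom <- 10 * log10(s$power[i] / (stats::median(s$power[sel]) + 1e-300))
  structure(pk$freq, prominence_db = prom, prominent = prom >= prominence_db)
}

## lowest prominent local maximum in band (used for octave disambiguation);
## a -40 dB floor relative to the in-band maximum keeps leakage ripples out
lowest_prominent_peak <- function(s, band, prominence_db = 6, floor_db = -40) {
  sel <- which(s$frequencies >= band[1] & s$frequencies <= band[2])
  lm <- local_maxima(s$power, sel)
  if (!length(lm)) return(NA_real_)
  med <- stats::median(s$power[sel]) + 1e-300
  floor_pow <- max(s$power[sel]) * 10^(floor_db / 10)
  prom <- lm[10 * log10(s$power[lm] / med) >= prominence_db &
             s$power[lm] >= floor_pow]
  if (!length(prom)) return(NA_real_)
  interp_peak(s$frequencies, s$power, min(prom))$freq
}

#' Locate overtone peaks of a fundamental
#'
#' For each integer harmonic number k >= 2 with
#' `k * fundamental <= max_freq`, searches the window
#' `k * fundamental +/- rel_tolerance * fundamental` for prominent local
#' maxima (at least `prominence_db` above the window median power) and
#' reports the one nearest the expected harmonic frequency, refined by
#' parabolic interpolation. Harmonics without a prominent peak are
#' simply absent from the output.
#'
#' @param s A `call_spectrum`.
#' @param fundamental Fundamental frequency in Hz (> 0).
#' @param max_freq Upper frequency limit in Hz (default 100, the B-call
#'   energy band).
#' @param rel_tolerance Half-width of each search window as a fraction of
#'   the fundamental (default 0.25).
#' @param prominence_db Peak prominence threshold in dB above the window
#'   median (default 6).
#' @param floor_db Dynamic-range floor in dB relative to the spectrum's
#'   maximum power (default -60): candidate peaks below it are treated as
#'   leakage/noise, not overtones.
#' @return An object of class `harmonic_structure` with fields
#'   `fundamental`, `harmonic` (integer harmonic numbers), `overtones`
#'   (Hz, ascending), `amplitudes` (peak power) and `n_overtones`.
#' @export
find_harmonics <- function(s, fundamental, max_freq = 100,
                           rel_tolerance = 0.25, prominence_db = 6,
                           floor_db = -60) {
  if (!inherits(s, "call_spectrum")) stop("s must be a call_spectrum")
  if (!is.numeric(fundamental) || fundamental <= 0)
    stop("fundamental must be positive")
  ks <- seq_len(floor(max_freq / fundamental))
  ks <- ks[ks >= 2]
  floor_pow <- max(s$power) * 10^(floor_db / 10)
  ov <- numeric(0); amp <- numeric(0); hk <- integer(0)
  for (k in ks) {
    f_exp <- k * fundamental
    sel <- which(s$frequencies >= f_exp - rel_tolerance * fundamental &
                 s$frequencies <= f_exp + rel_tolerance * fundamental)
    if (length(sel) < 3L) next
    lm <- local_maxima(s$power, sel)
    if (!length(lm)) next
    med <- stats::median(s$power[sel]) + 1e-300
    lm <- lm[10 * log10(s$power[lm] / med) >= prominence_db &
             s$power[lm] >= floor_pow]
    if (!length(lm)) next
    i <- lm[which.min(abs(s$frequencies[lm] - f_exp))]
    pk <- interp_peak(s$frequencies, s$power, i)
    ov <- c(ov, pk$freq); amp <- c(amp, pk$power); hk <- c(hk, k)
  }
  structure(
    list(fundamental = fundamental, harmonic = hk, overtones = ov,
         amplitudes = amp, n_overtones = length(ov)),
    class = "harmonic_structure"
  )
}

#' @export
print.harmonic_structure <- function(x, ...) {
  cat(sprintf("<harmonic_structure> fundamental %.3f Hz, %d overtones\n",
              x$fundamental, x$n_overtones))
  if (x$n_overtones)
    cat("  overtones (Hz):", paste(sprintf("%.2f", x$overtones), collapse = ", "), "\n")
  invisible(x)
}

#' Frame-wise fundamental-frequency track
#'
#' Runs the in-band peak estimator of [estimate_fundamental()] on each
#' spectrogram frame, producing the fundamental track that a
#' variable-interval pulse schedule shifts over time.
#'
#' @param w A [waveform()].
#' @param band Search band in Hz.
#' @param window_s,overlap_fraction,zero_pad_factor Passed to
#'   [spectrogram()].
#' @param prominence_db Prominence flag threshold per frame.
#' @return A data.frame with columns `time` (s, window centers), `f0`
#'   (Hz, NA when a frame has no in-band local maximum),
#'   `prominence_db` and `prominent`.
#' @export
f0_track <- function(w, band = c(5, 25), window_s = 2,
                     overlap_fraction = 0.75, zero_pad_factor = 4,
                     prominence_db = 6) {
  sg <- spectrogram(w, window_s, overlap_fraction, zero_pad_factor)
  sel <- which(sg$frequencies >= band[1] & sg$frequencies <= band[2])
  if (length(sel) < 3L) stop("band too narrow for this window length")
  out <- lapply(seq_along(sg$times), function(j) {
    p <- sg$power[, j]
    lm <- local_maxima(p, sel)
    if (!length(lm)) return(c(NA_real_, NA_real_))
    i <- lm[which.max(p[lm])]
    prom <- 10 * log10(p[i] / (stats::median(p[sel]) + 1e-300))
    c(interp_peak(sg$frequencies, p, i)$freq, prom)
  })
  m <- do.call(rbind, out)
  data.frame(time = sg$times, f0 = m[, 1], prominence_db = m[, 2],
             prominent = !is.na(m[, 2]) & m[, 2] >= prominence_db)
}
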