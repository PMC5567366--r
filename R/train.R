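#' Inter-pulse interval schedule
#'
#' Holds the pulse onset times of a call. The fundamental frequency of the
#' synthesized call equals the reciprocal of the local inter-pulse
#' interval, so the schedule fully controls the harmonic structure.
#'
#' @param intervals Positive inter-pulse intervals in seconds. The first
#'   onset is placed at t = 0; onset k+1 follows onset k by
#'   `intervals[k]`. An empty vector yields a single onset at 0.
#' @return An object of class `interval_schedule` with fields `onsets`
#'   and `intervals`.
#' @seealso [constant_intervals()], [intervals_from_f0()]
#' @export
interval_schedule <- function(intervals = numeric()) {
  intervals <- as.numeric(intervals)
  if (length(intervals) && (!all(is.finite(intervals)) || any(intervals <= 0)))
    stop("all intervals must be positive and finite")
  onsets <- c(0, cumsum(intervals))
  structure(list(onsets = onsets, intervals = intervals),
            class = "interval_schedule")
}

#' @export
print.interval_schedule <- function(x, ...) {
  rng <- if (length(x$intervals)) sprintf("intervals in [%.4g, %.4g] s",
                                          min(x$intervals), max(x$intervals))
         else "single onset"
  cat(sprintf("<interval_schedule> %d onsets over %.3f s; %s\n",
              length(x$onsets), max(x$onsets), rng))
  invisible(x)
}

#' Constant-interval schedule covering a record
#'
#' @param interval Inter-pulse interval in seconds (> 0).
#' @param total_duration Record length in seconds; onsets cover
#'   `[0, total_duration)`.
#' @return An [interval_schedule()].
#' @export
constant_intervals <- function(interval, total_duration) {
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
    stop("interval must be a single positive number")
  if (!is.numeric(total_duration) || total_duration <= 0)
    stop("total_duration must be positive")
  n <- ceiling(total_duration / interval - 1e-9)
  interval_schedule(rep(interval, max(n - 1L, 0L)))
}

#' Schedule from a fundamental-frequency track
#'
#' Generates pulse onsets so that the local inter-pulse interval equals
#' the reciprocal of the fundamental-frequency track at that time:
#' varying the interval is exactly the mechanism by which the model
#' shifts the call's fundamental and overtones.
#'
#' @param f0_values Fundamental-frequency samples in Hz (> 0), assumed
#'   uniformly spaced over `[0, total_duration]`. A single value gives a
#'   constant schedule.
#' @param total_duration Record length in seconds; onsets cover
#'   `[0, total_duration)`.
#' @return An [interval_schedule()].
#' @examples
#' sch <- intervals_from_f0(14.73, 7)     # ~103 intervals of 1/14.73 s
#' range(sch$intervals)
#' @export
intervals_from_f0 <- function(f0_values, total_duration) {
  f0_values <- as.numeric(f0_values)
  if (!length(f0_values) || !all(is.finite(f0_values)) || any(f0_values <= 0))
    stop("all f0 values must be positive and finite")
  if (!is.numeric(total_duration) || total_duration <= 0)
    stop("total_duration must be positive")
  f_at <- if (length(f0_values) == 1L) {
    function(t) f0_values
  } else {
    tg <- seq(0, total_duration, length.out = length(f0_values))
    function(t) stats::approx(tg, f0_values, xout = t, rule = 2)$y
  }
  onsets <- numeric(0)
  t <- 0
  while (t < total_duration - 1e-12) {
    onsets <- c(onsets, t)
    t <- t + 1 / f_at(t)
  }
  interval_schedule(diff(onsets))
}

#' Pulse-train call specification
#'
#' Everything needed to deterministically synthesize a call: the wavelet
#' shape, its rescaled duration, the onset schedule, record length,
#' sample rate and amplitude taper.
#'
#' @param schedule An [interval_schedule()].
#' @param total_duration Record length in seconds (> 0).
#' @param sample_rate Sampling rate in Hz. Must comfortably exceed twice
#'   the highest overtone of interest (2 kHz default covers the < 100 Hz
#'   B-call band many times over).
#' @param pulse_duration Effective wavelet duration in seconds after
#'   rescaling (default 0.068 s, the B-call model wavelet).
#' @param shape A [pulse_shape()].
#' @param taper_fraction Fraction of the record covered by the
#'   raised-cosine ramps of the whole-train taper (see [cosine_taper()]).
#' @return An object of class `pulse_train_spec`.
#' @seealso [bcall_spec()] for the canonical B-call configuration.
#' @export
pulse_train_spec <- function(schedule, total_duration, sample_rate = 2000,
                             pulse_duration = 0.068, shape = pulse_shape(),
                             taper_fraction = 0.1) {
  if (!inherits(schedule, "interval_schedule"))
    stop("schedule must be an interval_schedule")
  if (!is.numeric(total_duration) || total_duration <= 0)
    stop("total_duration must be positive")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  if (!is.numeric(pulse_duration) || pulse_duration <= 0)
    stop("pulse_duration must be positive")
  if (!inherits(shape, "pulse_shape"))
    stop("shape must be a pulse_shape")
  if (!is.numeric(taper_fraction) || taper_fraction < 0 || taper_fraction > 1)
    stop("taper_fraction must be in [0, 1]")
  structure(
    list(shape = shape, pulse_duration = pulse_duration, schedule = schedule,
         total_duration = total_duration, sample_rate = sample_rate,
         taper_fraction = taper_fraction),
    class = "pulse_train_spec"
  )
}

#' Canonical B-call pulse-train specification
#'
#' Convenience constructor for the reference B-call model: a 0.068 s
#' wavelet repeated at a constant interval of `1/f0` over a 7 s record at
#' 2 kHz. The default fundamental of 14.73 Hz places the five overtones
#' below 100 Hz at 29.5, 44.2, 58.9, 73.6 and 88.4 Hz.
#'
#' @param f0 Fundamental frequency in Hz; the inter-pulse interval is
#'   `1/f0`.
#' @param total_duration,sample_rate,pulse_duration,taper_fraction,shape
#'   Passed to [pulse_train_spec()].
#' @return A `pulse_train_spec`.
#' @export
bcall_spec <- function(f0 = 14.73, total_duration = 7, sample_rate = 2000,
                       pulse_duration = 0.068, taper_fraction = 0.1,
                       shape = pulse_shape()) {
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0)
    stop("f0 must be a single positive number (Hz)")
  pulse_train_spec(constant_intervals(1 / f0, total_duration),
                   total_duration, sample_rate, pulse_duration,
                   shape, taper_fraction)
}

#' Raised-cosine (Tukey) amplitude taper
#'
#' Symmetric envelope with maximum 1 whose two raised-cosine ramps
#' together cover `taper_fraction` of the record (half at each end).
#' `taper_fraction = 0` gives a rectangular window, `taper_fraction = 1`
#' the full Hann window.
#'
#' @param n_samples Envelope length (>= 2).
#' @param taper_fraction Fraction in [0, 1].
#' @return Numeric envelope vector of length `n_samples`.
#' @export
cosine_taper <- function(n_samples, taper_fraction) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2)
    stop("n_samples must be at least 2")
  if (!is.numeric(taper_fraction) || taper_fraction < 0 || taper_fraction > 1)
    stop("taper_fraction must be in [0, 1]")
  n <- as.integer(n_samples)
  if (taper_fraction == 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  env <- rep(1, n)
  half <- taper_fraction / 2
  lo <- x < half
  env[lo] <- 0.5 * (1 + cos(pi * (x[lo] / half - 1)))
  hi <- x > 1 - half
  env[hi] <- 0.5 * (1 + cos(pi * ((x[hi] - 1 + half) / half)))
  env
}

#' Synthesize a pulse-train call waveform
#'
#' Overlap-adds peak-normalized copies of the (rescaled) source wavelet
#' so that each copy's maximum-amplitude sample sits at its scheduled
#' onset time (nearest-sample placement), then applies the whole-train
#' raised-cosine taper. Because the harmonic structure of the result is
#' keyed to the time spacing of the wavelet amplitude maxima, the
#' fundamental of the output equals the reciprocal inter-pulse interval.
#'
#' @param spec A [pulse_train_spec()].
#' @return A [waveform()] of length `total_duration * sample_rate`.
#' @examples
#' w <- synthesize_train(bcall_spec())
#' s <- power_spectrum(w)
#' estimate_fundamental(s, band = c(5, 25))   # ~14.73 Hz
#' @export
synthesize_train <- function(spec) {
  if (!inherits(spec, "pulse_train_spec"))
    stop("spec must be a pulse_train_spec")
  n <- round(spec$total_duration * spec$sample_rate)
  if (n < 2) stop("total_duration too short at this sample_rate")
  onsets <- spec$schedule$onsets
  if (max(onsets) >= spec$total_duration)
    stop("schedule onset beyond total_duration")
  base <- sample_pulse(spec$shape, spec$sample_rate)
  if (round(length(base$samples) *
            spec$pulse_duration / effective_duration(base)) < 4)
    stop("sample_rate too low to represent the rescaled pulse")
  wl <- rescale_duration(base, spec$pulse_duration)
  v <- wl$samples / max(abs(wl$samples))
  pk <- which.max(abs(v))
  x <- numeric(n)
  offs <- seq_along(v) - pk
  for (o in onsets) {
    js <- round(o * spec$sample_rate) + 1L + offs
    ok <- js >= 1L & js <= n
    x[js[ok]] <- x[js[ok]] + v[ok]
  }
  x <- x * cosine_taper(n, spec$taper_fraction)
  waveform(x, spec$sample_rate)
}
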