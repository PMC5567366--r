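#' Uniformly sampled waveform
#'
#' The universal container passed between every module of the package: a
#' numeric amplitude vector on a uniform time grid. Amplitudes are
#' dimensionless (the toolkit carries no absolute pressure calibration).
#'
#' @param samples Numeric vector of amplitudes; all values must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `waveform` with fields `samples`,
#'   `sample_rate` and `start_time`.
#' @examples
#' w <- waveform(sin(2 * pi * 14.73 * seq(0, 1, by = 1/2000)), 2000)
#' wave_duration(w)
#' @export
waveform <- function(samples, sample_rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("waveform needs at least one sample")
  if (!all(is.finite(samples)))
    stop("waveform samples must all be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a single positive number (Hz)")
  if (!is.numeric(start_time) || length(start_time) != 1L || !is.finite(start_time))
    stop("start_time must be a single finite number (seconds)")
  structure(
    list(samples = samples, sample_rate = sample_rate, start_time = start_time),
    class = "waveform"
  )
}

#' Test whether an object is a waveform
#'
#' @param x Any object.
#' @return `TRUE` if `x` is a [waveform()].
#' @export
is_waveform <- function(x) inherits(x, "waveform")

as_waveform <- function(x, sample_rate) {
  if (is_waveform(x)) x else waveform(x, sample_rate)
}

stopifnot_waveform <- function(x, arg = deparse(substitute(x))) {
  if (!is_waveform(x)) stop(sprintf("`%s` must be a waveform object", arg))
  invisible(x)
}

#' Duration of a waveform in seconds
#'
#' @param w A [waveform()].
#' @return Record length in seconds (`n / sample_rate`).
#' @export
wave_duration <- function(w) {
  stopifnot_waveform(w)
  length(w$samples) / w$sample_rate
}

#' Time axis of a waveform
#'
#' @param w A [waveform()].
#' @return Numeric vector of sample times in seconds.
#' @export
time_axis <- function(w) {
  stopifnot_waveform(w)
  w$start_time + (seq_along(w$samples) - 1) / w$sample_rate
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
    length(x$samples), x$sample_rate, wave_duration(x),
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ...) {
  graphics::plot(time_axis(x), x$samples, type = "l",
                 xlab = "time (s)", ylab = "amplitude", ...)
  invisible(x)
}
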