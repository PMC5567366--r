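#' Parameters of the source pulse wavelet
#'
#' The pulsed-air model builds a B call from copies of a single short
#' biphasic pressure pulse `P(t) = dq/dt`, where `q` is a piecewise
#' rational function peaking at `t = a`:
#' \deqn{q(t) = 1 / ((t - a)^2 + 0.01), \quad t < a}
#' \deqn{q(t) = 10 / ((t - a)^2 + 0.1), \quad t > a}
#' `a` sets the time position (and hence usable length) of the pulse;
#' the default constants make `q` continuous at `t = a` (both branches
#' equal 100 there).
#'
#' @param a Peak-time constant in seconds (> 0). Default 0.3, which keeps
#'   the pulse support inside `t > 0` and under a second.
#' @param eps_pre Pre-peak denominator offset (> 0), default 0.01.
#' @param eps_post Post-peak denominator offset (> 0), default 0.1.
#' @param scale_post Post-peak numerator scale (> 0), default 10.
#'
#' @return An object of class `pulse_shape`.
#' @examples
#' sh <- pulse_shape()
#' eval_q(0.3, sh)      # 100: both branches agree at the peak
#' eval_pulse(0.3, sh)  # 0: the derivative vanishes at t = a
#' @export
pulse_shape <- function(a = 0.3, eps_pre = 0.01, eps_post = 0.1, scale_post = 10) {
  for (nm in c("a", "eps_pre", "eps_post", "scale_post")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive finite number", nm))
  }
  structure(
    list(a = a, eps_pre = eps_pre, eps_post = eps_post, scale_post = scale_post),
    class = "pulse_shape"
  )
}

#' @export
print.pulse_shape <- function(x, ...) {
  cat(sprintf("<pulse_shape> a = %g s, eps_pre = %g, eps_post = %g, scale_post = %g\n",
              x$a, x$eps_pre, x$eps_post, x$scale_post))
  invisible(x)
}

#' Evaluate the pulse potential q(t)
#'
#' Piecewise rational function whose time derivative is the source pulse.
#' At `t = a` the left-branch value `1/eps_pre` is returned; with the
#' default constants both one-sided limits coincide (100).
#'
#' @param t Time(s) in seconds; vectorized. Must be finite.
#' @param shape A [pulse_shape()].
#' @return q(t), dimensionless, positive everywhere.
#' @export
eval_q <- function(t, shape = pulse_shape()) {
  if (!is.numeric(t) || !all(is.finite(t)))
    stop("`t` must be finite numeric")
  u <- t - shape$a
  ifelse(u < 0, 1 / (u^2 + shape$eps_pre),
         ifelse(u > 0, shape$scale_post / (u^2 + shape$eps_post),
                1 / shape$eps_pre))
}

#' Evaluate the source pulse P(t) = dq/dt
#'
#' Analytic closed-form derivative of [eval_q()]:
#' \deqn{P(t) = -2 (t - a) / ((t - a)^2 + eps_{pre})^2, \quad t < a}
#' \deqn{P(t) = -2\, scale_{post} (t - a) / ((t - a)^2 + eps_{post})^2, \quad t > a}
#' and `P(a) = 0` (both one-sided derivatives vanish there). The pulse is
#' biphasic: positive for `t < a`, negative for `t > a`.
#'
#' @inheritParams eval_q
#' @return P(t), dimensionless.
#' @export
eval_pulse <- function(t, shape = pulse_shape()) {
  if (!is.numeric(t) || !all(is.finite(t)))
    stop("`t` must be finite numeric")
  u <- t - shape$a
  ifelse(u < 0, -2 * u / (u^2 + shape$eps_pre)^2,
         ifelse(u > 0, -2 * shape$scale_post * u / (u^2 + shape$eps_post)^2,
                0))
}

#' Sample the source pulse on a uniform grid
#'
#' @param shape A [pulse_shape()].
#' @param sample_rate Sampling rate in Hz.
#' @param support Time interval `c(t0, t1)` to sample, seconds. Default
#'   `c(0, 2 * a)`, which brackets the full biphasic pulse. `t0 >= 0` and
#'   `t1 > t0` required. Samples cover `[t0, t1)`.
#' @return A [waveform()] of `P(t)` values in natural (unnormalized)
#'   units; peak normalization happens at train-synthesis time so the
#'   closed-form values stay directly checkable.
#' @export
sample_pulse <- function(shape = pulse_shape(), sample_rate = 2000,
                         support = c(0, 2 * shape$a)) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be positive")
  if (!is.numeric(support) || length(support) != 2L || !all(is.finite(support)))
    stop("support must be a finite numeric interval c(t0, t1)")
  if (support[1] < 0)
    stop("support must lie within t >= 0")
  n <- floor((support[2] - support[1]) * sample_rate + 1e-9)
  if (n < 1L)
    stop("empty support: support[2] must exceed support[1] by at least one sample period")
  t <- support[1] + (seq_len(n) - 1) / sample_rate
  waveform(eval_pulse(t, shape), sample_rate, start_time = support[1])
}

#' Effective duration of a pulse waveform
#'
#' Operational definition of "pulse duration": the width of the interval
#' over which `|P|` is at least `rel_threshold` (default 1%) of its
#' maximum absolute amplitude.
#'
#' @param w A [waveform()].
#' @param rel_threshold Relative amplitude threshold in (0, 1).
#' @return Duration in seconds.
#' @export
effective_duration <- function(w, rel_threshold = 0.01) {
  stopifnot_waveform(w)
  if (!is.numeric(rel_threshold) || rel_threshold <= 0 || rel_threshold >= 1)
    stop("rel_threshold must be in (0, 1)")
  aa <- abs(w$samples)
  idx <- which(aa >= rel_threshold * max(aa))
  (max(idx) - min(idx)) / w$sample_rate
}

#' Rescale a pulse to a target effective duration
#'
#' Compresses (or stretches) the time axis of a sampled pulse so that its
#' [effective_duration()] equals `target_duration`, preserving the
#' amplitude shape up to resampling. The output keeps the input sample
#' rate. This is the step that turns the canonical `a = 0.3` pulse
#' (roughly 0.6 s of support) into the 0.068 s wavelet used in the
#' B-call model.
#'
#' @param pulse A [waveform()] holding a single pulse.
#' @param target_duration Desired effective duration in seconds (> 0).
#' @param rel_threshold Threshold passed to [effective_duration()].
#' @return A [waveform()]; rejected if fewer than 4 output samples would
#'   remain.
#' @export
rescale_duration <- function(pulse, target_duration, rel_threshold = 0.01) {
  stopifnot_waveform(pulse)
  if (!is.numeric(target_duration) || length(target_duration) != 1L ||
      !is.finite(target_duration) || target_duration <= 0)
    stop("target_duration must be a single positive number (seconds)")
  cur <- effective_duration(pulse, rel_threshold)
  factor <- target_duration / cur
  n_in <- length(pulse$samples)
  n_out <- round(n_in * factor)
  if (n_out < 4L)
    stop("target_duration too short: fewer than 4 samples would remain")
  if (n_out == n_in) return(pulse)
  y <- stats::spline(x = seq_len(n_in), y = pulse$samples,
                     xout = seq(1, n_in, length.out = n_out))$y
  waveform(y, pulse$sample_rate, start_time = pulse$start_time)
}
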