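#' Parameters of the variable-phase sinusoid (resonance-style) model
#'
#' The comparison model against which the pulse train is judged: a sine
#' summation with a per-sample amplitude interpolation and an accumulated
#' variable phase term, after the spectral-peak-tracking detector model
#' of Mellinger & Clark. Two readings are provided:
#'
#' * `"literal-chirp"`: the printed formula taken literally. Sample
#'   `i` (0-based, i = 0..N-2) has amplitude `a0 + i (a1 - a0)/(N - 1)`
#'   and phase `P + (2 pi / R) * sum_{j=0}^{i} (j (f1 - f0)/N + f0)`, so
#'   the instantaneous frequency ramps linearly from `f0` towards `f1`.
#' * `"harmonic-stack"`: the stated intent for a B call - two harmonic
#'   components centred at `f0` and `f1` (fundamental and first
#'   overtone), each sweeping linearly from `centre + sweep_halfwidth`
#'   down to `centre - sweep_halfwidth` over the record (downswept, the
#'   B-call convention), with amplitudes `a0` and `a1`.
#'
#' Default amplitudes (1 and 0.5) keep the summed signal within ±1.5.
#'
#' @param sample_rate Sample rate R in Hz.
#' @param n_samples Number of data points N (>= 2); the product of the
#'   sample rate and the duration in seconds.
#' @param phase Initial phase P in radians (default 0).
#' @param a0,a1 Amplitude coefficients (dimensionless).
#' @param f0,f1 Frequencies in Hz (> 0). In literal-chirp mode these are
#'   the start and end of the sweep; in harmonic-stack mode the centre
#'   frequencies of the two components (defaults 14.73 and 29.5 Hz).
#' @param mode `"harmonic-stack"` (default) or `"literal-chirp"`.
#' @param sweep_halfwidth Half-width of the frequency sweep in Hz
#'   (default 0.42; harmonic-stack mode only).
#' @return An object of class `sinusoid_params`.
#' @export
sinusoid_params <- function(sample_rate = 2000, n_samples = 14000, phase = 0,
                            a0 = 1, a1 = 0.5, f0 = 14.73, f1 = 29.5,
                            mode = c("harmonic-stack", "literal-chirp"),
                            sweep_halfwidth = 0.42) {
  mode <- match.arg(mode)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  if (!is.numeric(n_samples) || n_samples < 2)
    stop("n_samples must be at least 2")
  if (!is.numeric(f0) || !is.numeric(f1) || f0 <= 0 || f1 <= 0)
    stop("f0 and f1 must be positive (Hz)")
  if (!is.numeric(sweep_halfwidth) || sweep_halfwidth < 0)
    stop("sweep_halfwidth must be non-negative")
  structure(
    list(sample_rate = sample_rate, n_samples = as.integer(n_samples),
         phase = phase, a0 = a0, a1 = a1, f0 = f0, f1 = f1,
         mode = mode, sweep_halfwidth = sweep_halfwidth),
    class = "sinusoid_params"
  )
}

#' @export
print.sinusoid_params <- function(x, ...) {
  cat(sprintf("<sinusoid_params> mode = %s, f0 = %g Hz, f1 = %g Hz, N = %d @ %g Hz\n",
              x$mode, x$f0, x$f1, x$n_samples, x$sample_rate))
  invisible(x)
}

#' Synthesize the literal-chirp sinusoid model
#'
#' Evaluates the printed variable-phase sine summation as a time series
#' of N - 1 samples (the outer sum indexes output samples). The
#' accumulated phase makes the instantaneous frequency ramp linearly
#' from `f0` towards `f1`.
#'
#' @param params A [sinusoid_params()]; `mode` is ignored here.
#' @return A [waveform()] of length `n_samples - 1`.
#' @export
synthesize_sp <- function(params) {
  if (!inherits(params, "sinusoid_params"))
    stop("params must be sinusoid_params")
  N <- params$n_samples
  if (N < 2) stop("n_samples must be at least 2")
  i <- 0:(N - 2)
  amp <- params$a0 + i * (params$a1 - params$a0) / (N - 1)
  finst <- i * (params$f1 - params$f0) / N + params$f0
  ph <- params$phase + (2 * pi / params$sample_rate) * cumsum(finst)
  waveform(amp * sin(ph), params$sample_rate)
}

#' Synthesize the harmonic-stack sinusoid model
#'
#' Sum of two components centred at `f0` and `f1`, each sweeping
#' linearly from `centre + sweep_halfwidth` down to
#' `centre - sweep_halfwidth` over the record, with amplitudes `a0` and
#' `a1`. With the defaults (14.73 and 29.5 Hz, ±0.42 Hz, amplitudes
#' 1 and 0.5) this reproduces the slightly downswept two-harmonic B-call
#' stack bounded within ±1.5.
#'
#' @param params A [sinusoid_params()]; `mode` is ignored here.
#' @return A [waveform()] of length `n_samples`.
#' @export
synthesize_harmonic_stack <- function(params) {
  if (!inherits(params, "sinusoid_params"))
    stop("params must be sinusoid_params")
  N <- params$n_samples
  i <- 0:(N - 1)
  sweep <- params$sweep_halfwidth * (1 - 2 * i / (N - 1))
  k <- 2 * pi / params$sample_rate
  x <- params$a0 * sin(params$phase + k * cumsum(params$f0 + sweep)) +
       params$a1 * sin(params$phase + k * cumsum(params$f1 + sweep))
  waveform(x, params$sample_rate)
}

#' Synthesize a sinusoid model according to its mode
#'
#' Dispatches to [synthesize_sp()] or [synthesize_harmonic_stack()]
#' based on `params$mode`.
#'
#' @param params A [sinusoid_params()].
#' @return A [waveform()].
#' @export
synthesize_sinusoid <- function(params) {
  if (!inherits(params, "sinusoid_params"))
    stop("params must be sinusoid_params")
  switch(params$mode,
         "literal-chirp" = synthesize_sp(params),
         "harmonic-stack" = synthesize_harmonic_stack(params))
}
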