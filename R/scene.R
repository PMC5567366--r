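#' Synthetic hydrophone scene configuration
#'
#' Describes a ground-truth call plus the two propagation effects a
#' shallow-water hydrophone record adds on top of it: delayed, scaled and
#' possibly polarity-flipped multipath copies (the lower-amplitude
#' secondary arrivals seen between the fundamental peaks of real B
#' calls, at delays near 0.03-0.04 s), and band-limited ambient noise
#' from wind and surface waves. The scene keeps full truth metadata so
#' parameter-recovery experiments can score themselves.
#'
#' @param truth A [pulse_train_spec()] or [sinusoid_params()] describing
#'   the clean call.
#' @param echo_delays Echo delays in seconds (> 0), default
#'   `c(0.03, 0.04)`.
#' @param echo_gains Echo amplitude gains, `|gain| < 1` (echoes are lower
#'   amplitude than the direct arrival), default `c(0.4, 0.3)`.
#' @param echo_polarities Echo polarities, each +1 or -1, default
#'   `c(-1, 1)`.
#' @param snr_db In-band signal-to-noise ratio in dB; `Inf` disables
#'   noise.
#' @param noise_band Ambient-noise band in Hz, default `c(5, 400)` (flat
#'   in band).
#' @param seed Integer RNG seed; a fixed seed makes the scene bit-exactly
#'   reproducible.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(truth = bcall_spec(),
                         echo_delays = c(0.03, 0.04),
                         echo_gains = c(0.4, 0.3),
                         echo_polarities = c(-1, 1),
                         snr_db = 10,
                         noise_band = c(5, 400),
                         seed = 1L) {
  if (!inherits(truth, "pulse_train_spec") && !inherits(truth, "sinusoid_params"))
    stop("truth must be a pulse_train_spec or sinusoid_params")
  k <- length(echo_delays)
  if (length(echo_gains) != k || length(echo_polarities) != k)
    stop("echo_delays, echo_gains and echo_polarities must have equal length")
  if (k && (any(echo_delays <= 0) || any(!is.finite(echo_delays))))
    stop("echo delays must be positive")
  if (k && any(abs(echo_gains) >= 1))
    stop("echo gains must have magnitude < 1")
  if (k && !all(echo_polarities %in% c(-1, 1)))
    stop("echo polarities must be +1 or -1")
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("snr_db must be a single number (possibly Inf)")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer")
  structure(
    list(truth = truth, echo_delays = echo_delays, echo_gains = echo_gains,
         echo_polarities = echo_polarities, snr_db = snr_db,
         noise_band = noise_band, seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Add multipath echo copies to a waveform
#'
#' Adds `sum_k polarity_k * gain_k * w(t - delay_k)` to the input
#' (zero-padded shifts, nearest-sample delays): the linear propagation
#' operator standing in for reflections off the sea surface, seafloor or
#' reef structures.
#'
#' @param w A [waveform()].
#' @param delays Echo delays in seconds, each positive and shorter than
#'   the record.
#' @param gains Echo gains (same length as `delays`).
#' @param polarities +1/-1 per echo (same length).
#' @return A [waveform()] of the same length.
#' @export
add_multipath <- function(w, delays, gains, polarities) {
  stopifnot_waveform(w)
  k <- length(delays)
  if (length(gains) != k || length(polarities) != k)
    stop("delays, gains and polarities must have equal length")
  if (!k) return(w)
  if (any(delays <= 0)) stop("delays must be positive")
  if (any(delays >= wave_duration(w))) stop("delay at or beyond record length")
  x <- w$samples
  n <- length(x)
  y <- x
  for (i in seq_len(k)) {
    d <- round(delays[i] * w$sample_rate)
    if (d >= 1)
      y[(d + 1):n] <- y[(d + 1):n] + polarities[i] * gains[i] * x[1:(n - d)]
    else
      y <- y + polarities[i] * gains[i] * x
  }
  waveform(y, w$sample_rate, w$start_time)
}

## evaluate fn with a temporary RNG state, restoring the caller's state
with_local_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Add band-limited Gaussian ambient noise at a prescribed in-band SNR
#'
#' Gaussian noise band-passed to `band` (flat in band) is scaled so that
#' the ratio of in-band signal power to noise power equals `snr_db`, then
#' added to the waveform. In-band signal power is measured by passing a
#' copy of the signal through the same filter. A fixed seed gives
#' bit-exactly reproducible output and leaves the caller's RNG state
#' untouched.
#'
#' @param w A [waveform()].
#' @param snr_db Target in-band SNR in dB; `Inf` returns the input
#'   unchanged.
#' @param band Noise band in Hz, `0 < low < high < Nyquist`.
#' @param seed Optional integer seed.
#' @return A [waveform()] of the same length.
#' @export
add_noise <- function(w, snr_db, band = c(5, 400), seed = NULL) {
  stopifnot_waveform(w)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("snr_db must be a single number")
  if (is.infinite(snr_db) && snr_db > 0) return(w)
  nyq <- w$sample_rate / 2
  if (!is.numeric(band) || length(band) != 2L || band[1] <= 0 ||
      band[2] <= band[1] || band[2] >= nyq)
    stop("invalid noise band")
  gen <- function() stats::rnorm(length(w$samples))
  z <- if (is.null(seed)) gen() else with_local_seed(seed, gen)
  bf <- signal::butter(4, band / nyq, type = "pass")
  noise <- signal::filtfilt(bf, z)
  sig_ib <- signal::filtfilt(bf, w$samples)
  p_sig <- mean(sig_ib^2)
  if (p_sig <= 0) stop("silent input: in-band SNR undefined")
  scale <- sqrt(p_sig / mean(noise^2) / 10^(snr_db / 10))
  waveform(w$samples + scale * noise, w$sample_rate, w$start_time)
}

#' Simulate a synthetic hydrophone scene
#'
#' Synthesizes the ground-truth call from `config$truth`, applies the
#' multipath echoes, then the ambient noise, and returns both the clean
#' and observed waveforms together with the configuration.
#'
#' @param config A [scene_config()].
#' @return An object of class `hydrophone_scene` with fields `clean`
#'   (truth waveform), `observed` (clean + echoes + noise) and `config`.
#' @examples
#' sc <- simulate_scene(scene_config(snr_db = 10, seed = 42))
#' fit <- fit_pulse_train(sc$observed)
#' abs(fit$params$interval - 1/14.73) / (1/14.73)   # < 1% interval error
#' @export
simulate_scene <- function(config) {
  if (!inherits(config, "scene_config"))
    stop("config must be a scene_config")
  clean <- if (inherits(config$truth, "pulse_train_spec"))
    synthesize_train(config$truth)
  else
    synthesize_sinusoid(config$truth)
  obs <- add_multipath(clean, config$echo_delays, config$echo_gains,
                       config$echo_polarities)
  obs <- add_noise(obs, config$snr_db, config$noise_band, seed = config$seed)
  structure(list(clean = clean, observed = obs, config = config),
            class = "hydrophone_scene")
}

#' @export
print.hydrophone_scene <- function(x, ...) {
  kind <- if (inherits(x$config$truth, "pulse_train_spec")) "pulse-train" else "sinusoid"
  cat(sprintf(
    "<hydrophone_scene> %s truth, %d echoes, SNR %g dB, seed %d; %.2f s @ %g Hz\n",
    kind, length(x$config$echo_delays), x$config$snr_db, x$config$seed,
    wave_duration(x$observed), x$observed$sample_rate))
  invisible(x)
}
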