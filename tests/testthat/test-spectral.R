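test_that("a pure tone yields a single dominant in-band peak", {
  t <- (0:13999) / 2000
  w <- waveform(sin(2 * pi * 20 * t), 2000)
  s <- power_spectrum(w)
  expect_equal(s$frequencies[which.max(s$power)], 20, tolerance = 0.05)
  f0 <- estimate_fundamental(s, band = c(5, 25))
  expect_equal(as.numeric(f0), 20, tolerance = 0.01)
  expect_true(attr(f0, "prominent"))
})

test_that("a DC-only record peaks at 0 Hz", {
  s <- power_spectrum(waveform(rep(1, 512), 100))
  expect_equal(which.max(s$power), 1L)
  expect_equal(s$frequencies[1], 0)
})

test_that("spectrum rejects invalid inputs", {
  w <- waveform(rnorm(100), 100)
  expect_error(power_spectrum(w, zero_pad_factor = 0), ">= 1")
  expect_error(power_spectrum(waveform(1:8, 10)), "too short")
  expect_error(estimate_fundamental(power_spectrum(w), band = c(40, 20)),
               "low < high")
})

test_that("Parseval holds between windowed energy and spectral power", {
  set.seed(11)
  w <- waveform(rnorm(2048), 1000)
  s <- power_spectrum(w, zero_pad_factor = 2)
  # reassemble the two-sided sum from the single-sided spectrum (nfft even)
  two_sided <- s$power[1] + s$power[length(s$power)] +
    2 * sum(s$power[2:(length(s$power) - 1)])
  h <- 0.5 - 0.5 * cos(2 * pi * (0:2047) / 2047)
  energy <- sum((w$samples * h)^2)
  expect_equal(two_sided / s$nfft, energy, tolerance = 1e-6)
})

test_that("fundamental estimator bias is below one padded bin over a tone grid", {
  sr <- 500; n <- 2000
  t <- (0:(n - 1)) / sr
  bin <- sr / (4 * n)
  errs <- vapply(seq(6, 24, length.out = 100), function(f) {
    s <- power_spectrum(waveform(sin(2 * pi * f * t + 0.7), sr))
    abs(as.numeric(estimate_fundamental(s, band = c(5, 25))) - f)
  }, numeric(1))
  expect_lt(max(errs), bin)
})

test_that("noise-only estimates carry a much weaker prominence than tones", {
  set.seed(4)
  sr <- 2000
  wn <- waveform(rnorm(7 * sr), sr)
  fn <- estimate_fundamental(power_spectrum(wn), band = c(5, 25))
  expect_true(is.finite(as.numeric(fn)))
  tone <- waveform(sin(2 * pi * 14.73 * (0:(7 * sr - 1)) / sr), sr)
  ft <- estimate_fundamental(power_spectrum(tone), band = c(5, 25))
  expect_gt(attr(ft, "prominence_db"), attr(fn, "prominence_db") + 10)
})

test_that("harmonic finding reports an ideal comb and nothing for a sine", {
  comb <- tone_comb(14.73, 1:6)
  h <- find_harmonics(power_spectrum(comb), 14.73, max_freq = 100)
  expect_equal(h$n_overtones, 5L)
  expect_equal(h$overtones, c(29.46, 44.19, 58.92, 73.65, 88.38),
               tolerance = 1e-3)
  expect_true(all(diff(h$overtones) > 0))
  pure <- tone_comb(14.73, 1)
  expect_equal(find_harmonics(power_spectrum(pure), 14.73)$n_overtones, 0L)
})

test_that("a notched harmonic is absent while its neighbours are found", {
  notched <- tone_comb(14.73, c(1, 2, 4, 5, 6))
  h <- find_harmonics(power_spectrum(notched), 14.73, max_freq = 100)
  expect_false(3L %in% h$harmonic)
  expect_true(all(c(2L, 4L, 5L, 6L) %in% h$harmonic))
})

test_that("reported overtones are near integer multiples of the fundamental", {
  rel_tol <- 0.25
  w <- quick_train(duration = 5)
  h <- find_harmonics(power_spectrum(w), 14.73, max_freq = 100,
                      rel_tolerance = rel_tol)
  expect_true(all(abs(h$overtones / 14.73 - h$harmonic) < rel_tol))
})

test_that("spectrogram ridges behave for steady, silent and swept input", {
  sr <- 2000
  t <- (0:(8 * sr - 1)) / sr
  tone <- waveform(sin(2 * pi * 16 * t), sr)
  sg <- spectrogram(tone, window_s = 2, overlap_fraction = 0.5)
  ridge <- sg$frequencies[apply(sg$power, 2, which.max)]
  expect_true(all(abs(ridge - 16) < 0.2))
  silence <- waveform(rep(1e-12, 4 * sr), sr)
  expect_lt(max(spectrogram(silence, window_s = 2)$power), 1e-12)
  expect_error(spectrogram(waveform(rnorm(100), 100), window_s = 2),
               "longer than the record")
})

test_that("frame-wise f0 follows the reciprocal local interval", {
  dur <- 12
  sch <- intervals_from_f0(c(1 / 0.23, 1 / 0.16), dur)
  spec <- pulse_train_spec(sch, dur, 2000, pulse_duration = 0.16)
  w <- synthesize_train(spec)
  tr <- f0_track(w, band = c(3.5, 7.5), window_s = 2)
  mids <- utils::head(sch$onsets, -1) + sch$intervals / 2
  keep <- tr$time >= 2 & tr$time <= dur - 2
  truth <- stats::approx(mids, 1 / sch$intervals, xout = tr$time[keep])$y
  expect_lt(max(abs(tr$f0[keep] - truth) / truth), 0.05)
})
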