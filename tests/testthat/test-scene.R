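test_that("multipath is the identity without echoes and exact for impulses", {
  w <- waveform(c(1, numeric(999)), 1000)
  expect_identical(add_multipath(w, numeric(), numeric(), numeric()), w)
  y <- add_multipath(w, delays = 0.03, gains = 0.5, polarities = -1)
  expect_equal(y$samples[1], 1)
  expect_equal(y$samples[31], -0.5)      # 0.03 s at 1 kHz = 30 samples
  expect_equal(sum(y$samples != 0), 2L)
})

test_that("multipath is linear and validates arguments", {
  set.seed(8)
  w <- waveform(rnorm(2000), 1000)
  mp <- function(x) add_multipath(x, c(0.03, 0.04), c(0.4, 0.3), c(-1, 1))
  scaled <- mp(waveform(2.5 * w$samples, 1000))
  expect_equal(scaled$samples, 2.5 * mp(w)$samples, tolerance = 1e-12)
  expect_error(add_multipath(w, 0.03, c(0.4, 0.3), -1), "equal length")
  expect_error(add_multipath(w, 5, 0.4, -1), "beyond record")
})

test_that("secondary arrivals land between the fundamental peaks", {
  w <- quick_train(duration = 4, taper = 0)
  y <- add_multipath(w, c(0.03, 0.04), c(0.4, 0.3), c(-1, 1))
  # the echo of each pulse peak arrives 0.03 s later: within the
  # 0.068 s inter-pulse gap, not on the next pulse
  expect_lt(0.03, 1 / 14.73)
  expect_false(isTRUE(all.equal(y$samples, w$samples)))
  expect_equal(length(y$samples), length(w$samples))
})

test_that("seeded noise is reproducible and leaves the caller's RNG alone", {
  w <- quick_train(duration = 4)
  a <- add_noise(w, 10, seed = 99)
  set.seed(1); before <- rnorm(1)
  b <- add_noise(w, 10, seed = 99)
  set.seed(1); after <- rnorm(1)
  expect_identical(a$samples, b$samples)
  expect_identical(before, after)
  expect_identical(add_noise(w, Inf, seed = 1), w)
})

test_that("the realized in-band SNR matches the request", {
  w <- quick_train(duration = 30)
  noisy <- add_noise(w, 0, band = c(5, 400), seed = 7)
  noise <- noisy$samples - w$samples
  bp <- function(x) bandpass(waveform(x, 2000), 5, 400)$samples
  ratio <- mean(bp(w$samples)^2) / mean(bp(noise)^2)
  expect_equal(ratio, 1, tolerance = 0.1)
})

test_that("scene simulation composes truth, echoes and noise with full truth", {
  cfg <- scene_config(snr_db = 10, seed = 5)
  sc <- simulate_scene(cfg)
  expect_s3_class(sc, "hydrophone_scene")
  expect_equal(length(sc$clean$samples), length(sc$observed$samples))
  expect_identical(sc$observed$samples, simulate_scene(cfg)$observed$samples)
  quiet <- scene_config(echo_delays = numeric(), echo_gains = numeric(),
                        echo_polarities = numeric(), snr_db = Inf)
  sq <- simulate_scene(quiet)
  expect_identical(sq$observed$samples, sq$clean$samples)
})

test_that("a default scene is recovered to within 1% interval error", {
  sc <- simulate_scene(scene_config(seed = 1))
  fit <- fit_pulse_train(sc$observed)
  expect_lt(abs(fit$params$interval - 1 / 14.73) * 14.73, 0.01)
  expect_gt(fit$r, 0.9)
})

test_that("a noiseless, echo-free scene fits its own model almost perfectly", {
  quiet <- scene_config(echo_delays = numeric(), echo_gains = numeric(),
                        echo_polarities = numeric(), snr_db = Inf)
  sc <- simulate_scene(quiet)
  fit <- fit_pulse_train(sc$observed)
  expect_gt(fit$r, 0.999)
})

test_that("a sinusoid-mechanism scene ranks the sinusoid model first", {
  truth <- sinusoid_params(2000, 14000)
  sc <- simulate_scene(scene_config(truth = truth, echo_delays = numeric(),
                                    echo_gains = numeric(),
                                    echo_polarities = numeric(),
                                    snr_db = 10, seed = 12))
  tab <- compare_models(sc$observed)
  expect_equal(tab$kind[1], "sinusoid")
})

test_that("scene configuration enforces its physical invariants", {
  expect_error(scene_config(echo_gains = c(1.2, 0.3)), "magnitude < 1")
  expect_error(scene_config(echo_delays = c(-0.01, 0.04)), "positive")
  expect_error(scene_config(echo_polarities = c(2, 1)), "polarities")
  expect_error(scene_config(truth = list()), "pulse_train_spec or sinusoid")
})
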