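test_that("q evaluates the piecewise rational closed form", {
  sh <- pulse_shape()
  expect_equal(eval_q(0.3, sh), 100)                     # both branches agree at t = a
  expect_equal(eval_q(0.2, sh), 1 / ((-0.1)^2 + 0.01))   # = 50
  expect_equal(eval_q(0.6, sh), 10 / (0.3^2 + 0.1))      # ~52.63
  expect_true(all(eval_q(seq(-1, 2, by = 0.01), sh) > 0))
  expect_error(eval_q(NaN, sh), "finite")
  expect_error(eval_q(Inf, sh), "finite")
})

test_that("q is continuous at the peak for the default constants", {
  sh <- pulse_shape()
  deltas <- 10^seq(-2, -8)
  gap <- abs(eval_q(sh$a - deltas, sh) - eval_q(sh$a + deltas, sh))
  expect_true(all(diff(gap) < 0))      # shrinks monotonically
  expect_lt(gap[length(gap)], 1e-9)
  expect_equal(1 / sh$eps_pre, sh$scale_post / sh$eps_post)
})

test_that("P(t) matches the extrema located by a dense grid-search oracle", {
  sh <- pulse_shape()
  expect_identical(eval_pulse(sh$a, sh), 0)
  # oracle: dense numeric search for the extrema of P
  tg <- seq(0.01, 1.2, by = 1e-5)
  p <- eval_pulse(tg, sh)
  expect_equal(tg[which.max(p)], sh$a - sqrt(sh$eps_pre / 3), tolerance = 1e-3)
  expect_equal(max(p), 649.5191, tolerance = 1e-4)
  expect_equal(tg[which.min(p)], sh$a + sqrt(sh$eps_post / 3), tolerance = 1e-3)
  expect_equal(min(p), -205.396, tolerance = 1e-4)
})

test_that("analytic P agrees with the finite-difference oracle of q", {
  sh <- pulse_shape()
  h <- 1e-5
  t <- seq(0.01, 1, by = 0.001)
  t <- t[abs(t - sh$a) > 2 * h]
  fd <- (eval_q(t + h, sh) - eval_q(t - h, sh)) / (2 * h)
  expect_lt(max(abs(eval_pulse(t, sh) - fd) / abs(fd)), 1e-3)
})

test_that("P is positive before the peak and negative after", {
  sh <- pulse_shape()
  tpre <- seq(1e-4, sh$a - 1e-4, length.out = 500)
  tpost <- seq(sh$a + 1e-4, 3, length.out = 500)
  expect_true(all(eval_pulse(tpre, sh) > 0))
  expect_true(all(eval_pulse(tpost, sh) < 0))
})

test_that("sampling produces the biphasic wavelet on the expected grid", {
  w <- sample_pulse(pulse_shape(), 2000, c(0, 0.6))
  expect_s3_class(w, "waveform")
  expect_length(w$samples, 1200)
  expect_lt(which.max(w$samples), which.min(w$samples))  # peak precedes trough
  expect_lt(effective_duration(w), 1)
  expect_error(sample_pulse(pulse_shape(), 2000, c(0.3, 0.3)), "empty support")
  expect_error(sample_pulse(pulse_shape(), 2000, c(-0.1, 0.5)), "t >= 0")
})

test_that("sampled P matches the finite difference of sampled q", {
  sh <- pulse_shape()
  sr <- 20000
  w <- sample_pulse(sh, sr)
  t <- time_axis(w)
  q <- eval_q(t, sh)
  fd <- (q[3:length(q)] - q[1:(length(q) - 2)]) * sr / 2
  mid <- 2:(length(q) - 1)
  away <- abs(t[mid] - sh$a) > 3 / sr
  rel <- abs(w$samples[mid][away] - fd[away]) / pmax(abs(fd[away]), 1)
  expect_lt(max(rel), 1e-3)
})

test_that("pulse energy is sample-rate independent after normalization", {
  energies <- vapply(c(2000, 4000, 8000), function(sr) {
    w <- sample_pulse(pulse_shape(), sr)
    v <- w$samples / max(abs(w$samples))
    sum(v^2) / sr                       # quadrature of the squared pulse
  }, numeric(1))
  expect_lt(max(abs(energies - energies[1]) / energies[1]), 1e-3)
})

test_that("duration rescaling hits the target and is an identity at it", {
  w <- sample_pulse(pulse_shape(), 2000)
  same <- rescale_duration(w, effective_duration(w))
  expect_equal(same$samples, w$samples)
  short <- rescale_duration(w, 0.068)
  # discretization allows at most one sample period of mismatch
  expect_lte(abs(effective_duration(short) - 0.068), 1 / 2000 + 1e-12)
  expect_identical(short$sample_rate, w$sample_rate)
  expect_error(rescale_duration(w, 1e-4), "fewer than 4")
})

test_that("halving the duration doubles the spectral peak frequency", {
  w <- sample_pulse(pulse_shape(), 8000)
  f_at <- function(p) {
    # isolated pulse in a padded record so the spectrum is smooth
    s <- power_spectrum(waveform(c(p$samples, numeric(8000)), 8000),
                        zero_pad_factor = 4)
    sel <- which(s$frequencies > 0.5)   # skip DC region
    s$frequencies[sel[which.max(s$power[sel])]]
  }
  a <- rescale_duration(w, 0.2)
  b <- rescale_duration(w, 0.1)
  expect_equal(f_at(b) / f_at(a), 2, tolerance = 0.1)
})
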