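---
title: "The pulsed-air model of blue whale B calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pulsed-air model of blue whale B calls: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pulsecall)
```

## The scientific problem

Northeastern Pacific blue whales produce a long (10–20 s) tonal "B call"
whose spectrum is a harmonic comb: a fundamental near 14.7 Hz with
overtones at integer multiples (29.5, 44.2, 58.9, 73.6, 88.4 Hz). The
classical explanation is Helmholtz-style resonance of air-filled organs,
which ties call frequency to body size. The pulsed-air hypothesis offers
an alternative: the call is a rapid train of short pneumatic pressure
pulses — produced by cyclic opening and closing of laryngeal respiratory
valves — and the harmonic structure follows purely from the pulse
repetition rate. Under that model the fundamental equals the reciprocal
of the inter-pulse interval, and the whale can shift its call frequency
by re-timing the pulses rather than by changing a resonator.

`pulsecall` implements that model end to end: the closed-form source
pulse, train synthesis, the competing sinusoid model, harmonic spectral
analysis, normalized-cross-correlation fitting, and a synthetic
hydrophone scene generator for recovery experiments.

## The source wavelet

The elementary pulse is defined through a piecewise rational potential

$$q(t) = \frac{1}{(t-a)^2 + 0.01} \;\; (t < a), \qquad
  q(t) = \frac{10}{(t-a)^2 + 0.1} \;\; (t > a),$$

with the pressure pulse $P(t) = dq/dt$. The constant $a$ (default 0.3 s)
positions the peak; with the default constants both branches equal 100 at
$t = a$, so $q$ is continuous there. We evaluate $P$ with its analytic
derivative (a finite-difference oracle of $q$ appears only in the tests)
and define $P(a) = 0$, which both one-sided derivatives justify. The
result is a biphasic pulse: positive rise before $a$, sharper negative
overshoot after.

```{r wavelet}
w <- sample_pulse(pulse_shape(), sample_rate = 2000)
plot(w, main = "Source pulse P(t), a = 0.3")
effective_duration(w)
```

**Pulse duration** is not defined by the closed form alone, so we
operationalize it as the width of the region where $|P|$ is at least 1%
of its maximum — a reproducible, threshold-based support measure. The
canonical $a = 0.3$ pulse spans roughly 0.6 s; the B-call model uses a
0.068 s wavelet. These are reconciled by an explicit time-axis
compression step, `rescale_duration()`, which resamples the pulse so its
effective duration hits the target while preserving its shape. We treat
the rescaling as part of the model definition: it is the only reading
that makes a sub-second canonical pulse and a 0.068 s model wavelet
mutually consistent.

## Train synthesis

A call is an overlap-add of peak-normalized wavelet copies whose
amplitude maxima sit at scheduled onset times, followed by a whole-train
raised-cosine taper:

```{r train}
spec <- bcall_spec()   # 1/14.73 s interval, 0.068 s wavelet, 7 s, 2 kHz
call <- synthesize_train(spec)
plot(call, xlim = c(3, 3.5), main = "Synthesized B-call model (detail)")
```

Design choices worth stating:

* **Interval, not pulse count, is the controlling parameter.** The pulse
  count is always derived from record duration and the schedule; a 7 s
  record at a 0.068 s interval implies ~103 pulses.
* **The canonical interval is `1/14.73` s (≈ 0.0679 s).** The model's
  stated fundamental (14.73 Hz) is given to four significant figures,
  the interval (0.068 s) only to two; taking the interval as the exact
  reciprocal of the fundamental reproduces *all six* printed harmonic
  frequencies to better than 0.05 Hz, whereas literally 0.068 s would
  misplace the sixth harmonic by 0.16 Hz.
* **Onsets are real-valued, placement is nearest-sample.** At the 2 kHz
  default the placement error is at most 0.25 ms, two orders of
  magnitude below the interval; fractional-delay interpolation would add
  complexity without measurable benefit at these frequencies.
* **Taper fraction defaults to 0.1** (5% raised-cosine ramp per end).
  A cosine taper is part of the model description but its extent is not;
  0.1 is a conventional Tukey choice that suppresses record-edge
  splatter without eroding the steady-state comb.
* Wavelets may overlap (`pulse_duration` can exceed the interval);
  overlap-add handles this naturally.

Varying the schedule shifts the fundamental in real time — the
mechanism's signature:

```{r track}
sch <- intervals_from_f0(c(1/0.23, 1/0.16), 15)  # intervals 0.23 -> 0.16 s
wv <- synthesize_train(pulse_train_spec(sch, 15, 2000, pulse_duration = 0.16))
tr <- f0_track(wv, band = c(3.5, 7.5))
plot(tr$time, tr$f0, type = "b", xlab = "time (s)", ylab = "f0 (Hz)")
```

## The competing sinusoid model

The resonance-style comparison model is a sine summation with a variable
(accumulated) phase term. The printed formula, read literally, sweeps a
single component from `f0` to `f1`; the surrounding description instead
calls for two harmonic components (14.73 and 29.5 Hz) each swept by
±0.42 Hz. The package implements **both readings**, labelled
`"literal-chirp"` and `"harmonic-stack"`, rather than silently choosing;
the harmonic stack is the default used in model comparisons because it
is the configuration that actually resembles a B call. The stack sweeps
downward (from centre + 0.42 Hz to centre − 0.42 Hz) because B calls
step down in frequency. Whether the published sweep applied to start,
end, or both frequencies is not stated; a symmetric sweep about the
centre is our choice. Default amplitudes 1 and 0.5 bound the summed
signal within ±1.5.

```{r sine}
stack <- synthesize_harmonic_stack(sinusoid_params(2000, 14000))
range(stack$samples)
```

## Spectral analysis

All spectra are single-sided Hann-windowed FFTs with 4x zero padding;
peak frequencies are refined by 3-point parabolic interpolation on log
power. A 7 s record at 2 kHz has a raw Rayleigh resolution of ~0.14 Hz;
padding plus interpolation is what makes 14.73 Hz distinguishable from
14.7 Hz. Tolerance used by the package's own acceptance checks is
0.1 Hz, the printed precision of the overtone table.

Peak acceptance uses two thresholds chosen because "a peak" is otherwise
undefined:

* **prominence**: at least 6 dB above the median power of the local
  search window (separates comb peaks from the noise floor), and
* **dynamic-range floor**: within 60 dB of the spectrum maximum
  (rejects spectral-leakage ripples in near-noiseless synthetic
  records, which can be locally prominent but are physically
  meaningless).

`find_harmonics()` searches ±0.25 × fundamental around each integer
multiple and reports the nearest accepted peak; harmonics that fail the
thresholds are simply absent, which is how a notched or missing overtone
manifests.

```{r spectrum}
s <- power_spectrum(call)
f0 <- estimate_fundamental(s, band = c(5, 25))
find_harmonics(s, as.numeric(f0), max_freq = 100)
```

## Model fitting by normalized cross-correlation

Model–data agreement is quantified by `r`: the zero-mean, unit-energy
cross-correlation maximized over lags within ±0.5 s (recordings have an
arbitrary time origin). Both signals are band-passed to 10–100 Hz (the
call's energy band) with a zero-phase Butterworth filter before scoring.
The lag search is FFT-based with per-lag means and energies from
cumulative sums; an O(n²) direct-sum oracle in the test suite pins the
implementation to 1e-9.

`fit_pulse_train()` is a forward-modelling grid search, not a gradient
optimizer, because the objective is multi-modal in the interval: a
harmonic comb correlates at subharmonic spacings (octave ambiguity). Two
safeguards address this:

* candidates whose implied fundamental disagrees with the lowest
  prominent spectral peak of the observation by more than 35% are
  deprioritized;
* the default interval grid (0.060–0.076 s in 0.4 ms steps) covers the
  B-call band without subharmonics.

After the coarse pass, two local refinement passes shrink the grid step
8x each around the winner. Refinement matters because interval mismatch
accumulates as phase drift across the whole record: a 0.16% interval
error already costs ~0.1 in r on a 7 s record. Ties break toward the
smaller interval, then the smaller wavelet duration.

## Synthetic hydrophone scenes

The original shallow-water hydrophone recordings are not publicly
deposited, so the package carries a scene generator whose defaults
emulate the documented recording conditions rather than standing in for
them quantitatively:

* **Truth call**: the canonical pulse-train model (or a sinusoid stack).
* **Multipath**: echo copies at 0.03 and 0.04 s delays — the observed
  secondary-arrival delays between fundamental peaks — with gains 0.4
  and 0.3 and polarities −1/+1. True gains and polarities at the site
  are unknown; these are configuration, not claims.
* **Ambient noise**: Gaussian noise band-limited to 5–400 Hz, flat in
  band, scaled to a prescribed in-band SNR. Real wind/wave noise is
  broadband centred near 200 Hz and not flat; a flat band is the
  simplest stand-in whose SNR is exactly measurable and testable.
* **Determinism**: a fixed seed reproduces a scene bit-exactly, and the
  generator restores the caller's RNG state.

What passing recovery tests therefore show: the fitting machinery
recovers the generating interval to well under 1% at 10 dB SNR and
ranks the generating mechanism first, *under these idealized
propagation and noise assumptions*. They do not show that real B calls
are pulse trains — that inference belongs to the original recordings,
whose correlations (r = 0.93 pulse model vs 0.87 sinusoid model) cannot
be recomputed without the data.

```{r scene}
sc <- simulate_scene(scene_config(snr_db = 10, seed = 42))
fit <- fit_pulse_train(sc$observed)
fit
```

## Numerical choices and degenerate inputs

* Spectra guard `log(0)` with a 1e-300 floor; parabolic offsets are
  clamped to ±0.5 bin.
* `xcorr_r` requires at least 1 s of overlap at every searched lag and
  errors on constant (zero-variance) inputs rather than returning NaN.
* `eval_q`/`eval_pulse` reject non-finite times; `sample_pulse` rejects
  empty or negative-time supports; `rescale_duration` refuses targets
  leaving fewer than 4 samples.
* Problem sizes used throughout the package's own experiments — 7 s
  records at 2 kHz, 20 scenes per SNR in recovery studies, grids of ~40
  interval candidates — were chosen as the smallest sizes at which the
  relevant effects are clearly resolved.

## Known limitations

* No absolute amplitude calibration (no dB re 1 µPa source levels).
* No physical propagation model: the multipath operator is a delayed
  linear sum, deliberately so — at these wavelengths (~100 m) and site
  depths (~55 m) ray approximations are themselves invalid.
* The sinusoid model's published amplitude-coefficient schedule is not
  fully specified; the package exposes `a0`/`a1` but does not fit
  time-varying amplitudes.
* No call detection or segmentation in continuous recordings: inputs to
  the fitting path are assumed to be call-length excerpts.
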