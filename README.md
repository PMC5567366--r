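# pulsecall

Synthesis and analysis toolkit for the **pulsed-air model of blue whale
B calls**.

Northeastern Pacific blue whale B calls are long (10–20 s) tonal sounds
whose spectrum is a harmonic comb — a fundamental near 14.7 Hz with
overtones at integer multiples (29.5, 44.2, 58.9, 73.6, 88.4 Hz). The
pulsed-air hypothesis holds that the call is not an air-cavity resonance
but a rapid train of short pneumatic pressure pulses gated by the
laryngeal respiratory valves: the fundamental then equals the reciprocal
of the inter-pulse interval, and the animal can shift its call frequency
by re-timing pulses. `pulsecall` is aimed at bioacousticians who want to
synthesize such calls, read harmonic structure off recordings, and test
the pulse-train model against the competing sinusoid (resonance-style)
model on real or simulated hydrophone data.

## The model

The elementary source pulse is `P(t) = dq/dt` with the piecewise
rational potential

    q(t) = 1 / ((t - a)^2 + 0.01)    for t < a
    q(t) = 10 / ((t - a)^2 + 0.1)    for t > a

(`a` = 0.3 s by default; both branches equal 100 at `t = a`). The pulse
is rescaled to a 0.068 s wavelet, peak-normalized, and overlap-added at
a constant or time-varying inter-pulse interval Δt with a raised-cosine
taper. The spectrum of the result is a harmonic comb with fundamental
`1/Δt`. Model–data agreement is scored by the normalized
cross-correlation `r`, maximized over lag, after identical 10–100 Hz
band-passing — against the alternative variable-phase sinusoid model
(a two-component harmonic stack at 14.73 and 29.5 Hz swept by ±0.42 Hz).

## Worked example

```r
library(pulsecall)

# the canonical B-call model: 0.068 s wavelet at 1/14.73 s intervals,
# 7 s record, 2 kHz
call <- synthesize_train(bcall_spec())

s  <- power_spectrum(call)
f0 <- estimate_fundamental(s, band = c(5, 25))
as.numeric(f0)
#> [1] 14.72997
find_harmonics(s, as.numeric(f0), max_freq = 100)
#> <harmonic_structure> fundamental 14.730 Hz, 5 overtones
#>   overtones (Hz): 29.46, 44.19, 58.92, 73.65, 88.38
```

The synthesized train reproduces the B call's published harmonic
structure: the fundamental is recovered at 14.730 Hz and the five
overtones below 100 Hz sit within 0.05 Hz of the reported values.

Fitting a noisy, multipath-contaminated synthetic scene recovers the
generating interval:

```r
sc  <- simulate_scene(scene_config(snr_db = 10, seed = 42))
fit <- fit_pulse_train(sc$observed)
fit
#> <call_fit> pulse-train model: r = 0.9479 at lag 0.0015 s; interval = 0.06789 s (f0 = 14.729 Hz)
compare_models(sc$observed)[, c("model", "r")]
#>         model         r
#> 1 pulse-train 0.9479040
#> 2    sinusoid 0.4523948
```

`r` close to 1 with the correct interval — and a clear margin over the
sinusoid model — is the pulse mechanism's signature. A command-line
front end (`exec/pulsecall`) exposes the same operations as
`synth-train`, `synth-sine`, `simulate`, `analyze`, `fit` and `compare`
subcommands, each writing WAV/CSV/JSON outputs plus run metadata.

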