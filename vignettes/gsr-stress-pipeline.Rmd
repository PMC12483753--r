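---
title: "Quantifying stress from galvanic skin response streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress from galvanic skin response streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsrstress)
```

## The signal and the problem

Galvanic skin response (GSR, also called electrodermal activity) is the
electrical conductance of the skin. Sweat-gland activity under sympathetic
arousal raises conductance, so a rise in GSR tracks a rise in stress. A
wearable GSR device reads the sensor through an ADC and must turn a noisy
stream of integer counts into a stress level a person can act on. Two
obstacles stand in the way: sensor noise, and the large differences between
individuals' resting conductance and reactivity, which make any fixed
threshold on the raw signal meaningless across subjects.

`gsrstress` implements the processing chain such a device runs, as a tested
library that can replay recorded or simulated streams:

1. **Bit-depth mapping.** The sensor is read at 12-bit resolution
   (0–4095) and linearly rescaled to the 10-bit working scale (0–1023):
   $A_{10} = A_{12} \times 1023/4095$. The mapping keeps full precision;
   rounding is a display option only, so the filter never consumes
   quantized input twice.
2. **Scalar Kalman filtering.** With estimated error $E_p$ and
   measurement error $E_m$, each new reading $z$ updates the state
   estimate $X$ by
   $K = E_p/(E_p + E_m)$, $X \leftarrow X + K (z - X)$,
   $E_p \leftarrow (1 - K) E_p$.
3. **Baseline calibration and dynamic range normalization.** A
   per-subject offset is added ($A_{cal} = X + C_{offset}$) and the result
   rescaled against the subject's own baseline range:
   $\mathrm{GSR}_{norm} = (A_{cal} - B_{min})/(B_{max} - B_{min}) \times 500$,
   so 0 means "at this subject's calibrated minimum" and 500 "at their
   maximum", whatever their skin's absolute conductance.
4. **Classification.** Four bands on the normalized scale, upper-inclusive:
   No stress ($\le 200$), Minor stress ($200 < x \le 300$), High stress
   ($300 < x \le 400$), Very high stress ($> 400$).

A separate calibration curve relates the sensor's 10-bit serial reading to
skin resistance through the Grove GSR voltage divider,
$R = (1024 + 2\,\mathrm{SPR}) \times 10^4 / (\mathrm{cal} - \mathrm{SPR})$
ohms, with conductance its reciprocal. A reading at or above the
calibration baseline is rejected rather than mapped to an infinite
resistance, so downstream arithmetic stays finite.

## Design choices where the design was open

Several pieces of the chain admit more than one reading; the package
commits to the following.

**The innovation sign in the state update.** The update is implemented in
the standard innovation form $X + K(z - X)$. The additive variant
$X + K(z + X)$ diverges geometrically for any $K > 0$ and cannot smooth
anything; only the innovation form behaves as a noise filter.

**Error recursion without process noise.** The recursion
$E_p \leftarrow (1-K)E_p$ drives $E_p$ — and with it the gain —
monotonically to zero: in closed form $1/E_p$ grows by $1/E_m$ per step,
so the filter converges to a static weighted average of everything it has
seen. That is the exact published recursion and is what `kalman_params()`
gives by default (`q = 0`). It is also useless for tracking a moving
signal over thousands of samples, so the parameters expose an additive
process-noise term `q` applied to $E_p$ after each update. With `q > 0`
the gain settles at a fixed point instead of decaying
($E_p^* = (q + \sqrt{q^2 + 4 q E_m})/2$), giving a conventional
exponential-style smoother. All tests that pin down the printed recursion
use `q = 0`; the streaming recovery experiments use `q = 1`.

**Filter defaults.** No published trace exists from which to
reverse-engineer the device's $E_{p0}$, $E_m$ or initial state, so the
defaults are the package's own: `e_p0 = 1`, `e_m = 4` in 10-bit units
(treat each raw reading as roughly four counts of error against a
well-trusted state), and the initial state seeded from the first
measurement so a constant stream passes through unchanged. Every test
that depends on filter behaviour passes explicit parameters.

**Classification bands.** The four-band scheme capped nominally at 500 is
used, with the lowest band closed at 200 and the top band open-ended:
recorded cohort tables contain values of 501, so classification accepts
any non-negative value even though `normalize_gsr()` clamps its own
output to $[0, 500]$ (and flags the clamp). "Moderate" in an alternative
three-band phrasing is treated as a synonym for Minor stress.

**Baseline estimation.** How $B_{min}$ and $B_{max}$ are derived is not
specified by the device description; `estimate_baseline()` takes the plain
minimum and maximum of at least ten filtered samples from a calibration
window, with an optional upward guard fraction `eps` and no outlier
rejection — a single artifact sample widens the range, and the tests
document exactly that sensitivity. Constant windows are rejected as
degenerate rather than producing a zero-width range.

**Offset default.** $C_{offset}$ defaults to 0; no derivation for it is
published, and it exists to let a deployment shift a subject's filtered
signal onto their previously recorded baseline range.

## The synthetic signal model

`simulate_subject_stream()` generates per-subject streams with known
ground truth, emulating the statistical structure the pipeline assumes:

- a resting **baseline** (default 1200 counts) with slow linear **drift**
  (default 2 counts/min);
- a **tonic elevation** under stress, expressed as a fraction of the
  subject's dynamic range (default 400 counts): 0.2 at rest, 0.5 / 0.7 /
  0.9 under Minor / High / Very-high scheduled states. The fractions sit
  at the centres of the classification bands once the stream is
  normalized against its own calibration window;
- **SCRs** (skin conductance responses): transient pulses with linear
  rise (1 s), exponential decay (4 s), exponentially distributed
  amplitude (mean 15 counts), arriving as a Poisson process at 3 events
  per minute at rest, scaled ×2/×3/×4 under increasing stress — the
  standard phasic model in electrodermal analysis;
- additive Gaussian **sensor noise** (default sd 8 counts, up to 20 in
  the noisy-recovery experiments);
- an opening **calibration window** (default 30 s) that sweeps the full
  dynamic range — rest, ramp to maximal response, hold, return to rest —
  emulating the relax/stimulus procedure a per-subject calibration
  performs in practice. Deriving `estimate_baseline()` anchors from this
  window is what makes the subsequent normalization land scheduled states
  in their intended bands.

Each stream uses one locally seeded generator and restores the caller's
RNG state, so identical seeds give bit-identical output and the simulator
never perturbs surrounding code. The per-sample ground-truth label is the
band implied by the tonic fraction, which is also defined during the
calibration sweep.

What the simulator does *not* model: motion artifacts, electrode contact
loss, temperature and humidity effects, habituation, and the
autocorrelated non-Gaussian noise of real skin-electrode interfaces.
Passing the recovery tests therefore shows the chain is self-consistent
under its own assumptions — it does not certify field accuracy on real
skin.

`simulate_cohort()` is a separate, simpler generator for study-layout
experiments: each subject is assigned a band (cycling Very high / High /
Minor / No stress, mirroring the bundled printed table) and draws
normalized values uniformly within it; the default 32 subjects × 20
readings yield 640 records.

## The bundled cohort table

`load_table2_fixture()` returns a recorded 16-person cohort of normalized
readings, each column labelled with the band its readings occupy. It is
stored as plain CSV exactly as printed: Persons 1–4 carry 14 readings,
Persons 5–16 carry 13, so the rectangular table pads the final row with
`NA` and `classify_table()` skips missing cells. Count-based tests
therefore pin the 14-reading block only. Person 5 and Person 13 each
contain a reading of 501 — slightly above the nominal scale cap — which is
why classification accepts values beyond 500.

## Numerical choices

- Band edges are decided by `findInterval(..., left.open = TRUE)`, giving
  exactly the printed lower-exclusive/upper-inclusive intervals; an
  exhaustive 0.01-grid sweep in the tests confirms every value in
  $[0, 500]$ receives exactly one band.
- `normalize_gsr()` rejects degenerate profiles at construction
  (`b_max > b_min` strictly), so the denominator is always positive.
- The resistance curve rejects readings at or above the calibration
  baseline instead of returning infinity.
- Display rounding uses `round()` (half to even).
- Replay timings are measured per stage (read, filter, normalize, emit)
  with `proc.time()` and attached as an attribute; they are
  instrumentation for parity with on-device stage breakdowns and are
  never asserted against — they depend entirely on the host.

## Problem sizes in the test suite

The suite exercises the statistical properties at sizes a laptop runs in
seconds: label-recovery and filter-benefit experiments use 50 seeded
150-second streams at 10 Hz (1500 samples each, four scheduled states
after the calibration window); the noise-reduction property uses 100
seeded 40-second streams; the running-mean oracle uses random sequences
up to length 100 against a brute-force cumulative mean; normalization
anchors are checked over 1000 random profiles at tolerance $10^{-9}$.

## A worked replay

```{r replay}
sim <- simulate_subject_stream(simulator_config(
  seed = 42, duration_s = 150, noise_sd = 20,
  stress_state_schedule = data.frame(
    start_s = c(30, 60, 90, 120), end_s = c(60, 90, 120, 150),
    level = c("minor", "high", "very_high", "no_stress"))))

adc10 <- map_12bit_to_10bit(sim$samples$adc12)
filtered <- kalman_filter(adc10, kalman_params(e_m = 4, e_p0 = 1, q = 1))
profile <- estimate_baseline(as.numeric(filtered)[sim$calibration_idx])

cfg <- pipeline_config(kalman = kalman_params(e_m = 4, e_p0 = 1, q = 1),
                       calibration = profile)
records <- run_replay(sim$samples, cfg)
summarize_levels(records)

post <- setdiff(seq_len(nrow(records)), sim$calibration_idx)
percent_agreement(records$level[post], sim$labels[post])
```

## Known limitations

- The filter is strictly scalar; multivariate or adaptive-noise variants
  are out of scope.
- Baseline estimation has no outlier rejection; calibration windows must
  be clean.
- The four-band thresholds are fixed constants of the normalized scale,
  not learned from data.
- Stage timings are host-dependent instrumentation, not performance
  claims.
- The CLI replays files; it does not talk to sensor hardware, displays,
  or cloud services.
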