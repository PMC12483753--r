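# gsrstress

Stress quantification from galvanic skin response (GSR / electrodermal
activity) streams, as a wearable device would compute it — implemented as a
tested R library with a replay engine, a synthetic signal simulator, and a
command-line interface.

Skin conductance rises with sympathetic arousal, so a GSR sensor tracks
stress — but the raw stream is noisy, and resting conductance differs so
much between people that no fixed threshold on the raw signal works across
subjects. `gsrstress` implements the processing chain that addresses both:

1. **ADC bit-depth mapping** — raw 12-bit counts onto the 10-bit working
   scale, `A10 = A12 × 1023/4095`;
2. **Scalar Kalman filtering** — gain `K = Ep/(Ep + Em)`, state update
   `X ← X + K (z − X)`, error update `Ep ← (1 − K) Ep` (optional process
   noise `q` for streaming use);
3. **Baseline calibration + dynamic range normalization** — per-subject
   offset, then `GSRnorm = (Acal − Bmin)/(Bmax − Bmin) × 500`, anchoring
   each subject's own range onto 0–500;
4. **Four-band classification** — No stress (≤ 200), Minor (200–300],
   High (300–400], Very high (> 400);
5. **Skin-resistance calibration curve** — the Grove GSR voltage-divider
   form `R = (1024 + 2·SPR) × 10⁴ / (cal − SPR)` ohms, conductance its
   reciprocal.

It is aimed at anyone prototyping or validating electrodermal stress
pipelines: the same functions run on recorded CSV streams, on the bundled
16-person cohort table of normalized readings, and on simulated streams
with known ground-truth labels.

## Worked example

Simulate a noisy subject stream that visits every stress state, calibrate
from its opening rest/stimulus window, and replay it through the full
chain:

```r
library(gsrstress)

sim <- simulate_subject_stream(simulator_config(
  seed = 42, duration_s = 150, noise_sd = 20,
  stress_state_schedule = data.frame(
    start_s = c(30, 60, 90, 120), end_s = c(60, 90, 120, 150),
    level = c("minor", "high", "very_high", "no_stress"))))

adc10    <- map_12bit_to_10bit(sim$samples$adc12)
filtered <- kalman_filter(adc10, kalman_params(e_m = 4, e_p0 = 1, q = 1))
profile  <- estimate_baseline(as.numeric(filtered)[sim$calibration_idx])
profile
#> <calibration_profile> c_offset = 0 | b_min = 291.0813 | b_max = 402.4626

cfg <- pipeline_config(kalman = kalman_params(e_m = 4, e_p0 = 1, q = 1),
                       calibration = profile)
records <- run_replay(sim$samples, cfg)
summarize_levels(records)
#>              level count  fraction
#> 1        No stress   430 0.2866667
#> 2     Minor stress   358 0.2386667
#> 3      High stress   340 0.2266667
#> 4 Very high stress   372 0.2480000

post <- setdiff(seq_len(nrow(records)), sim$calibration_idx)
percent_agreement(records$level[post], sim$labels[post])
#> [1] 98.66667
```

The profile says this subject's filtered signal spans roughly 291–402
10-bit counts between rest and maximal response; normalization maps that
span onto 0–500 so the band thresholds apply to them as to anyone else.
The pipeline recovers the scheduled stress state for 98.7% of samples
despite 20 counts of sensor noise.

Classifying the bundled cohort table reproduces its column labels:

```r
classify_table(load_table2_fixture())[, 1:4]
#>                  Person 1 Person 2 Person 3 Person 4
#> No stress               0        0        0       14
#> Minor stress            0        0       14        0
#> High stress             0       14        0        0
#> Very high stress       14        0        0        0
```

And the calibration curve, for a sensor calibrated at 700 counts:

```r
skin_resistance(c(100, 300, 500), acquisition_config(700L))
#>   reading resistance  conductance
#> 1     100      20400 4.901961e-05
#> 2     300      40600 2.463054e-05
#> 3     500     101200 9.881423e-06
```

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "gsr", package = "gsrstress")`:

```sh
gsr simulate --seed 5 --duration 60 --out stream.csv
gsr calibrate --in stream.csv --config config.yaml       # writes b_min/b_max back
gsr replay --in stream.csv --config config.yaml --out records.jsonl --summary summary.csv
gsr summarize --in records.jsonl
gsr simulate-cohort --subjects 32 --samples 20 --seed 1 --out cohort.csv
```

Exit codes: 0 success, 2 config error, 3 input error. The YAML config has
`acquisition`, `kalman`, `calibration` and `pipeline` sections; see
`?read_pipeline_config`.

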