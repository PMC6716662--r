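# gaitwave

Step detection and real-world gait-speed estimation from waist-worn
tri-axial accelerometry, designed for the hard case: slow (orthogeriatric)
walkers below 0.8 m/s, where classical heel-strike peak-picking starts
missing or double-counting steps.

The package is aimed at researchers working with digital mobility outcomes
who need per-step events and per-section walking speeds from a single
waist sensor, validated against a rolling-wheel reference.

## What it computes

The core detector (**stepwave**) tracks the *phase* of the walking
oscillation instead of picking peaks:

1. zero-phase Butterworth band-pass 0.7–3 Hz; overlapping 2.5 s windows;
2. per-window dominant cadence from a zero-padded FFT, with plausibility
   gating on gravity direction (upright posture), activity level, and
   spectral peak prominence;
3. per axis, a narrowband filter around the gait frequency (step rate for
   the vertical x and longitudinal z axes, stride rate for the lateral y)
   and the analytic signal via the Hilbert transform, giving amplitude
   envelope A, instantaneous phase P and frequency F;
4. one step per 2π cycle of the unwrapped vertical phase, with per-step
   mean envelopes Ax, Ay, Az; duplicates from overlapping windows merged.

Per-step gait speed is a linear model on the amplitude envelopes and their
pairwise interactions,

    v = b0 + b1·Ax + b2·Ay + b3·Az + b4·Ax·Ay + b5·Ax·Az + b6·Ay·Az  (m/s),

fit by OLS against reference speeds and clipped to [0, 3] m/s.

Also included: the legacy adaptive-threshold heel-strike detector
(**stepslc**) as comparator; a measuring-wheel ("perambulator") reference
method that turns the quadrature gravity sinusoids of a wheel-mounted
sensor into speed at 25 cm resolution; agreement statistics (Bland–Altman
with 1.96·SD limits, regression agreement, RMSE, speed-binned mean
differences with t-tests, step-count deviation); and a synthetic-gait
simulator with exact ground truth that drives the whole validation.

## Worked example

Simulate a two-pace walk (30 s at 0.6 m/s, then 25 s at 1.1 m/s), detect
steps, fit the speed model against the ground-truth speeds, and aggregate
per section:

```r
library(gaitwave)

sc <- gait_scenario(segments = data.frame(duration = c(30, 25),
                                          speed    = c(0.6, 1.1),
                                          activity = "walk"), seed = 11)
sim   <- simulate_walk(sc)          # 91 true steps
steps <- detect_steps_wave(sim$recording)
steps
#> <step_events> 91 steps | span 0.1-54.9 s | median cadence 1.87 Hz | mean Ax 1.78 m/s^2

truth <- approx(sim$truth$time, sim$truth$speed, steps$t_start, rule = 2)$y
model <- fit_speed_model(steps, truth)
model
#> <speed_model> per-step gait speed ~ Ax + Ay + Az + pairwise interactions
#>   fitted on 91 steps, residual SD 0.0381 m/s

aggregate_section_speed(predict(model, steps), sim$truth$sections)
#>   section     speed n_steps
#> 1 walk_01 0.6054272      45
#> 2 walk_02 1.0946908      46
```

All 91 simulated steps are recovered, the fitted model explains per-step
speed to a residual SD of 0.038 m/s, and the two section means land within
0.01 m/s of the programmed 0.6 and 1.1 m/s.

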