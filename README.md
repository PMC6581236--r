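# pairflight

Tools for quantifying what it costs a bird to fly with a partner.
Homing pigeons released in pairs navigate home more accurately than
solo birds, but they also change the way they beat their wings. This
package implements the full analysis chain needed to measure both
sides of that trade-off from bio-logging data — 200 Hz tri-axial
accelerometry and 5 Hz GPS — together with a synthetic-data generator
with known ground truth, so every stage can be validated by parameter
recovery.

## What it computes

**Wingbeat kinematics** (`wingbeat_metrics()` and friends): traces are
smoothed with a short running mean, gravity is removed with a long
running mean (or a 4th-order zero-phase 1 Hz Butterworth high-pass for
head-mounted loggers), wingbeats are delimited by successive maxima of
the dorsal dynamic acceleration, and each beat yields its frequency
`f = 1/period`, peak-to-peak acceleration, stroke-phase durations
(max-to-min = downstroke, min-to-max = upstroke), and the peak-to-peak
oscillatory displacement from per-beat double integration — for a
harmonic wave of acceleration amplitude `a`, displacement is
`a / (2 pi f)^2`.

**Trajectories** (`route_accuracy()`, `pair_spacing()`, ...):
great-circle distances (haversine, R = 6371 km), forward azimuths,
take-off/landing trimming, time-matched pair spacing with a 50 m
inclusion rule and a 90% consistent-leader rule, and route accuracy

```
A = (1/D) * sum_i d_i cos(theta_i)
```

the distance-weighted mean cosine of the angle between each step's
heading and the bearing to the goal (1 = beeline, -1 = straight away).

**Air data** (`wind_triangle()`, `humid_air_density()`): wind support,
crosswind and airspeed from ground velocity minus the wind vector, and
humid air density via the ideal gas law with the Arden Buck saturation
vapour pressure.

**Hierarchical inference** (`fit_pair_model()` and three companions):
flight-median responses are modelled as

```
y ~ N(delta0 * 1_pair + delta1 * |Ti - Tj| + omega_i mu_i
      + (1 - omega_i) mu_j + gamma X, sigma)
omega_i = logit^-1(eta1 + eta * |Ti - Tj|)
```

with hierarchical per-bird solo means `mu_i`, priors centred on the
null and scaled from the solo data, sampled by adaptive
Metropolis-within-Gibbs with split-chain R-hat convergence checks
(criterion 1.1). Companions: a wingbeat-level spacing model (pairing
effect at 0 m plus a per-metre slope, per-flight random effects
marginalised analytically), a front-bird/behind-bird frequency
coupling regression, and a Bernoulli leadership model.

**Power accounting** (`classical_power()`, `parasite_power_change()`,
...): the classical partition P = parasite (~U^3) + profile (~const) +
induced (~1/U), plus the ratio arithmetic for work per wingbeat and
cost of transport, and a wingbeat budget from distance, accuracy,
airspeed and frequency.

## Worked example

```r
library(pairflight)

# a bird whose solo wingbeat frequency is 5.48 Hz, flying paired at a
# +1.00 Hz effect: simulate the dorsal trace and segment it
birds <- make_birds(2, seed = 1, freq_sd_hz = 0)
truth <- truth_record(delta0_hz = 1.00, residual_sd_hz = 0,
                      spacing_slope_hz_per_m = 0)
plan  <- list(flight_id = "F1", condition = "pair",
              bird1 = "S01", bird2 = "S02")
wb <- wingbeat_metrics(simulate_accel(plan, birds, truth, seed = 1)[[1]])
median(wb$freq_hz)                     # 6.479 Hz (solo 5.48 + 1.00 effect)
median(wb$pp_disp_mm, na.rm = TRUE)    # 15.9 mm  (22.0 mm when flown solo)

# what that frequency rise means energetically, using the study's
# printed ratios: +3.3% airspeed, +18.2% frequency, +2.2% total power
parasite_power_change(1.033)        # 10.23  % more parasite power
work_per_beat_change(1.022, 1.182)  # -13.54 % work per wingbeat
cost_of_transport_change(1.029, 1.033)  # -0.39 % cost of transport
```

The first block shows the round trip generator -> segmentation: the
recovered median frequency is the generated 6.48 Hz within 0.01 Hz,
and the displacement drops by about a quarter against the same bird
flown solo (22.0 mm at 5.48 Hz) because the same acceleration
amplitude is integrated over a shorter period. The second block is the power arithmetic: a 3.3% airspeed rise
costs 10.2% more parasite power, yet at the published total-power and
frequency ratios each wingbeat does 13.5% less work and the cost of
transport even falls slightly.

The full pipeline (simulate -> process -> summarise -> fit -> power)
runs via `run_pipeline("all", pipeline_config())` or the CLI wrapper
`inst/scripts/pairflight-pipeline.R`.

## Documentation

See `vignettes/pairflight-methods.Rmd` for the models, their
assumptions, the generator's stated world, and numerical choices.
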