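---
title: "Methods: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science the package implements, the
assumptions baked into each stage, the stated world of the
synthetic-data generator, and the numerical choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

When homing pigeons fly in pairs rather than alone they home more
accurately, but they also raise their wingbeat frequency
substantially, mostly by shortening the upstroke phase of each beat,
with only a small rise in airspeed and a marked drop in the
oscillatory displacement of the body. Quantifying that trade-off from
bio-logging data requires four ingredients: per-wingbeat kinematics
from accelerometry; trajectory statistics from GPS; airspeed and air
density from station weather; and a hierarchical model that separates
the pairing effect from bird identity, partner identity, and
environmental covariates. The package implements all four plus a
generator that emulates the experimental design — 20 birds flown
through 4 phases (solo, similar-sized pairs, different-sized pairs,
solo) from a release site 7.06 km from the loft — with configurable
true effects, so that every estimator can be checked against known
truth.

## Wingbeat kinematics

The dorsal accelerometer's vertical channel oscillates once per
wingbeat. The chain is: a 3-sample centred running mean (0.015 s at
200 Hz) to suppress sensor noise; gravity removal by subtracting a
long centred running mean (default 2.75 s, about 15 wingbeat cycles at
5.5 Hz — a fixed window rather than an adaptive per-bird one, which
would be under-specified; it is configurable); segmentation at
successive acceleration maxima; and per-beat metrics.

*Peak detection.* Local maxima must be separated by at least 55 ms
(admitting frequencies to ~10 Hz at twice the upper frequency of
interest) and have prominence of at least 0.3 times the channel's
inter-quartile range (rejecting double-peaks within a beat). Both
thresholds are configurable.

*Sub-sample extremum timing.* At 200 Hz a 5.48 Hz beat spans 36.5
samples, so per-beat periods quantise to 180/185 ms and naive peak
indices cannot resolve median frequency to 0.01 Hz. Extremum times are
therefore refined by fitting a shared-apex piecewise polynomial
(`h + a_side (t - t0)^2 + b_side (t - t0)^4`, separate coefficients on
each side of the apex) to the 7 samples around the discrete extremum
over a fine grid of candidate apex times, interpolating the RSS
minimum. This matters because the wingbeat waveform is asymmetric: the
downstroke (max-to-min) is much shorter than the upstroke, so the
curvature differs on the two sides of each peak and a symmetric
3-point parabola is biased by several milliseconds toward the flatter
side. The piecewise fit is unbiased for any locally C1 waveform; on
constructed two-segment waves the test suite recovers 48.7/133.8 ms
phase durations within 1 ms and chirped frequencies monotonically.

*Stroke phases.* Downstroke = time from acceleration maximum to the
following minimum; upstroke = minimum to the next maximum. These are
acceleration-defined phases that lag the kinematic strokes slightly;
the two durations sum to the period exactly by construction. Where
multiple equal extrema occur, the earliest is taken.

*Displacement.* Acceleration (g converted at 9.80665 m/s2) is
integrated twice by the trapezoid rule independently within each beat;
the velocity is de-meaned over the beat and the displacement linearly
detrended before taking max minus min. Per-beat integration was chosen
over global integration with drift correction because it is simpler,
has no tuning constants, and is validated against the closed form for
a harmonic wave (`a / (2 pi f)^2`, within 3% across 3-10 Hz in the
tests). Beats spanning fewer than 3 samples are omitted.

*Head-mounted variant.* 5-sample smoothing and a 4th-order zero-phase
Butterworth high-pass at 1 Hz instead of the running-mean gravity
step. The filter is designed by bilinear transform of the analog
prototype (verified against the analog magnitude response at
pre-warped frequencies) and applied forward-backward with
odd-reflection padding sized to the filter's transient.

## Trajectories

A spherical Earth with R = 6,371 km is assumed throughout (the choice
of radius moves a 7 km distance by far less than GPS noise). Route
accuracy is the distance-weighted mean cosine of the angle between
each step's forward azimuth and the bearing to the goal, recomputed at
every fix; it is defined on any sub-track, so separated-pair sections
can be scored separately. Tracks are trimmed within 200 m of the
release site and loft to drop take-off and landing.

Paired tracks are matched by nearest timestamp with a 0.2 s tolerance
(two unsynchronised 5 Hz loggers can disagree by up to half a fix
interval). Spacing is horizontal only, since GPS is less precise
vertically. Sections with spacing of 50 m or more are excluded; the
front bird per match is the one whose displacement from its partner
projects positively on the circular-mean pair heading; a flight has a
"consistent leader" when one bird is in front for more than 90% of
matches. Matches during which the non-majority bird leads are excluded
from paired summaries for both birds — the cleaner of the two possible
readings of the exclusion rule, applied symmetrically and flagged in
the output so users can choose otherwise.

## Air data

Wind support, crosswind and airspeed come from the wind triangle: the
wind vector points in the direction the air moves (meteorological
direction plus 180 degrees), the air velocity is ground velocity minus
wind, wind support is the signed projection of the wind on the track
direction. A single per-flight wind vector (the station's running-mean
wind bearing at release) is applied to all fixes.

Humid air density uses the ideal gas law,
`rho = P_d/(R_d T) + P_v/(R_v T)` with `R_d = 287.05` and
`R_v = 461.495 J/kg/K`, vapour pressure `P_v = phi * P_sat` (relative
humidity entered in percent and used as a fraction), and the Arden
Buck saturation vapour pressure. The Buck constant 0.61121 is
kPa-valued even though the quantity is sometimes labelled in hPa; the
package evaluates the formula in kPa and converts to Pa, the
physically correct reading (611.21 Pa at 0 degrees C — a moist-air
density near 1.2 kg/m3 follows only under this reading).

## The hierarchical models

The row unit is the flight median. For bird i flying with partner j:

- solo rows: `y ~ N(mu_i + gamma X, sigma)`
- paired rows: `y ~ N(delta0 + delta1 |Ti - Tj| + omega_i mu_i +
  (1 - omega_i) mu_j + gamma X, sigma)` with
  `omega_i = logit^-1(eta1 + eta |Ti - Tj|)`

`delta0` is the pairing effect in the response units, `delta1` the
effect per mm of absolute tarsus difference, and `omega_i` a mixing
weight that lets a bird's paired frequency sit anywhere between its
own and its partner's solo baseline. For solo rows the weighted term
is exactly `mu_i`. Per-bird means are hierarchical,
`mu_i ~ N(mu0, tau_mu)`. Priors are centred on the null with scales
taken from the solo rows: effects and covariate coefficients
`N(0, SD_solo)`, the population mean `N(mean_solo, SD_solo)`, scale
parameters half-normal with scale `sqrt(SD_solo)`. The mixing-weight
coefficients have no empirical anchor, so their prior scale (default
1.5 on the logit scale, roughly uniform in omega) is configuration.
Continuous covariates are centred, not scaled, so coefficients stay in
interpretable per-unit terms; release date enters as sum-to-zero
categories; airspeed is a covariate in every model except models of
airspeed itself.

Three companion models: (1) a wingbeat-level model adding a pairing
intercept at 0 m spacing and a per-metre slope, with a Gaussian
per-flight effect for the repeated wingbeats sampled from one flight —
the flight effects are marginalised analytically (compound-symmetry
covariance per flight), which gives identical inference for the fixed
effects while shrinking the sampling problem from ~100 dimensions to
5; (2) a regression of the behind bird's median frequency on the front
bird's with per-pair intercepts and slopes partially pooled around
population means (a pooled slope of 1 would mean directly coupled
frequencies); (3) a Bernoulli regression of which bird leads on one
within-pair predictor difference at a time, with complete separation
detected and flagged.

### Sampler

No Stan-style backend is assumed; the contract is only "posterior
draws whose split-chain R-hat is at most 1.1 on every parameter". The
backend is adaptive Metropolis-within-Gibbs: one Gaussian proposal per
parameter per sweep, with per-parameter log step sizes adapted in
batches of 50 during warm-up toward a 0.44 acceptance rate
(Roberts-Rosenthal), frozen afterwards. Positive parameters are
sampled on the log scale with the Jacobian included. Chains start from
jittered data-based initials. The default budget mirrors a
full-accounting run (configurable to 8 chains of 12,500 + 12,500);
tests and the acceptance script use 4 chains of 2,000 + 2,000 or less,
which the R-hat criterion itself polices — fits that miss 1.1 return a
non-convergence flag and warning rather than silently passing.

## The generator's stated world

Defaults are the conditions of the emulated experiment: 20 birds with
solo frequencies `N(5.48, 0.19^2)` Hz; 4 phases of 6 releases
(solo/similar pairs/different pairs/solo); a release site 7.06 km from
the loft on a 282-degree loft-to-release bearing; releases only below
7 m/s wind; a +1.00 Hz pairing effect, no tarsus effect, a -0.011 Hz/m
spacing slope, route accuracies 0.86 solo / 0.92 paired, 2.5 g
peak-to-peak dorsal acceleration, an upstroke of 133.8 ms in a
182.5 ms cycle, and 0.2 Hz residual SD on flight medians. Tarsus
(33.5 +/- 1.5 mm) and mass (450 +/- 40 g) are field-plausible values
for homing pigeons chosen once; weather covariates are mild-summer
ranges. Weather is constant within a flight.

*Tracks.* Headings aim at the goal plus i.i.d. von Mises error; the
concentration is calibrated by inverting the Bessel ratio
`I1(kappa)/I0(kappa)` so the expected cosine of the heading error
equals the target accuracy — i.i.d. errors are the simplest process
for which route accuracy is analytically calibrable, and the
calibration is verified empirically to 0.01. Ground velocity is air
velocity plus wind. Paired birds share one heading-error sequence (a
perfectly correlated heading process, so both carry the calibrated
accuracy) and the follower flies a parallel course offset ~12 m,
mostly behind, with a zero-mean mean-reverting station-keeping wiggle
(30 s relaxation). The wiggle's scale is kept small so the follower's
measured accuracy stays within ~0.005 of the calibrated value — a
requirement of the stated world, in which both paired birds are
calibrated to the paired accuracy target.

GPS jitter (default 1.5 m per component) is an additive observation
layer. At 5 Hz the jitter is comparable to the 3.8 m step length, so
measured route accuracy of jittered fixes is biased low relative to
the heading-process calibration; the calibration statement refers to
the noise-free trajectory, and the recovery worlds that test the
calibration switch jitter off. This is a real limitation of 5 Hz GPS,
not an artefact: route accuracy on real tracks is likewise depressed
by fix noise.

*Traces.* Each wingbeat is a two-segment waveform: a half-cosine from
maximum to minimum over the downstroke and a half-cosine back over the
upstroke — smooth, one maximum and one minimum per cycle, with exactly
controllable phase durations that sum to the period. The downstroke
duration is pinned at its solo value, so condition-driven frequency
changes shorten only the upstroke, as observed. The flight-level
frequency follows the generative equation including the spacing term
(`delta0 + slope * spacing` for paired flights). By contrast,
`simulate_flight_summaries()` — the generator behind the
model-recovery worlds — implements the flight-median model exactly as
the inference assumes it (no spacing term), since its purpose is
parameter recovery for that model, not waveform emulation.

*What a green test does not establish.* The generator does not emulate
wake interactions between paired birds, altitude dynamics, logger
failure, per-fix weather variation, non-stationary heading error, or
wingbeat-to-wingbeat frequency jitter within a flight trace. Recovery
tests therefore establish the estimators' correctness under the model,
not robustness to every field condition.

## Power accounting

The classical partition: parasite power `rho U^3 Sb CDb / 2`, induced
power `k (mg)^2 / (2 rho U A)` with disk area `A = pi b^2/4`, profile
power constant. Defaults: span 0.67 m, aspect ratio 6.9, `CDb = 0.1`,
`k = 1.2`, body frontal area `0.00813 m^0.666`, and profile power
`(8.4/aspect ratio)` times the minimum of the parasite+induced curve —
the usual profile-power-ratio convention. Because the published
absolute power figures depend on an external program's defaults
(including an unprinted body mass), absolute outputs require the mass
as configuration and only the structural property is asserted in
tests: above the minimum-power speed, the percent change in total
power for a small speed rise lies strictly between the induced
(negative) and parasite (positive) percent changes. The published
consequences of the optimal-vortex-wake treatment are reproduced as
pure ratio arithmetic (work per beat = power ratio over frequency
ratio; cost of transport = power ratio over speed ratio); the wake
model itself is out of scope.

## Numerical and policy choices

- Wingbeat boundary is max-to-max; the phase durations are unaffected
  by this choice.
- g to SI conversion: 9.80665 m/s2. Earth radius 6,371,000 m.
- `which.min`/`which.max` tie-breaks take the earliest sample.
- The per-flight spacing entering the trace generator is the
  configured mean spacing; per-wingbeat spacing variation appears only
  in the wingbeat-level generator.
- Config hashes use a small deterministic string hash (djb2) — a
  provenance stamp, not a cryptographic guarantee.
- Sample counts in the coverage and contraction tests are scaled down
  (10 birds, 6+6 flights; reduced MCMC budgets) to fit the test-time
  budget; effect sizes, noise levels and priors stay at their
  defaults.

## Known limitations

- The adaptive Metropolis-within-Gibbs sampler mixes more slowly than
  gradient-based samplers; hierarchical scale parameters near zero
  (e.g. between-bird SD when birds are truly identical) mix worst, and
  the R-hat criterion will flag such fits rather than hide them.
- Divergent-transition accounting is sampler-specific and not
  meaningful for a random-walk backend; it is not reported.
- Route accuracy from 5 Hz fixes is biased low under GPS noise (see
  above); comparisons between conditions remain valid because the bias
  is shared.
- The leadership model follows the published specification with an
  inverse-logit link on the linear predictor; with one record per
  pair-flight and weak predictors, its posterior is prior-dominated,
  which the tests exercise deliberately.
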