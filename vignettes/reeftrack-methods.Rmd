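---
title: "Methods: positioning, space use and hidden-state models in reeftrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positioning, space use and hidden-state models in reeftrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`reeftrack` implements a complete analysis chain for fine-scale acoustic
telemetry of fish at artificial reefs and offshore-wind structures: a
ground-truthed synthetic data generator, receiver clock synchronization and
TDOA positioning with quality filtering, daily diel-split kernel home
ranges with structure association and fidelity, a four-state hidden Markov
model (HMM) that infers hiding inside reef structures from detection-derived
streams, a three-state behavioural HMM on step length and body acceleration,
and a penalized additive model of the daily hiding proportion. This
vignette records the models, their assumptions, the tunable parameters, and
the design decisions taken where the methodology is genuinely open.

## The synthetic world

Real deployments of this kind cannot ship with a package, so every stage is
exercised against a simulator whose statistical structure matches what the
downstream analysis assumes. The stated world is:

* **Array**: 16 receivers on a 4 x 4 grid with 225 m spacing (within the
  deployed 200–250 m range), four artificial reefs on the diagonals at
  280 m from a central turbine monopile, at ~30 m depth. Coordinates are
  local planar metres anchored at the array centre; latitude/longitude
  (51.70 N, 3.05 E) is kept only for solar day/night computation. This
  avoids projection machinery: every distance in the analysis is metres.
* **Tags**: transmissions at uniform random delays of 50–100 s, alternating
  pressure and acceleration payloads; acceleration is the tag's VeDBA
  summary over a 37 s window; nominal battery life 278 days.
* **Movement**: a three-regime Markov chain at a 60 s step. *Hiding* pins
  the animal within 2 m of its home reef; *local* is a discrete
  mean-reverting (Ornstein–Uhlenbeck-like) walk around the home reef;
  *transit* is a directed walk towards another structure or an exit beyond
  the array edge. Regime-specific VeDBA is Gamma distributed. No published
  movement model exists for this setting; any regime-switching generator
  with separable step/VeDBA distributions suffices for recovery testing,
  which is all the generator must support.
* **Detection physics**: a transmission at distance `d` is detected with
  probability `plogis((d50 - d) / slope)` (defaults `d50 = 300` m,
  `slope = 60` m), multiplied by the regime's detectability. Hiding inside
  concrete pipes is modelled as a multiplicative occlusion factor, default
  0.02. That value is a free simulator parameter, not an empirical one: the
  field observation is only that in-pipe emissions are strongly attenuated.
  Arrival times get Gaussian jitter (`timing_sd`, default 1e-4 s ≈ 0.15 m
  at 1500 m/s) and pass through a linear per-receiver clock
  (`local = true * (1 + drift) + offset`, drift ~ N(0, 1e-5)), which a
  linear-regression correction can invert exactly. Receivers also emit sync
  pings on a staggered 600 s schedule so synchronization is testable.
* **Environment**: current speed is a rectified 12.42 h (M2 tidal)
  sinusoid, amplitude 0.6 m/s; SST a seasonal sinusoid peaking at day of
  year 215. Both carry Gaussian noise.

What the generator does **not** emulate: hydrodynamic propagation,
multipath, bathymetry, tide-dependent detection range, 3-D positions, or
signal collisions beyond an optional logistic network-load damping. A green
recovery test therefore establishes that the estimators invert the stated
generative model, not that they are robust to every artefact of real
deployments.

## Positioning

**Clock synchronization.** For two receivers hearing the same sync ping,
the difference of local arrival times equals the known travel-time
difference plus the relative offset and a term linear in time (relative
drift). Offsets and drifts are estimated by least squares per receiver
against a reference, transitively (breadth-first) for receivers that never
share enough pings with the reference; at least 10 shared pings are
required per link. Synchronized timestamps live on the reference receiver's
clock.

**TDOA solving.** Detections are grouped per tag by a greedy coincidence
window of 1.5 x (array diagonal / sound speed). Each group with at least
three receivers is solved by Gauss–Newton on pairwise
time-difference-of-arrival residuals, initialized at the centroid of
detecting receivers, with Levenberg damping, a 1e-6 m step tolerance and at
most 50 iterations. If the residual RMS stays above the timing-noise floor
the solver restarts from each receiver position and keeps the best fit —
this resolves wrong local minima. With only three receivers the TDOA
problem genuinely admits two exact solutions (a mirror ambiguity); such
fixes can converge to either point. Over-determined fixes (4+ receivers)
are unique and, with noise-free input, recovered to well below 1e-3 m.

**HPE.** The vendor's position-error formula is proprietary. The package
defines `HPE = sqrt(trace(cov(x, y))) / (c * timing_sd)` with
`cov = timing_sd^2 (J'J)^{-1}` from the linearized least squares. The noise
scale cancels, leaving a dimensionless dilution-of-precision measure that
is monotone in geometry quality, specific to one network set-up, and
filterable by quantile — the only properties the analysis uses. Collinear
receiver sets return an infinite sentinel. The filter removes positions
above the nearest-rank 98th percentile (strictly greater), so 1000 distinct
values keep exactly 980 and full ties keep everything. A strict quantile
trim is not idempotent on distinct values (re-application removes a further
2%); the pipeline applies it once per dataset.

**Tag-loss screening.** A tag is truncated from the start of the first
7-day window in which its positions stay within 5 m of their centroid *and*
mean VeDBA stays below 0.02 m/s². Both conditions are required so a
stationary but active (hiding) animal is never discarded. The thresholds
are declared defaults, not field-derived values.

## Space use

Daily, per animal and diel period (day = solar elevation > 0 at the array
anchor, by the NOAA solar algorithm; early-morning night records belong to
the night that started the previous date), positions are smoothed with a
fixed-bandwidth bivariate Gaussian kernel, `h = 6` m, on a 1 m grid padded
4h beyond the data, renormalized to mass one. The home range is the
smallest region holding 95% of the utilization distribution: cells ranked
by density, thresholded at the level that first accumulates 0.95, giving a
mass in `[0.95, 0.95 + one cell)`. Polygons are accepted only with at least
6 positions and an in-polygon time extent above 2 h. Disjoint components
all count for containment; the centroid and the structure association
(nearest structure within 30 m, lexicographic tie-break) use the
largest-mass component. Fidelity is the inside fraction `N_p / N` — the
printed source formula has the ratio inverted relative to its own stated
range, so the bounded form is used. `N` counts positions of the same
(animal, date, diel) window. Residency is elapsed days from release to last
detection, flagged censored within 5 days of the battery life.

## The hidden Markov machinery

Both analyses share one engine: states emit independent observations on
named streams — Gamma (mean/sd parametrization, optionally with a per-state
point mass at zero) or Bernoulli — and switch with multinomial-logit
transition probabilities whose logits are linear in covariates (the
diagonal is the reference category, so the realized rows always sum to
one). The zero mass exists because receiver counts and step lengths can be
exactly zero, where a Gamma density is undefined. Missing stream values
contribute likelihood one in their bin, so partially observed bins stay in
the sequence. Animal identity enters as fixed-effect dummy covariates on
the transition logits; this mirrors treating individual as a transition
covariate rather than a true random effect.

Fitting is direct numerical maximum likelihood on the scaled forward
recursion (implemented in C++), over unconstrained transforms (log means
and sds, logit probabilities, free logit coefficients), with BFGS,
numerical gradients, relative tolerance 1e-8, and jittered multi-starts
(seed-controlled). EM was rejected because covariate-dependent transitions
leave no closed-form M-step. The initial state distribution is the
stationary distribution of the transition matrix at the covariate means
unless overridden. Default emission starts are quantile-split moment
estimates of each stream. Decoding is by the Viterbi algorithm with ties
broken toward the lower state index; model comparison is by AIC
(`2k - 2 logL`) with stable tie order.

## Hiding analysis

All detections (positioned or not) are binned per 10 min into three
streams: mean distance to the closest reef (linearly interpolated in time
across bins without positions, nearest-value extended at the ends, and
flagged), the number of unique receivers (zero-inflated Gamma), and a
binary positioning-success indicator (Bernoulli). Bins with zero detections
are retained — the "away, not positioned" state needs them. The four
states are: HS1 at reef without positioning (hiding inside the pipes), HS2
at reef with positioning, HS3 away with positioning, HS4 away without
positioning. Initial values encode those semantics; after fitting, states
are relabelled to the pattern: the two smallest fitted distance means are
"at reef" (split from the rest at the geometric midpoint of the two
groups), and within each pair the Bernoulli probability separates hidden
from visible. Distance means too close to split raise a diagnostic error.

Daily hiding proportion (HS1 bins over all bins; a full day has 144) is
modelled with a binomial-family penalized additive model with per-day bin
counts as weights: animal id as a ridge-penalized random intercept, reef as
categorical, and REML-selected smooths of current speed (k = 9), day of
year (k = 9) and the daily number of distinct animals detected anywhere in
the array (k = 5). The binomial family respects the count construction
(the source does not state a family); the network-load covariate absorbs
detection loss from signal collisions when many tags are active. Constant
covariates are dropped with a warning and smooth bases are capped by the
number of distinct values.

## Behavioural analysis

Positions are averaged per 10-min bin; the step length is the Euclidean
distance between consecutive bin means (missing when either bin is empty —
the bin-mean convention, since the source is ambiguous between raw and
binned positions), and VeDBA is the mean of in-bin acceleration payloads.
The three states follow the conventional pattern: BS1 locally inactive
(low step, low VeDBA), BS2 locally active (low step, high VeDBA), BS3
transit (large step). Relabelling orders states by step mean and breaks the
local pair by VeDBA mean; inseparable step means fall back to plain
step-mean ordering with a warning (or an error under `strict_labels`).

Transition covariates are selected by AIC with forward selection from the
id-only base over current speed, SST, day of year, hour of day, tag extent
(0 at release, 1 at departure = last detection) and distance to the closest
reef, with the full set always fitted as well — an all-subsets search is
exponential and the forward path plus full model brackets the reported
optimum. Periodic covariates (hour, day of year) enter as sine/cosine
pairs, since a raw linear term cannot represent a cycle on a logit scale.
Decoded states are mapped in space with one normalized kernel density per
state (default h = 15 m; states under 10 positioned bins are omitted).

## Numerical choices and edge cases

* Gamma mean/sd maps to shape/scale via `k = mean²/sd²`,
  `theta = sd²/mean`; the round-trip is exact to 1e-12.
* Emission densities are floored at 1e-300 so a single impossible
  observation degrades the likelihood instead of producing `log(0)`.
* The forward recursion rescales at every step; independent animals sum
  their log-likelihoods.
* The UD grid step (1 m) changes UD95 areas by under 2% against a 0.5 m
  grid; the 4h padding keeps truncated kernel mass below 1e-6.
* Transmissions during `hiding` are still scheduled (the tag keeps
  pinging); only their detection probability collapses.
* The 2% HPE filter is global by default; a per-tag switch exists because
  the source does not state which was used.
* Whether "daily number of individuals detected" is per reef or per array
  is also unstated; the whole-array count is used.

## Known limitations

* No 3-D positioning; depth payloads pass through untouched.
* The behavioural HMM treats animal id as fixed dummies; with many animals
  and short series this can overfit transitions where a true random effect
  would shrink.
* AIC selection is over user-supplied candidates only; no state-number
  selection is attempted.
* The simulator's occlusion, detection and clock parameters are stated, not
  estimated; tests that pass against it validate the estimators under the
  stated world only.
* Three-receiver fixes carry an unresolvable mirror ambiguity; downstream
  summaries are robust because such fixes are rare in a 16-receiver array
  and carry high HPE when geometry is poor.
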