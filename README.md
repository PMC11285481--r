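# reeftrack

Fine-scale acoustic-telemetry analysis of fish at artificial reefs and
offshore-wind structures, as one tested, reusable R pipeline.

Tagged fish (e.g. Atlantic cod released at artificial reefs inside a wind
farm) are heard by a grid of moored acoustic receivers. From raw detections
the package reconstructs where the animals were, how much space they used,
when they were hiding inside the reef structures, and what behavioural mode
they were in:

1. **simulate** — a ground-truthed synthetic telemetry generator (tracks,
   transmissions, detections, sync pings, tidal current and SST series)
   with the statistical structure the downstream stages assume, so the
   whole chain is testable without field data.
2. **positioning** — receiver clock synchronization by linear regression on
   shared sync pings; time-difference-of-arrival (TDOA) multilateration by
   damped Gauss–Newton (at least 3 receivers per fix); a dimensionless
   horizontal position error, `HPE = sqrt(tr cov(x,y)) / (c sigma)`, with
   the top 2% filtered out; tag-loss/death screening.
3. **spaceuse** — daily, day/night kernel home ranges with fixed bandwidth
   h = 6 m; the UD95 isopleth (smallest region holding 95% of the
   utilization distribution); association of polygon centroids to
   structures within 30 m; site fidelity `F = N_p / N`; residency.
4. **hmm** — a hidden Markov engine with mixed Gamma (optionally
   zero-inflated) and Bernoulli emission streams, multinomial-logit
   transition probabilities with covariates (including animal id), direct
   maximum likelihood via a C++ forward recursion, Viterbi decoding, AIC
   ranking.
5. **hiding** — 10-min bins of (distance to closest reef, unique receiver
   count, positioning success) feed a 4-state HMM; HS1 = at reef without
   positioning, i.e. hiding inside the concrete pipes. Daily HS1 proportion
   is modelled with a binomial GAM (mgcv) over individual, reef, current
   speed, day of year and daily number of animals detected.
6. **behaviour** — 10-min step-length/VeDBA streams feed a 3-state HMM
   (locally inactive BS1, locally active BS2, transit BS3) with
   AIC-selected transition covariates, plus per-state spatial density maps.

## Worked example

Simulate four fish for eight days around the default 4 x 4 receiver array
(four reefs + monopile), position them, and fit the hiding model:

```r
library(reeftrack)

lay <- default_layout()            # 16 receivers, 4 reefs, 1 monopile
reg <- default_regimes()           # hiding / local / transit
tr  <- simulate_tracks(lay, reg, n_fish = 4, duration = 8, seed = 42)
cl  <- random_clocks(lay, seed = 43)
det <- simulate_detections(tr, lay, clock_models = cl, regimes = reg,
                           timing_sd = 1e-4, seed = 44)

res  <- estimate_positions(det$detections, det$sync, lay)
bins <- build_hiding_bins(det$detections, res$positions, lay)
hm   <- fit_hiding_hmm(bins, nstarts = 1, seed = 1)
hm$fit
```

```
Fitted HMM: 4 states, 36 parameters
  logL = -22227.219  AIC = 44526.438  (n = 4604 bins)
  dist: mean 5.34 5.65 124 151 | sd 2.2 2.24 66.4 79.1
  nrec: mean 1.42 8.89 9.57 2.61 | sd 0.596 0.999 2.37 1.37
  pos: p 0.00543 1 1 0.138
```

Read: states 1–2 sit ~5 m from a reef and states 3–4 far from one
(`dist` means); HS1 is almost never positioned (`pos` p = 0.005) and heard
by ~1.4 receivers — the acoustic signature of a fish inside a concrete
pipe — while HS2/HS3 are positioned essentially always. Against the
simulator's ground truth this decoding recovers true hiding bins with
balanced accuracy ≈ 0.96. `hm$occupancy` gives the share of time per
state; `daily_hiding()` + `fit_hiding_gam()` model the daily HS1
proportion.

The whole chain (including home ranges, residency and the behavioural HMM)
runs as one stage-ordered pipeline with a YAML-configurable parameter set
whose defaults are the study constants (h = 6 m, 30 m association, 2% HPE
filter, 10-min bins, 50–100 s delays, ...):

```r
run_pipeline(default_config(), seed = 1, out_dir = "run")
```

or from the shell: `inst/cli/reeftrack run-all --seed 1 --out run`.

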