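Package: reeftrack
Title: Fine-Scale Acoustic Telemetry Analysis of Fish at Artificial Reefs
Version: 0.1.0
Authors@R: person("Reeftrack", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline for fine-scale acoustic-telemetry
    studies of fish residency and behaviour at artificial reefs and offshore
    wind structures. Provides a ground-truthed synthetic telemetry generator;
    receiver clock synchronization and time-difference-of-arrival (TDOA)
    positioning with horizontal-position-error (HPE) filtering; daily,
    diel-split kernel utilization-distribution home ranges (UD95) with
    structure association, site fidelity and residency metrics; hidden Markov
    models with mixed Gamma/Bernoulli emission streams and
    covariate-dependent transition probabilities, including a four-state
    model of hiding inside reef structures and a three-state behavioural
    model on step length and body acceleration; and a penalized additive
    model of the daily hiding proportion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    data.table,
    mgcv,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
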