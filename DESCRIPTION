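Package: surradapt
Title: Simulation and Inference for Surrogate-Guided Adaptive Seamless
    Phase 2/3 Survival Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing two-stage adaptive dose-selection trials in
    which a continuous early surrogate endpoint drives interim arm selection
    and a time-to-event primary endpoint drives a closed-testing final
    analysis. The surrogate/primary linkage is a Bayesian log-normal
    accelerated-failure-time regression fitted to historical data by a Gibbs
    sampler with censored-data augmentation. The package simulates full
    trials (enrollment, exponential event and dropout times, interim
    snapshot, stage-2 continuation), performs the weighted inverse-normal
    combination test with Dunnett within-stage adjustment under the closure
    principle, and estimates operating characteristics by Monte Carlo:
    selection probabilities, overall and conditional power, futility and
    false-stopping probabilities, expected sample size, familywise error
    scans, and sample-size searches for both the adaptive and the
    traditional single-stage design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mvtnorm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    survival,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
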