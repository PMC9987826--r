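Package: mtoccu
Title: Multi-Trophic Dynamic Occupancy Models for Post-Fire Woodpecker
    and Woodboring-Beetle Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint hierarchical Bayesian modelling of black-backed
    woodpecker (Picoides arcticus) occupancy dynamics over the decade
    following wildfire, linked to a latent woodboring-beetle
    sign-intensity submodel estimated from bark surveys of fire-killed
    snags. Detection histories from removal-design point-count surveys
    are modelled with imperfect detection and an autologistic
    year-to-year persistence term; the latent occurrence sequence at
    each survey point is marginalised exactly by a two-state forward
    algorithm, and accumulated beetle sign is modelled as a binomial
    outcome whose success probability is a logit-linear function of
    fire age and pine proportion. Includes an adaptive
    Metropolis-within-Gibbs sampler, convergence diagnostics, posterior
    summaries and prediction curves, and a synthetic-data generator
    replicating the multi-fire staggered-entry study design so the full
    simulate-fit-predict loop runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
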