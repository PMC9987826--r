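# mtoccu

Joint hierarchical Bayesian modelling of black-backed woodpecker
(*Picoides arcticus*) occupancy dynamics in the decade after wildfire,
linked to a latent woodboring-beetle sign-intensity submodel estimated
from bark surveys of fire-killed snags. The package is aimed at avian and
disturbance ecologists who have multi-year detection/non-detection
surveys at points nested in fires, plus a single-year survey of
accumulated beetle sign, and want to ask whether prey sign predicts
predator occurrence and how that relationship shifts with time since
fire.

## The model

Detection of interval *k* at point *j* in year *t* is imperfect:

    y_jkt ~ Bernoulli(z_jt * p_jkt),      logit(p_jkt) = α0 + α_type type_k

with a removal design (intervals after the first detection are censored).
The true occurrence state follows a dynamic occupancy model with a
fire-level random intercept and an autologistic persistence term:

    z_jt ~ Bernoulli(ψ_jt)
    logit(ψ_jt) = β0_j + β_elev elev_j + β_lat lat_j + β_snag snag_jt
                  + β_beetle intensity_jt + β_ageXbeetle age_jt intensity_jt
                  + φ z_j,t-1                     (φ term absent in year 1)
    β0_j ~ Normal(μ_β0, 1/τ_β0)

The trophic link is a latent, deterministic beetle sign intensity,

    logit(intensity_jt) = γ0 + γ_age age_jt + γ_pine pine_j
                          + γ_ageXpine age_jt pine_j

observed in the final survey year as a binomial count of summed per-tree
activity scores: `activity_j ~ Binomial(numTrees_j × 8, intensity_j,T)`.
The latent occurrence sequences are marginalised exactly by a two-state
forward algorithm (no data augmentation), and the posterior is sampled by
an adaptive Metropolis-within-Gibbs sampler with vague Normal(0, prec 0.1)
priors. See the methods vignette
(`vignettes/multitrophic-occupancy-model.Rmd`) for assumptions, scaling
conventions and numerical choices.

## Worked example

Simulate a dataset on the built-in 22-fire / 128-point reference design
and refit it with a reduced MCMC run:

```r
library(mtoccu)

sim <- simulate_dataset(generator_config(seed = 1))
fit <- fit_mtocc(sim$dataset,
                 mcmc_config(n_chains = 2, n_iter = 2000, n_burnin = 2000,
                             thin = 4, seed = 1))
print(fit)
```

```
Multi-trophic occupancy model fit
Study design: 22 fires, 128 points, reference year 2018 (T = 10 model years)
  posterior: 2 chain(s), 1000 retained draws

Key parameters (posterior mean [95% CrI]):
  alpha0            -4.91 [ -6.26,  -3.66] *
  alpha_type         4.88 [  3.67,   6.18] *
  mu_beta0           1.09 [ -0.84,   3.28]
  beta_beetle       -3.41 [ -7.49,   0.02]
  beta_ageXbeetle   -1.00 [ -1.60,  -0.44] *
  phi                0.39 [ -0.41,   1.17]
  gamma0            -0.10 [ -0.22,   0.01]
  gamma_age          0.31 [  0.22,   0.42] *
  gamma_pine         0.39 [  0.19,   0.61] *
  gamma_ageXpine    -0.65 [ -0.83,  -0.49] *
```

The dataset was generated at the reference parameter values
(`reference_params()`), so the fit illustrates what a 128-point design
identifies: the detection block, the gamma (beetle) block and the focal
age-by-beetle interaction (truth −0.95, recovered −1.00 with the interval
excluding zero) are well estimated, while the main beetle effect is
wide — exactly the behaviour reported for the field data. A `*` flags
parameters whose 95% credible interval excludes zero. `summary(fit)`
returns the full table with Gelman–Rubin statistics;
`plot(fit, type = "intensity")` and `plot(fit, type = "occupancy")` draw
the prediction curves (beetle sign rising with age in pine-free stands
and falling in pine-dominated ones; the occupancy–sign slope flipping
from positive in early post-fire years to negative by late years).

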