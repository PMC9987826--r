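# Model-fitting front end: one fitting function returning a classed object
# with the usual method surface (print, summary, coef, predict, plot,
# simulate).

#' Fit the multi-trophic occupancy model
#'
#' Fits the joint woodpecker-occupancy / beetle-intensity model to a survey
#' dataset by MCMC. Covariates are standardized (z-scores for elevation,
#' latitude, snag index and fire age; pine and intensity stay on \[0, 1\])
#' and the scaling constants are kept with the fit so predictions can be
#' asked for in natural units.
#'
#' @param dataset An `mtocc_data` object.
#' @param config An `mtocc_mcmc_config`; the default mirrors the reference
#'   analysis (3 chains of 50,000 iterations thinned by 50 after a 50,000
#'   burn-in, i.e. 3,000 retained draws). Use a reduced configuration for
#'   exploratory runs.
#' @param fixed Optional named values to clamp (see [sample_posterior()]).
#' @return An object of class `mtocc`.
#' @export
fit_mtocc <- function(dataset, config = mcmc_config(), fixed = NULL) {
  stopifnot(inherits(dataset, "mtocc_data"))
  if (is.null(dataset$std)) dataset <- standardize_covariates(dataset)
  draws <- sample_posterior(dataset, config, fixed = fixed)
  out <- structure(list(draws = draws, dataset = dataset,
                        scaling = dataset$scaling, config = config,
                        fixed = fixed),
                   class = "mtocc")
  out$summary <- summarize_posterior(draws)
  out
}

#' Fit only the beetle sign-intensity submodel
#'
#' Clamps everything except the gamma block at zero (the detection and
#' occupancy parameters are irrelevant when the dataset carries no
#' detection histories) and samples the gamma posterior from the binomial
#' beetle observations.
#'
#' @param dataset An `mtocc_data` object (typically from
#'   [simulate_beetle_points()] or a beetle-only field table).
#' @param config An `mtocc_mcmc_config`.
#' @return An `mtocc` fit whose non-gamma parameters are constant.
#' @export
fit_beetle_submodel <- function(dataset, config = mcmc_config()) {
  fixed <- list(alpha0 = 0, alpha_type = 0, beta0 = 0, mu_beta0 = 0,
                tau_beta0 = 1, beta_elev = 0, beta_lat = 0, beta_snag = 0,
                beta_beetle = 0, beta_ageXbeetle = 0, phi = 0)
  fit_mtocc(dataset, config, fixed = fixed)
}

#' @export
print.mtocc <- function(x, ...) {
  cat("Multi-trophic occupancy model fit\n")
  print(x$dataset$design)
  d <- dim(x$draws$draws)
  cat("  posterior:", d[1], "chain(s),", d[1] * d[2], "retained draws\n")
  key <- c("alpha0", "alpha_type", "mu_beta0", "beta_beetle",
           "beta_ageXbeetle", "phi", "gamma0", "gamma_age", "gamma_pine",
           "gamma_ageXpine")
  s <- x$summary[x$summary$parameter %in% key, ]
  cat("\nKey parameters (posterior mean [95% CrI]):\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %6.2f [%6.2f, %6.2f]%s\n", s$parameter[i],
                s$mean[i], s$lower[i], s$upper[i],
                if (isTRUE(s$evidence[i])) " *" else ""))
  invisible(x)
}

#' @export
summary.mtocc <- function(object, ...) object$summary

#' @export
coef.mtocc <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Posterior prediction curves from a fitted model
#'
#' `type = "intensity"` returns beetle sign intensity over a fire-age grid
#' for each pine proportion; `type = "occupancy"` returns occupancy against
#' beetle intensity for each fire age (population-level, i.e. at the fire
#' intercept hyper-mean and standardized covariate means). Fire ages are
#' given in natural years since fire and converted internally with the
#' fit's scaling constants.
#'
#' @param object An `mtocc` fit.
#' @param type `"occupancy"` or `"intensity"`.
#' @param age_values Fire ages (years) at which occupancy curves are drawn.
#' @param intensity_grid Beetle-intensity grid for occupancy curves.
#' @param age_grid Fire-age grid (years) for intensity curves.
#' @param pine_values Pine proportions for intensity curves.
#' @param ribbon `"partial"` (only the beetle slope and the age-by-beetle
#'   interaction vary across draws; everything else at posterior means) or
#'   `"full"`; occupancy curves only.
#' @param ... Unused.
#' @return An `mtocc_curve` data frame (see [predict_occupancy_curve()]).
#' @export
predict.mtocc <- function(object, type = c("occupancy", "intensity"),
                          age_values = c(1, 3, 5, 7, 10),
                          intensity_grid = seq(0.01, 0.99, length.out = 50),
                          age_grid = 1:10, pine_values = c(0, 0.5, 1),
                          ribbon = "partial", ...) {
  type <- match.arg(type)
  if (type == "occupancy")
    predict_occupancy_curve(object$draws, age_values, intensity_grid,
                            ribbon = ribbon, scaling = object$scaling)
  else
    predict_intensity_curve(object$draws, age_grid, pine_values,
                            scaling = object$scaling)
}

#' @export
plot.mtocc <- function(x, type = c("intensity", "occupancy"), ...) {
  type <- match.arg(type)
  curve <- predict(x, type = type, ...)
  plot(curve)
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws `nsim` parameter vectors from the retained posterior sample and
#' runs the generative process on the fitted design once per draw
#' (posterior predictive replicates of the full survey dataset).
#'
#' @param object An `mtocc` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `mtocc_sim` objects.
#' @export
simulate.mtocc <- function(object, nsim = 1, seed = 1L, ...) {
  a <- object$draws$draws
  d <- dim(a)
  flat <- matrix(a, d[1] * d[2], d[3])
  colnames(flat) <- object$draws$parameters
  set.seed(seed)
  picks <- sample.int(nrow(flat), nsim, replace = nsim > nrow(flat))
  lapply(seq_len(nsim), function(s) {
    pars <- unpack_params(flat[picks[s], ])
    simulate_dataset(generator_config(design = object$dataset$design,
                                      true_params = pars,
                                      seed = seed + s))
  })
}
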