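# Deterministic model skeleton: linear predictors and probability transforms.
# All transforms go through stats::plogis, which is numerically stable for
# large |logit| (detection logits in this system reach beyond +/-5).

#' Per-interval detection probability
#'
#' Detection of a black-backed woodpecker in one survey interval, given true
#' presence, follows `logit(p) = alpha0 + alpha_type * type` where `type` is
#' 0 for a passive interval and 1 for a broadcast interval.
#'
#' @param params An `mtocc_params` object (only `alpha0` and `alpha_type`
#'   are used).
#' @param survey_type 0/1 vector: passive = 0, broadcast = 1.
#' @return Detection probabilities in (0, 1), vectorized over `survey_type`.
#' @export
detection_prob <- function(params, survey_type) {
  if (!all(survey_type %in% c(0, 1))) stop("survey_type must be 0 or 1")
  stats::plogis(params$alpha0 + params$alpha_type * survey_type)
}

#' Latent beetle sign intensity
#'
#' Cumulative woodboring-beetle sign intensity at a point is a deterministic
#' logit-linear function of fire age and the proportion of sampled trees of
#' the genus Pinus:
#' `logit(intensity) = gamma0 + gamma_age * age + gamma_pine * pine +
#' gamma_ageXpine * age * pine`. There is no residual noise on intensity;
#' uncertainty flows entirely through the gamma coefficients.
#'
#' @param params An `mtocc_params` object (gamma block used).
#' @param age Years since fire, on the scale used at fitting time
#'   (standardized by default in fitted models).
#' @param pine Proportion of pines among sampled trees, in \[0, 1\].
#' @return Intensities strictly inside (0, 1), vectorized.
#' @export
beetle_intensity <- function(params, age, pine) {
  if (any(pine < 0 | pine > 1)) stop("pine must lie in [0, 1]")
  stats::plogis(params$gamma0 + params$gamma_age * age +
                  params$gamma_pine * pine +
                  params$gamma_ageXpine * age * pine)
}

# Occupancy linear predictor without the autologistic term (first-year form).
occupancy_logit <- function(params, elev, lat, snag, age, intensity,
                            beta0 = NULL) {
  if (is.null(beta0)) beta0 <- params$mu_beta0
  beta0 + params$beta_elev * elev + params$beta_lat * lat +
    params$beta_snag * snag + params$beta_beetle * intensity +
    params$beta_ageXbeetle * age * intensity
}

#' Annual occupancy probability
#'
#' Probability that a survey point is truly occupied in a given year. In the
#' first post-fire year the logit is
#' `beta0_j + beta_elev*elev + beta_lat*lat + beta_snag*snag +
#' beta_beetle*intensity + beta_ageXbeetle*age*intensity`; in later years an
#' autologistic term `phi * z_prev` is added, where `z_prev` is the true
#' occurrence status of the previous year.
#'
#' @param params An `mtocc_params` object.
#' @param covariates List or data frame with elements `elev`, `lat`, `snag`,
#'   `age` (on the fitted scale).
#' @param intensity Beetle sign intensity in (0, 1) for the same point-year.
#' @param z_prev Previous-year true occurrence (0/1), or `NULL` for the
#'   first post-fire year.
#' @param beta0 Fire-level intercept; defaults to the hyper-mean `mu_beta0`
#'   (population-level prediction).
#' @return Occupancy probabilities in (0, 1).
#' @export
occupancy_prob <- function(params, covariates, intensity, z_prev = NULL,
                           beta0 = NULL) {
  eta <- occupancy_logit(params, covariates$elev, covariates$lat,
                         covariates$snag, covariates$age, intensity, beta0)
  if (!is.null(z_prev)) {
    if (!all(z_prev %in% c(0, 1))) stop("z_prev must be 0 or 1")
    eta <- eta + params$phi * z_prev
  }
  stats::plogis(eta)
}
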