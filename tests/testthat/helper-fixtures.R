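# Small in-code fixtures shared across tests.

empty_detections <- function() {
  data.frame(fire_id = character(0), point_id = character(0),
             year = integer(0), interval = integer(0), type = integer(0),
             detected = integer(0), censored = integer(0))
}

empty_beetle <- function() {
  data.frame(point_id = character(0), num_trees = integer(0),
             activity = integer(0))
}

# one fire burned 2016, two points, surveys 2017-2018 (T = 2 window)
mini_design <- function(year_burned = 2016, survey_years = c(2017, 2018),
                        n_points = 2) {
  study_design(data.frame(fire_id = "f1", year_burned = year_burned,
                          n_points = n_points),
               list(f1 = survey_years), reference_year = 2018)
}

mini_covariates <- function(n_points = 2) {
  data.frame(point_id = paste0("p", seq_len(n_points)), fire_id = "f1",
             elevation_m = seq(1500, 1700, length.out = n_points),
             latitude = seq(38, 38.4, length.out = n_points),
             pine_prop = seq(0.2, 0.8, length.out = n_points))
}

mini_dataset <- function(detections = empty_detections(),
                         beetle = empty_beetle(), n_points = 2, ...) {
  survey_dataset(mini_design(n_points = n_points, ...), detections, beetle,
                 mini_covariates(n_points))
}

# one broadcast detection record
det_row <- function(point, year, interval = 1, type = 1, detected = 0,
                    censored = 0) {
  data.frame(fire_id = "f1", point_id = point, year = year,
             interval = interval, type = type,
             detected = if (censored == 1) NA_integer_ else detected,
             censored = censored)
}

# a fake draws object with given parameter columns (single chain unless
# a 3-d array is supplied)
fake_draws <- function(values, n_chains = 1) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (length(dim(values)) == 2) {
    a <- array(NA_real_, c(n_chains, nrow(values), ncol(values)),
               dimnames = list(NULL, NULL, colnames(values)))
    for (ch in seq_len(n_chains)) a[ch, , ] <- values
  } else a <- values
  structure(list(draws = a, parameters = dimnames(a)[[3]],
                 config = mcmc_config(n_chains = dim(a)[1], n_iter = dim(a)[2],
                                      n_burnin = 0, thin = 1),
                 accept = list(), checksum = "fixture"),
            class = "mtocc_draws")
}

# full parameter draw matrix at constant values (for curve tests)
const_draw_matrix <- function(params, n = 4) {
  v <- mtoccu:::pack_params(mtoccu:::expand_beta0(params,
                                                  list(J = 1, fire_ids = "f1")),
                            "f1")
  matrix(rep(v, each = n), n, length(v), dimnames = list(NULL, names(v)))
}

# Random parameters for likelihood property tests.
rand_params <- function() {
  model_params(alpha0 = rnorm(1, -1, 1), alpha_type = rnorm(1, 1, 1),
               beta0 = rnorm(1), mu_beta0 = rnorm(1), tau_beta0 = rgamma(1, 2),
               beta_elev = rnorm(1, 0, 0.5), beta_lat = rnorm(1, 0, 0.5),
               beta_snag = rnorm(1, 0, 0.5), beta_beetle = rnorm(1, 0, 0.5),
               beta_ageXbeetle = rnorm(1, 0, 0.5), phi = rnorm(1),
               gamma0 = rnorm(1, 0, 0.5), gamma_age = rnorm(1, 0, 0.5),
               gamma_pine = rnorm(1, 0, 0.5), gamma_ageXpine = rnorm(1, 0, 0.5))
}

# random removal-design detection history for one fire/two points over the
# given survey years
rand_detections <- function(survey_years, p_missing = 0.2) {
  rows <- list()
  for (pt in c("p1", "p2")) for (yr in survey_years) {
    if (runif(1) < p_missing) next  # point-year with no survey
    types <- if (runif(1) < 0.5) c(0L, 0L, 0L, 1L, 1L, 1L) else c(1L, 1L, 1L)
    found <- FALSE
    for (k in seq_along(types)) {
      if (found) {
        rows[[length(rows) + 1L]] <- det_row(pt, yr, k, types[k],
                                             censored = 1)
      } else {
        y <- rbinom(1, 1, 0.3)
        rows[[length(rows) + 1L]] <- det_row(pt, yr, k, types[k],
                                             detected = y)
        if (y == 1) found <- TRUE
      }
    }
  }
  if (!length(rows)) return(empty_detections())
  do.call(rbind, rows)
}

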