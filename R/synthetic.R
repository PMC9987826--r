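# Synthetic-data generator: runs the model forward (covariates -> latent
# intensity -> occurrence sequences -> interval detections with removal
# censoring -> final-year beetle surveys), replicating the 22-fire
# staggered-entry study design so every module is testable without field
# data.

#' The 22-fire reference study design
#'
#' The multi-fire layout of the California post-fire monitoring study:
#' 22 fires burned 2008-2017 in the Sierra Nevada and Southern Cascades,
#' 4-6 beetle survey points per fire (128 points in total), woodpecker
#' surveys in staggered subsets of 2009-2018 with every fire surveyed in
#' 2018 (the beetle-survey reference year).
#'
#' @return An `mtocc_design` with reference year 2018.
#' @export
make_table1_design <- function() {
  rows <- list(
    list("Aspen",       2013, 6, c(2014, 2015, 2016, 2017, 2018)),
    list("Bald",        2014, 6, c(2015, 2016, 2017, 2018)),
    list("Barry Point", 2012, 6, c(2013, 2014, 2015, 2018)),
    list("Clark",       2016, 6, c(2017, 2018)),
    list("Cold",        2008, 6, c(2012, 2013, 2014, 2016, 2017, 2018)),
    list("Cougar",      2011, 6, c(2012, 2014, 2015, 2018)),
    list("Cove",        2017, 6, 2018),
    list("Fox",         2008, 6, c(2011, 2013, 2014, 2015, 2016, 2017, 2018)),
    list("Frog",        2015, 6, c(2016, 2017, 2018)),
    list("George",      2012, 5, c(2013, 2014, 2015, 2016, 2017, 2018)),
    list("Granite",     2009, 6, c(2010, 2011, 2013, 2014, 2015, 2016, 2017,
                                   2018)),
    list("Lion",        2009, 6, c(2010, 2011, 2013, 2014, 2015, 2016, 2017,
                                   2018)),
    list("Minerva 5",   2017, 6, 2018),
    list("Onion 2",     2008, 5, c(2010, 2011, 2012, 2013, 2014, 2015, 2016,
                                   2017, 2018)),
    list("Owens River", 2016, 6, c(2017, 2018)),
    list("Peak",        2012, 6, c(2015, 2016, 2017, 2018)),
    list("Pier",        2017, 6, 2018),
    list("Railroad",    2017, 6, 2018),
    list("Rough",       2015, 4, c(2017, 2018)),
    list("Scotch",      2008, 6, c(2009, 2010, 2012, 2013, 2014, 2015, 2018)),
    list("Soup 2",      2016, 6, c(2017, 2018)),
    list("Steele",      2017, 6, 2018))
  fires <- data.frame(fire_id = vapply(rows, `[[`, "", 1),
                      year_burned = vapply(rows, `[[`, 0, 2),
                      n_points = vapply(rows, `[[`, 0, 3))
  sy <- lapply(rows, `[[`, 4)
  names(sy) <- fires$fire_id
  study_design(fires, sy, reference_year = 2018L)
}

#' Enlarge a design by recycling its fire templates
#'
#' Builds a design of `n_fires` fires by cycling through the burn-year and
#' survey-year patterns of a base design (staggered fire ages are
#' preserved), with `n_points` points per fire.
#'
#' @param base An `mtocc_design` to take templates from.
#' @param n_fires Number of fires in the new design.
#' @param n_points Points per fire.
#' @return An `mtocc_design`.
#' @export
expand_design <- function(base, n_fires, n_points = 6L) {
  k <- nrow(base$fires)
  pick <- ((seq_len(n_fires) - 1L) %% k) + 1L
  ids <- sprintf("F%03d", seq_len(n_fires))
  fires <- data.frame(fire_id = ids,
                      year_burned = base$fires$year_burned[pick],
                      n_points = as.integer(n_points))
  sy <- base$survey_years[base$fires$fire_id[pick]]
  names(sy) <- ids
  study_design(fires, sy, reference_year = base$reference_year)
}

#' Generator configuration
#'
#' @param design `"table1"` for the 22-fire reference preset, or an
#'   `mtocc_design`.
#' @param true_params Generating `mtocc_params`; defaults to
#'   [reference_params()]. Fire intercepts are drawn from
#'   Normal(`mu_beta0`, `tau_beta0`) unless `beta0` is supplied per fire.
#' @param seed Integer seed for the whole generation.
#' @param elev_range,lat_range Fire-level uniform ranges for elevation (m)
#'   and latitude (decimal degrees), spanning the Sierra Nevada / Southern
#'   Cascades extent; points jitter around their fire's value.
#' @param pine_shape Beta distribution shape parameters for the per-point
#'   pine proportion.
#' @param trees_probs Probabilities of sampling 6, 5 or 4 snags per beetle
#'   survey.
#' @param draw_beta0 If `TRUE` (default) fire intercepts are drawn from the
#'   hyper-distribution; if `FALSE` every fire sits at `mu_beta0`.
#' @return An object of class `mtocc_genconfig`.
#' @export
generator_config <- function(design = "table1",
                             true_params = reference_params(),
                             seed = 1L,
                             elev_range = c(1200, 2400),
                             lat_range = c(35.5, 41.5),
                             pine_shape = c(2, 2),
                             trees_probs = c(`6` = 0.90, `5` = 0.06,
                                             `4` = 0.04),
                             draw_beta0 = TRUE) {
  if (identical(design, "table1")) design <- make_table1_design()
  stopifnot(inherits(design, "mtocc_design"),
            inherits(true_params, "mtocc_params"))
  structure(list(design = design, true_params = true_params,
                 seed = as.integer(seed), elev_range = elev_range,
                 lat_range = lat_range, pine_shape = pine_shape,
                 trees_probs = trees_probs, draw_beta0 = draw_beta0),
            class = "mtocc_genconfig")
}

# categorise a snag count into the field category labels
snag_category <- function(count) {
  SNAG_CATEGORIES[findInterval(count, c(0, 6, 16, 31, 51, 101)) ]
}

#' Simulate a survey dataset from the generative model
#'
#' Draws covariates from the configured covariate model, computes the
#' deterministic beetle sign intensity, simulates the latent occurrence
#' sequence of every point from its first post-fire year (autologistic
#' persistence thereafter), generates interval detection histories for the
#' surveyed point-years (every point gets a 3-interval broadcast survey;
#' alternating points are preceded by a 3-interval passive survey; removal
#' censoring applies after the first detection), and draws final-year
#' beetle activity scores as binomial counts. The linear predictors use the
#' same covariate standardization that [fit_mtocc()] applies, so generation
#' and fitting share one scale.
#'
#' @param config An `mtocc_genconfig` (or arguments for
#'   [generator_config()] via `...`).
#' @param ... Passed to [generator_config()] when `config` is missing.
#' @return An object of class `mtocc_sim`: `$dataset` (validated
#'   `mtocc_data`), `$truth` (true `z` and intensity matrices, per-fire
#'   intercepts, generating parameters), `$config`.
#' @export
simulate_dataset <- function(config = NULL, ...) {
  if (is.null(config)) config <- generator_config(...)
  stopifnot(inherits(config, "mtocc_genconfig"))
  set.seed(config$seed)
  des <- config$design
  pars <- config$true_params
  Tn <- design_T(des)
  year0 <- design_year0(des)
  Jf <- nrow(des$fires)

  # fire intercepts
  if (length(pars$beta0) == Jf && Jf > 1) {
    b0 <- pars$beta0
  } else if (config$draw_beta0) {
    b0 <- stats::rnorm(Jf, pars$mu_beta0, 1 / sqrt(pars$tau_beta0))
  } else {
    b0 <- rep(pars$mu_beta0, Jf)
  }
  names(b0) <- des$fires$fire_id
  pars$beta0 <- b0

  # covariates ---------------------------------------------------------------
  fire_elev <- stats::runif(Jf, config$elev_range[1], config$elev_range[2])
  fire_lat <- stats::runif(Jf, config$lat_range[1], config$lat_range[2])
  cov_rows <- list(); pt_fire <- integer(0)
  for (f in seq_len(Jf)) {
    np <- des$fires$n_points[f]
    fid <- des$fires$fire_id[f]
    for (p in seq_len(np)) {
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        point_id = sprintf("%s_p%02d", gsub("[^A-Za-z0-9]", "", fid), p),
        fire_id = fid,
        elevation_m = fire_elev[f] + stats::rnorm(1, 0, 50),
        latitude = fire_lat[f] + stats::rnorm(1, 0, 0.02),
        pine_prop = stats::rbeta(1, config$pine_shape[1],
                                 config$pine_shape[2]))
      pt_fire <- c(pt_fire, f)
    }
  }
  cv <- do.call(rbind, cov_rows)
  n <- nrow(cv)

  # snag category columns for each fire's survey years: latent size-class
  # counts decay slowly with age, then are binned into field categories
  all_years <- sort(unique(unlist(des$survey_years)))
  snag_cols <- as.vector(outer(SNAG_CLASSES, all_years,
                               function(cl, yr) paste0("snag_", cl, "_", yr)))
  snag_mat <- matrix(NA_character_, n, length(snag_cols),
                     dimnames = list(NULL, snag_cols))
  base_log <- c(small = 3.4, medium = 2.6, large = 1.6)
  decay <- c(small = 0.06, medium = 0.08, large = 0.10)
  pt_noise <- stats::rnorm(n, 0, 0.5)
  for (i in seq_len(n)) {
    f <- pt_fire[i]
    yb <- des$fires$year_burned[f]
    for (yr in des$survey_years[[des$fires$fire_id[f]]]) {
      age <- yr - yb
      for (cl in SNAG_CLASSES) {
        lam <- exp(base_log[cl] - decay[cl] * age + pt_noise[i] +
                     stats::rnorm(1, 0, 0.3))
        snag_mat[i, paste0("snag_", cl, "_", yr)] <-
          snag_category(stats::rpois(1, lam))
      }
    }
  }
  cv <- cbind(cv, as.data.frame(snag_mat))

  num_trees <- as.integer(sample(names(config$trees_probs), n, replace = TRUE,
                                 prob = config$trees_probs))

  # skeleton dataset to obtain the standardized design matrices
  empty_det <- data.frame(fire_id = character(0), point_id = character(0),
                          year = integer(0), interval = integer(0),
                          type = integer(0), detected = integer(0),
                          censored = integer(0))
  empty_bt <- data.frame(point_id = character(0), num_trees = integer(0),
                         activity = integer(0))
  skel <- survey_dataset(des, empty_det, empty_bt, cv)
  skel <- standardize_covariates(skel)
  ctx <- build_model_context(skel)
  intensity <- intensity_matrix(pars, ctx)
  eta <- eta_matrix(pars, ctx, intensity)

  # latent occurrence sequences ----------------------------------------------
  z <- matrix(NA_integer_, n, Tn)
  for (t in seq_len(Tn)) {
    act <- ctx$entry_t <= t
    if (!any(act)) next
    zprev <- if (t == 1L) rep(0L, n) else
      ifelse(ctx$entry_t < t, z[, t - 1L], 0L)  # 0 before entry
    psi <- stats::plogis(eta[, t] + pars$phi * zprev)
    z[act, t] <- stats::rbinom(sum(act), 1, psi[act])
  }

  # interval detections with removal censoring -------------------------------
  p_pass <- detection_prob(pars, 0)
  p_brod <- detection_prob(pars, 1)
  r_fid <- r_pid <- character(0); r_yr <- r_k <- r_ty <- r_y <- r_c <- integer(0)
  cap <- 0L; len <- 0L
  grow <- function(need) {
    if (len + need <= cap) return(invisible())
    cap <<- max(2L * cap, len + need, 256L)
    length(r_fid) <<- cap; length(r_pid) <<- cap; length(r_yr) <<- cap
    length(r_k) <<- cap; length(r_ty) <<- cap; length(r_y) <<- cap
    length(r_c) <<- cap
  }
  for (i in seq_len(n)) {
    f <- pt_fire[i]
    fid <- des$fires$fire_id[f]
    pt_index_in_fire <- sum(pt_fire[seq_len(i)] == f)
    has_passive <- pt_index_in_fire %% 2L == 1L  # alternating points
    types <- if (has_passive) c(0L, 0L, 0L, 1L, 1L, 1L) else c(1L, 1L, 1L)
    for (yr in des$survey_years[[fid]]) {
      t <- yr - year0
      zz <- z[i, t]
      found <- FALSE
      grow(length(types))
      for (k in seq_along(types)) {
        len <- len + 1L
        r_fid[len] <- fid; r_pid[len] <- cv$point_id[i]; r_yr[len] <- yr
        r_k[len] <- k; r_ty[len] <- types[k]
        if (found) {
          r_y[len] <- NA_integer_; r_c[len] <- 1L
        } else {
          p <- if (types[k] == 1L) p_brod else p_pass
          y <- stats::rbinom(1, 1, zz * p)
          r_y[len] <- y; r_c[len] <- 0L
          if (y == 1L) found <- TRUE
        }
      }
    }
  }
  keep <- seq_len(len)
  detections <- data.frame(fire_id = r_fid[keep], point_id = r_pid[keep],
                           year = r_yr[keep], interval = r_k[keep],
                           type = r_ty[keep], detected = r_y[keep],
                           censored = r_c[keep])

  # final-year beetle surveys -------------------------------------------------
  beetle <- data.frame(point_id = cv$point_id, num_trees = num_trees,
                       activity = stats::rbinom(n, num_trees * 8L,
                                                intensity[, Tn]))

  dataset <- survey_dataset(des, detections, beetle, cv)
  dataset$scaling <- skel$scaling
  dataset$std <- skel$std
  structure(list(dataset = dataset,
                 truth = list(z = z, intensity = intensity, beta0 = b0,
                              params = pars),
                 config = config),
            class = "mtocc_sim")
}

#' @export
print.mtocc_sim <- function(x, ...) {
  cat("Simulated survey dataset (seed", x$config$seed, ")\n")
  print(x$dataset)
  invisible(x)
}

#' Write the latent truth record of a simulation
#'
#' One row per in-window point-year with the true occurrence state and
#' deterministic beetle intensity; intended for test harnesses and recovery
#' scoring, not for fitting.
#'
#' @param sim An `mtocc_sim` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(sim, path) {
  cv <- sim$dataset$covariates
  Tn <- ncol(sim$truth$z)
  year0 <- design_year0(sim$dataset$design)
  rows <- which(!is.na(sim$truth$z), arr.ind = TRUE)
  df <- data.frame(point_id = cv$point_id[rows[, 1]],
                   year = year0 + rows[, 2],
                   z = sim$truth$z[rows],
                   intensity = sim$truth$intensity[rows])
  utils::write.csv(df[order(df$point_id, df$year), ], path, row.names = FALSE)
  invisible(path)
}

# Minimal beetle-submodel design: each point is its own single-point fire
# surveyed only in the reference year, so per-point fire ages span 1..10.
# Used for submodel-only recovery experiments.

#' Simulate a beetle-submodel-only dataset
#'
#' Generates `n_points` independent points with pine proportion uniform on
#' (0, 1) and fire age uniform on 1..10 years (each point is a single-point
#' fire, so ages vary per point), then draws final-year activity scores
#' from the binomial observation model at the given parameters. No
#' woodpecker detection data are generated, so fitting this dataset
#' informs only the gamma block.
#'
#' @param n_points Number of beetle survey points.
#' @param params Generating `mtocc_params` (gamma block used).
#' @param seed Integer seed.
#' @param num_trees Snags sampled per point (default 6, i.e. 48 trials).
#' @return An `mtocc_sim` object (with an all-`NA` occurrence truth).
#' @export
simulate_beetle_points <- function(n_points, params = reference_params(),
                                   seed = 1L, num_trees = 6L) {
  set.seed(seed)
  ref <- 2018L
  ages <- sample(1:10, n_points, replace = TRUE)
  ids <- sprintf("B%04d", seq_len(n_points))
  fires <- data.frame(fire_id = ids, year_burned = ref - ages, n_points = 1L)
  sy <- rep(list(ref), n_points)
  names(sy) <- ids
  des <- study_design(fires, sy, reference_year = ref)
  cv <- data.frame(point_id = paste0(ids, "_p01"), fire_id = ids,
                   elevation_m = stats::runif(n_points, 1200, 2400),
                   latitude = stats::runif(n_points, 35.5, 41.5),
                   pine_prop = stats::runif(n_points))
  empty_det <- data.frame(fire_id = character(0), point_id = character(0),
                          year = integer(0), interval = integer(0),
                          type = integer(0), detected = integer(0),
                          censored = integer(0))
  skel <- survey_dataset(des, empty_det,
                         data.frame(point_id = character(0),
                                    num_trees = integer(0),
                                    activity = integer(0)), cv)
  skel <- standardize_covariates(skel)
  ctx <- build_model_context(skel)
  pars <- params
  pars$beta0 <- rep(pars$mu_beta0, n_points)
  intensity <- intensity_matrix(pars, ctx)
  p <- intensity[, ctx$Tn]
  beetle <- data.frame(point_id = cv$point_id,
                       num_trees = as.integer(num_trees),
                       activity = stats::rbinom(n_points, num_trees * 8L, p))
  dataset <- survey_dataset(des, empty_det, beetle, cv)
  dataset$scaling <- skel$scaling
  dataset$std <- skel$std
  structure(list(dataset = dataset,
                 truth = list(z = matrix(NA_integer_, n_points, ctx$Tn),
                              intensity = intensity, beta0 = pars$beta0,
                              params = pars),
                 config = list(seed = seed, n_points = n_points)),
            class = "mtocc_sim")
}
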