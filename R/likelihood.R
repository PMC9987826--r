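# Exact joint log-likelihood. The latent occurrence sequence z at each point
# is marginalised by a two-state forward recursion (no Monte Carlo, no data
# augmentation), so the likelihood is a deterministic function of the
# parameters. A brute-force enumeration over all 2^T sequences is provided
# as an independent oracle.

# Build the numerical context the likelihood works on: standardized design
# matrices plus per-point-year detection interval counts. Emission
# probabilities depend on the detection block only, occupancy logits on the
# beta/gamma blocks, so both can be recomputed independently.
build_model_context <- function(dataset) {
  if (is.null(dataset$std)) dataset <- standardize_covariates(dataset)
  des <- dataset$design
  std <- dataset$std
  cv <- dataset$covariates
  n <- nrow(cv)
  Tn <- design_T(des)
  year0 <- design_year0(des)

  det_b <- nondet_b <- det_p <- nondet_p <- matrix(0L, n, Tn)
  surveyed <- matrix(FALSE, n, Tn)
  d <- dataset$detections
  if (nrow(d)) {
    i <- match(d$point_id, cv$point_id)
    t <- d$year - year0
    obs <- d$censored == 0
    for (r in which(obs)) {
      ii <- i[r]; tt <- t[r]
      surveyed[ii, tt] <- TRUE
      if (d$type[r] == 1) {
        if (d$detected[r] == 1) det_b[ii, tt] <- det_b[ii, tt] + 1L
        else nondet_b[ii, tt] <- nondet_b[ii, tt] + 1L
      } else {
        if (d$detected[r] == 1) det_p[ii, tt] <- det_p[ii, tt] + 1L
        else nondet_p[ii, tt] <- nondet_p[ii, tt] + 1L
      }
    }
    # a point-year whose every interval is censored still counts as surveyed
    for (r in which(!obs)) surveyed[i[r], t[r]] <- TRUE
  }
  any_det <- (det_b + det_p) > 0
  has_det_data <- any(surveyed)

  bt <- dataset$beetle
  beetle_i <- match(bt$point_id, cv$point_id)

  list(n = n, J = nrow(des$fires), Tn = Tn, year0 = year0,
       fire = std$fire, fire_ids = des$fires$fire_id,
       entry_t = std$entry_t,
       elev = std$elev, lat = std$lat, pine = std$pine,
       snag = std$snag, age = std$age,
       det_b = det_b, nondet_b = nondet_b, det_p = det_p,
       nondet_p = nondet_p, any_det = any_det, surveyed = surveyed,
       has_det_data = has_det_data,
       beetle_i = beetle_i, beetle_trials = bt$num_trees * 8L,
       beetle_activity = bt$activity,
       scaling = dataset$scaling)
}

# intensity matrix (n x Tn) from the gamma block; NA outside the window
intensity_matrix <- function(params, ctx) {
  stats::plogis(params$gamma0 + params$gamma_age * ctx$age +
                  params$gamma_pine * ctx$pine +
                  params$gamma_ageXpine * ctx$age * ctx$pine)
}

# occupancy logit matrix without the autologistic term
eta_matrix <- function(params, ctx, intensity) {
  b0 <- params$beta0
  if (length(b0) == 1L) b0 <- rep(b0, ctx$J)
  b0[ctx$fire] + params$beta_elev * ctx$elev + params$beta_lat * ctx$lat +
    params$beta_snag * ctx$snag + params$beta_beetle * intensity +
    params$beta_ageXbeetle * ctx$age * intensity
}

# log emission matrices given the detection block: e1 = log P(data_t | z=1),
# e0 = log P(data_t | z=0); zero where the point-year has no usable data.
emission_matrices <- function(params, ctx) {
  p_b <- stats::plogis(params$alpha0 + params$alpha_type)
  p_p <- stats::plogis(params$alpha0)
  xlogy <- function(k, logp) ifelse(k == 0L, 0, k * logp)  # 0 * -Inf -> 0
  le1 <- xlogy(ctx$det_b, log(p_b)) + xlogy(ctx$nondet_b, log1p(-p_b)) +
    xlogy(ctx$det_p, log(p_p)) + xlogy(ctx$nondet_p, log1p(-p_p))
  le0 <- ifelse(ctx$any_det, -Inf, 0)
  list(le1 = le1, le0 = le0)
}

# Vectorised forward recursion across all points; returns the per-point
# log marginal likelihood of the detection histories.
site_loglik_vec <- function(params, ctx, em = NULL, intensity = NULL) {
  if (!ctx$has_det_data) return(numeric(ctx$n))
  if (is.null(intensity)) intensity <- intensity_matrix(params, ctx)
  if (is.null(em)) em <- emission_matrices(params, ctx)
  eta <- eta_matrix(params, ctx, intensity)
  n <- ctx$n
  a0 <- rep(1, n); a1 <- rep(0, n)   # P(z_{t-1} = 0/1, data so far)
  ll <- numeric(n)
  for (t in seq_len(ctx$Tn)) {
    keep <- ctx$entry_t > t  # series not started yet: carry state unchanged
    psi0 <- stats::plogis(eta[, t])               # z_prev = 0 (also year 1)
    psi1 <- stats::plogis(eta[, t] + params$phi)  # z_prev = 1
    e1 <- exp(em$le1[, t]); e0 <- exp(em$le0[, t])
    b1 <- (a0 * psi0 + a1 * psi1) * e1
    b0 <- (a0 * (1 - psi0) + a1 * (1 - psi1)) * e0
    s <- b0 + b1
    s[keep] <- 1; b0[keep] <- a0[keep]; b1[keep] <- a1[keep]
    bad <- s <= 0 & !keep
    if (any(bad)) { ll[bad] <- -Inf; s[bad] <- 1; b0[bad] <- 1; b1[bad] <- 0 }
    ll <- ll + log(s)
    a0 <- b0 / s; a1 <- b1 / s
  }
  ll
}

# per-point beetle log-likelihood vector at the reference year
beetle_loglik_vec <- function(params, ctx, intensity = NULL) {
  if (!length(ctx$beetle_i)) return(numeric(0))
  if (is.null(intensity)) intensity <- intensity_matrix(params, ctx)
  p <- intensity[ctx$beetle_i, ctx$Tn]
  stats::dbinom(ctx$beetle_activity, ctx$beetle_trials, p, log = TRUE)
}

#' Binomial log-likelihood of a beetle survey
#'
#' Summed beetle sign over the sampled snags at a point is binomial with
#' `num_trees * 8` trials (8 is the maximum activity score per tree) and
#' success probability equal to the latent sign intensity at the reference
#' year.
#'
#' @param params An `mtocc_params` object (gamma block used).
#' @param activity Observed summed activity score(s).
#' @param num_trees Number of snags sampled (1-6).
#' @param age,pine Covariates at which the intensity is evaluated (age on
#'   the fitted scale).
#' @return Log-likelihood, vectorized over surveys.
#' @export
beetle_loglik <- function(params, activity, num_trees, age, pine) {
  if (any(activity < 0 | activity > num_trees * 8))
    stop("activity must lie in [0, num_trees * 8]")
  p <- beetle_intensity(params, age, pine)
  stats::dbinom(activity, num_trees * 8, p, log = TRUE)
}

#' Detection-history emission probability for one point-year
#'
#' Likelihood contribution of the (non-censored) survey intervals of a
#' point-year conditional on the true occurrence state: if `z = 0` the
#' probability is 1 when no interval recorded a detection and 0 otherwise;
#' if `z = 1` it is the product of Bernoulli interval probabilities. A
#' point-year with no records contributes 1.
#'
#' @param params An `mtocc_params` object (detection block used).
#' @param records Data frame with columns `type`, `detected`, `censored`
#'   for one point-year.
#' @param z True occurrence state, 0 or 1.
#' @return The emission probability.
#' @export
interval_emission <- function(params, records, z) {
  stopifnot(z %in% c(0, 1))
  if (is.null(records) || nrow(records) == 0L) return(1)
  records <- records[records$censored == 0, , drop = FALSE]
  if (nrow(records) == 0L) return(1)
  if (z == 0) return(as.numeric(all(records$detected == 0)))
  p <- detection_prob(params, records$type)
  prod(ifelse(records$detected == 1, p, 1 - p))
}

# records and covariate slices for one point, used by the reference and
# enumeration implementations
point_slice <- function(dataset, ctx, point) {
  i <- match(point, dataset$covariates$point_id)
  if (is.na(i)) stop("unknown point: ", point)
  d <- dataset$detections
  recs <- lapply(seq_len(ctx$Tn), function(t) {
    yr <- ctx$year0 + t
    d[d$point_id == point & d$year == yr, , drop = FALSE]
  })
  list(i = i, records = recs)
}

#' Marginal log-likelihood of one point's detection history
#'
#' Integrates the latent occurrence sequence out of the detection-history
#' likelihood for a single survey point. `method = "forward"` uses the
#' two-state forward recursion over the point's post-fire years;
#' `method = "enumerate"` sums over all `2^T` occurrence sequences
#' explicitly and serves as an independent oracle. The occupancy
#' probability in the first post-fire year has no autologistic term; later
#' years add `phi * z_prev`.
#'
#' @param params An `mtocc_params` object.
#' @param dataset An `mtocc_data` object (standardized on the fly if
#'   needed).
#' @param point A point id present in the dataset.
#' @param method `"forward"` (default) or `"enumerate"`.
#' @return The log marginal likelihood of the point's detection data.
#' @export
site_marginal_loglik <- function(params, dataset, point,
                                 method = c("forward", "enumerate")) {
  method <- match.arg(method)
  if (is.null(dataset$std)) dataset <- standardize_covariates(dataset)
  ctx <- build_model_context(dataset)
  ps <- point_slice(dataset, ctx, point)
  i <- ps$i
  intensity <- intensity_matrix(params, ctx)
  eta <- eta_matrix(params, ctx, intensity)
  tf <- ctx$entry_t[i]
  years <- tf:ctx$Tn
  psi_given <- function(t, z_prev) {
    stats::plogis(eta[i, t] + if (t > tf) params$phi * z_prev else 0)
  }
  em <- function(t, z) interval_emission(params, ps$records[[t]], z)

  if (method == "forward") {
    a <- c(`0` = 1, `1` = 0)  # state probs entering the first year
    ll <- 0
    for (t in years) {
      psi0 <- psi_given(t, 0); psi1 <- psi_given(t, 1)
      b1 <- (a[1] * psi0 + a[2] * psi1) * em(t, 1)
      b0 <- (a[1] * (1 - psi0) + a[2] * (1 - psi1)) * em(t, 0)
      s <- b0 + b1
      if (s <= 0) return(-Inf)
      ll <- ll + log(s)
      a <- c(b0, b1) / s
    }
    return(unname(ll))
  }

  # enumeration over all 2^T sequences
  Tlen <- length(years)
  total <- 0
  for (code in 0:(2^Tlen - 1)) {
    zseq <- as.integer(intToBits(code))[seq_len(Tlen)]
    pr <- 1
    for (k in seq_len(Tlen)) {
      t <- years[k]
      psi <- psi_given(t, if (k > 1) zseq[k - 1] else 0)
      pr <- pr * (if (zseq[k] == 1) psi else 1 - psi) * em(t, zseq[k])
    }
    total <- total + pr
  }
  log(total)
}

#' Joint log-likelihood of a survey dataset
#'
#' Sum over points of the marginal detection-history log-likelihood plus
#' the binomial beetle-survey log-likelihood. The latent beetle intensity
#' is recomputed from the current gamma block for both components, so a
#' perturbation of gamma moves both.
#'
#' @param params An `mtocc_params` object.
#' @param dataset An `mtocc_data` object.
#' @return The joint log-likelihood (a scalar).
#' @export
joint_loglik <- function(params, dataset) {
  if (is.null(dataset$std)) dataset <- standardize_covariates(dataset)
  ctx <- build_model_context(dataset)
  params <- expand_beta0(params, ctx)
  intensity <- intensity_matrix(params, ctx)
  sum(site_loglik_vec(params, ctx, intensity = intensity)) +
    sum(beetle_loglik_vec(params, ctx, intensity = intensity))
}

# align beta0 with the design's fire order (recycle a scalar, match names)
expand_beta0 <- function(params, ctx) {
  b0 <- params$beta0
  if (length(b0) == 1L) b0 <- rep(b0, ctx$J)
  else if (!is.null(names(b0)) && all(ctx$fire_ids %in% names(b0)))
    b0 <- b0[ctx$fire_ids]
  else if (length(b0) != ctx$J)
    stop("beta0 must be scalar or one value per fire")
  params$beta0 <- as.numeric(b0)
  params
}

#' Joint log prior density
#'
#' Vague priors: every fixed effect (detection, occupancy slopes, the
#' autologistic term, the gamma block) and the hyper-mean `mu_beta0` get a
#' Normal(0, precision 0.1) prior; fire intercepts are
#' Normal(`mu_beta0`, precision `tau_beta0`); the hyper-precision gets a
#' Gamma(0.1, 0.1) prior. Returns `-Inf` when `tau_beta0 <= 0`.
#'
#' @param params An `mtocc_params` object (or a list with the same fields;
#'   `tau_beta0 <= 0` is tolerated and yields `-Inf`).
#' @return The log prior density.
#' @export
log_prior <- function(params) {
  if (params$tau_beta0 <= 0) return(-Inf)
  sd0 <- sqrt(1 / 0.1)
  fixed <- c(params$alpha0, params$alpha_type, params$mu_beta0,
             params$beta_elev, params$beta_lat, params$beta_snag,
             params$beta_beetle, params$beta_ageXbeetle, params$phi,
             params$gamma0, params$gamma_age, params$gamma_pine,
             params$gamma_ageXpine)
  sum(stats::dnorm(fixed, 0, sd0, log = TRUE)) +
    sum(stats::dnorm(params$beta0, params$mu_beta0,
                     1 / sqrt(params$tau_beta0), log = TRUE)) +
    stats::dgamma(params$tau_beta0, shape = 0.1, rate = 0.1, log = TRUE)
}

# full log posterior kernel used by the sampler
log_posterior <- function(params, ctx) {
  lp <- log_prior(params)
  if (!is.finite(lp)) return(list(lp = -Inf, site = NULL, beetle = NULL))
  intensity <- intensity_matrix(params, ctx)
  site <- site_loglik_vec(params, ctx, intensity = intensity)
  beetle <- beetle_loglik_vec(params, ctx, intensity = intensity)
  list(lp = lp + sum(site) + sum(beetle), site = site, beetle = beetle)
}
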