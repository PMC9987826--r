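# Posterior sampling: adaptive random-walk Metropolis within Gibbs over the
# marginalised joint posterior. Scalar fixed effects get univariate
# random-walk updates; the fire intercepts are proposed in parallel and
# accepted fire-by-fire (the likelihood factorises over fires given the
# rest); the intercept hyperparameters have conjugate Gibbs updates.
# Proposal scales adapt toward a target acceptance rate during burn-in only,
# so the post-burn-in kernel is fixed and preserves detailed balance.

#' MCMC configuration
#'
#' @param n_chains Number of chains.
#' @param n_iter Post-burn-in iterations per chain; must be divisible by
#'   `thin`.
#' @param n_burnin Burn-in iterations (discarded; adaptation happens here).
#' @param thin Thinning interval; retained draws per chain =
#'   `n_iter / thin`.
#' @param seed Integer seed; all randomness in a run derives from it.
#' @param adapt_window Iterations per adaptation batch during burn-in.
#' @param target_accept Target acceptance rate for the univariate
#'   random-walk updates.
#' @param init_spread Spread multiplier for over-dispersed chain starts
#'   (0 starts every chain at the prior mean).
#' @return An object of class `mtocc_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 50000L, n_burnin = 50000L,
                        thin = 50L, seed = 1L, adapt_window = 50L,
                        target_accept = 0.44, init_spread = 0.25) {
  stopifnot(n_chains >= 1, n_iter >= 0, n_burnin >= 0, thin >= 1,
            adapt_window >= 1, target_accept > 0, target_accept < 1,
            init_spread >= 0)
  if (n_iter %% thin != 0)
    stop("thin (", thin, ") must divide n_iter (", n_iter, ") evenly")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_window = as.integer(adapt_window),
                 target_accept = target_accept, init_spread = init_spread),
            class = "mtocc_mcmc_config")
}

#' Retained posterior sample size implied by a configuration
#'
#' @param config An `mtocc_mcmc_config`.
#' @return `n_chains * n_iter / thin`.
#' @export
n_retained <- function(config) {
  config$n_chains * (config$n_iter %/% config$thin)
}

# scalar parameters updated by univariate random-walk Metropolis
RW_PARAMS <- c("alpha0", "alpha_type", "beta_elev", "beta_lat", "beta_snag",
               "beta_beetle", "beta_ageXbeetle", "phi",
               "gamma0", "gamma_age", "gamma_pine", "gamma_ageXpine")

#' Over-dispersed chain starting values
#'
#' Draws each chain's initial parameter vector from the prior with its
#' standard deviation multiplied by `init_spread`, deterministically given
#' the seed and chain index. `init_spread = 0` starts every chain at the
#' prior mean (zero for the fixed effects).
#'
#' @param config An `mtocc_mcmc_config`.
#' @param dataset An `mtocc_data` object (supplies the fire layout).
#' @return A list of `mtocc_params`, one per chain.
#' @export
initialize_chains <- function(config, dataset) {
  J <- nrow(dataset$design$fires)
  fire_ids <- dataset$design$fires$fire_id
  sd0 <- sqrt(1 / 0.1) * config$init_spread
  lapply(seq_len(config$n_chains), function(ch) {
    set.seed(chain_seed(config$seed, ch))
    draw <- function() stats::rnorm(1, 0, sd0)
    mu <- draw()
    b0 <- mu + stats::rnorm(J, 0, config$init_spread)
    names(b0) <- fire_ids
    model_params(alpha0 = draw(), alpha_type = draw(),
                 beta0 = b0, mu_beta0 = mu, tau_beta0 = 1,
                 beta_elev = draw(), beta_lat = draw(), beta_snag = draw(),
                 beta_beetle = draw(), beta_ageXbeetle = draw(), phi = draw(),
                 gamma0 = draw(), gamma_age = draw(), gamma_pine = draw(),
                 gamma_ageXpine = draw())
  })
}

chain_seed <- function(seed, chain) {
  (abs(seed) %% 1000000L) * 1000L + 7L * chain
}

#' Sample the joint posterior
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler on the marginalised
#' posterior of all model parameters given a survey dataset. Update blocks
#' per iteration: each scalar fixed effect (detection pair, occupancy
#' slopes, `phi`, gamma block) by univariate random walk; all fire
#' intercepts in parallel with fire-wise acceptance; `mu_beta0` and
#' `tau_beta0` by their conjugate normal/gamma conditionals. Parameters
#' named in `fixed` are clamped at the supplied values and never updated
#' (use `"beta0"` to clamp the whole intercept block) — useful for fitting
#' one submodel in isolation.
#'
#' @param dataset An `mtocc_data` object.
#' @param config An `mtocc_mcmc_config`.
#' @param fixed Optional named numeric list/vector of parameters to hold
#'   fixed; `beta0` may be a scalar or per-fire vector.
#' @return An object of class `mtocc_draws`: draws array
#'   `(chain, iteration, parameter)`, config echo, per-block acceptance
#'   rates and a dataset checksum.
#' @export
sample_posterior <- function(dataset, config = mcmc_config(), fixed = NULL) {
  stopifnot(inherits(config, "mtocc_mcmc_config"))
  if (is.null(dataset$std)) dataset <- standardize_covariates(dataset)
  ctx <- build_model_context(dataset)
  inits <- initialize_chains(config, dataset)
  fixed_names <- names(fixed)
  keep_per_chain <- config$n_iter %/% config$thin
  par_names <- names(pack_params(expand_beta0(inits[[1]], ctx), ctx$fire_ids))
  draws <- array(NA_real_,
                 dim = c(config$n_chains, keep_per_chain, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  acc <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seed(config$seed, ch) + 500000L)
    st <- expand_beta0(inits[[ch]], ctx)
    # clamp fixed parameters
    if (!is.null(fixed)) {
      for (nm in fixed_names) {
        if (nm == "beta0") {
          b0 <- fixed[["beta0"]]
          st$beta0 <- if (length(b0) == 1L) rep(b0, ctx$J) else as.numeric(b0)
        } else st[[nm]] <- fixed[[nm]]
      }
    }
    res <- run_chain(st, ctx, config, fixed_names, draws_slots = keep_per_chain)
    draws[ch, , ] <- res$draws
    acc[[ch]] <- res$accept
  }

  structure(list(draws = draws, parameters = par_names, config = config,
                 accept = acc, fixed = fixed,
                 checksum = dataset_checksum(dataset)),
            class = "mtocc_draws")
}

run_chain <- function(st, ctx, config, fixed_names, draws_slots) {
  update_rw <- setdiff(RW_PARAMS, fixed_names)
  update_b0 <- !("beta0" %in% fixed_names)
  update_mu <- !("mu_beta0" %in% fixed_names)
  update_tau <- !("tau_beta0" %in% fixed_names)

  lpost <- log_posterior(st, ctx)
  if (!is.finite(lpost$lp))
    stop("log-posterior is not finite at the initial values; ",
         "re-seed or reduce init_spread")
  cur_lp <- lpost$lp
  cur_site <- lpost$site

  ls_scale <- c(stats::setNames(rep(0.1, length(update_rw)), update_rw),
                beta0 = 0.2)
  n_acc <- n_try <- ls_scale * 0
  batch_acc <- batch_try <- ls_scale * 0
  n_total <- config$n_burnin + config$n_iter
  out <- matrix(NA_real_, draws_slots,
                length(pack_params(st, ctx$fire_ids)))
  slot <- 0L

  for (iter in seq_len(n_total)) {
    adapting <- iter <= config$n_burnin

    for (nm in update_rw) {
      prop <- st
      prop[[nm]] <- st[[nm]] + stats::rnorm(1, 0, ls_scale[nm])
      lp_prop <- log_posterior(prop, ctx)
      batch_try[nm] <- batch_try[nm] + 1; n_try[nm] <- n_try[nm] + 1
      if (is.finite(lp_prop$lp) &&
          log(stats::runif(1)) < lp_prop$lp - cur_lp) {
        st <- prop; cur_lp <- lp_prop$lp; cur_site <- lp_prop$site
        batch_acc[nm] <- batch_acc[nm] + 1; n_acc[nm] <- n_acc[nm] + 1
      }
    }

    if (update_b0) {
      prop <- st
      prop$beta0 <- st$beta0 + stats::rnorm(ctx$J, 0, ls_scale["beta0"])
      intensity <- intensity_matrix(st, ctx)  # gamma unchanged in this block
      site_prop <- site_loglik_vec(prop, ctx, intensity = intensity)
      if (is.null(cur_site)) cur_site <- site_loglik_vec(st, ctx,
                                                         intensity = intensity)
      sd_b0 <- 1 / sqrt(st$tau_beta0)
      dsite <- vapply(seq_len(ctx$J), function(j) {
        pts <- ctx$fire == j
        sum(site_prop[pts]) - sum(cur_site[pts])
      }, numeric(1))
      dprior <- stats::dnorm(prop$beta0, st$mu_beta0, sd_b0, log = TRUE) -
        stats::dnorm(st$beta0, st$mu_beta0, sd_b0, log = TRUE)
      take <- log(stats::runif(ctx$J)) < dsite + dprior
      batch_try["beta0"] <- batch_try["beta0"] + 1
      n_try["beta0"] <- n_try["beta0"] + 1
      if (any(take)) {
        st$beta0[take] <- prop$beta0[take]
        frac <- mean(take)
        batch_acc["beta0"] <- batch_acc["beta0"] + frac
        n_acc["beta0"] <- n_acc["beta0"] + frac
        lpost <- log_posterior(st, ctx)
        cur_lp <- lpost$lp; cur_site <- lpost$site
      } else {
        batch_acc["beta0"] <- batch_acc["beta0"] + 0
      }
    }

    # conjugate Gibbs draws for the intercept hyperparameters
    if (update_mu) {
      prec <- 0.1 + ctx$J * st$tau_beta0
      mean_mu <- ctx$J * st$tau_beta0 * mean(st$beta0) / prec
      st$mu_beta0 <- stats::rnorm(1, mean_mu, 1 / sqrt(prec))
    }
    if (update_tau) {
      st$tau_beta0 <- stats::rgamma(1, shape = 0.1 + ctx$J / 2,
                                    rate = 0.1 +
                                      sum((st$beta0 - st$mu_beta0)^2) / 2)
    }
    if (update_mu || update_tau) {
      lpost <- log_posterior(st, ctx)
      cur_lp <- lpost$lp; cur_site <- lpost$site
    }

    # batch adaptation of proposal scales, burn-in only
    if (adapting && iter %% config$adapt_window == 0L) {
      rate <- ifelse(batch_try > 0, batch_acc / batch_try, NA)
      step <- min(0.25, 2 / sqrt(iter / config$adapt_window))
      for (nm in names(ls_scale)) {
        if (!is.na(rate[nm]))
          ls_scale[nm] <- ls_scale[nm] *
            exp(step * (rate[nm] - config$target_accept))
      }
      batch_acc[] <- 0; batch_try[] <- 0
    }

    if (!adapting) {
      k <- iter - config$n_burnin
      if (k %% config$thin == 0L) {
        slot <- slot + 1L
        out[slot, ] <- pack_params(st, ctx$fire_ids)
      }
    }
  }
  list(draws = out, accept = ifelse(n_try > 0, n_acc / n_try, NA),
       scales = ls_scale)
}

dataset_checksum <- function(dataset) {
  cv <- dataset$covariates
  sprintf("n%01d_f%01d_det%d_act%d_e%.3f",
          nrow(cv), nrow(dataset$design$fires),
          sum(dataset$detections$detected, na.rm = TRUE),
          sum(dataset$beetle$activity),
          sum(cv$elevation_m) %% 1000)
}

#' @export
print.mtocc_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("Posterior draws:", d[1], "chain(s) x", d[2], "retained iterations x",
      d[3], "parameters\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance ratio per parameter,
#' `sqrt(((n - 1) / n * W + B / n) / W)` with `B` the between-chain and `W`
#' the within-chain variance. Values near 1 indicate convergence; the
#' conventional pass threshold used in this package is 1.1. Chains that are
#' exact copies give a value at or below 1; parameters held fixed (zero
#' variance everywhere) report 1.
#'
#' @param draws An `mtocc_draws` object, or a matrix with one column per
#'   chain for a single parameter.
#' @return Named vector of statistics (or a scalar for a matrix input).
#' @export
gelman_rubin <- function(draws) {
  psrf1 <- function(mat) {  # iterations x chains
    m <- ncol(mat); n <- nrow(mat)
    if (m < 2L) stop("gelman_rubin needs at least 2 chains")
    if (n < 2L) stop("gelman_rubin needs at least 2 retained draws per chain")
    W <- mean(apply(mat, 2, stats::var))
    B <- n * stats::var(colMeans(mat))
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  if (is.matrix(draws)) return(psrf1(draws))
  stopifnot(inherits(draws, "mtocc_draws"))
  a <- draws$draws
  out <- vapply(seq_len(dim(a)[3]),
                function(k) psrf1(t(a[, , k, drop = TRUE])), numeric(1))
  names(out) <- draws$parameters
  out
}

#' Write posterior draws as a tidy delimited table
#'
#' One row per (chain, iteration, parameter) triple, plus a sidecar
#' metadata file echoing the configuration, seed, dataset checksum and
#' per-block acceptance rates.
#'
#' @param draws An `mtocc_draws` object.
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".meta")`.
#' @return Invisibly, `path`.
#' @export
write_draws <- function(draws, path) {
  a <- draws$draws
  d <- dim(a)
  df <- data.frame(chain = rep(seq_len(d[1]), times = d[2] * d[3]),
                   iteration = rep(rep(seq_len(d[2]), each = d[1]),
                                   times = d[3]),
                   parameter = rep(draws$parameters, each = d[1] * d[2]),
                   value = as.vector(a))
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- draws$config
  meta <- c(sprintf("n_chains=%d", cfg$n_chains),
            sprintf("n_iter=%d", cfg$n_iter),
            sprintf("n_burnin=%d", cfg$n_burnin),
            sprintf("thin=%d", cfg$thin),
            sprintf("seed=%d", cfg$seed),
            sprintf("checksum=%s", draws$checksum),
            vapply(seq_along(draws$accept), function(ch)
              sprintf("accept_chain%d=%s", ch,
                      paste(sprintf("%s:%.3f", names(draws$accept[[ch]]),
                                    draws$accept[[ch]]), collapse = ";")),
              ""))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
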