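# Posterior summaries and prediction curves.

#' Posterior summary table
#'
#' Per-parameter posterior mean and equal-tailed 95% credible bounds from
#' the pooled post-burn-in draws, the Gelman-Rubin statistic (when at least
#' two chains are available), and an evidence flag (both credible bounds on
#' the same side of zero).
#'
#' @param draws An `mtocc_draws` object.
#' @param prob Credible-interval mass (default 0.95).
#' @return A data frame of class `mtocc_summary` with columns `parameter`,
#'   `mean`, `lower`, `upper`, `rhat`, `evidence`.
#' @export
summarize_posterior <- function(draws, prob = 0.95) {
  stopifnot(inherits(draws, "mtocc_draws"))
  a <- draws$draws
  d <- dim(a)
  if (d[2] < 1L) stop("no retained draws to summarize")
  flat <- matrix(a, d[1] * d[2], d[3])
  alpha <- (1 - prob) / 2
  qs <- apply(flat, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  rhat <- if (d[1] >= 2L && d[2] >= 2L) gelman_rubin(draws) else
    rep(NA_real_, d[3])
  out <- data.frame(parameter = draws$parameters,
                    mean = colMeans(flat),
                    lower = qs[1, ], upper = qs[2, ],
                    rhat = unname(rhat))
  out$evidence <- out$lower * out$upper > 0
  class(out) <- c("mtocc_summary", "data.frame")
  out
}

# pooled draw matrix with parameter names as columns
pooled_draws <- function(draws) {
  a <- draws$draws
  d <- dim(a)
  flat <- matrix(a, d[1] * d[2], d[3])
  colnames(flat) <- draws$parameters
  flat
}

# map a natural-scale fire age to the fitted (standardized) scale
scale_age <- function(age, scaling) {
  if (is.null(scaling)) return(age)
  zscore(age, scaling$age["center"], scaling$age["spread"])
}

#' Occupancy-versus-beetle-intensity prediction curves
#'
#' Population-level occupancy probability over a grid of beetle sign
#' intensity, one curve per fire age. Curves use the fire-intercept
#' hyper-mean `mu_beta0` and hold elevation, latitude and snag density at
#' their (standardized) means unless other conditioning values are given.
#' With `ribbon = "partial"` only the beetle slope and the age-by-beetle
#' interaction vary across posterior draws (all other parameters at their
#' posterior means), isolating the uncertainty of the trophic link; with
#' `"full"` every parameter varies.
#'
#' @param draws An `mtocc_draws` object.
#' @param age_values Fire ages in natural years since fire.
#' @param intensity_grid Intensity values in (0, 1).
#' @param conditioning Named list of standardized conditioning values
#'   (`elev`, `lat`, `snag`; default 0 = covariate means).
#' @param ribbon `"partial"` or `"full"`.
#' @param scaling Scaling constants from a standardized dataset or fit;
#'   `NULL` treats `age_values` as already on the fitted scale.
#' @param prob Ribbon mass.
#' @return A data frame of class `mtocc_curve`: `age`, `x` (intensity),
#'   `mean`, `lower`, `upper`.
#' @export
predict_occupancy_curve <- function(draws, age_values = c(1, 3, 5, 7, 10),
                                    intensity_grid = seq(0.01, 0.99,
                                                         length.out = 50),
                                    conditioning = list(elev = 0, lat = 0,
                                                        snag = 0),
                                    ribbon = c("partial", "full"),
                                    scaling = NULL, prob = 0.95) {
  ribbon <- match.arg(ribbon)
  flat <- pooled_draws(draws)
  pm <- colMeans(flat)
  if (ribbon == "partial") {
    kept <- flat[, c("beta_beetle", "beta_ageXbeetle"), drop = FALSE]
    flat <- matrix(pm, nrow(flat), length(pm), byrow = TRUE,
                   dimnames = list(NULL, names(pm)))
    flat[, c("beta_beetle", "beta_ageXbeetle")] <- kept
  }
  alpha <- (1 - prob) / 2
  out <- list()
  for (age in age_values) {
    age_s <- scale_age(age, scaling)
    for (I in intensity_grid) {
      eta <- flat[, "mu_beta0"] +
        flat[, "beta_elev"] * conditioning$elev +
        flat[, "beta_lat"] * conditioning$lat +
        flat[, "beta_snag"] * conditioning$snag +
        flat[, "beta_beetle"] * I +
        flat[, "beta_ageXbeetle"] * age_s * I
      psi <- stats::plogis(eta)
      out[[length(out) + 1L]] <- data.frame(
        age = age, x = I, mean = mean(psi),
        lower = stats::quantile(psi, alpha, names = FALSE),
        upper = stats::quantile(psi, 1 - alpha, names = FALSE))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "response") <- "occupancy"
  class(res) <- c("mtocc_curve", "data.frame")
  res
}

#' Beetle-intensity-versus-age prediction curves
#'
#' Posterior mean and full credible ribbon of the latent beetle sign
#' intensity over a fire-age grid, one curve per pine proportion.
#'
#' @param draws An `mtocc_draws` object.
#' @param age_grid Fire ages in natural years since fire.
#' @param pine_values Pine proportions in \[0, 1\].
#' @param scaling Scaling constants (as in [predict_occupancy_curve()]).
#' @param prob Ribbon mass.
#' @return A data frame of class `mtocc_curve`: `pine`, `x` (age in natural
#'   years), `mean`, `lower`, `upper`.
#' @export
predict_intensity_curve <- function(draws, age_grid = 1:10,
                                    pine_values = c(0, 0.5, 1),
                                    scaling = NULL, prob = 0.95) {
  if (any(pine_values < 0 | pine_values > 1))
    stop("pine_values must lie in [0, 1]")
  flat <- pooled_draws(draws)
  alpha <- (1 - prob) / 2
  out <- list()
  for (pine in pine_values) {
    for (age in age_grid) {
      age_s <- scale_age(age, scaling)
      eta <- flat[, "gamma0"] + flat[, "gamma_age"] * age_s +
        flat[, "gamma_pine"] * pine + flat[, "gamma_ageXpine"] * age_s * pine
      intensity <- stats::plogis(eta)
      out[[length(out) + 1L]] <- data.frame(
        pine = pine, x = age, mean = mean(intensity),
        lower = stats::quantile(intensity, alpha, names = FALSE),
        upper = stats::quantile(intensity, 1 - alpha, names = FALSE))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "response") <- "intensity"
  class(res) <- c("mtocc_curve", "data.frame")
  res
}

#' @export
plot.mtocc_curve <- function(x, ...) {
  resp <- attr(x, "response")
  group_col <- if (!is.null(x$age)) "age" else "pine"
  groups <- unique(x[[group_col]])
  cols <- grDevices::hcl.colors(max(2L, length(groups)), "Zissou 1")
  xlab <- if (identical(resp, "occupancy")) "Beetle sign intensity" else
    "Years since fire"
  ylab <- if (identical(resp, "occupancy")) "Occupancy probability" else
    "Beetle sign intensity"
  graphics::plot(range(x$x), c(0, 1), type = "n", xlab = xlab, ylab = ylab,
                 ...)
  for (g in seq_along(groups)) {
    sub <- x[x[[group_col]] == groups[g], ]
    graphics::polygon(c(sub$x, rev(sub$x)), c(sub$lower, rev(sub$upper)),
                      col = grDevices::adjustcolor(cols[g], 0.2),
                      border = NA)
    graphics::lines(sub$x, sub$mean, col = cols[g], lwd = 2)
  }
  graphics::legend("topright", bty = "n", lwd = 2, col = cols[seq_along(groups)],
                   legend = paste(group_col, "=", groups))
  invisible(x)
}
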