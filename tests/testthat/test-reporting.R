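test_that("posterior summaries report means, quantiles and evidence", {
  # constant draws collapse to a zero-width interval
  m <- cbind(a = rep(2.5, 50), b = rep(-1, 50))
  s <- summarize_posterior(fake_draws(m))
  expect_equal(s$mean, c(2.5, -1))
  expect_equal(s$lower, s$upper)
  expect_equal(s$lower, c(2.5, -1))
  # known sequence: empirical 95% interval of {1..1000}/1000
  s2 <- summarize_posterior(fake_draws(cbind(x = (1:1000) / 1000)))
  expect_equal(s2$mean, 0.5005)
  expect_lt(abs(s2$lower - 0.025), 2e-3)
  expect_lt(abs(s2$upper - 0.975), 2e-3)
  # symmetric straddle of zero: no evidence
  s3 <- summarize_posterior(fake_draws(cbind(x = seq(-1, 1, length.out = 99))))
  expect_false(s3$evidence)
  expect_true(s$evidence[1])
  expect_error(summarize_posterior(fake_draws(matrix(numeric(0), 0, 1,
                                                     dimnames = list(NULL, "x")))),
               "no retained draws")
})

test_that("summaries are invariant to chain order", {
  set.seed(3)
  a <- array(rnorm(2 * 40 * 3), c(2, 40, 3),
             dimnames = list(NULL, NULL, c("p1", "p2", "p3")))
  d12 <- fake_draws(a)
  d21 <- fake_draws(a[2:1, , , drop = FALSE])
  s12 <- summarize_posterior(d12)
  s21 <- summarize_posterior(d21)
  expect_equal(s12$mean, s21$mean)
  expect_equal(s12$lower, s21$lower)
  expect_equal(s12$rhat, s21$rhat)
})

test_that("prediction curves from one draw equal the deterministic model", {
  pars <- reference_params()
  flat <- const_draw_matrix(pars, n = 5)
  a <- array(flat, c(1, nrow(flat), ncol(flat)),
             dimnames = list(NULL, NULL, colnames(flat)))
  draws <- fake_draws(a)
  cur <- predict_intensity_curve(draws, age_grid = 1:10,
                                 pine_values = c(0, 1))
  for (r in sample(nrow(cur), 8)) {
    expect_equal(cur$mean[r],
                 beetle_intensity(pars, cur$x[r], cur$pine[r]),
                 tolerance = 1e-12)
  }
  # constant draws give zero-width ribbons that still contain the mean
  expect_equal(cur$lower, cur$mean, tolerance = 1e-12)
  expect_equal(cur$upper, cur$mean, tolerance = 1e-12)

  occ <- predict_occupancy_curve(draws, age_values = 4,
                                 intensity_grid = c(0.2, 0.8))
  expect_equal(occ$mean[1],
               occupancy_prob(pars, list(elev = 0, lat = 0, snag = 0,
                                         age = 4), 0.2),
               tolerance = 1e-12)
})

test_that("slope-free draws give flat occupancy curves", {
  pars <- model_params(mu_beta0 = -0.4)
  draws <- fake_draws(array(const_draw_matrix(pars, 6),
                            c(1, 6, ncol(const_draw_matrix(pars, 1))),
                            dimnames = list(NULL, NULL,
                                            colnames(const_draw_matrix(pars, 1)))))
  occ <- predict_occupancy_curve(draws, age_values = c(1, 10),
                                 intensity_grid = seq(0.1, 0.9, 0.2))
  expect_equal(unique(round(occ$mean, 12)), plogis(-0.4), tolerance = 1e-10)
})

test_that("ribbons contain the mean pointwise and responses stay in (0,1)", {
  set.seed(8)
  nms <- colnames(const_draw_matrix(reference_params(), 1))
  flat <- const_draw_matrix(reference_params(), 200)
  jitter_cols <- c("gamma0", "gamma_age", "gamma_pine", "gamma_ageXpine",
                   "beta_beetle", "beta_ageXbeetle", "mu_beta0")
  for (cl in jitter_cols) flat[, cl] <- flat[, cl] + rnorm(200, 0, 0.2)
  draws <- fake_draws(array(flat, c(1, 200, length(nms)),
                            dimnames = list(NULL, NULL, nms)))
  for (cur in list(predict_intensity_curve(draws),
                   predict_occupancy_curve(draws, ribbon = "full"),
                   predict_occupancy_curve(draws, ribbon = "partial"))) {
    expect_true(all(cur$lower <= cur$mean + 1e-12))
    expect_true(all(cur$upper >= cur$mean - 1e-12))
    expect_true(all(cur$mean > 0 & cur$mean < 1))
  }
  expect_error(predict_occupancy_curve(draws, ribbon = "fancy"), "arg")
})

test_that("reference estimates reproduce the qualitative field patterns", {
  pars <- reference_params()
  nms <- colnames(const_draw_matrix(pars, 1))
  draws <- fake_draws(array(const_draw_matrix(pars, 3), c(1, 3, length(nms)),
                            dimnames = list(NULL, NULL, nms)))
  scaling <- list(age = c(center = 5.5, spread = sd(1:10)))
  # beetle sign accumulates with age in pine-free stands, declines in pure
  # pine stands
  cur <- predict_intensity_curve(draws, age_grid = 1:10,
                                 pine_values = c(0, 1), scaling = scaling)
  expect_true(all(diff(cur$mean[cur$pine == 0]) > 0))
  expect_true(all(diff(cur$mean[cur$pine == 1]) < 0))
  # occupancy-vs-intensity slope flips sign between early and late years
  occ <- predict_occupancy_curve(draws, age_values = c(1, 10),
                                 intensity_grid = c(0.2, 0.8),
                                 scaling = scaling)
  slope_early <- diff(occ$mean[occ$age == 1])
  slope_late <- diff(occ$mean[occ$age == 10])
  expect_gt(slope_early, 0)
  expect_lt(slope_late, 0)
})
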