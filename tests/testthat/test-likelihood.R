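test_that("beetle log-likelihood is the binomial log-pmf", {
  p_half <- model_params()  # all gammas 0 -> intensity 0.5
  # all-success corner: 48 * ln(0.5)
  expect_equal(beetle_loglik(p_half, 48, 6, age = 0, pine = 0),
               48 * log(0.5), tolerance = 1e-12)
  # 4 successes of 8 trials at 0.5: ln(C(8,4) * 0.5^8)
  expect_equal(beetle_loglik(p_half, 4, 1, age = 0, pine = 0),
               log(choose(8, 4) * 0.5^8), tolerance = 1e-12)
  # pmf normalization at an arbitrary intensity
  p <- reference_params()
  lls <- beetle_loglik(p, 0:48, rep(6, 49), age = rep(0.7, 49),
                       pine = rep(0.4, 49))
  expect_equal(sum(exp(lls)), 1, tolerance = 1e-12)
  expect_error(beetle_loglik(p, 49, 6, 0, 0), "activity")
})

test_that("interval emission matches the conditional detection model", {
  p <- reference_params()
  recs0 <- rbind(det_row("p1", 2018, 1, detected = 0),
                 det_row("p1", 2018, 2, detected = 0))
  expect_equal(interval_emission(p, recs0, z = 0), 1)
  rec1 <- det_row("p1", 2018, 1, detected = 1)
  expect_equal(interval_emission(p, rec1, z = 0), 0)
  # one broadcast detection given presence = the detection probability
  expect_equal(interval_emission(p, rec1, z = 1), 0.5744425,
               tolerance = 1e-6)
  # empty record set contributes 1 either way
  expect_equal(interval_emission(p, empty_detections(), 0), 1)
  expect_equal(interval_emission(p, empty_detections(), 1), 1)
  # censored intervals are excluded
  recs_c <- rbind(det_row("p1", 2018, 1, detected = 1),
                  det_row("p1", 2018, 2, censored = 1))
  expect_equal(interval_emission(p, recs_c, z = 1),
               interval_emission(p, rec1, z = 1))
})

test_that("single-year marginal likelihood has the closed form psi * p", {
  ds <- mini_dataset(detections = det_row("p1", 2018, detected = 1),
                     survey_years = 2018, year_burned = 2017)
  ds <- standardize_covariates(ds)
  pars <- rand_params()
  ll <- site_marginal_loglik(pars, ds, "p1")
  ctx <- mtoccu:::build_model_context(ds)
  pe <- mtoccu:::expand_beta0(pars, ctx)
  intensity <- mtoccu:::intensity_matrix(pe, ctx)
  psi <- plogis(mtoccu:::eta_matrix(pe, ctx, intensity)[1, ctx$Tn])
  expect_equal(ll, log(psi * detection_prob(pars, 1)), tolerance = 1e-12)
  # a point with no surveys at all contributes zero log-likelihood
  expect_equal(site_marginal_loglik(pars, ds, "p2"), 0)
})

test_that("forward recursion equals brute-force enumeration", {
  set.seed(42)
  for (rep in 1:12) {
    Tn <- sample(2:6, 1)
    yb <- 2018 - Tn
    yrs <- (yb + 1):2018
    sy <- sort(unique(c(2018, yrs[sample.int(Tn, sample.int(Tn, 1))])))
    ds <- survey_dataset(mini_design(year_burned = yb, survey_years = sy),
                         rand_detections(sy), empty_beetle(),
                         mini_covariates())
    ds <- standardize_covariates(ds)
    pars <- rand_params()
    for (pt in c("p1", "p2")) {
      f <- site_marginal_loglik(pars, ds, pt)
      e <- site_marginal_loglik(pars, ds, pt, method = "enumerate")
      expect_equal(f, e, tolerance = 1e-10)
    }
  }
})

test_that("with phi = 0 the marginal factorizes over years", {
  set.seed(11)
  sy <- c(2015, 2017, 2018)
  ds <- survey_dataset(mini_design(year_burned = 2013, survey_years = sy),
                       rand_detections(sy, p_missing = 0), empty_beetle(),
                       mini_covariates())
  ds <- standardize_covariates(ds)
  pars <- rand_params()
  pars$phi <- 0
  ctx <- mtoccu:::build_model_context(ds)
  pe <- mtoccu:::expand_beta0(pars, ctx)
  intensity <- mtoccu:::intensity_matrix(pe, ctx)
  psi <- plogis(mtoccu:::eta_matrix(pe, ctx, intensity))
  for (pt in c("p1", "p2")) {
    i <- match(pt, ds$covariates$point_id)
    per_year <- 0
    for (t in ctx$entry_t[i]:ctx$Tn) {
      recs <- ds$detections[ds$detections$point_id == pt &
                              ds$detections$year == ctx$year0 + t, ]
      per_year <- per_year +
        log(psi[i, t] * interval_emission(pars, recs, 1) +
              (1 - psi[i, t]) * interval_emission(pars, recs, 0))
    }
    expect_equal(site_marginal_loglik(pars, ds, pt), per_year,
                 tolerance = 1e-10)
  }
})

test_that("marginal likelihood normalizes over all observable outcomes", {
  # 2 survey years, 2 broadcast intervals per year under the removal design:
  # per-year outcomes are (no detection | first detection at k)
  pars <- rand_params()
  outcomes <- function(pt, yr, o) {
    if (o == 0) rbind(det_row(pt, yr, 1, detected = 0),
                      det_row(pt, yr, 2, detected = 0))
    else if (o == 1) rbind(det_row(pt, yr, 1, detected = 1),
                           det_row(pt, yr, 2, censored = 1))
    else rbind(det_row(pt, yr, 1, detected = 0),
               det_row(pt, yr, 2, detected = 1))
  }
  total <- 0
  for (o1 in 0:2) for (o2 in 0:2) {
    det <- rbind(outcomes("p1", 2017, o1), outcomes("p1", 2018, o2))
    ds <- standardize_covariates(
      mini_dataset(detections = det))
    total <- total + exp(site_marginal_loglik(pars, ds, "p1"))
  }
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("joint likelihood is additive and order-invariant", {
  sim <- simulate_dataset(generator_config(seed = 8))
  ds <- sim$dataset
  pars <- sim$truth$params
  set.seed(88)
  ll <- joint_loglik(pars, ds)
  # permuting point order leaves the joint unchanged
  perm <- sample(nrow(ds$covariates))
  ds2 <- ds
  ds2$covariates <- ds$covariates[perm, ]
  ds2$std <- NULL; ds2$scaling <- NULL
  expect_equal(joint_loglik(pars, ds2), ll, tolerance = 1e-8)
  # two points with identical beetle data and covariates contribute equally
  cv_eq <- mini_covariates()
  cv_eq$pine_prop <- c(0.5, 0.5)
  one <- standardize_covariates(
    survey_dataset(mini_design(),
                   det_row("p1", 2018, detected = 1),
                   data.frame(point_id = c("p1", "p2"),
                              num_trees = 6, activity = c(20, 20)),
                   cv_eq))
  ctx1 <- mtoccu:::build_model_context(one)
  pe <- mtoccu:::expand_beta0(rand_params(), ctx1)
  site <- mtoccu:::site_loglik_vec(pe, ctx1)
  beetle <- mtoccu:::beetle_loglik_vec(pe, ctx1)
  expect_equal(beetle[1], beetle[2], tolerance = 1e-9)
})

test_that("a gamma perturbation moves beetle and occupancy components", {
  sim <- simulate_dataset(generator_config(seed = 9))
  ds <- standardize_covariates(sim$dataset)
  ctx <- mtoccu:::build_model_context(ds)
  pars <- mtoccu:::expand_beta0(sim$truth$params, ctx)
  h <- 1e-5
  comp <- function(g) {
    p <- pars; p$gamma_age <- g
    intensity <- mtoccu:::intensity_matrix(p, ctx)
    c(site = sum(mtoccu:::site_loglik_vec(p, ctx, intensity = intensity)),
      beetle = sum(mtoccu:::beetle_loglik_vec(p, ctx, intensity = intensity)))
  }
  up <- comp(pars$gamma_age + h); dn <- comp(pars$gamma_age - h)
  grad <- (up - dn) / (2 * h)
  # both components respond to the shared latent intensity
  expect_gt(abs(grad["site"]), 0)
  expect_gt(abs(grad["beetle"]), 0)
  # and their sum matches the central difference of the joint likelihood
  pu <- pars; pu$gamma_age <- pars$gamma_age + h
  pd <- pars; pd$gamma_age <- pars$gamma_age - h
  joint_grad <- (joint_loglik(pu, ds) - joint_loglik(pd, ds)) / (2 * h)
  expect_equal(joint_grad, sum(grad), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("log prior matches the vague-prior specification", {
  # 13 fixed effects at 0, one fire intercept at mu, tau = 1
  p <- model_params(beta0 = 0, tau_beta0 = 1)
  lp <- log_prior(p)
  fixed_term <- 13 * dnorm(0, 0, sqrt(10), log = TRUE)  # 0.5*log(0.1/2pi) each
  expect_equal(lp, fixed_term + dnorm(0, 0, 1, log = TRUE) +
                 dgamma(1, 0.1, 0.1, log = TRUE), tolerance = 1e-12)
  expect_equal(dnorm(0, 0, sqrt(10), log = TRUE), -2.070231, tolerance = 1e-6)
  # a centered random effect sits at the mode of its conditional
  p2 <- model_params(mu_beta0 = 0.8, beta0 = 0.8)
  p3 <- model_params(mu_beta0 = 0.8, beta0 = 1.3)
  expect_gt(log_prior(p2), log_prior(p3))
  # precision positivity
  p_bad <- model_params()
  p_bad$tau_beta0 <- -1
  expect_identical(log_prior(p_bad), -Inf)
})
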