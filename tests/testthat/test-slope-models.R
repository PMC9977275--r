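test_that("standardize centres and scales with the n-1 sd", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(c(5, 5, 5)), "constant")
})

test_that("model specs enforce response-family compatibility", {
  expect_error(model_spec("strain_count", family = "nb_linear"), "admissible")
  expect_error(model_spec("polymorphism_rate", family = "trunc_poisson"),
               "admissible")
  sp <- model_spec("strain_count", family = "trunc_nb_quadratic")
  expect_s3_class(sp, "model_spec")
})

test_that("direct-ML count fits agree with glmmTMB on the same data", {
  d <- simulate_slope_data(60, 5, slope = 0.4, family = "trunc_nb_quadratic",
                           seed = 2)
  for (fam in c("trunc_poisson", "trunc_nb_quadratic", "nb_linear")) {
    spec <- model_spec("strain_count",
                       family = if (fam == "nb_linear") NULL else fam,
                       random_effects = character())
    dat <- microdiv:::prepare_slope_data(d, spec, FALSE)
    ml <- microdiv:::fit_one_count(dat, spec, fam, FALSE)
    tmb <- microdiv:::fit_count_tmb(dat, "div_z + rc_z", character(), fam)
    expect_equal(ml$logL, tmb$logL, tolerance = 1e-4)
    expect_equal(ml$coefficients$estimate[1:3], tmb$coefficients$estimate[1:3],
                 tolerance = 1e-3)
  }
})

test_that("cross-sectional fits recover a planted positive slope", {
  d <- simulate_slope_data(150, 10, slope = 0.5, family = "trunc_nb_quadratic",
                           seed = 3)
  spec <- model_spec("strain_count", random_effects = character())
  f <- fit_cross_sectional(d, spec)
  expect_true(f$converged)
  expect_gt(f$slope, 0)
  expect_lt(abs(f$slope - 0.5), 2.5 * f$slope_se)
  # AIC family selection happened over the three zero-truncated families
  expect_true(f$family %in% c("trunc_poisson", "trunc_nb_linear",
                              "trunc_nb_quadratic"))
  lrt <- drop_one_lrt(f, "div_z")
  expect_lt(lrt$p_value, 1e-6)
  nc <- null_model_comparison(f)
  expect_gt(nc$delta_AIC, 0)
})

test_that("mixed-model engine handles species random intercepts", {
  d <- simulate_slope_data(80, 8, slope = 0.5, family = "trunc_poisson",
                           species_sd = 0.4, seed = 4)
  spec <- model_spec("strain_count", family = "trunc_poisson",
                     random_effects = "species")
  f <- fit_cross_sectional(d, spec)
  expect_identical(f$engine, "glmmTMB")
  expect_true(f$converged)
  expect_lt(abs(f$slope - 0.5), 3 * f$slope_se)
  lrt <- drop_one_lrt(f, "div_z")
  expect_lt(lrt$p_value, 0.01)
})

test_that("flat responses yield near-zero slopes", {
  d <- simulate_slope_data(100, 5, slope = 0, family = "trunc_poisson", seed = 5)
  f <- fit_cross_sectional(d, model_spec("strain_count",
                                         family = "trunc_poisson",
                                         random_effects = character()))
  expect_lt(abs(f$slope / f$slope_se), 2.5)
})

test_that("overdispersed counts fit with Poisson raise the diagnostic", {
  d <- simulate_slope_data(80, 8, slope = 0.3, family = "trunc_nb_quadratic",
                           dispersion = 0.8, species_sd = 0, seed = 6)
  spec_p <- model_spec("strain_count", family = "trunc_poisson",
                       random_effects = "species")
  f <- fit_cross_sectional(d, spec_p)
  expect_gt(f$overdispersion, 1.2)
  # and AIC family selection prefers a negative-binomial parameterization
  spec_all <- model_spec("strain_count", random_effects = character())
  fa <- fit_cross_sectional(d, spec_all)
  expect_true(fa$family %in% c("trunc_nb_linear", "trunc_nb_quadratic"))
})

test_that("beta-logit smooth models recover the sign of the rate slope", {
  set.seed(7)
  n_host <- 120; n_sp <- 5
  H <- rnorm(n_host, 2.5, 0.5)
  z <- standardize(H)
  d <- expand.grid(host = seq_len(n_host), species = seq_len(n_sp))
  d$shannon <- H[d$host]
  d$read_count <- round(2e7 * exp(rnorm(nrow(d), 0, 0.2)))
  mu <- plogis(-4 + 0.5 * z[d$host])
  phi <- 60
  d$polymorphism_rate <- rbeta(nrow(d), mu * phi, (1 - mu) * phi)
  d$species <- sprintf("sp%d", d$species)
  d$sample <- sprintf("H%d_S1", d$host)
  d$host <- sprintf("H%d", d$host)
  spec <- model_spec("polymorphism_rate", random_effects = c("species", "host"))
  f <- fit_cross_sectional(d, spec)
  expect_identical(f$engine, "mgcv")
  expect_gt(f$slope, 0)
  lrt <- drop_one_lrt(f, "div_z")
  expect_lt(lrt$p_value, 0.01)
})

test_that("temporal interaction models recover a lag-dependent effect", {
  d <- simulate_slope_data(150, 8, slope = 0.3, family = "nb_quadratic",
                           intercept = 1, response = "genes_lost",
                           lag_effect = 0.4, lag_levels = 4, seed = 8)
  spec <- model_spec("genes_lost", interaction_with_lag = TRUE,
                     random_effects = character())
  f <- fit_temporal(d, spec)
  expect_true(f$converged)
  co <- f$coefficients
  est <- co$estimate[co$term == "div_z:lag_z"]
  se <- co$std_error[co$term == "div_z:lag_z"]
  expect_gt(est, 0)
  expect_lt(abs(est - 0.4), 3 * se)
  lrt <- drop_one_lrt(f, "div_z:lag_z")
  expect_lt(lrt$p_value, 0.01)
})

test_that("a constant time lag makes the interaction inestimable", {
  d <- simulate_slope_data(40, 4, slope = 0.3, family = "nb_quadratic",
                           intercept = 1, response = "genes_lost",
                           lag_effect = 0, lag_levels = 2, seed = 9)
  d$delta_days <- 180
  spec <- model_spec("genes_lost", interaction_with_lag = TRUE,
                     random_effects = character())
  f <- fit_temporal(d, spec)
  expect_false(f$converged)
  expect_match(f$failure, "collinear")
})

test_that("temporal polymorphism change uses the transformed Gaussian model", {
  set.seed(10)
  n <- 400
  H <- rnorm(n, 2.5, 0.5)
  d <- data.frame(shannon = H, read_count = round(2e7 * runif(n, .8, 1.2)),
                  delta_days = sample(c(30, 90, 180), n, TRUE),
                  species = "sp1", host = sprintf("H%d", seq_len(n)),
                  sample = sprintf("S%d", seq_len(n)))
  d$polymorphism_change <- 1e-4 * standardize(H) + rnorm(n, 0, 2e-4)
  spec <- model_spec("polymorphism_change", random_effects = character())
  f <- fit_temporal(d, spec)
  expect_identical(f$family, "gaussian_log_response")
  expect_gt(f$slope, 0)
  expect_lt(drop_one_lrt(f, "div_z")$p_value, 0.01)
})

test_that("LRT of identical models is zero with p = 1", {
  d <- simulate_slope_data(50, 4, slope = 0.2, family = "trunc_poisson", seed = 11)
  f <- fit_cross_sectional(d, model_spec("strain_count",
                                         family = "trunc_poisson",
                                         random_effects = character()))
  # lag_z is not in a cross-sectional model: reduced model equals the full one
  lrt <- drop_one_lrt(f, "lag_z")
  expect_equal(lrt$statistic, 0, tolerance = 1e-6)
  expect_equal(lrt$df, 0)
  expect_equal(lrt$p_value, 1)
})

test_that("cohort-derived model data joins diversity and metadata", {
  sim <- simulate_cohort(sim_params(n_hosts = 10, n_focal_species = 2, seed = 13))
  dv <- diversity_table(sim$tables)
  gl <- gain_loss_table(sim$tables, run_config())
  td <- temporal_data(gl, dv, sim$tables)
  expect_true(all(c("shannon", "read_count", "delta_days", "species", "host")
                  %in% names(td)))
  expect_false(anyNA(td$shannon))
  sp_dv <- dv[dv$rank == "species", ]
  expect_equal(td$shannon[1], sp_dv$shannon[sp_dv$sample_id == td$t1[1]])
})
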