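test_that("the Gaussian likelihood and deviance follow their closed forms", {
  p <- demo_params("A")
  rec <- make_records(n = 3, params = p, psi = -0.5)
  psi <- psi_table(psi = -0.5)
  # predictions identical to measurements at sigma = 1/sqrt(2*pi): peak
  # density is exactly 1, so the log-likelihood is 0
  expect_equal(log_likelihood(rec, p, psi, sigma = 1 / sqrt(2 * pi)), 0,
               tolerance = 1e-10)
  # one exact record at sigma = 0.1
  expect_equal(log_likelihood(rec[1, ], p, psi, sigma = 0.1),
               log(1 / (0.1 * sqrt(2 * pi))), tolerance = 1e-10)
  # additivity under duplication
  ll1 <- log_likelihood(rec, p, psi, sigma = 0.2)
  ll2 <- log_likelihood(dplyr::bind_rows(rec, rec), p, psi, sigma = 0.2)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)

  expect_equal(deviance_from_loglik(0), 0)
  expect_equal(deviance_from_loglik(711.5), -1423)
  expect_equal(deviance_from_loglik(-5), 10)
})

test_that("prior bounds are respected by every draw and counts are right", {
  des <- synthetic_design(n_obs_per_group = 1, n_days = 2,
                          hours = seq(8, 16, 4), n_leaves = 1,
                          noise_sd = 0.05, seed = 10)
  sim <- generate_dataset(des)
  pri <- prior_spec()
  fit <- fit_level(sim$records, "OBS", priors = pri,
                   control = mcmc_control(iterations = 200, chains = 2,
                                          seed = 11, init = "prior"))
  # free-parameter bookkeeping: 3 units x 5 + 6 obs-days + c_lambda
  expect_equal(fit$n_free_parameters, 3 * 5 + 6 + 1)
  for (nm in fit$par_names) {
    b <- if (grepl("^psi\\.", nm)) pri$psi_day
         else if (nm == "c_lambda") pri$c_lambda
         else if (nm == "sigma") pri$sigma
         else pri[[sub("^.*\\.", "", nm)]]
    expect_true(all(fit$draws[, nm] >= b[1] & fit$draws[, nm] <= b[2]),
                label = paste("bounds of", nm))
  }
  # identical seeds reproduce the chains exactly
  fit2 <- fit_level(sim$records, "OBS", priors = pri,
                    control = mcmc_control(iterations = 200, chains = 2,
                                           seed = 11, init = "prior"))
  expect_identical(fit$draws, fit2$draws)
})

test_that("a flat likelihood leaves uniform prior marginals (detailed balance)", {
  rec <- make_records(n = 1, params = demo_params("A"), psi = -1)
  # pinning sigma at a huge value makes the likelihood flat in all
  # structural parameters; the sampler must then reproduce its priors
  pri <- prior_spec(sigma = c(1e6, 1e6 + 1))
  fit <- fit_level(rec, "GLB", priors = pri,
                   control = mcmc_control(iterations = 10000, chains = 2,
                                          seed = 12, init = "prior"),
                   psi_fixed = psi_table(psi = -1), c_lambda = 3.13)
  expect_equal(nrow(fit$draws), 10000)
  for (par in c("k_psi", "g_p", "pi_0", "xi")) {
    b <- pri[[par]]
    ks <- suppressWarnings(
      stats::ks.test(fit$draws[, paste0("GLB.", par)], "punif", b[1], b[2]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("pooled-level fit recovers the residual SD and DIC bookkeeping", {
  des <- synthetic_design(groups = "SUBS", n_obs_per_group = 2, n_days = 2,
                          hours = 7:18, n_leaves = 2, noise_sd = 0.08,
                          seed = 99)
  sim <- generate_dataset(des)
  fit <- fit_level(sim$records, "GLB",
                   control = mcmc_control(iterations = 1500, chains = 2,
                                          seed = 8),
                   psi_fixed = sim$truth$psi_day, c_lambda = 3.13)
  # residual SD within 10% of the generating noise
  expect_lt(abs(fit$residual_sd - 0.08) / 0.08, 0.1)
  # the plug-in deviance at the posterior means beats the average deviance
  expect_lte(fit$deviance_at_mean, mean(fit$deviance_trace))
  g <- glance(fit)
  expect_equal(g$dic,
               2 * mean(fit$deviance_trace) - fit$deviance_at_mean,
               tolerance = 1e-10)
  expect_equal(g$n_free_parameters, 5)
  # demand-limited parameters are identified at the pooled level
  expect_lt(abs(fit$params$k_psi - 1.42) / 1.42, 0.25)
  expect_lt(abs(fit$params$g_p - 0.00566) / 0.00566, 0.25)
})

test_that("group-level fits require the observation-level hand-off", {
  rec <- make_records(n = 3)
  expect_error(fit_level(rec, "PFT"), "psi_fixed")
  expect_error(fit_level(rec, "GLB"), "psi_fixed")
})

test_that("credible intervals cover the truth across replicate simulations", {
  cover <- 0; total <- 0
  for (r in 1:20) {
    des <- synthetic_design(groups = "SUBS", n_obs_per_group = 1, n_days = 3,
                            hours = seq(7, 18, 2), n_leaves = 2,
                            noise_sd = 0.05, seed = 300 + r)
    sim <- generate_dataset(des)
    fit <- fit_level(sim$records, "OBS",
                     control = mcmc_control(iterations = 1600, chains = 2,
                                            seed = 400 + r))
    td <- tidy(fit)
    for (par in c("k_psi", "g_p", "k_i", "pi_0", "xi")) {
      row <- td[td$term == paste0("SUBS_01.", par), ]
      total <- total + 1
      if (sim$truth$params[[par]] >= row$conf.low &&
          sim$truth$params[[par]] <= row$conf.high) cover <- cover + 1
    }
  }
  expect_gte(cover / total, 0.8)
})
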