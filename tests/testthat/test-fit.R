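cfg <- analysis_config()

truth_rich <- population_model(
  theta = theta_vector(5.66, 150, 1, beta_wt_v = 1, beta_hiv_v = 1,
                       beta_age_cl = -0.25),
  omega2 = c(cl = 0.09, v = 0.09, ka = 0.09), sigma_prop = 0.15
)

test_that("near-noiseless rich data identify the fixed effects to 0.5%", {
  noiseless <- population_model(
    theta = truth_rich$theta,
    omega2 = c(cl = 0, v = 0, ka = 0), sigma_prop = 1e-4
  )
  trial <- simulate_trial(simulation_config(
    n_subjects = 50, seed = 21, true_model = noiseless,
    schedule = rich_schedule()
  ))
  init <- population_model(
    theta = theta_vector(4.5, 120, 1.3, beta_wt_v = 0.7, beta_hiv_v = 1,
                         beta_age_cl = 0),
    omega2 = c(cl = 0, v = 0, ka = 0), sigma_prop = 1e-3
  )
  fit <- fit_population(trial$records, trial$subjects, init = init,
                        config = cfg, compute_se = FALSE)
  est <- fit$parameters$estimate
  names(est) <- fit$parameters$parameter
  tv <- unclass(truth_rich$theta)
  for (p in c("tvcl", "tvv", "tvka")) {
    expect_lt(abs(est[[p]] - tv[[p]]) / tv[[p]], 0.005)
  }
  expect_lt(abs(est[["beta_wt_v"]] - 1), 0.005)
  expect_lt(abs(est[["beta_age_cl"]] - (-0.25)), 0.005 * 0.25)
})

test_that("the fitted objective is no worse than at random parameter draws", {
  trial <- simulate_trial(simulation_config(
    n_subjects = 25, seed = 31, true_model = truth_rich,
    schedule = rich_schedule()
  ))
  fit <- fit_population(trial$records, trial$subjects, init = truth_rich,
                        config = cfg, compute_se = FALSE)
  set.seed(99)
  for (i in 1:20) {
    m <- population_model(
      theta = theta_vector(runif(1, 2, 12), runif(1, 60, 300),
                           runif(1, 0.4, 2.5), runif(1, 0, 2), 1,
                           runif(1, -1, 1)),
      omega2 = c(cl = runif(1, 0.01, 0.3), v = runif(1, 0.01, 0.3),
                 ka = runif(1, 0.01, 0.5)),
      sigma_prop = runif(1, 0.05, 0.4)
    )
    val <- tryCatch(
      marginal_neg2ll(m, trial$records, trial$subjects, cfg),
      error = function(e) Inf
    )
    expect_gte(val, fit$neg2ll - 1e-6)
  }
})

test_that("degenerate data are rejected with a clear error", {
  ds <- one_subject_data(c(2, 12), c(1000, 800))
  expect_error(
    fit_population(ds$records, ds$subjects, init = truth_rich, config = cfg),
    "at least 2 subjects"
  )
  flat <- bind_datasets(
    one_subject_data(c(2, 12), c(1000, 1000)),
    one_subject_data(c(2, 12), c(1000, 1000), id = "S2")
  )
  expect_error(
    fit_population(flat$records, flat$subjects, init = truth_rich,
                   config = cfg),
    "degenerate"
  )
})

test_that("standard errors shrink like 1/sqrt(n) when the data double", {
  sim1 <- simulate_trial(simulation_config(
    n_subjects = 40, seed = 41, true_model = truth_rich,
    schedule = rich_schedule()
  ))
  sim2 <- simulate_trial(simulation_config(
    n_subjects = 40, seed = 42, true_model = truth_rich,
    schedule = rich_schedule()
  ))
  sim2$records$subject_id <- paste0(sim2$records$subject_id, "b")
  sim2$subjects$subject_id <- paste0(sim2$subjects$subject_id, "b")
  both <- bind_datasets(sim1, sim2)
  # estimate only the structural typical values to keep the surface small
  fix <- c(beta_wt_v = FALSE, beta_age_cl = FALSE,
           omega2_v = FALSE, omega2_ka = FALSE)
  f1 <- fit_population(sim1$records, sim1$subjects, init = truth_rich,
                       config = cfg, estimate = fix)
  f2 <- fit_population(both$records, both$subjects, init = truth_rich,
                       config = cfg, estimate = fix)
  se1 <- f1$parameters$se[f1$parameters$parameter == "tvcl"]
  se2 <- f2$parameters$se[f2$parameters$parameter == "tvcl"]
  expect_false(is.na(se1) || is.na(se2))
  expect_lt(abs(se2 / se1 - 1 / sqrt(2)), 0.15 / sqrt(2))
})

test_that("SEs of the typical values decrease monotonically with residual noise", {
  ses <- vapply(c(0.2, 0.1, 0.05), function(sig) {
    truth <- population_model(theta = truth_rich$theta,
                              omega2 = c(cl = 0, v = 0, ka = 0),
                              sigma_prop = sig)
    trial <- simulate_trial(simulation_config(
      n_subjects = 30, seed = 51, true_model = truth,
      schedule = rich_schedule()
    ))
    fit <- fit_population(trial$records, trial$subjects, init = truth,
                          config = cfg,
                          estimate = c(beta_wt_v = FALSE, beta_age_cl = FALSE))
    fit$parameters$se[fit$parameters$parameter == "tvcl"]
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("the SE matches the analytic curvature of a hand-written likelihood", {
  # one subject, additive error, only TVCL estimated: the marginal likelihood
  # is an ordinary nonlinear least-squares likelihood whose curvature we can
  # difference by hand
  tads <- c(2, 6, 12, 24)
  sub <- tibble::tibble(subject_id = "S1", weight = 70, age = 45,
                        status = "healthy", group = "ISG")
  sigma_add <- 50
  true_cl <- 5.66
  pred0 <- conc_ss(tads, true_cl, 150, 1, cfg$regimen)
  ds <- one_subject_data(tads, pred0, status = "healthy")
  ds2 <- bind_datasets(ds, one_subject_data(tads, pred0, id = "S2",
                                            status = "healthy"))
  init <- population_model(theta = theta_vector(tvcl = 5, tvv = 150, tvka = 1),
                           omega2 = c(cl = 0, v = 0, ka = 0),
                           sigma_prop = 0, sigma_add = sigma_add)
  fit <- fit_population(ds2$records, ds2$subjects, init = init, config = cfg,
                        estimate = c(tvcl = TRUE, tvv = FALSE, tvka = FALSE,
                                     beta_wt_v = FALSE, beta_age_cl = FALSE,
                                     sigma_add = FALSE))
  est_cl <- fit$parameters$estimate[fit$parameters$parameter == "tvcl"]
  expect_equal(est_cl, true_cl, tolerance = 1e-4)

  nll <- function(cl) {
    -sum(dnorm(rep(pred0, 2), conc_ss(rep(tads, 2), cl, 150, 1, cfg$regimen),
               sigma_add, log = TRUE))
  }
  h <- 1e-3
  curv <- (nll(est_cl + h) - 2 * nll(est_cl) + nll(est_cl - h)) / h^2
  se_oracle <- sqrt(1 / curv)
  se_fit <- fit$parameters$se[fit$parameters$parameter == "tvcl"]
  expect_equal(se_fit, se_oracle, tolerance = 0.02)
})

test_that("tidy and glance expose the fit in broom style", {
  trial <- simulate_trial(simulation_config(
    n_subjects = 20, seed = 61, true_model = truth_rich,
    schedule = rich_schedule()
  ))
  fit <- fit_population(trial$records, trial$subjects, init = truth_rich,
                        config = cfg, compute_se = FALSE)
  td <- generics::tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(nrow(td), sum(fit$parameters$estimated))
  gl <- generics::glance(fit)
  expect_equal(gl$neg2ll, fit$neg2ll)
  expect_equal(gl$AIC, fit$neg2ll + 2 * nrow(td))
})
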