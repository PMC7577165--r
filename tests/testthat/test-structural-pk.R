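reg <- dosing_regimen()   # 100 mg q24h

test_that("covariates act on the right parameters only", {
  cfg <- analysis_config()
  th <- theta_vector(5.66, 150, 1, beta_wt_v = 0.9, beta_hiv_v = 0.8,
                     beta_age_cl = -0.3)
  ref <- tibble::tibble(subject_id = "ref", weight = cfg$weight_ref,
                        age = cfg$age_ref, status = "healthy")
  p <- typical_params(ref, th, cfg)
  expect_equal(c(p$cl, p$v, p$ka), c(5.66, 150, 1))

  # null coefficients: no subject's covariates matter
  th0 <- theta_vector(5.66, 150, 1, beta_wt_v = 0, beta_hiv_v = 1,
                      beta_age_cl = 0)
  subs <- tibble::tibble(subject_id = c("a", "b", "c"),
                         weight = c(50, 80, 120), age = c(20, 45, 70),
                         status = c("hiv", "healthy", "hiv"))
  p0 <- typical_params(subs, th0, cfg)
  expect_true(all(p0$cl == 5.66) && all(p0$v == 150) && all(p0$ka == 1))

  # weight moves V/F only; age moves CL/F only; status moves V/F only
  two <- tibble::tibble(subject_id = c("x", "y"), weight = c(60, 90),
                        age = c(45, 45), status = "hiv")
  pw <- typical_params(two, th, cfg)
  expect_equal(pw$cl[1], pw$cl[2])
  expect_false(isTRUE(all.equal(pw$v[1], pw$v[2])))

  two_age <- tibble::tibble(subject_id = c("x", "y"), weight = c(70, 70),
                            age = c(25, 65), status = "hiv")
  pa <- typical_params(two_age, th, cfg)
  expect_equal(pa$v[1], pa$v[2])
  expect_false(isTRUE(all.equal(pa$cl[1], pa$cl[2])))

  two_st <- tibble::tibble(subject_id = c("x", "y"), weight = 70, age = 45,
                           status = c("healthy", "hiv"))
  ps <- typical_params(two_st, th, cfg)
  expect_equal(ps$v[2] / ps$v[1], 0.8)
  expect_equal(ps$cl[1], ps$cl[2])

  expect_error(typical_params(dplyr::mutate(two, weight = -1), th, cfg),
               "positive")
})

test_that("steady-state concentration matches superposition of many doses", {
  for (cl in c(3, 6, 12)) for (v in c(60, 150)) for (ka in c(0.5, 1)) {
    t <- c(0.25, 1, 6, 12, 24)
    ss <- conc_ss(t, cl, v, ka, reg)
    sup <- conc_profile_n_doses(250 * 24 + t, 251, cl, v, ka, reg)
    expect_lt(max(abs(ss - sup) / ss), 1e-6)
  }
})

test_that("steady state is periodic and positive", {
  set.seed(42)
  for (i in 1:20) {
    cl <- runif(1, 2, 15); v <- runif(1, 40, 200); ka <- runif(1, 0.3, 3)
    c0 <- conc_ss(0, cl, v, ka, reg)
    ctau <- conc_ss(24, cl, v, ka, reg)
    expect_lt(abs(c0 - ctau) / ctau, 1e-10)
    expect_true(all(conc_ss(seq(0, 24, by = 0.5), cl, v, ka, reg) > 0))
  }
  expect_error(conc_ss(25, 6, 60, 1, reg), "0, tau")
  expect_error(conc_ss(1, -6, 60, 1, reg), "positive")
})

test_that("finite-dose profile starts at zero and converges to steady state", {
  expect_equal(conc_profile_n_doses(0, 1, 6, 60, 1, reg), 0)
  # single dose equals the Bateman form written out independently
  t <- c(0.5, 2, 10, 20)
  d <- reg$amount_nmol; ke <- 6 / 60
  bateman <- d * 1 / (60 * (1 - ke)) * (exp(-ke * t) - exp(-1 * t))
  expect_equal(conc_profile_n_doses(t, 1, 6, 60, 1, reg), bateman,
               tolerance = 1e-12)
  # convergence to the periodic solution (ke = 0.1 >= 0.05 per hour)
  approx50 <- conc_profile_n_doses(49 * 24 + 12, 50, 6, 60, 1, reg)
  expect_lt(abs(approx50 - conc_ss(12, 6, 60, 1, reg)) / approx50, 1e-4)
  expect_error(conc_profile_n_doses(-1, 5, 6, 60, 1, reg), "non-negative")
})

test_that("exposure metrics: AUC identity, peak maximality, analytic tmax", {
  p <- tibble::tibble(subject_id = "s", cl = 5.66, v = 150, ka = 1)
  m <- steady_state_metrics(p, reg)
  expect_equal(m$auc24, reg$amount_nmol / 5.66 / 1000)
  expect_equal(m$auc24, 41.50, tolerance = 1e-3)
  expect_equal(m$c24, conc_ss(24, 5.66, 150, 1, reg))
  expect_gte(m$cmax, m$c24)

  grid <- seq(0, 24, by = 1e-3)
  cg <- conc_ss(grid, 6, 60, 1, reg)
  m2 <- steady_state_metrics(tibble::tibble(cl = 6, v = 60, ka = 1), reg)
  expect_true(all(m2$cmax >= cg - 1e-9))
  # refine the argmax to a 1e-4 grid around the coarse peak
  t0 <- grid[which.max(cg)]
  fine <- seq(max(0, t0 - 2e-3), min(24, t0 + 2e-3), by = 1e-4)
  expect_lt(abs(m2$tmax - fine[which.max(conc_ss(fine, 6, 60, 1, reg))]), 2e-4)
})

test_that("trapezoidal AUC over the interval equals dose over clearance", {
  for (ke_tau in c(0.5, 2, 5)) {
    v <- 100; cl <- ke_tau / 24 * v
    tg <- seq(0, 24, length.out = 1e5)
    cc <- conc_ss(tg, cl, v, 1.4, reg)
    auc <- sum(diff(tg) * (cc[-1] + cc[-length(cc)]) / 2)
    expect_lt(abs(auc - reg$amount_nmol / cl) / (reg$amount_nmol / cl), 1e-4)
  }
})

test_that("the equal-rate limit is continuous and used when ka ~ ke", {
  cl <- 6; v <- 60; ke <- cl / v
  t <- c(1, 6, 12, 24)
  near <- conc_ss(t, cl, v, ke * (1 + 1e-6), reg)
  lim <- conc_ss(t, cl, v, ke, reg)     # triggers the limit branch
  expect_lt(max(abs(near - lim) / lim), 1e-4)
  m_near <- steady_state_metrics(tibble::tibble(cl = cl, v = v,
                                                ka = ke * (1 + 1e-6)), reg)
  m_lim <- steady_state_metrics(tibble::tibble(cl = cl, v = v, ka = ke), reg)
  expect_lt(abs(m_near$tmax - m_lim$tmax), 1e-3)
})

test_that("all metrics scale linearly with dose", {
  reg2 <- dosing_regimen(dose_mg = 200)
  m1 <- steady_state_metrics(tibble::tibble(cl = 6, v = 60, ka = 1), reg)
  m2 <- steady_state_metrics(tibble::tibble(cl = 6, v = 60, ka = 1), reg2)
  expect_equal(m2$auc24, 2 * m1$auc24)
  expect_equal(m2$cmax, 2 * m1$cmax)
  expect_equal(m2$c24, 2 * m1$c24)
  expect_equal(m2$tmax, m1$tmax)
})
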