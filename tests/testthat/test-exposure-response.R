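# helper: tibble of endpoints + matching exposures for constructed designs
two_level_design <- function(n_per = 100, resp1 = 90, resp2 = 90,
                             x = c(1, 2)) {
  ids <- sprintf("P%03d", seq_len(2 * n_per))
  endpoints <- tibble::tibble(
    subject_id = ids,
    response = c(rep(1L, resp1), rep(0L, n_per - resp1),
                 rep(1L, resp2), rep(0L, n_per - resp2)),
    excluded = FALSE, approach = "snapshot", threshold = 50
  )
  exposures <- tibble::tibble(subject_id = ids,
                              c24 = rep(x, each = n_per))
  list(endpoints = endpoints, exposures = exposures)
}

test_that("snapshot rule: observed below threshold responds, missing fails", {
  eff <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    week48_rna = c(35, 45, NA),
    disc_reason = c("none", "none", "other")
  )
  at50 <- classify_snapshot(eff, 50)
  expect_equal(at50$response, c(1L, 1L, 0L))
  expect_false(any(at50$excluded))
  at40 <- classify_snapshot(eff, 40)
  expect_equal(at40$response, c(1L, 0L, 0L))
  expect_error(classify_snapshot(eff, -1), "positive")
})

test_that("observed-failure rule: efficacy dropouts fail, others are excluded", {
  eff <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    week48_rna = c(60, NA, NA, 20),
    disc_reason = c("none", "lack_of_efficacy", "other", "none"),
    disc_week = c(NA, 30, 22, NA)
  )
  of <- classify_observed_failure(eff, 50)
  expect_equal(of$response, c(0L, 0L, NA_integer_, 1L))
  expect_equal(of$excluded, c(FALSE, FALSE, TRUE, FALSE))
  # intermittent missingness: excluded with a warning
  eff2 <- tibble::tibble(subject_id = "e", week48_rna = NA_real_,
                         disc_reason = "none")
  expect_warning(of2 <- classify_observed_failure(eff2, 50), "intermittent")
  expect_true(of2$excluded)
})

test_that("a flat two-level design recovers intercept logit(0.9) and slope 0", {
  d <- two_level_design(100, 90, 90)
  fit <- fit_er_model(d$endpoints, d$exposures, metric = "c24",
                      form = "linear")
  expect_equal(fit$slope, 0, tolerance = 1e-4)
  expect_equal(fit$intercept, qlogis(0.9), tolerance = 1e-4)
})

test_that("a two-level contrast recovers the logit difference as slope", {
  d <- two_level_design(100, 80, 95)
  fit <- fit_er_model(d$endpoints, d$exposures, metric = "c24",
                      form = "linear")
  expect_equal(fit$slope, qlogis(0.95) - qlogis(0.80), tolerance = 1e-3)
  expect_equal(fit$intercept, 2 * qlogis(0.8) - qlogis(0.95),
               tolerance = 1e-3)
  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "slope"], fit$slope)
  expect_true(fit$slope_ci95[1] < fit$slope && fit$slope < fit$slope_ci95[2])
})

test_that("an all-responder outcome raises the separation flag", {
  d <- two_level_design(50, 50, 50, x = c(1, 2))
  fit <- fit_er_model(d$endpoints, d$exposures, metric = "c24")
  expect_true(fit$separation)
  expect_true(is.na(fit$slope_p))
  expect_error(prediction_band(fit), "separation")
  # identical exposures are a design error
  d2 <- two_level_design(20, 18, 15, x = c(1, 1))
  expect_error(fit_er_model(d2$endpoints, d2$exposures, metric = "c24"),
               "distinct")
})

test_that("AIC comparison prefers the lower value and breaks ties to linear", {
  d <- two_level_design(100, 80, 95)
  lin <- fit_er_model(d$endpoints, d$exposures, metric = "c24",
                      form = "linear")
  lg <- fit_er_model(d$endpoints, d$exposures, metric = "c24", form = "log")
  cmp <- compare_models_aic(lin, lg)
  expect_equal(cmp$delta_aic, lin$aic - lg$aic)
  expect_equal(cmp$selected, if (cmp$delta_aic <= 0) "linear" else "log")
  # a two-level design is saturated under either transform: AIC ties, linear
  expect_equal(cmp$delta_aic, 0, tolerance = 1e-6)
  expect_equal(cmp$selected, "linear")
  d_sub <- two_level_design(50, 40, 48)
  lg2 <- fit_er_model(d_sub$endpoints, d_sub$exposures, metric = "c24",
                      form = "log")
  expect_error(compare_models_aic(lin, lg2), "same analysis set")
})

test_that("quartile summary: exact CIs and a partition of the analysis set", {
  set.seed(7)
  n <- 40
  ids <- sprintf("Q%02d", 1:n)
  ep <- tibble::tibble(subject_id = ids, response = 1L, excluded = FALSE,
                       approach = "snapshot", threshold = 50)
  ex <- tibble::tibble(subject_id = ids, c24 = rlnorm(n, 7, 0.3))
  q <- quartile_summary(ep, ex, "c24")
  expect_equal(sum(q$n), n)
  expect_true(all(q$proportion == 1))
  expect_true(all(q$conf.high == 1))

  # a quartile with 0 of 10 responders: Clopper-Pearson upper bound
  # 1 - 0.025^(1/10) = 0.3085
  ord <- ids[order(ex$c24)]
  ep0 <- dplyr::mutate(ep, response = ifelse(subject_id %in% ord[1:10], 0L, 1L))
  q0 <- quartile_summary(ep0, ex, "c24")
  expect_equal(q0$n[1], 10L)
  expect_equal(q0$responders[1], 0L)
  expect_equal(q0$conf.low[1], 0)
  expect_equal(q0$conf.high[1], 1 - 0.025^(1 / 10), tolerance = 1e-6)
  expect_equal(q0$conf.high[1], 0.3085, tolerance = 1e-4)

  # partition property under arbitrary exposure vectors (with ties)
  set.seed(123)
  for (i in 1:25) {
    nn <- sample(8:60, 1)
    idn <- sprintf("R%03d", seq_len(nn))
    epn <- tibble::tibble(subject_id = idn,
                          response = rbinom(nn, 1, 0.8), excluded = FALSE,
                          approach = "snapshot", threshold = 50)
    exn <- tibble::tibble(subject_id = idn,
                          c24 = sample(round(rlnorm(nn, 7, 0.4), -1)))
    qn <- quartile_summary(epn, exn, "c24")
    expect_equal(sum(qn$n), nn)
  }
})

test_that("prediction band stays in [0,1], tracks a flat fit, matches bootstrap", {
  d <- two_level_design(100, 90, 90)
  fit <- fit_er_model(d$endpoints, d$exposures, metric = "c24")
  band <- prediction_band(fit, grid = seq(1, 2, length.out = 21))
  expect_true(all(band$conf.low >= 0 & band$conf.high <= 1))
  expect_true(all(band$conf.low <= band$prediction &
                    band$prediction <= band$conf.high))
  # slope ~ 0: the point prediction is flat across the grid
  expect_lt(diff(range(band$prediction)), 1e-4)

  # delta-method half-width vs parametric bootstrap from the fitted vcov
  d2 <- two_level_design(100, 80, 95)
  fit2 <- fit_er_model(d2$endpoints, d2$exposures, metric = "c24")
  x0 <- mean(fit2$x)
  band0 <- prediction_band(fit2, grid = x0)
  set.seed(5)
  draws <- MASS::mvrnorm(2000, c(fit2$intercept, fit2$slope), fit2$vcov)
  eta <- draws[, 1] + draws[, 2] * x0
  bs <- quantile(plogis(eta), c(0.025, 0.975))
  hw_delta <- (band0$conf.high - band0$conf.low) / 2
  hw_bs <- (bs[2] - bs[1]) / 2
  expect_lt(abs(hw_delta - hw_bs) / hw_bs, 0.10)

  # extrapolation beyond the data support is flagged, not refused
  wide <- prediction_band(fit2, grid = c(0.5, 1.5, 3))
  expect_equal(wide$extrapolated, c(TRUE, FALSE, TRUE))
})

test_that("a known nonzero slope is covered by the 95% CI in most replicates", {
  set.seed(202)
  covered <- 0L
  b <- 1.2; a <- qlogis(0.75)
  for (r in 1:60) {
    x <- rlnorm(2000, 0, 0.4)
    y <- rbinom(2000, 1, plogis(a + b * (x - 1)))
    ids <- as.character(seq_along(x))
    ep <- tibble::tibble(subject_id = ids, response = y, excluded = FALSE,
                         approach = "snapshot", threshold = 50)
    ex <- tibble::tibble(subject_id = ids, c24 = x)
    f <- fit_er_model(ep, ex, metric = "c24", form = "linear")
    if (f$slope_ci95[1] <= b && b <= f$slope_ci95[2]) covered <- covered + 1L
  }
  expect_gte(covered / 60, 0.90)
})

test_that("snapshot responders never exceed observed-failure responders plus exclusions", {
  set.seed(77)
  for (i in 1:20) {
    n <- 60
    eff <- tibble::tibble(
      subject_id = sprintf("M%02d", 1:n),
      week48_rna = ifelse(runif(n) < 0.15, NA_real_,
                          floor(exp(runif(n, 0, 9)))),
      disc_reason = sample(c("none", "lack_of_efficacy", "other"), n,
                           replace = TRUE)
    )
    snap <- classify_snapshot(eff, 50)
    of <- suppressWarnings(classify_observed_failure(eff, 50))
    lhs <- sum(snap$response)
    rhs <- sum(of$response[!of$excluded]) + sum(of$excluded)
    expect_lte(lhs, rhs)
  }
})
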