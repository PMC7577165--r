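# Seeded generator of sparse-sampling switch-trial datasets with full
# generative truth, emulating an immediate-switch cohort on 100 mg once
# daily: ~443 HIV-positive virologically suppressed adults, PK samples at
# day 1 (predose), week 4 (predose), week 12 (any time after dose), and
# weeks 24/48 (predose + 0.5-2 h postdose), and a week-48 binary virologic
# endpoint generated from a configurable (default flat) exposure-response
# truth.

#' Simulation configuration
#'
#' The full generative truth for a synthetic trial: cohort size, the true
#' population model, covariate distributions, the dosing regimen, the sparse
#' sampling schedule and the efficacy model.
#'
#' Covariates: body weight is log-normal (median `weight_median`, geometric
#' CV `weight_cv`); age is a truncated normal on `age_bounds`. All subjects
#' are HIV-positive members of the immediate-switch group unless
#' `status`/`group` are overridden.
#'
#' Efficacy: the true response probability is
#' `plogis(qlogis(p_response) + er_slope * (x - x_ref))` where `x` is the
#' subject's true steady-state exposure (`er_metric`) and `x_ref` the
#' typical-subject value of that metric, so `p_response` is the responder
#' probability of the typical subject and `er_slope = 0` (the default) gives
#' a flat exposure-response. A fraction `missing_fraction` of subjects have
#' missing week-48 RNA, split between discontinuation for lack of efficacy
#' (`missing_loe_fraction`) and other reasons.
#'
#' @param n_subjects Number of subjects. Default 443.
#' @param seed Integer seed; every random draw of the generator flows from it.
#' @param true_model A [population_model()] used as generative truth.
#' @param regimen A [dosing_regimen()].
#' @param weight_median,weight_cv Weight distribution (kg, fraction).
#' @param age_mean,age_sd,age_bounds Age distribution (years).
#' @param status,group Cohort labels applied to all subjects.
#' @param p_response Typical-subject responder probability. Default 0.90.
#' @param er_slope True logit-slope per unit of `er_metric`. Default 0.
#' @param er_metric Metric driving efficacy: `"c24"`, `"auc24"` or `"cmax"`.
#' @param response_threshold RNA threshold (copies/ml) under which generated
#'   responder RNA values fall. Default 40 so that responders respond at
#'   both the 40 and 50 copies/ml analysis thresholds.
#' @param missing_fraction Fraction with missing week-48 RNA. Default 0.08.
#' @param missing_loe_fraction Of the missing, fraction discontinued for
#'   lack of efficacy. Default 0.4.
#' @param schedule Sampling design: a tibble with columns `visit`, `week`,
#'   `tad_lo`, `tad_hi` (hours after dose; equal bounds give a fixed time,
#'   unequal bounds a uniform draw) and `usable` (logical: enters the fit).
#'   `NULL` (default) means the sparse switch-trial design of
#'   [default_schedule()] at the regimen's dosing interval;
#'   [rich_schedule()] gives a dense steady-state profile per subject.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 443,
                              seed = 1L,
                              true_model = population_model(),
                              regimen = dosing_regimen(),
                              weight_median = 74, weight_cv = 0.20,
                              age_mean = 45, age_sd = 11,
                              age_bounds = c(18, 78),
                              status = "hiv", group = "ISG",
                              p_response = 0.90,
                              er_slope = 0,
                              er_metric = c("c24", "auc24", "cmax"),
                              response_threshold = 40,
                              missing_fraction = 0.08,
                              missing_loe_fraction = 0.4,
                              schedule = NULL) {
  er_metric <- match.arg(er_metric)
  if (is.null(schedule)) schedule <- default_schedule(tau = regimen$tau)
  needed <- c("visit", "week", "tad_lo", "tad_hi", "usable")
  if (!all(needed %in% names(schedule))) {
    stop("`schedule` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(schedule$tad_lo > schedule$tad_hi) ||
      any(schedule$tad_lo < 0) || any(schedule$tad_hi > regimen$tau)) {
    stop("schedule windows must satisfy 0 <= tad_lo <= tad_hi <= tau",
         call. = FALSE)
  }
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (p_response <= 0 || p_response >= 1) {
    stop("`p_response` must lie in (0, 1)", call. = FALSE)
  }
  if (missing_fraction < 0 || missing_fraction >= 1 ||
      missing_loe_fraction < 0 || missing_loe_fraction > 1) {
    stop("missingness fractions out of range", call. = FALSE)
  }
  if (age_bounds[1] >= age_bounds[2]) {
    stop("`age_bounds` must be increasing", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         true_model = true_model, regimen = regimen,
         weight_median = weight_median, weight_cv = weight_cv,
         age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
         status = status, group = group,
         p_response = p_response, er_slope = er_slope, er_metric = er_metric,
         response_threshold = response_threshold,
         missing_fraction = missing_fraction,
         missing_loe_fraction = missing_loe_fraction,
         schedule = schedule),
    class = "simulation_config"
  )
}

# Visit weeks and the dose hour of the visit day (doses at 0, 24, 48, ...).
visit_dose_time <- function(week) week * 7 * 24

#' Sampling designs
#'
#' `default_schedule()` is the sparse switch-trial design: day 1 predose
#' (recorded, concentration zero, not usable for fitting), week 4 predose
#' (trough, time after dose 24 h), week 12 at a uniform random time after
#' dose in `[0, 24]` h, and weeks 24 and 48 predose plus a post-dose sample
#' at a uniform random 0.5-2 h after dose. `rich_schedule()` is a dense
#' steady-state profile (default 8 fixed times spanning a dosing interval at
#' week 4) used for parameter-recovery studies.
#'
#' @param tau Dosing interval, hours.
#' @return A schedule tibble (`visit`, `week`, `tad_lo`, `tad_hi`, `usable`).
#' @export
default_schedule <- function(tau = 24) {
  tibble::tribble(
    ~visit, ~week, ~tad_lo, ~tad_hi, ~usable,
    "day1_predose", 0, 0, 0, FALSE,
    "week4_predose", 4, tau, tau, TRUE,
    "week12_anytime", 12, 0, tau, TRUE,
    "week24_predose", 24, tau, tau, TRUE,
    "week24_postdose", 24, 0.5, 2, TRUE,
    "week48_predose", 48, tau, tau, TRUE,
    "week48_postdose", 48, 0.5, 2, TRUE
  )
}

#' @rdname default_schedule
#' @param times Fixed sampling times after dose, hours.
#' @export
rich_schedule <- function(times = c(0.5, 1, 2, 4, 8, 12, 18, 24), tau = 24) {
  tibble::tibble(
    visit = sprintf("week4_t%g", times), week = 4,
    tad_lo = times, tad_hi = times, usable = TRUE
  )
}

#' Per-subject PK sampling schedule
#'
#' Draws the per-subject sampling times of the configured design: one row
#' per subject and schedule entry, with the time after dose fixed or drawn
#' uniformly from the entry's window.
#'
#' @param config A [simulation_config()].
#' @return Tibble (`subject_id`, `visit`, `week`, `time`, `time_after_dose`,
#'   `usable`), one row per scheduled sample, times in hours since first
#'   dose. Uses the current RNG state; seed via [simulate_trial()] or
#'   `set.seed()`.
#' @export
sampling_schedule <- function(config = simulation_config()) {
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  out <- purrr::pmap_dfr(config$schedule, function(visit, week, tad_lo,
                                                   tad_hi, usable) {
    tad <- if (tad_lo == tad_hi) rep(tad_lo, n) else stats::runif(n, tad_lo, tad_hi)
    tibble::tibble(
      subject_id = ids, visit = visit, week = week,
      time = visit_dose_time(week) + ifelse(week == 0, 0, tad),
      time_after_dose = tad, usable = usable
    )
  })
  # order rows chronologically within subject
  dplyr::arrange(out, .data$subject_id, .data$time)
}

#' Simulate a complete synthetic switch trial
#'
#' Draws covariates, individual parameters (log-normal random effects around
#' the covariate-adjusted typical values), sparse PK samples with combined
#' proportional/additive residual error (truncated at zero), and week-48
#' virologic outcomes from the configured exposure-response truth. The
#' generative truth (true individual parameters, true exposures, true
#' response probabilities) is returned alongside for recovery testing.
#'
#' @param config A [simulation_config()].
#' @return A list of class `dorapop_trial`: `records` and `subjects` (the
#'   [read_pk_dataset()] tibbles), `efficacy` (tibble `subject_id`,
#'   `week48_rna`, `disc_reason`, `disc_week`), `truth` (tibble of true
#'   `cl`, `v`, `ka`, `auc24`, `cmax`, `c24`, `tmax`, `p_response`,
#'   `eta_cl`, `eta_v`, `eta_ka`) and the `config`.
#' @export
simulate_trial <- function(config = simulation_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_subjects
  m <- config$true_model
  ids <- sprintf("S%04d", seq_len(n))
  ana <- analysis_config(regimen = config$regimen, seed = config$seed)

  subjects <- tibble::tibble(
    subject_id = ids,
    weight = stats::rlnorm(n, log(config$weight_median),
                           sqrt(log(1 + config$weight_cv^2))),
    age = rtruncnorm(n, config$age_mean, config$age_sd, config$age_bounds),
    status = config$status, group = config$group
  )

  typ <- typical_params(subjects, m$theta, ana)
  eta <- cbind(
    stats::rnorm(n, 0, sqrt(m$omega2[["cl"]])),
    stats::rnorm(n, 0, sqrt(m$omega2[["v"]])),
    stats::rnorm(n, 0, sqrt(m$omega2[["ka"]]))
  )
  params <- tibble::tibble(
    subject_id = ids,
    cl = typ$cl * exp(eta[, 1]), v = typ$v * exp(eta[, 2]),
    ka = typ$ka * exp(eta[, 3])
  )
  metrics <- steady_state_metrics(params, config$regimen)

  sched <- sampling_schedule(config)
  i <- match(sched$subject_id, ids)
  pred <- ifelse(
    sched$usable,
    conc_ss(pmin(sched$time_after_dose, config$regimen$tau),
            params$cl[i], params$v[i], params$ka[i], config$regimen),
    0
  )
  eps <- stats::rnorm(nrow(sched))
  dv <- pred * (1 + m$sigma_prop * eps) +
    m$sigma_add * stats::rnorm(nrow(sched))
  dv <- pmax(dv, 0)
  dv[!sched$usable] <- 0

  obs <- tibble::tibble(
    subject_id = sched$subject_id, time = sched$time,
    time_after_dose = sched$time_after_dose,
    amt = 0, dv = dv, evid = 0L, mdv = ifelse(sched$usable, 0L, 1L)
  )
  doses <- tibble::tibble(
    subject_id = ids, time = 0, time_after_dose = 0,
    amt = config$regimen$amount_nmol, dv = NA_real_, evid = 1L, mdv = 1L
  )
  records <- dplyr::bind_rows(doses, obs) |>
    dplyr::arrange(.data$subject_id, .data$time, dplyr::desc(.data$evid))

  # efficacy truth on the chosen exposure metric, centred at the typical
  # subject so p_response is the typical responder probability
  ref_sub <- tibble::tibble(subject_id = "ref", weight = ana$weight_ref,
                            age = ana$age_ref, status = "healthy")
  ref_par <- typical_params(ref_sub, m$theta, ana)
  x_ref <- steady_state_metrics(ref_par, config$regimen)[[config$er_metric]]
  x <- metrics[[config$er_metric]]
  p_true <- stats::plogis(stats::qlogis(config$p_response) +
                            config$er_slope * (x - x_ref))
  responder <- stats::rbinom(n, 1, p_true) == 1L

  missing <- stats::runif(n) < config$missing_fraction
  loe <- missing & (stats::runif(n) < config$missing_loe_fraction)
  thr <- config$response_threshold
  rna <- ifelse(responder, floor(stats::runif(n, 0, thr)),
                floor(exp(stats::runif(n, log(50), log(1e5)))))
  efficacy <- tibble::tibble(
    subject_id = ids,
    week48_rna = ifelse(missing, NA_real_, rna),
    disc_reason = dplyr::case_when(loe ~ "lack_of_efficacy",
                                   missing ~ "other",
                                   TRUE ~ "none"),
    disc_week = ifelse(missing, floor(stats::runif(n, 4, 45)), NA_real_)
  )

  truth <- dplyr::bind_cols(
    params,
    dplyr::select(metrics, -"subject_id"),
    tibble::tibble(p_response = p_true, eta_cl = eta[, 1], eta_v = eta[, 2],
                   eta_ka = eta[, 3])
  )
  structure(
    list(records = records, subjects = subjects, efficacy = efficacy,
         truth = truth, config = config),
    class = "dorapop_trial"
  )
}

rtruncnorm <- function(n, mean, sd, bounds) {
  lo <- stats::pnorm(bounds[1], mean, sd)
  hi <- stats::pnorm(bounds[2], mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write the simulated trial to disk
#'
#' Emits the PK dataset in the [read_pk_dataset()] CSV dialect, the efficacy
#' table as CSV and the generative truth as JSON.
#'
#' @param trial A `dorapop_trial` from [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pk = file.path(dir, "pk_dataset.csv"),
    efficacy = file.path(dir, "efficacy.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_pk_dataset(trial, paths[["pk"]])
  readr::write_csv(trial$efficacy, paths[["efficacy"]], na = ".",
                   progress = FALSE)
  jsonlite::write_json(
    list(config = list(n_subjects = trial$config$n_subjects,
                       seed = trial$config$seed,
                       er_slope = trial$config$er_slope,
                       p_response = trial$config$p_response),
         truth = trial$truth),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
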