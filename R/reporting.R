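# Exposure summary statistics and the end-to-end analysis pipeline.

#' Summary statistics of a positive exposure distribution
#'
#' Geometric mean `exp(mean(log x))`, geometric percent CV
#' `100 * sqrt(exp(sd(log x)^2) - 1)` (sample SD, n-1 denominator) and
#' linear-interpolation percentiles — the standard log-normal-flavoured
#' summaries of steady-state exposure metrics.
#'
#' @param values Positive numeric vector (one value per subject).
#' @param metric Label carried into the output (e.g. `"auc24"`).
#' @param probs Percentiles to report, in percent.
#' @return One-row tibble: `metric`, `n`, `geo_mean`, `geo_cv_pct` and one
#'   `p<q>` column per requested percentile.
#' @export
exposure_summary <- function(values, metric = "exposure",
                             probs = c(5, 25, 50, 75, 95)) {
  if (length(values) < 1L) stop("need at least one value", call. = FALSE)
  if (any(!is.finite(values) | values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0)
    stop("non-positive exposure value at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  lx <- log(values)
  sd_ln <- if (length(values) > 1L) stats::sd(lx) else 0
  pct <- percentile_summary(values, probs = probs)
  out <- tibble::tibble(
    metric = metric, n = length(values),
    geo_mean = exp(mean(lx)),
    geo_cv_pct = 100 * sqrt(exp(sd_ln^2) - 1)
  )
  dplyr::bind_cols(out, tibble::as_tibble(as.list(stats::setNames(
    pct, paste0("p", probs)
  ))))
}

#' Percentiles by linear interpolation
#'
#' @param values Numeric vector (n >= 1; n >= 2 for meaningful spread).
#' @param probs Percentiles in percent (0-100).
#' @return Named non-decreasing numeric vector.
#' @export
percentile_summary <- function(values, probs = c(5, 25, 50, 75, 95)) {
  if (length(values) < 1L) stop("empty input", call. = FALSE)
  stats::quantile(values, probs / 100, type = 7, names = TRUE)
}

#' Exposure summaries for all steady-state metrics
#'
#' @param metrics Tibble from [steady_state_metrics()].
#' @return Tibble with one row per metric (`auc24`, `cmax`, `c24`).
#' @export
summarize_exposures <- function(metrics) {
  dplyr::bind_rows(
    exposure_summary(metrics$auc24, "auc24"),
    exposure_summary(metrics$cmax, "cmax"),
    exposure_summary(metrics$c24, "c24")
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a trial, fit the population PK model, compute
#' empirical-Bayes individual parameters and steady-state exposures,
#' summarise the exposure distributions, build both week-48 endpoints at
#' both thresholds, fit linear and log exposure-response models for every
#' metric/endpoint combination, compare them by AIC, and summarise the
#' primary (C24, snapshot, <50 copies/ml) analysis with observed quartiles
#' and a model confidence band.
#'
#' @param sim_config A [simulation_config()] (simulation mode), or `NULL`
#'   when `dataset` is given.
#' @param dataset Optional list with `records`, `subjects`, `efficacy`
#'   tibbles to analyse instead of simulating.
#' @param config An [analysis_config()].
#' @param init Initial [population_model()] for the fit; defaults to the
#'   simulation truth in simulation mode and `population_model()` otherwise.
#' @param outdir Optional directory; when given, all artifacts (CSV/JSON
#'   tables, fit, run log) are written there.
#' @param fit_args Extra arguments passed to [fit_population()].
#' @return A list of class `dorapop_report`: `trial`, `fit`, `ebes`,
#'   `metrics`, `exposure_summary`, `endpoints`, `er_fits` (tibble with one
#'   row per metric x approach x threshold x form, including slope, CI, p,
#'   AIC), `aic_comparison`, `quartiles`, `band`, `log`.
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         dataset = NULL,
                         config = analysis_config(),
                         init = NULL,
                         outdir = NULL,
                         fit_args = list()) {
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  if (is.null(dataset)) {
    if (is.null(sim_config)) stop("need `sim_config` or `dataset`", call. = FALSE)
    config <- analysis_config(regimen = sim_config$regimen,
                              seed = sim_config$seed,
                              thresholds = config$thresholds,
                              inner_tol = config$inner_tol,
                              outer_tol = config$outer_tol,
                              max_iter = config$max_iter)
    note("simulating trial: n=%d, seed=%d", sim_config$n_subjects,
         sim_config$seed)
    trial <- simulate_trial(sim_config)
    if (is.null(init)) init <- sim_config$true_model
  } else {
    trial <- dataset
    if (is.null(init)) init <- population_model()
  }
  if (is.null(init)) init <- population_model()

  note("fitting population model (%d subjects)", nrow(trial$subjects))
  fit <- do.call(fit_population, c(
    list(records = trial$records, subjects = trial$subjects, init = init,
         config = config), fit_args
  ))
  note("fit %s: -2LL = %.2f", if (fit$converged) "converged" else "did not converge",
       fit$neg2ll)

  note("computing empirical-Bayes individual parameters")
  ebes <- empirical_bayes(fit$model, trial$records, trial$subjects, config)
  metrics <- steady_state_metrics(ebes$params, config$regimen)
  expo_sum <- summarize_exposures(metrics)

  note("classifying endpoints and fitting exposure-response models")
  grid <- tidyr::expand_grid(
    metric = c("auc24", "cmax", "c24"),
    approach = c("snapshot", "observed_failure"),
    threshold = config$thresholds,
    form = c("linear", "log")
  )
  endpoints <- purrr::map_dfr(unique(grid$threshold), function(thr) {
    dplyr::bind_rows(
      classify_snapshot(trial$efficacy, thr),
      suppressWarnings(classify_observed_failure(trial$efficacy, thr))
    )
  })
  er_fits <- purrr::pmap_dfr(grid, function(metric, approach, threshold, form) {
    ep <- dplyr::filter(endpoints, .data$approach == !!approach,
                        .data$threshold == !!threshold)
    f <- fit_er_model(ep, metrics, metric = metric, form = form)
    dplyr::bind_cols(
      tibble::tibble(metric = metric, approach = approach,
                     threshold = threshold, form = form),
      tibble::tibble(slope = f$slope, slope_se = f$slope_se,
                     conf.low = f$slope_ci95[1], conf.high = f$slope_ci95[2],
                     slope_p = f$slope_p, aic = f$aic, n = f$n,
                     n_response = f$n_response, separation = f$separation)
    )
  })
  aic_cmp <- er_fits |>
    dplyr::group_by(.data$metric, .data$approach, .data$threshold) |>
    dplyr::summarise(
      aic_linear = .data$aic[.data$form == "linear"],
      aic_log = .data$aic[.data$form == "log"],
      delta_aic = .data$aic_linear - .data$aic_log,
      selected = if (.data$delta_aic[1] <= 0) "linear" else "log",
      .groups = "drop"
    )

  primary_thr <- if (50 %in% config$thresholds) 50 else config$thresholds[1]
  ep50 <- dplyr::filter(endpoints, .data$approach == "snapshot",
                        .data$threshold == primary_thr)
  primary <- fit_er_model(ep50, metrics, metric = "c24", form = "linear")
  quart <- quartile_summary(ep50, metrics, metric = "c24")
  band <- prediction_band(primary)
  note("primary analysis (C24, snapshot, <%g): slope p = %.3f", primary_thr,
       primary$slope_p)

  report <- structure(
    list(trial = trial, fit = fit, ebes = ebes, metrics = metrics,
         exposure_summary = expo_sum, endpoints = endpoints,
         er_fits = er_fits, aic_comparison = aic_cmp,
         primary_fit = primary, quartiles = quart, band = band,
         config = config, log = log_lines),
    class = "dorapop_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.dorapop_report <- function(x, ...) {
  cat("dorapop analysis report\n")
  cat(sprintf("  %d subjects, fit -2LL = %.2f (%s)\n", x$fit$n_subjects,
              x$fit$neg2ll, if (x$fit$converged) "converged" else "not converged"))
  cat("  exposure summary:\n")
  print(as.data.frame(x$exposure_summary), digits = 4, row.names = FALSE)
  cat(sprintf("  primary ER (C24, snapshot): slope = %.3g [%.3g, %.3g], p = %.3f\n",
              x$primary_fit$slope, x$primary_fit$slope_ci95[1],
              x$primary_fit$slope_ci95[2], x$primary_fit$slope_p))
  invisible(x)
}

#' Write all report artifacts to a directory
#'
#' @param report A `dorapop_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(report$trial, "dorapop_trial")) {
    write_trial(report$trial, file.path(dir, "trial"))
  }
  readr::write_csv(report$metrics, file.path(dir, "exposure_metrics.csv"),
                   progress = FALSE)
  readr::write_csv(report$exposure_summary,
                   file.path(dir, "exposure_summary.csv"), progress = FALSE)
  readr::write_csv(report$endpoints, file.path(dir, "endpoints.csv"),
                   na = ".", progress = FALSE)
  readr::write_csv(report$er_fits, file.path(dir, "er_fits.csv"),
                   progress = FALSE)
  readr::write_csv(report$aic_comparison, file.path(dir, "aic_comparison.csv"),
                   progress = FALSE)
  readr::write_csv(report$quartiles, file.path(dir, "quartile_summary.csv"),
                   progress = FALSE)
  readr::write_csv(report$band, file.path(dir, "prediction_band.csv"),
                   progress = FALSE)
  write_fit_json(report$fit, file.path(dir, "fit.json"))
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
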