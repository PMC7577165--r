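# Week-48 binary virologic endpoints and exposure-response analysis.

#' Classify week-48 virologic response
#'
#' Two endpoint rules for the binary "HIV-1 RNA below threshold at week 48"
#' outcome:
#'
#' * **snapshot** (the regulatory primary rule): a subject responds iff the
#'   week-48 RNA is observed and below the threshold; any missing value is a
#'   failure. No subject is excluded.
#' * **observed failure**: observed RNA is compared with the threshold;
#'   subjects with monotone missing data who discontinued for lack of
#'   efficacy count as failures, while subjects missing for any other reason
#'   are excluded from the analysis set. Missing values without a recorded
#'   discontinuation (intermittent missingness) are excluded with a warning,
#'   since the rule defines only the monotone case.
#'
#' @param efficacy Tibble with columns `subject_id`, `week48_rna` (copies/ml,
#'   `NA` when missing) and, for the observed-failure rule, `disc_reason`
#'   (`"none"`, `"lack_of_efficacy"`, `"other"`).
#' @param threshold Response threshold in copies/ml (40 or 50).
#' @return Tibble (`subject_id`, `response` (0/1, `NA` when excluded),
#'   `excluded`, `approach`, `threshold`).
#' @export
classify_snapshot <- function(efficacy, threshold = 50) {
  check_threshold(threshold)
  tibble::tibble(
    subject_id = efficacy$subject_id,
    response = as.integer(!is.na(efficacy$week48_rna) &
                            efficacy$week48_rna < threshold),
    excluded = FALSE,
    approach = "snapshot",
    threshold = threshold
  )
}

#' @rdname classify_snapshot
#' @export
classify_observed_failure <- function(efficacy, threshold = 50) {
  check_threshold(threshold)
  rna <- efficacy$week48_rna
  reason <- efficacy$disc_reason %||% rep("none", length(rna))
  response <- dplyr::case_when(
    !is.na(rna) ~ as.integer(rna < threshold),
    reason == "lack_of_efficacy" ~ 0L,
    TRUE ~ NA_integer_
  )
  intermittent <- is.na(rna) & reason == "none"
  if (any(intermittent)) {
    warning(sum(intermittent), " subject(s) with missing week-48 RNA and no ",
            "discontinuation record excluded (intermittent missingness)",
            call. = FALSE)
  }
  tibble::tibble(
    subject_id = efficacy$subject_id,
    response = response,
    excluded = is.na(response),
    approach = "observed_failure",
    threshold = threshold
  )
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("`threshold` must be a single positive number of copies/ml",
         call. = FALSE)
  }
  invisible(threshold)
}

#' Fit a binary exposure-response model
#'
#' Maximum-likelihood logistic regression of week-48 response on a
#' steady-state exposure metric, `logit P(response) = alpha + beta * g(x)`
#' with `g` the identity (`form = "linear"`) or the natural log
#' (`form = "log"`). A linear-probability variant (identity link on the
#' probability scale) is available via `link = "identity"`. Inference on the
#' slope is Wald by default (estimate ± 1.96 SE; two-sided p), with a
#' likelihood-ratio p-value as an option.
#'
#' @param endpoints Endpoint tibble from [classify_snapshot()] or
#'   [classify_observed_failure()]; excluded subjects are dropped.
#' @param exposures Tibble with `subject_id` and the exposure metric columns
#'   (as produced by [steady_state_metrics()]).
#' @param metric Which exposure metric to use: `"auc24"`, `"cmax"` or
#'   `"c24"`.
#' @param form `"linear"` (exposure enters untransformed) or `"log"`.
#' @param link `"logit"` (default) or `"identity"` (linear-probability).
#' @param p_method `"wald"` or `"lr"`.
#' @return An object of class `er_fit`: list with `intercept`, `slope`,
#'   `vcov` (2x2), `aic`, `slope_ci95`, `slope_p`, `slope_se`, `metric`,
#'   `form`, `n`, `n_response`, `separation` flag, the exposure vector `x`
#'   used, and the underlying `glm` object.
#' @export
fit_er_model <- function(endpoints, exposures,
                         metric = c("c24", "auc24", "cmax"),
                         form = c("linear", "log"),
                         link = c("logit", "identity"),
                         p_method = c("wald", "lr")) {
  metric <- match.arg(metric)
  form <- match.arg(form)
  link <- match.arg(link)
  p_method <- match.arg(p_method)
  d <- er_analysis_set(endpoints, exposures, metric)
  if (length(unique(d$x)) < 2L) {
    stop("need at least 2 distinct exposure values", call. = FALSE)
  }
  if (form == "log" && any(d$x <= 0)) {
    stop("log exposure form requires positive exposures", call. = FALSE)
  }
  d$g <- if (form == "log") log(d$x) else d$x

  separation <- length(unique(d$response)) < 2L
  fam <- if (link == "logit") stats::binomial() else
    stats::binomial(link = "identity")
  start <- if (link == "identity") c(mean(d$response), 0) else NULL
  w <- withCallingHandlers(
    {
      glm_fit <- suppressWarnings(
        stats::glm(response ~ g, family = fam, data = d, start = start)
      )
      NULL
    },
    warning = function(w) invokeRestart("muffleWarning")
  )
  probs <- stats::fitted(glm_fit)
  if (!glm_fit$converged || any(probs > 1 - 1e-10) || any(probs < 1e-10)) {
    separation <- TRUE
  }
  co <- stats::coef(glm_fit)
  vc <- stats::vcov(glm_fit)
  slope <- unname(co[2L])
  se <- sqrt(vc[2L, 2L])
  if (separation) {
    ci <- c(NA_real_, NA_real_)
    p <- NA_real_
  } else if (p_method == "wald") {
    ci <- slope + c(-1, 1) * 1.96 * se
    p <- 2 * stats::pnorm(-abs(slope / se))
  } else {
    null_fit <- stats::glm(response ~ 1, family = fam, data = d)
    p <- stats::pchisq(null_fit$deviance - glm_fit$deviance, df = 1,
                       lower.tail = FALSE)
    ci <- slope + c(-1, 1) * 1.96 * se
  }
  structure(
    list(
      intercept = unname(co[1L]), slope = slope, vcov = vc,
      aic = stats::AIC(glm_fit), slope_ci95 = ci, slope_p = p, slope_se = se,
      metric = metric, form = form, link = link, p_method = p_method,
      n = nrow(d), n_response = sum(d$response), separation = separation,
      x = d$x, subject_ids = d$subject_id, glm = glm_fit
    ),
    class = "er_fit"
  )
}

er_analysis_set <- function(endpoints, exposures, metric) {
  if (!metric %in% names(exposures)) {
    stop("exposure metric `", metric, "` not found in `exposures`",
         call. = FALSE)
  }
  endpoints |>
    dplyr::filter(!.data$excluded) |>
    dplyr::inner_join(exposures, by = "subject_id") |>
    dplyr::transmute(.data$subject_id, .data$response,
                     x = .data[[metric]]) |>
    dplyr::filter(!is.na(.data$x))
}

#' @export
print.er_fit <- function(x, ...) {
  cat(sprintf("Exposure-response fit: %s, %s exposure, %s link (n=%d, %d responders)\n",
              x$metric, x$form, x$link, x$n, x$n_response))
  if (x$separation) cat("  WARNING: separation/degenerate outcome; no Wald inference\n")
  cat(sprintf("  slope = %.4g [%.4g, %.4g], p = %.4g; AIC = %.2f\n",
              x$slope, x$slope_ci95[1], x$slope_ci95[2], x$slope_p, x$aic))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname fit_er_model
#' @param x An `er_fit`.
#' @param ... Unused.
tidy.er_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(sqrt(x$vcov[1, 1]), x$slope_se),
    conf.low = c(NA_real_, x$slope_ci95[1]),
    conf.high = c(NA_real_, x$slope_ci95[2]),
    p.value = c(NA_real_, x$slope_p)
  )
}

#' @exportS3Method generics::glance
#' @rdname fit_er_model
glance.er_fit <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, form = x$form, aic = x$aic, n = x$n,
    n_response = x$n_response, slope = x$slope, slope_p = x$slope_p,
    separation = x$separation
  )
}

#' Compare linear and log exposure-response fits by AIC
#'
#' @param fit_linear,fit_log Converged [fit_er_model()] results for the same
#'   endpoint analysis set.
#' @return Tibble (`aic_linear`, `aic_log`, `delta_aic`
#'   (= linear - log), `selected`). The lower-AIC form is selected; ties go
#'   to the linear form.
#' @export
compare_models_aic <- function(fit_linear, fit_log) {
  same <- fit_linear$n == fit_log$n &&
    setequal(fit_linear$subject_ids, fit_log$subject_ids)
  if (!same) {
    stop("fits were not computed on the same analysis set", call. = FALSE)
  }
  delta <- fit_linear$aic - fit_log$aic
  tibble::tibble(
    aic_linear = fit_linear$aic, aic_log = fit_log$aic,
    delta_aic = delta,
    selected = if (delta <= 0) "linear" else "log"
  )
}

#' Observed response by exposure quartile
#'
#' Splits the non-excluded analysis set at the 25th/50th/75th exposure
#' percentiles (linear-interpolation quantiles; values tied with a boundary
#' go to the lower quartile) and summarises the observed responder
#' proportion per quartile with an exact Clopper-Pearson 95% CI.
#'
#' @inheritParams fit_er_model
#' @return Tibble (`quartile`, `n`, `responders`, `proportion`,
#'   `conf.low`, `conf.high`, `exposure_median`). Empty quartiles (possible
#'   with heavy ties) are reported with `n = 0` and `NA` elsewhere.
#' @export
quartile_summary <- function(endpoints, exposures,
                             metric = c("c24", "auc24", "cmax")) {
  metric <- match.arg(metric)
  d <- er_analysis_set(endpoints, exposures, metric)
  if (nrow(d) < 8L) stop("need at least 8 non-excluded subjects", call. = FALSE)
  qs <- stats::quantile(d$x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  breaks <- unique(c(-Inf, qs, Inf))
  d$quartile <- cut(d$x, breaks = breaks, labels = FALSE, right = TRUE)
  purrr::map_dfr(seq_len(length(breaks) - 1L), function(q) {
    di <- d[d$quartile == q, ]
    n <- nrow(di)
    if (n == 0L) {
      return(tibble::tibble(quartile = q, n = 0L, responders = NA_integer_,
                            proportion = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_, exposure_median = NA_real_))
    }
    s <- sum(di$response)
    tibble::tibble(
      quartile = q, n = n, responders = s, proportion = s / n,
      conf.low = if (s == 0) 0 else stats::qbeta(0.025, s, n - s + 1),
      conf.high = if (s == n) 1 else stats::qbeta(0.975, s + 1, n - s),
      exposure_median = stats::median(di$x)
    )
  })
}

#' Model-predicted response with a 95% confidence band
#'
#' Evaluates the fitted exposure-response curve on a grid (by default 100
#' points spanning the 5th to 95th percentiles of the exposures used in the
#' fit) with a delta-method 95% CI: the linear predictor's SE from the
#' coefficient covariance, the band `inverse-link(eta ± 1.96 SE)`.
#'
#' @param fit A converged [fit_er_model()].
#' @param grid Optional numeric vector of exposure values. Values outside the
#'   range of the data used in the fit are flagged in the `extrapolated`
#'   column.
#' @return Tibble (`exposure`, `prediction`, `conf.low`, `conf.high`,
#'   `extrapolated`).
#' @export
prediction_band <- function(fit, grid = NULL) {
  if (fit$separation) {
    stop("no confidence band for a fit flagged with separation", call. = FALSE)
  }
  if (is.null(grid)) {
    lim <- stats::quantile(fit$x, c(0.05, 0.95), type = 7, names = FALSE)
    grid <- seq(lim[1], lim[2], length.out = 100L)
  }
  g <- if (fit$form == "log") log(grid) else grid
  eta <- fit$intercept + fit$slope * g
  se <- sqrt(fit$vcov[1, 1] + 2 * g * fit$vcov[1, 2] + g^2 * fit$vcov[2, 2])
  inv <- if (fit$link == "logit") stats::plogis else function(z) pmin(pmax(z, 0), 1)
  tibble::tibble(
    exposure = grid,
    prediction = inv(eta),
    conf.low = inv(eta - 1.96 * se),
    conf.high = inv(eta + 1.96 * se),
    extrapolated = grid < min(fit$x) | grid > max(fit$x)
  )
}
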