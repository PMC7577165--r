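#' Typical individual parameters from covariates
#'
#' Applies the covariate submodel to each subject:
#' \deqn{CL/F = TVCL \cdot (age/age_{ref})^{\beta_{age,CL}}}
#' \deqn{V/F  = TVV \cdot (weight/weight_{ref})^{\beta_{wt,V}} \cdot
#'   \beta_{hiv,V}^{[status = hiv]}}
#' \deqn{ka = TVKA}
#' Weight and infection status act only on V/F; age acts only on CL/F.
#'
#' @param subjects Tibble with columns `subject_id`, `weight`, `age`, `status`.
#' @param theta A [theta_vector()].
#' @param config An [analysis_config()] supplying the reference covariates.
#' @return Tibble with columns `subject_id`, `cl`, `v`, `ka`.
#' @export
typical_params <- function(subjects, theta = theta_vector(),
                           config = analysis_config()) {
  if (any(!is.finite(subjects$weight) | subjects$weight <= 0) ||
      any(!is.finite(subjects$age) | subjects$age <= 0)) {
    stop("subject covariates must be finite and positive", call. = FALSE)
  }
  th <- unclass(theta)
  tibble::tibble(
    subject_id = subjects$subject_id,
    cl = th[["tvcl"]] * (subjects$age / config$age_ref)^th[["beta_age_cl"]],
    v = th[["tvv"]] * (subjects$weight / config$weight_ref)^th[["beta_wt_v"]] *
      ifelse(subjects$status == "hiv", th[["beta_hiv_v"]], 1),
    ka = rep(th[["tvka"]], nrow(subjects))
  )
}

# Relative ka-vs-ke closeness below which the equal-rate limit branch is used.
.equal_rate_tol <- 1e-8

#' Steady-state concentration of the one-compartment oral model
#'
#' Closed-form concentration at time `t` after a dose, under repeated dosing
#' every `tau` hours at steady state:
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_e)} \left[
#'   \frac{e^{-k_e t}}{1 - e^{-k_e \tau}} -
#'   \frac{e^{-k_a t}}{1 - e^{-k_a \tau}} \right], \quad k_e = CL/V.}
#' When `ka` is within relative tolerance 1e-8 of `ke` the exact equal-rate
#' limit is used:
#' \deqn{C(t) = \frac{D k}{V} e^{-k t} \left[ \frac{t}{1-r} +
#'   \frac{\tau r}{(1-r)^2} \right], \quad r = e^{-k\tau}.}
#' With `D` in nmol and `V` in litres the result is in nM. All numeric
#' arguments are vectorised and recycled.
#'
#' @param t_after_dose Time since the most recent dose, hours, in `[0, tau]`.
#' @param cl,v,ka Individual apparent clearance (L/h), apparent volume (L)
#'   and absorption rate (1/h).
#' @param regimen A [dosing_regimen()].
#' @return Concentration in nM.
#' @export
conc_ss <- function(t_after_dose, cl, v, ka, regimen = dosing_regimen()) {
  tau <- regimen$tau
  if (any(t_after_dose < 0 | t_after_dose > tau)) {
    stop("`t_after_dose` must lie in [0, tau]", call. = FALSE)
  }
  if (any(cl <= 0) || any(v <= 0) || any(ka <= 0)) {
    stop("cl, v and ka must be positive", call. = FALSE)
  }
  d <- regimen$amount_nmol
  n <- max(length(t_after_dose), length(cl), length(v), length(ka))
  t <- rep_len(t_after_dose, n)
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  ke <- cl / v
  out <- numeric(n)
  eq <- abs(ka - ke) <= .equal_rate_tol * pmax(ka, ke)
  if (any(!eq)) {
    i <- !eq
    out[i] <- d * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * t[i]) / (1 - exp(-ke[i] * tau)) -
         exp(-ka[i] * t[i]) / (1 - exp(-ka[i] * tau)))
  }
  if (any(eq)) {
    i <- eq
    k <- ke[i]
    r <- exp(-k * tau)
    out[i] <- d * k / v[i] * exp(-k * t[i]) *
      (t[i] / (1 - r) + tau * r / (1 - r)^2)
  }
  pmax(out, 0)
}

#' Concentration after a finite number of repeated doses
#'
#' Superposition of single-dose profiles for doses given at
#' `0, tau, ..., (n_doses - 1) * tau`, evaluated at time `t` since the first
#' dose. Converges to [conc_ss()] at `t mod tau` as `n_doses` grows.
#'
#' @param t Time since the first dose, hours (>= 0); vectorised.
#' @param n_doses Number of doses administered (>= 1).
#' @inheritParams conc_ss
#' @return Concentration in nM.
#' @export
conc_profile_n_doses <- function(t, n_doses, cl, v, ka,
                                 regimen = dosing_regimen()) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (n_doses < 1) stop("`n_doses` must be >= 1", call. = FALSE)
  tau <- regimen$tau
  n <- max(length(t), length(cl), length(v), length(ka))
  t <- rep_len(t, n)
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  out <- numeric(n)
  for (m in seq_len(n_doses) - 1L) {
    td <- t - m * tau
    active <- td >= 0
    if (!any(active)) next
    out[active] <- out[active] +
      conc_single_dose(td[active], cl[active], v[active], ka[active], regimen)
  }
  out
}

# Single oral dose at t = 0; standard Bateman form with equal-rate limit.
conc_single_dose <- function(t, cl, v, ka, regimen) {
  d <- regimen$amount_nmol
  ke <- cl / v
  eq <- abs(ka - ke) <= .equal_rate_tol * pmax(ka, ke)
  out <- numeric(length(t))
  if (any(!eq)) {
    i <- !eq
    out[i] <- d * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * t[i]) - exp(-ka[i] * t[i]))
  }
  if (any(eq)) {
    i <- eq
    out[i] <- d * ke[i] / v[i] * t[i] * exp(-ke[i] * t[i])
  }
  pmax(out, 0)
}

#' Steady-state exposure metrics per subject
#'
#' For each row of individual parameters computes the steady-state metrics of
#' a dosing interval: `auc24 = D / CL` (reported in uM*h), the time of the
#' concentration peak
#' \deqn{t_{max} = \frac{\ln\left[k_a (1 - e^{-k_e\tau}) / (k_e (1 -
#'   e^{-k_a\tau}))\right]}{k_a - k_e},}
#' `cmax = conc_ss(tmax)` and the trough `c24 = conc_ss(tau)` (both nM).
#'
#' @param params Tibble with columns `cl`, `v`, `ka` and optionally
#'   `subject_id` (carried through).
#' @param regimen A [dosing_regimen()].
#' @return Tibble with columns (`subject_id`,) `auc24`, `cmax`, `c24`, `tmax`.
#' @export
steady_state_metrics <- function(params, regimen = dosing_regimen()) {
  cl <- params$cl; v <- params$v; ka <- params$ka
  if (any(cl <= 0) || any(v <= 0) || any(ka <= 0)) {
    stop("individual parameters must be positive", call. = FALSE)
  }
  tau <- regimen$tau
  d <- regimen$amount_nmol
  ke <- cl / v
  eq <- abs(ka - ke) <= .equal_rate_tol * pmax(ka, ke)
  tmax <- numeric(length(cl))
  tmax[!eq] <- log(ka[!eq] * (1 - exp(-ke[!eq] * tau)) /
                     (ke[!eq] * (1 - exp(-ka[!eq] * tau)))) / (ka[!eq] - ke[!eq])
  if (any(eq)) {
    k <- ke[eq]
    r <- exp(-k * tau)
    tmax[eq] <- 1 / k - tau * r / (1 - r)
  }
  tmax <- pmin(pmax(tmax, 0), tau)
  out <- tibble::tibble(
    auc24 = d / cl / 1000,
    cmax = conc_ss(tmax, cl, v, ka, regimen),
    c24 = conc_ss(rep(tau, length(cl)), cl, v, ka, regimen),
    tmax = tmax
  )
  if ("subject_id" %in% names(params)) {
    out <- dplyr::bind_cols(tibble::tibble(subject_id = params$subject_id), out)
  }
  out
}
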