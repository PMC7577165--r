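#' Dosing regimen
#'
#' Describes a repeated oral dosing regimen. Dose amounts are stored in mg and
#' converted to nmol through the molecular weight so that, with volumes in
#' litres, concentrations emerge in nM and AUC in nM*h.
#'
#' @param dose_mg Dose per administration, mg. Default 100 mg.
#' @param tau Dosing interval, hours. Default 24 h (once daily).
#' @param molecular_weight Molecular weight, g/mol. Default 425.75 g/mol
#'   (doravirine free base); override for other compounds or salt forms.
#' @return An object of class `dosing_regimen`: a list with elements
#'   `dose_mg`, `tau`, `molecular_weight` and the derived `amount_nmol`.
#' @examples
#' dosing_regimen()            # 100 mg once daily
#' dosing_regimen(50, tau = 12)
#' @export
dosing_regimen <- function(dose_mg = 100, tau = 24, molecular_weight = 425.75) {
  if (!is.numeric(dose_mg) || length(dose_mg) != 1 || !is.finite(dose_mg) || dose_mg <= 0) {
    stop("`dose_mg` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single positive number of hours", call. = FALSE)
  }
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1 ||
      !is.finite(molecular_weight) || molecular_weight <= 0) {
    stop("`molecular_weight` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      dose_mg = dose_mg,
      tau = tau,
      molecular_weight = molecular_weight,
      amount_nmol = dose_to_amount(dose_mg, molecular_weight)
    ),
    class = "dosing_regimen"
  )
}

#' Convert a dose in mg to a molar amount in nmol
#'
#' `amount_nmol = dose_mg / molecular_weight * 1e6`. The factor 1e6 carries
#' mg/(g/mol) = mmol to nmol.
#'
#' @param dose_mg Dose in mg, or a `dosing_regimen` object.
#' @param molecular_weight Molecular weight in g/mol (ignored when `dose_mg`
#'   is a regimen).
#' @return Amount in nmol.
#' @examples
#' dose_to_amount(100, 425.75)   # ~234881 nmol
#' @export
dose_to_amount <- function(dose_mg, molecular_weight = 425.75) {
  if (inherits(dose_mg, "dosing_regimen")) {
    molecular_weight <- dose_mg$molecular_weight
    dose_mg <- dose_mg$dose_mg
  }
  if (any(!is.finite(dose_mg)) || any(dose_mg <= 0)) {
    stop("dose must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(molecular_weight)) || any(molecular_weight <= 0)) {
    stop("molecular weight must be positive and finite", call. = FALSE)
  }
  dose_mg / molecular_weight * 1e6
}

#' Analysis configuration
#'
#' Bundles the constants shared by every stage of the analysis: the dosing
#' regimen, covariate reference values used by the covariate submodel,
#' optimisation tolerances, endpoint thresholds and the random seed.
#'
#' @param regimen A [dosing_regimen()].
#' @param weight_ref Reference body weight, kg. Covariate effects on V/F are
#'   expressed relative to this weight. Default 70 kg.
#' @param age_ref Reference age, years; covariate effects on CL/F are relative
#'   to it. Default 45 years (the generator's median age).
#' @param thresholds HIV-1 RNA response thresholds, copies/ml. Default c(40, 50).
#' @param inner_tol Convergence tolerance (gradient norm) of the per-subject
#'   random-effect mode search. Default 1e-10.
#' @param outer_tol Relative tolerance on the marginal objective for the
#'   population fit. Default 1e-8.
#' @param max_iter Iteration cap for the population optimiser. Default 500.
#' @param seed Integer seed used by simulation helpers when no seed is given
#'   explicitly.
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(regimen = dosing_regimen(),
                            weight_ref = 70,
                            age_ref = 45,
                            thresholds = c(40, 50),
                            inner_tol = 1e-10,
                            outer_tol = 1e-8,
                            max_iter = 500,
                            seed = 20201) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (weight_ref <= 0 || age_ref <= 0) {
    stop("reference covariate values must be positive", call. = FALSE)
  }
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  structure(
    list(
      regimen = regimen,
      weight_ref = weight_ref,
      age_ref = age_ref,
      thresholds = thresholds,
      inner_tol = inner_tol,
      outer_tol = outer_tol,
      max_iter = max_iter,
      seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' Fixed-effect (theta) vector of the population model
#'
#' Typical-value parameters of the one-compartment model together with the
#' covariate coefficients: a power of body weight and a healthy-vs-HIV factor
#' on apparent volume, and a power of age on apparent clearance.
#'
#' @param tvcl Typical apparent clearance CL/F, L/h.
#' @param tvv Typical apparent volume V/F, L.
#' @param tvka Typical first-order absorption rate ka, 1/h.
#' @param beta_wt_v Weight exponent on V/F (dimensionless).
#' @param beta_hiv_v Multiplicative factor on V/F for HIV-positive status
#'   (dimensionless, > 0; 1 = no effect).
#' @param beta_age_cl Age exponent on CL/F (dimensionless).
#' @return A named numeric vector of class `theta_vector`.
#' @export
theta_vector <- function(tvcl = 5.66, tvv = 150, tvka = 1,
                         beta_wt_v = 1, beta_hiv_v = 1, beta_age_cl = -0.25) {
  if (tvcl <= 0 || tvv <= 0 || tvka <= 0) {
    stop("typical CL/F, V/F and ka must be positive", call. = FALSE)
  }
  if (beta_hiv_v <= 0) stop("`beta_hiv_v` must be positive", call. = FALSE)
  structure(
    c(tvcl = tvcl, tvv = tvv, tvka = tvka,
      beta_wt_v = beta_wt_v, beta_hiv_v = beta_hiv_v, beta_age_cl = beta_age_cl),
    class = "theta_vector"
  )
}

#' Population PK model
#'
#' Fixed effects, between-subject variances of log-normal random effects on
#' CL/F, V/F and ka (diagonal Omega), and a combined proportional + additive
#' residual-error model: `sd(obs) = sqrt(sigma_add^2 + (sigma_prop * pred)^2)`.
#'
#' @param theta A [theta_vector()].
#' @param omega2 Named numeric vector of between-subject variances
#'   `c(cl = , v = , ka = )` on the log scale; entries must be >= 0 (0 switches
#'   that random effect off).
#' @param sigma_prop Proportional residual SD (dimensionless).
#' @param sigma_add Additive residual SD, nM (may be 0).
#' @return An object of class `population_model`.
#' @export
population_model <- function(theta = theta_vector(),
                             omega2 = c(cl = 0.23^2, v = 0.15^2, ka = 0.45^2),
                             sigma_prop = 0.2,
                             sigma_add = 0) {
  if (!inherits(theta, "theta_vector")) theta <- do.call(theta_vector, as.list(theta))
  omega2 <- omega2[c("cl", "v", "ka")]
  if (anyNA(omega2)) stop("`omega2` must be named c(cl=, v=, ka=)", call. = FALSE)
  if (any(omega2 < 0)) stop("`omega2` entries must be >= 0", call. = FALSE)
  # both SDs may be zero for a noise-free generative model; estimation
  # requires a positive residual error and checks separately
  if (sigma_prop < 0 || sigma_add < 0) stop("residual SDs must be >= 0", call. = FALSE)
  structure(
    list(theta = theta, omega2 = omega2,
         sigma_prop = sigma_prop, sigma_add = sigma_add),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (one compartment, first-order absorption)\n")
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), unclass(x$theta)),
                        collapse = ", "), "\n")
  cat("  omega2:", paste(sprintf("%s=%.4g", names(x$omega2), x$omega2),
                         collapse = ", "), "\n")
  cat(sprintf("  residual: sigma_prop=%.4g, sigma_add=%.4g\n",
              x$sigma_prop, x$sigma_add))
  invisible(x)
}

#' Read or write an analysis/simulation configuration as YAML
#'
#' The YAML mirrors the constructors: top-level keys `regimen`,
#' `weight_ref`, `age_ref`, `thresholds`, tolerances and seed, plus an
#' optional `simulation` block mirroring [simulation_config()].
#'
#' @param path File path to a YAML configuration.
#' @return For `read_config()`, a list with elements `analysis`
#'   (an `analysis_config`) and, when a `simulation` block is present,
#'   `simulation` (a `simulation_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  reg <- do.call(dosing_regimen, raw$regimen %||% list())
  ana_args <- raw[intersect(names(raw), c("weight_ref", "age_ref", "thresholds",
                                          "inner_tol", "outer_tol", "max_iter", "seed"))]
  ana <- do.call(analysis_config, c(list(regimen = reg), ana_args))
  out <- list(analysis = ana)
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    if (!is.null(sim$true_model)) {
      tm <- sim$true_model
      theta <- do.call(theta_vector, tm$theta %||% list())
      sim$true_model <- population_model(
        theta = theta,
        omega2 = unlist(tm$omega2 %||% list(cl = 0.23^2, v = 0.15^2, ka = 0.45^2)),
        sigma_prop = tm$sigma_prop %||% 0.2,
        sigma_add = tm$sigma_add %||% 0
      )
    }
    out$simulation <- do.call(simulation_config,
                              c(sim, list(regimen = reg))[unique(c(names(sim), "regimen"))])
  }
  out
}

#' @rdname read_config
#' @param config A list as returned by [read_config()], or an
#'   `analysis_config`.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "analysis_config")) config <- list(analysis = config)
  ana <- config$analysis
  raw <- list(
    regimen = list(dose_mg = ana$regimen$dose_mg, tau = ana$regimen$tau,
                   molecular_weight = ana$regimen$molecular_weight),
    weight_ref = ana$weight_ref, age_ref = ana$age_ref,
    thresholds = ana$thresholds,
    inner_tol = ana$inner_tol, outer_tol = ana$outer_tol,
    max_iter = ana$max_iter, seed = ana$seed
  )
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    raw$simulation <- list(
      n_subjects = sim$n_subjects,
      seed = sim$seed,
      true_model = list(
        theta = as.list(unclass(sim$true_model$theta)),
        omega2 = as.list(sim$true_model$omega2),
        sigma_prop = sim$true_model$sigma_prop,
        sigma_add = sim$true_model$sigma_add
      ),
      weight_median = sim$weight_median, weight_cv = sim$weight_cv,
      age_mean = sim$age_mean, age_sd = sim$age_sd,
      age_bounds = sim$age_bounds,
      p_response = sim$p_response, er_slope = sim$er_slope,
      er_metric = sim$er_metric,
      missing_fraction = sim$missing_fraction,
      missing_loe_fraction = sim$missing_loe_fraction
    )
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
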