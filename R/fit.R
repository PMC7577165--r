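# Population estimation: maximum (Laplace-approximate marginal) likelihood
# over the fixed effects, random-effect variances and residual error, plus
# empirical-Bayes post hoc individual parameters.

# Parameter table driving the transformation between the natural scale and
# the unconstrained optimisation scale. Positives are log-transformed;
# covariate exponents are free.
par_spec <- function(init, estimate = NULL) {
  th <- unclass(init$theta)
  spec <- tibble::tibble(
    name = c("tvcl", "tvv", "tvka", "beta_wt_v", "beta_hiv_v", "beta_age_cl",
             "omega2_cl", "omega2_v", "omega2_ka", "sigma_prop", "sigma_add"),
    trans = c("log", "log", "log", "identity", "log", "identity",
              "log", "log", "log", "log", "log"),
    init = c(th[["tvcl"]], th[["tvv"]], th[["tvka"]], th[["beta_wt_v"]],
             th[["beta_hiv_v"]], th[["beta_age_cl"]],
             init$omega2[["cl"]], init$omega2[["v"]], init$omega2[["ka"]],
             init$sigma_prop, init$sigma_add)
  )
  spec$estimate <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                     init$omega2 > 0, init$sigma_prop > 0, init$sigma_add > 0)
  if (!is.null(estimate)) {
    unknown <- setdiff(names(estimate), spec$name)
    if (length(unknown)) {
      stop("unknown parameter name(s) in `estimate`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    spec$estimate[match(names(estimate), spec$name)] <- unname(estimate)
  }
  bad <- spec$estimate & spec$trans == "log" & spec$init <= 0
  if (any(bad)) {
    stop("cannot estimate ", paste(spec$name[bad], collapse = ", "),
         " from a zero initial value", call. = FALSE)
  }
  spec
}

to_trans <- function(x, trans) {
  i <- trans == "log"
  x[i] <- log(x[i])
  x
}

from_trans <- function(x, trans) {
  i <- trans == "log"
  x[i] <- exp(x[i])
  x
}

model_from_pars <- function(vals) {
  population_model(
    theta = theta_vector(
      tvcl = vals[["tvcl"]], tvv = vals[["tvv"]], tvka = vals[["tvka"]],
      beta_wt_v = vals[["beta_wt_v"]], beta_hiv_v = vals[["beta_hiv_v"]],
      beta_age_cl = vals[["beta_age_cl"]]
    ),
    omega2 = c(cl = vals[["omega2_cl"]], v = vals[["omega2_v"]],
               ka = vals[["omega2_ka"]]),
    sigma_prop = vals[["sigma_prop"]], sigma_add = vals[["sigma_add"]]
  )
}

#' Fit the population PK model by Laplace-approximate maximum likelihood
#'
#' Minimises [marginal_neg2ll()] over the transformed parameter vector
#' (log for positive parameters, free for the covariate exponents) with
#' `stats::nlminb`. Which parameters move is controlled by `estimate`;
#' by default all typical values, the weight and age exponents, every
#' random-effect variance that starts positive, and every residual SD that
#' starts positive are estimated, while the healthy-vs-HIV factor is
#' estimated only when requested (it is unidentifiable in a single-status
#' cohort).
#'
#' @param records,subjects Dataset tibbles (or a `pk_dataset` as `records`).
#' @param init A [population_model()] giving initial values.
#' @param config An [analysis_config()].
#' @param estimate Optional named logical vector overriding the default
#'   choice of estimated parameters, e.g. `c(beta_hiv_v = TRUE)`. Valid names
#'   are `tvcl`, `tvv`, `tvka`, `beta_wt_v`, `beta_hiv_v`, `beta_age_cl`,
#'   `omega2_cl`, `omega2_v`, `omega2_ka`, `sigma_prop`, `sigma_add`.
#' @param compute_se Compute standard errors at the optimum (adds a
#'   finite-difference Hessian pass). Default `TRUE`.
#' @return An object of class `pop_pk_fit`: list with the fitted `model`,
#'   `neg2ll`, `converged`, `message`, `n_subjects`, `n_obs`, a parameter
#'   tibble `parameters` (name, estimate, se, estimated flag), the
#'   optimiser object and bookkeeping needed to resume (`par_trans`, `spec`).
#' @export
fit_population <- function(records, subjects = NULL, init = population_model(),
                           config = analysis_config(), estimate = NULL,
                           compute_se = TRUE) {
  nd <- prepare_nlme_data(records, subjects, config)
  if (nd$n_subj < 2L) stop("need at least 2 subjects", call. = FALSE)
  usable <- tabulate(nd$obs$subj, nd$n_subj)
  if (nd$n_obs < 2L || stats::sd(nd$obs$dv) == 0) {
    stop("degenerate data: need at least 2 usable observations with ",
         "non-constant DV", call. = FALSE)
  }
  spec <- par_spec(init, estimate)
  est <- spec$estimate
  p0 <- to_trans(spec$init, spec$trans)[est]
  names(p0) <- spec$name[est]
  lower <- ifelse(spec$trans[est] == "log", log(1e-8), -20)
  upper <- ifelse(spec$trans[est] == "log", 20, 20)

  cache <- new.env(parent = emptyenv())
  cache$eta <- NULL
  objective <- function(p) {
    vals <- spec$init
    vals[est] <- from_trans(p, spec$trans[est])
    names(vals) <- spec$name
    m <- model_from_pars(vals)
    res <- tryCatch(
      marginal_neg2ll_nd(m, nd, eta0 = cache$eta, details = TRUE),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$neg2ll)) return(1e10)
    cache$eta <- res$eta
    res$neg2ll
  }

  ctrl <- list(rel.tol = config$outer_tol, iter.max = config$max_iter,
               eval.max = 4L * config$max_iter)
  opt <- stats::nlminb(p0, objective, lower = lower, upper = upper,
                       control = ctrl)
  # restarts from the solution separate genuine non-convergence from the
  # optimizer stalling on finite-difference noise at the optimum
  converged <- opt$convergence == 0L
  tries <- 0L
  while (!converged && tries < 3L) {
    opt2 <- stats::nlminb(opt$par, objective, lower = lower, upper = upper,
                          control = ctrl)
    improved <- opt$objective - opt2$objective
    if (opt2$objective <= opt$objective) opt <- opt2
    converged <- opt$convergence == 0L ||
      improved <= max(1e-4, 1e-7 * abs(opt$objective))
    tries <- tries + 1L
  }
  vals <- spec$init
  vals[est] <- from_trans(opt$par, spec$trans[est])
  names(vals) <- spec$name
  model <- model_from_pars(vals)

  parameters <- tibble::tibble(
    parameter = spec$name, estimate = unname(vals),
    se = NA_real_, estimated = est
  )
  fit <- structure(
    list(model = model, neg2ll = opt$objective,
         converged = converged, message = opt$message,
         n_subjects = nd$n_subj, n_obs = nd$n_obs,
         parameters = parameters, optimizer = opt,
         par_trans = opt$par, spec = spec, config = config),
    class = "pop_pk_fit"
  )
  if (compute_se) {
    se <- tryCatch(standard_errors(fit, records, subjects, config),
                   error = function(e) NULL)
    if (!is.null(se)) {
      fit$parameters$se[match(se$parameter, fit$parameters$parameter)] <- se$se
      fit$vcov_trans <- attr(se, "vcov_trans")
      fit$se_condition <- attr(se, "condition")
    }
  }
  fit
}

#' @export
print.pop_pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("  -2LL = %.3f (%s)\n", x$neg2ll,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  print(as.data.frame(dplyr::filter(x$parameters, .data$estimated)), digits = 4)
  invisible(x)
}

#' Standard errors of the population estimates
#'
#' Inverts a central finite-difference Hessian of half the objective
#' (`-2LL / 2`, i.e. the negative log-likelihood) on the transformed scale
#' at the optimum, and maps the resulting SDs to the natural reporting scale
#' by the delta method (for log-transformed parameters,
#' `se_natural = estimate * se_log`).
#'
#' @param fit A converged [fit_population()] result.
#' @param records,subjects,config The data and configuration used in the fit.
#' @return Tibble (`parameter`, `estimate`, `se`) for the estimated
#'   parameters, with the transformed-scale covariance in attribute
#'   `vcov_trans`. If the Hessian is not positive definite the SEs are `NA`
#'   and the condition number is reported in attribute `condition` with a
#'   warning.
#' @export
standard_errors <- function(fit, records, subjects = NULL, config = NULL) {
  if (is.null(config)) config <- fit$config
  nd <- prepare_nlme_data(records, subjects, config)
  spec <- fit$spec
  est <- spec$estimate
  p <- fit$par_trans
  np <- length(p)
  cache <- new.env(parent = emptyenv()); cache$eta <- NULL
  f <- function(pp) {
    vals <- spec$init
    vals[est] <- from_trans(pp, spec$trans[est])
    names(vals) <- spec$name
    res <- marginal_neg2ll_nd(model_from_pars(vals), nd, eta0 = cache$eta,
                              details = TRUE)
    cache$eta <- res$eta
    res$neg2ll / 2
  }
  h <- pmax(1e-3, 1e-3 * abs(p))
  H <- matrix(0, np, np)
  f0 <- f(p)
  for (j in seq_len(np)) {
    ej <- rep(0, np); ej[j] <- h[j]
    H[j, j] <- (f(p + ej) - 2 * f0 + f(p - ej)) / h[j]^2
    if (j > 1L) {
      for (k in seq_len(j - 1L)) {
        ek <- rep(0, np); ek[k] <- h[k]
        H[j, k] <- H[k, j] <-
          (f(p + ej + ek) - f(p + ej - ek) - f(p - ej + ek) + f(p - ej - ek)) /
          (4 * h[j] * h[k])
      }
    }
  }
  H <- (H + t(H)) / 2
  est_names <- spec$name[est]
  nat <- from_trans(p, spec$trans[est])
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    warning("Hessian at the optimum is not positive definite; standard ",
            "errors unavailable (condition number ",
            format(kappa(H), digits = 3), ")", call. = FALSE)
    out <- tibble::tibble(parameter = est_names, estimate = unname(nat),
                          se = NA_real_)
    attr(out, "condition") <- kappa(H)
    return(out)
  }
  vcov_trans <- chol2inv(ch)
  se_trans <- sqrt(diag(vcov_trans))
  se_nat <- ifelse(spec$trans[est] == "log", nat * se_trans, se_trans)
  out <- tibble::tibble(parameter = est_names, estimate = unname(nat),
                        se = unname(se_nat))
  attr(out, "vcov_trans") <- vcov_trans
  attr(out, "condition") <- kappa(H)
  out
}

#' Empirical-Bayes (post hoc) individual parameters
#'
#' With the population model held fixed, finds for every subject the mode of
#' the joint density of that subject's observations and random effects (the
#' MAP eta), and returns the implied individual parameters
#' `typical * exp(eta)`. Subjects with no usable observations sit at the
#' prior mode `eta = 0` (individual parameters equal to typical values) and
#' are flagged.
#'
#' @param model A [population_model()] (typically `fit$model`).
#' @param records,subjects Dataset tibbles (or a `pk_dataset` as `records`).
#' @param config An [analysis_config()].
#' @return An object of class `ebe_result`: list with `eta` (tibble:
#'   `subject_id`, `eta_cl`, `eta_v`, `eta_ka`, `n_obs`, `no_data` flag),
#'   `params` (tibble: `subject_id`, `cl`, `v`, `ka`) and `shrinkage`
#'   (tibble from [eta_shrinkage()]).
#' @export
empirical_bayes <- function(model, records, subjects = NULL,
                            config = analysis_config()) {
  nd <- prepare_nlme_data(records, subjects, config)
  tol <- max(config$inner_tol, 1e-8)
  sol <- map_eta_search(model, nd, tol = tol)
  n_obs <- tabulate(nd$obs$subj, nd$n_subj)
  eta <- tibble::tibble(
    subject_id = nd$subjects$subject_id,
    eta_cl = sol$eta[, 1L], eta_v = sol$eta[, 2L], eta_ka = sol$eta[, 3L],
    n_obs = n_obs, no_data = n_obs == 0L
  )
  typ <- typical_params(nd$subjects, model$theta, config)
  params <- tibble::tibble(
    subject_id = typ$subject_id,
    cl = typ$cl * exp(eta$eta_cl),
    v = typ$v * exp(eta$eta_v),
    ka = typ$ka * exp(eta$eta_ka)
  )
  out <- structure(list(eta = eta, params = params, model = model),
                   class = "ebe_result")
  out$shrinkage <- tryCatch(eta_shrinkage(out, model), error = function(e) NULL)
  out
}

#' Eta shrinkage of the empirical-Bayes estimates
#'
#' `shrinkage_k = (1 - SD(eta_k) / omega_k) * 100`, the standard diagnostic
#' for how strongly the post hoc estimates contract toward the typical
#' values when individual data are uninformative. Random effects with
#' `omega2 = 0` are reported as `NA` (not applicable).
#'
#' @param ebes An `ebe_result` from [empirical_bayes()], or its `eta` tibble.
#' @param model The [population_model()] supplying `omega2`.
#' @return Tibble (`eta`, `omega`, `sd_eta`, `shrinkage_pct`).
#' @export
eta_shrinkage <- function(ebes, model) {
  eta <- if (inherits(ebes, "ebe_result")) ebes$eta else ebes
  if (nrow(eta) < 10L) {
    stop("shrinkage needs at least 10 subjects", call. = FALSE)
  }
  omega <- sqrt(model$omega2)
  sds <- c(stats::sd(eta$eta_cl), stats::sd(eta$eta_v), stats::sd(eta$eta_ka))
  tibble::tibble(
    eta = c("eta_cl", "eta_v", "eta_ka"),
    omega = unname(omega),
    sd_eta = sds,
    shrinkage_pct = ifelse(omega > 0, (1 - sds / omega) * 100, NA_real_)
  )
}

#' Residual table for goodness-of-fit diagnostics
#'
#' Population (typical-value) and individual (post hoc) predictions for every
#' usable observation, with individual weighted residuals
#' `IWRES = (DV - IPRED) / sd(IPRED)`.
#'
#' @inheritParams empirical_bayes
#' @param ebes Optional precomputed [empirical_bayes()] result.
#' @return Tibble (`subject_id`, `time`, `time_after_dose`, `dv`, `pred`,
#'   `ipred`, `iwres`).
#' @export
residual_table <- function(model, records, subjects = NULL,
                           config = analysis_config(), ebes = NULL) {
  if (inherits(records, "pk_dataset")) {
    subjects <- records$subjects
    records <- records$records
  }
  if (is.null(ebes)) ebes <- empirical_bayes(model, records, subjects, config)
  obs <- records |>
    dplyr::filter(.data$evid == 0L, .data$mdv == 0L, !is.na(.data$dv))
  typ <- typical_params(subjects, model$theta, config)
  i <- match(obs$subject_id, typ$subject_id)
  j <- match(obs$subject_id, ebes$params$subject_id)
  pred <- conc_ss(obs$time_after_dose, typ$cl[i], typ$v[i], typ$ka[i],
                  config$regimen)
  ipred <- conc_ss(obs$time_after_dose, ebes$params$cl[j], ebes$params$v[j],
                   ebes$params$ka[j], config$regimen)
  sd_i <- pmax(sqrt(model$sigma_add^2 + (model$sigma_prop * ipred)^2), 1e-12)
  tibble::tibble(
    subject_id = obs$subject_id, time = obs$time,
    time_after_dose = obs$time_after_dose, dv = obs$dv,
    pred = pred, ipred = ipred, iwres = (obs$dv - ipred) / sd_i
  )
}

#' Serialise a population fit to JSON
#'
#' @param fit A `pop_pk_fit`.
#' @param path Output path.
#' @param dataset_hash Optional provenance string stored alongside.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, dataset_hash = NULL) {
  x <- list(
    parameters = fit$parameters,
    neg2ll = fit$neg2ll, converged = fit$converged,
    n_subjects = fit$n_subjects, n_obs = fit$n_obs,
    settings = list(inner_tol = fit$config$inner_tol,
                    outer_tol = fit$config$outer_tol,
                    max_iter = fit$config$max_iter,
                    seed = fit$config$seed),
    dataset_hash = dataset_hash
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
#' @rdname fit_population
#' @param x A `pop_pk_fit`.
#' @param ... Unused.
tidy.pop_pk_fit <- function(x, ...) {
  x$parameters |>
    dplyr::filter(.data$estimated) |>
    dplyr::transmute(term = .data$parameter, estimate = .data$estimate,
                     std.error = .data$se)
}

#' @exportS3Method generics::glance
#' @rdname fit_population
glance.pop_pk_fit <- function(x, ...) {
  tibble::tibble(
    neg2ll = x$neg2ll, logLik = -x$neg2ll / 2,
    AIC = x$neg2ll + 2 * sum(x$parameters$estimated),
    n_subjects = x$n_subjects, n_obs = x$n_obs, converged = x$converged
  )
}
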