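# Nonlinear mixed-effects machinery: per-subject joint density, vectorised
# MAP (mode) search for the log-normal random effects, and the Laplace
# approximation to the marginal -2 log-likelihood.

# Assemble the internal fitting structure: usable observations (EVID=0,
# MDV=0, DV present) with a steady-state time-after-dose, indexed by subject.
prepare_nlme_data <- function(records, subjects, config) {
  if (inherits(records, "pk_dataset")) {
    subjects <- records$subjects
    records <- records$records
  }
  obs <- records |>
    dplyr::filter(.data$evid == 0L, .data$mdv == 0L, !is.na(.data$dv))
  if (any(is.na(obs$time_after_dose))) {
    stop("usable observations must have a time after dose (TAD column or a ",
         "preceding dose event)", call. = FALSE)
  }
  tau <- config$regimen$tau
  tad <- pmin(pmax(obs$time_after_dose, 0), tau)
  subj_idx <- match(obs$subject_id, subjects$subject_id)
  if (anyNA(subj_idx)) {
    stop("observations for subjects absent from the subject table: ",
         paste(unique(obs$subject_id[is.na(subj_idx)]), collapse = ", "),
         call. = FALSE)
  }
  list(
    subjects = subjects,
    n_subj = nrow(subjects),
    obs = list(tad = tad, dv = obs$dv, subj = subj_idx),
    n_obs = nrow(obs),
    config = config
  )
}

# Pre-resolve everything about (model, data) that does not depend on eta:
# typical individual parameters, residual SD components, active dimensions.
make_model_ctx <- function(model, nd) {
  typ <- typical_params(nd$subjects, model$theta, nd$config)
  s <- nd$obs$subj
  list(
    model = model, nd = nd,
    cl_t = typ$cl[s], v_t = typ$v[s], ka_t = typ$ka[s],
    s = s, tad = nd$obs$tad, dv = nd$obs$dv,
    tau = nd$config$regimen$tau, d_amt = nd$config$regimen$amount_nmol,
    act = which(model$omega2 > 0),
    omega = sqrt(pmax(model$omega2, 0))
  )
}

# Per-subject negative joint log-density g_i(eta) = -log p(y_i | eta_i)
# - log p(eta_i), vectorised across subjects. `eta` is an S x 3 matrix
# (columns cl, v, ka). Returns a length-S vector.
subject_neg_joint <- function(eta, ctx) {
  nd <- ctx$nd
  s <- ctx$s
  cl <- ctx$cl_t * exp(eta[s, 1L])
  v <- ctx$v_t * exp(eta[s, 2L])
  ka <- ctx$ka_t * exp(eta[s, 3L])
  ke <- cl / v
  tau <- ctx$tau
  t <- ctx$tad
  eq <- abs(ka - ke) <= .equal_rate_tol * pmax(ka, ke)
  pred <- numeric(length(t))
  if (any(!eq)) {
    i <- !eq
    pred[i] <- ctx$d_amt * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * t[i]) / (1 - exp(-ke[i] * tau)) -
         exp(-ka[i] * t[i]) / (1 - exp(-ka[i] * tau)))
  }
  if (any(eq)) {
    i <- eq
    k <- ke[i]
    r <- exp(-k * tau)
    pred[i] <- ctx$d_amt * k / v[i] * exp(-k * t[i]) *
      (t[i] / (1 - r) + tau * r / (1 - r)^2)
  }
  pred <- pmax(pred, 0)
  sd <- pmax(sqrt(ctx$model$sigma_add^2 + (ctx$model$sigma_prop * pred)^2), 1e-12)
  ll <- stats::dnorm(ctx$dv, mean = pred, sd = sd, log = TRUE)
  persub <- numeric(nd$n_subj)
  if (length(ll)) {
    agg <- rowsum(ll, s)
    persub[as.integer(rownames(agg))] <- agg[, 1L]
  }
  prior <- 0
  for (k in ctx$act) {
    prior <- prior + stats::dnorm(eta[, k], 0, ctx$omega[[k]], log = TRUE)
  }
  -(persub + prior)
}

#' Per-subject negative joint log-density of data and random effects
#'
#' The integrand of the marginal likelihood: for each subject,
#' `-log p(y_i | eta_i) - log p(eta_i)` under the population model, with
#' log-normal random effects on CL/F, V/F and ka. Exposed for diagnostics
#' and for independent numerical integration of the marginal likelihood.
#'
#' @param eta Numeric length-3 vector `(eta_cl, eta_v, eta_ka)`, or an
#'   `n_subjects x 3` matrix with one row per subject.
#' @param model A [population_model()].
#' @param records,subjects Dataset tibbles (or a `pk_dataset` as `records`).
#' @param config An [analysis_config()].
#' @return Numeric vector of per-subject negative joint log-densities.
#' @export
joint_neg_log_density <- function(eta, model, records, subjects = NULL,
                                  config = analysis_config()) {
  nd <- prepare_nlme_data(records, subjects, config)
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = nd$n_subj, ncol = 3, byrow = TRUE)
  subject_neg_joint(eta, make_model_ctx(model, nd))
}

# Central-difference gradient of g_i over the active eta dimensions.
# Returns an S x length(act) matrix.
neg_joint_grad <- function(eta, ctx, h = 1e-5) {
  act <- ctx$act
  gr <- matrix(0, nrow(eta), length(act))
  for (j in seq_along(act)) {
    k <- act[j]
    ep <- eta; ep[, k] <- ep[, k] + h
    em <- eta; em[, k] <- em[, k] - h
    gr[, j] <- (subject_neg_joint(ep, ctx) - subject_neg_joint(em, ctx)) / (2 * h)
  }
  gr
}

# Finite-difference Hessian (of the gradient) over active dimensions:
# S x d x d array, symmetrised.
neg_joint_hess <- function(eta, ctx, h = 1e-4) {
  act <- ctx$act
  d <- length(act)
  H <- array(0, c(nrow(eta), d, d))
  for (j in seq_len(d)) {
    k <- act[j]
    ep <- eta; ep[, k] <- ep[, k] + h
    em <- eta; em[, k] <- em[, k] - h
    H[, j, ] <- (neg_joint_grad(ep, ctx) - neg_joint_grad(em, ctx)) / (2 * h)
  }
  (H + aperm(H, c(1, 3, 2))) / 2
}

# Damped Newton search for the per-subject posterior mode, run for all
# subjects simultaneously. Returns the mode, the Hessian there, per-subject
# gradient norms and a convergence flag.
map_eta_search <- function(model, nd, eta0 = NULL, tol = 1e-8, max_iter = 50L) {
  S <- nd$n_subj
  ctx <- make_model_ctx(model, nd)
  act <- ctx$act
  eta <- if (is.null(eta0)) matrix(0, S, 3) else eta0
  eta[, setdiff(1:3, act)] <- 0
  if (length(act) == 0L) {
    return(list(eta = eta, hess = array(0, c(S, 0, 0)), act = act,
                g = subject_neg_joint(eta, ctx),
                grad_norm = rep(0, S), converged = rep(TRUE, S)))
  }
  d <- length(act)
  g <- subject_neg_joint(eta, ctx)
  bad <- !is.finite(g)
  if (any(bad)) {        # unusable warm start for these subjects
    eta[bad, ] <- 0
    g <- subject_neg_joint(eta, ctx)
  }
  H <- NULL
  for (iter in seq_len(max_iter)) {
    gr <- neg_joint_grad(eta, ctx)
    gnorm <- apply(abs(gr), 1, max)
    if (all(gnorm < tol)) break
    H <- neg_joint_hess(eta, ctx)
    step <- matrix(0, S, d)
    for (i in which(gnorm >= tol)) {
      Hi <- H[i, , , drop = TRUE]
      if (d == 1L) Hi <- matrix(Hi, 1, 1)
      ridge <- 0
      repeat {
        ch <- tryCatch(chol(Hi + diag(ridge, d)), error = function(e) NULL)
        if (!is.null(ch)) break
        ridge <- if (ridge == 0) max(abs(diag(Hi))) * 1e-6 + 1e-8 else ridge * 10
        if (ridge > 1e8) break
      }
      if (!is.null(ch)) {
        step[i, ] <- -backsolve(ch, backsolve(ch, gr[i, ], transpose = TRUE))
      } else {
        step[i, ] <- -gr[i, ] / (max(abs(Hi)) + 1)
      }
    }
    step[!is.finite(step)] <- 0
    # trust region: cap the per-iteration move on any eta component
    big <- apply(abs(step), 1, max)
    cap <- which(big > 2)
    if (length(cap)) step[cap, ] <- step[cap, , drop = FALSE] * (2 / big[cap])
    scale <- rep(1, S)
    for (half in 1:15) {
      trial <- eta
      trial[, act] <- eta[, act] + scale * step
      g_new <- subject_neg_joint(trial, ctx)
      worse <- !is.finite(g_new) | g_new > g + 1e-12
      if (!any(worse)) { eta <- trial; g <- g_new; break }
      scale[worse] <- scale[worse] / 2
      if (half == 15L) {
        keep <- !worse
        eta[keep, act] <- trial[keep, act, drop = FALSE]
        g[keep] <- g_new[keep]
      }
    }
  }
  gr <- neg_joint_grad(eta, ctx)
  gnorm <- apply(abs(gr), 1, max)
  H <- neg_joint_hess(eta, ctx)
  list(eta = eta, hess = H, act = act, g = g, grad_norm = gnorm,
       converged = gnorm < max(tol, 1e-6))
}

# Log-determinant of each subject's d x d Hessian; ridges non-PD cases and
# reports them.
subject_logdet <- function(H, d) {
  S <- dim(H)[1]
  out <- numeric(S)
  ok <- rep(TRUE, S)
  for (i in seq_len(S)) {
    Hi <- H[i, , , drop = TRUE]
    if (d == 1L) Hi <- matrix(Hi, 1, 1)
    ch <- tryCatch(chol(Hi), error = function(e) NULL)
    if (is.null(ch)) {
      ok[i] <- FALSE
      ch <- chol(Hi + diag(max(abs(diag(Hi))) * 1e-6 + 1e-8, d))
    }
    out[i] <- 2 * sum(log(diag(ch)))
  }
  list(logdet = out, pd = ok)
}

#' Marginal -2 log-likelihood by Laplace approximation
#'
#' Integrates the per-subject random effects out of the joint likelihood by
#' a Laplace approximation at the per-subject posterior mode (an inner
#' Newton optimisation), the deterministic analogue of first-order
#' conditional estimation. Random-effect dimensions with `omega2 = 0` are
#' fixed at zero and excluded from the integral; with all variances zero the
#' value reduces to the residual-error -2 log-likelihood at the typical
#' parameters.
#'
#' @inheritParams joint_neg_log_density
#' @param eta0 Optional warm-start matrix of modes (`n_subjects x 3`).
#' @param details If `TRUE`, return per-subject components alongside the sum.
#' @return The scalar -2 log marginal likelihood, or (with
#'   `details = TRUE`) a list with elements `neg2ll`, `per_subject`, `eta`,
#'   `converged`.
#' @export
marginal_neg2ll <- function(model, records, subjects = NULL,
                            config = analysis_config(), eta0 = NULL,
                            details = FALSE) {
  nd <- prepare_nlme_data(records, subjects, config)
  marginal_neg2ll_nd(model, nd, eta0 = eta0, details = details)
}

# Same computation on a pre-assembled fitting structure (hot path for the
# population optimiser, which re-evaluates this hundreds of times).
marginal_neg2ll_nd <- function(model, nd, eta0 = NULL, details = FALSE) {
  if (model$sigma_prop == 0 && model$sigma_add == 0) {
    stop("likelihood evaluation needs a positive residual SD", call. = FALSE)
  }
  config <- nd$config
  tol <- max(config$inner_tol, 1e-8)
  fit <- map_eta_search(model, nd, eta0 = eta0, tol = tol)
  d <- length(fit$act)
  if (d == 0L) {
    per <- 2 * fit$g
  } else {
    ld <- subject_logdet(fit$hess, d)
    if (!all(ld$pd)) {
      warning("non-positive-definite curvature at the mode for ",
              sum(!ld$pd), " subject(s); ridged", call. = FALSE)
    }
    per <- 2 * fit$g - d * log(2 * pi) + ld$logdet
  }
  if (any(!fit$converged & tabulate(nd$obs$subj, nd$n_subj) > 0)) {
    stop("inner mode search failed for subject(s): ",
         paste(utils::head(nd$subjects$subject_id[!fit$converged], 5),
               collapse = ", "), call. = FALSE)
  }
  if (details) {
    list(neg2ll = sum(per), per_subject = per, eta = fit$eta,
         converged = fit$converged)
  } else {
    sum(per)
  }
}
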