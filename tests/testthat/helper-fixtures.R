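# Shared fixtures and independent oracles for the test suite.

# A tiny NONMEM-dialect CSV written to a temp file: one subject, one dose,
# two observations (plus optional extra lines).
write_toy_csv <- function(extra_lines = character()) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  lines <- c(
    "ID,TIME,TAD,AMT,DV,EVID,MDV,WT,AGE,STAT,GRP",
    "S1,0,0,234880,.,1,1,70,45,hiv,ISG",
    "S1,672,24,0,1100,0,0,70,45,hiv,ISG",
    "S1,673,1,0,2100,0,0,70,45,hiv,ISG",
    extra_lines
  )
  writeLines(lines, path)
  path
}

# A small simulated trial with default truth unless overridden.
small_trial <- function(n = 40, seed = 1, ...) {
  simulate_trial(simulation_config(n_subjects = n, seed = seed, ...))
}

# Single-subject dataset builder: observations at given times-after-dose at
# steady state, with specified DV values.
one_subject_data <- function(tad, dv, id = "S1", weight = 70, age = 45,
                             status = "hiv", amt = dose_to_amount(100)) {
  records <- tibble::tibble(
    subject_id = id,
    time = c(0, 672 + seq_along(tad)),
    time_after_dose = c(0, tad),
    amt = c(amt, rep(0, length(tad))),
    dv = c(NA_real_, dv),
    evid = c(1L, rep(0L, length(tad))),
    mdv = c(1L, rep(0L, length(tad)))
  )
  subjects <- tibble::tibble(subject_id = id, weight = weight, age = age,
                             status = status, group = "ISG")
  list(records = records, subjects = subjects)
}

bind_datasets <- function(...) {
  ds <- list(...)
  list(records = dplyr::bind_rows(lapply(ds, `[[`, "records")),
       subjects = dplyr::bind_rows(lapply(ds, `[[`, "subjects")))
}

# ---- independent oracle: adaptive Gauss-Hermite quadrature -----------------
# Integrates each subject's joint density over the active random effects
# with a tensor Gauss-Hermite rule centred at a mode found by stats::optim
# and scaled by a pracma::hessian curvature estimate. Shares only the
# integrand with the implementation under test.
agq_neg2ll <- function(model, records, subjects, config, n_nodes = 9) {
  act <- which(model$omega2 > 0)
  d <- length(act)
  gh <- pracma::gaussHermite(n_nodes)
  total <- 0
  for (sid in subjects$subject_id) {
    rec_i <- dplyr::filter(records, subject_id == sid)
    sub_i <- dplyr::filter(subjects, subject_id == sid)
    g_i <- function(eta_act) {
      eta <- numeric(3)
      eta[act] <- eta_act
      joint_neg_log_density(eta, model, rec_i, sub_i, config)
    }
    opt <- stats::optim(rep(0, d), g_i, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
    m <- opt$par
    H <- pracma::hessian(g_i, m)
    L <- t(chol(solve((H + t(H)) / 2)))
    nodes <- as.matrix(expand.grid(rep(list(gh$x), d)))
    w <- as.matrix(expand.grid(rep(list(gh$w), d)))
    logw <- rowSums(log(w))
    vals <- vapply(seq_len(nrow(nodes)), function(j) {
      z <- nodes[j, ]
      -g_i(m + sqrt(2) * as.vector(L %*% z)) + sum(z^2) + logw[j]
    }, numeric(1))
    mx <- max(vals)
    log_int <- (d / 2) * log(2) + sum(log(diag(L))) + mx + log(sum(exp(vals - mx)))
    total <- total - 2 * log_int
  }
  total
}
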