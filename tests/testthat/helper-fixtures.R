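# Shared fixtures and independent oracles for the test suite.

default_model <- meropenem_model()

# model stripped of all randomness (deterministic typical subject)
noiseless_model <- local({
  m <- default_model
  m$omega_cl <- m$omega_vc <- m$omega_vp <- 0
  m$sigma_prop <- 0
  m
})

# fast outer-optimiser settings for small test fits
fast_ctrl <- list(rel_tol = 1e-5, maxit = 150)

# Independent ODE oracle: two-compartment amounts integrated with deSolve,
# infusion and washout integrated as separate legs so the input
# discontinuity never crosses an integrator step.
ode_conc_2cmt <- function(p, dose, tinf, times, rtol = 1e-11) {
  deriv <- function(t, y, parms) {
    list(c(parms$rate - (p$cl / p$vc + p$q / p$vc) * y[1] + (p$q / p$vp) * y[2],
           (p$q / p$vc) * y[1] - (p$q / p$vp) * y[2]))
  }
  run_leg <- function(y0, tt, rate) {
    if (length(tt) < 2) return(matrix(y0, 1))
    out <- deSolve::lsoda(y0, tt, deriv, list(rate = rate),
                          rtol = rtol, atol = 1e-12)
    out[, 2:3, drop = FALSE]
  }
  times <- sort(unique(c(0, tinf, times)))
  leg1_t <- times[times <= tinf]
  leg2_t <- times[times >= tinf]
  a1 <- run_leg(c(0, 0), leg1_t, dose / tinf)
  a2 <- run_leg(a1[nrow(a1), ], leg2_t, 0)
  conc <- c(a1[, 1], a2[-1, 1]) / p$vc
  names(conc) <- c(leg1_t, leg2_t[-1])
  conc
}

# simulate observation values for an existing dataset design under a model
# (R closed-form path; used for self-simulation calibration tests)
resimulate_dataset <- function(model, dataset) {
  for (sid in unique(dataset$id)) {
    rows <- dataset$id == sid
    d <- dataset[rows, ]
    doses <- d[d$evid == 1, ]
    obs_i <- which(rows & dataset$evid == 0)
    p <- sample_individual(model, d$ce[1], 1)
    ctrue <- conc_dose_history_test(p, doses$time, doses$amt, doses$tinf,
                                    dataset$time[obs_i])
    dv <- numeric(length(ctrue))
    pos <- ctrue > 0
    if (any(pos)) dv[pos] <- apply_residual_error(model, ctrue[pos])
    dataset$dv[obs_i] <- dv
    dataset$blq[obs_i] <- dv < 0.2
  }
  dataset
}

conc_dose_history_test <- function(p, dose_times, amounts, tinfs, t) {
  out <- numeric(length(t))
  for (j in seq_along(dose_times)) {
    out <- out + conc_single_dose(p, amounts[j], tinfs[j], t - dose_times[j])
  }
  out
}

# A rich-sampling dataset (many observations/subject) for calibration tests
make_rich_dataset <- function(model, n_subjects, obs_times, regimen,
                              n_doses = 3, ce = NULL) {
  if (is.null(ce)) ce <- runif(n_subjects, 40, 140)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    dose_times <- (seq_len(n_doses) - 1) * regimen$interval
    p <- sample_individual(model, ce[i], 1)
    ctrue <- conc_dose_history_test(p, dose_times, rep(regimen$dose, n_doses),
                                    rep(regimen$tinf, n_doses), obs_times)
    dv <- apply_residual_error(model, pmax(ctrue, 1e-6))
    rows[[i]] <- rbind(
      data.frame(id = i, time = dose_times, evid = 1L, amt = regimen$dose,
                 tinf = regimen$tinf, dv = NA_real_, blq = NA, ce = ce[i]),
      data.frame(id = i, time = obs_times, evid = 0L, amt = NA_real_,
                 tinf = NA_real_, dv = as.numeric(dv), blq = dv < 0.2,
                 ce = ce[i]))
  }
  out <- do.call(rbind, lapply(rows, function(d) d[order(d$time, -d$evid), ]))
  rownames(out) <- NULL
  out
}

# 64-node Gauss-Hermite marginal likelihood for a single subject with IIV on
# CL only; fully independent of the C++ Laplace path (R closed-form conc).
# Returns -2 log L with n*log(2*pi) dropped (package OFV convention).
gh_ofv_single <- function(model, dataset_one_subject) {
  gh <- pracma::gaussHermite(64)
  d <- dataset_one_subject
  doses <- d[d$evid == 1, ]
  obs <- d[d$evid == 0 & !d$blq, ]
  tvcl <- typical_cl(model, d$ce[1])
  loglik_eta <- function(eta) {
    p <- list(cl = tvcl * exp(eta), vc = model$vc, vp = model$vp, q = model$q)
    f <- pmax(conc_dose_history_test(p, doses$time, doses$amt, doses$tinf,
                                     obs$time), 1e-12)
    v <- model$sigma_prop^2 * f^(2 * model$power)
    sum(-0.5 * (log(v) + (obs$dv - f)^2 / v)) # 2*pi dropped here
  }
  om <- model$omega_cl
  # eta = sqrt(2)*om*x maps the GH weight exp(-x^2) onto the N(0, om^2) prior
  vals <- vapply(gh$x, function(x) {
    eta <- sqrt(2) * om * x
    loglik_eta(eta)
  }, numeric(1))
  lse <- max(vals)
  marg <- sum(gh$w / sqrt(pi) * exp(vals - lse)) # prior absorbed by GH kernel
  -2 * (lse + log(marg))
}
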