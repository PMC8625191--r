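# Laplace-based NLME estimation for the two-compartment infusion model.
#
# The marginal likelihood of each subject's observations is approximated by
# the Laplace method at the conditional mode of the random effects, with the
# residual variance evaluated at the conditional prediction (the
# "interaction" convention). Additive 2*pi constants are dropped from the
# objective (OFV), so nested-model Delta-OFVs follow the usual chi-square
# thresholds. This is an in-spirit FOCE/Laplace implementation, not a
# re-implementation of any specific estimation software.

# --- dataset preparation ----------------------------------------------------

# Split a pk_dataset into per-subject likelihood structures. Observations
# flagged below the LLOQ are dropped from the likelihood and counted.
prepare_subjects <- function(dataset) {
  validate_pk_dataset(dataset)
  ids <- unique(dataset$id)
  subjects <- vector("list", length(ids))
  ce <- numeric(length(ids))
  n_blq <- 0L
  for (k in seq_along(ids)) {
    d <- dataset[dataset$id == ids[k], , drop = FALSE]
    doses <- d[d$evid == 1L, , drop = FALSE]
    obs <- d[d$evid == 0L, , drop = FALSE]
    blq <- isTRUE_vec(obs$blq)
    n_blq <- n_blq + sum(blq)
    obs <- obs[!blq, , drop = FALSE]
    if (nrow(doses) == 0L) stop("subject ", ids[k], " has no dose records")
    subjects[[k]] <- list(
      y = as.numeric(obs$dv),
      tsd = outer(as.numeric(obs$time), as.numeric(doses$time), "-"),
      tinf = as.numeric(doses$tinf),
      rate = as.numeric(doses$amt) / as.numeric(doses$tinf),
      time = as.numeric(obs$time))
    ce[k] <- d$ce[1]
  }
  keep <- vapply(subjects, function(s) length(s$y) > 0L, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with no quantifiable observations dropped")
  }
  list(subjects = subjects[keep], ids = ids[keep], ce = ce[keep],
       n_blq = n_blq)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & as.logical(x)

param_vector <- function(model) {
  c(theta_cl = model$theta_cl, theta_cov = model$theta_cov,
    vc = model$vc, q = model$q, vp = model$vp,
    omega_cl = model$omega_cl, omega_vc = model$omega_vc,
    omega_vp = model$omega_vp, sigma_prop = model$sigma_prop,
    power = model$power)
}

model_from_params <- function(p, template) {
  m <- template
  for (nm in names(p)) m[[nm]] <- unname(p[[nm]])
  class(m) <- "pk_model"
  m
}

# OFV of prepared subjects at a parameter vector. tvcl floored at 0.01 L/h
# (linear covariate guard).
ofv_prepared <- function(prep, p, ce_ref, f_unbound = 0.98, detail = FALSE) {
  tvcl <- pmax(p[["theta_cl"]] * (1 + p[["theta_cov"]] * (prep$ce - ce_ref)),
               0.01)
  .nlme_ofv_cpp(prep$subjects, tvcl, p[["vc"]], p[["q"]], p[["vp"]],
                c(p[["omega_cl"]], p[["omega_vc"]], p[["omega_vp"]]),
                p[["sigma_prop"]], p[["power"]], detail)
}

#' Objective function value (approximate -2 log marginal likelihood)
#'
#' Per-subject Laplace approximation at the conditional mode of the random
#' effects, residual variance evaluated at the conditional prediction
#' (interaction); additive 2*pi constants dropped.
#'
#' @param model A [pk_model] at which to evaluate the objective.
#' @param dataset A PK dataset (see [read_pk_dataset()]); observations
#'   flagged `blq` are excluded from the likelihood.
#' @param method Approximation; only `"laplace_foce"` is implemented.
#' @return The OFV (numeric scalar) with attributes `ofv_subject`,
#'   `eta_hat` (subjects x 3 matrix), `converged` and `n_blq`.
#' @export
ofv_nlme <- function(model, dataset, method = "laplace_foce") {
  method <- match.arg(method)
  prep <- prepare_subjects(dataset)
  res <- ofv_prepared(prep, param_vector(model), model$ce_ref)
  if (!all(res$converged)) {
    stop("inner optimisation failed for subject(s): ",
         paste(prep$ids[!res$converged], collapse = ", "))
  }
  structure(res$ofv, ofv_subject = res$ofv_subject, eta_hat = res$eta_hat,
            converged = res$converged, n_blq = prep$n_blq, ids = prep$ids)
}

# --- fitting ----------------------------------------------------------------

#' Fit the population model by Laplace approximation
#'
#' Outer quasi-Newton (`nlminb`) minimisation of the Laplace OFV. Structural
#' parameters are optimised on the identity scale (box-constrained
#' positive); variance-scale parameters (`omega_*`, `sigma_prop`, `power`)
#' on the log scale. The inner conditional-mode search restarts from 0 at
#' every outer iteration.
#'
#' @param dataset A PK dataset with a `ce` covariate column.
#' @param init A [pk_model] supplying initial values (and the eGFR
#'   centering `ce_ref`, which is not estimated).
#' @param fixed Character vector of parameter names fixed at their initial
#'   values (from `theta_cl`, `theta_cov`, `vc`, `q`, `vp`, `omega_cl`,
#'   `omega_vc`, `omega_vp`, `sigma_prop`, `power`). An omega fixed at 0
#'   removes that random effect.
#' @param compute_se Compute standard errors from the numerical Hessian of
#'   the outer objective (slower); RSEs are reported on the natural scale.
#' @param control List: `rel_tol` (relative OFV convergence tolerance,
#'   default 1e-6), `maxit` (outer iteration cap, default 300),
#'   `trace` (0/1).
#' @return An object of class `est_result`: estimates as a [pk_model],
#'   `ofv`, per-parameter `se`/`rse` (% of estimate), empirical Bayes
#'   estimates `ebe`, `shrinkage` (%), convergence status, and BLQ
#'   bookkeeping.
#' @export
fit_nlme <- function(dataset, init = meropenem_model(), fixed = character(),
                     compute_se = TRUE, control = list()) {
  ctrl <- utils::modifyList(list(rel_tol = 1e-6, maxit = 300, trace = 0),
                            control)
  validate_pk_model(init)
  prep <- prepare_subjects(dataset)
  p0 <- param_vector(init)
  bad <- setdiff(fixed, names(p0))
  if (length(bad)) stop("unknown parameter(s) in fixed: ",
                        paste(bad, collapse = ", "))
  log_scale <- c("omega_cl", "omega_vc", "omega_vp", "sigma_prop", "power")
  free <- setdiff(names(p0), fixed)
  # an omega initialised at 0 cannot be estimated on the log scale
  free <- setdiff(free, names(p0)[p0 == 0 & names(p0) %in% log_scale])

  to_opt <- function(p) {
    ls <- names(p) %in% log_scale
    p[ls] <- log(p[ls])
    p
  }
  from_opt <- function(x, nm) {
    ls <- nm %in% log_scale
    x[ls] <- exp(x[ls])
    x
  }

  x0 <- to_opt(p0)[free]
  lower <- ifelse(free %in% c("theta_cl", "vc", "q", "vp"), 1e-3,
                  ifelse(free %in% log_scale, -15, -Inf))
  upper <- ifelse(free %in% log_scale, 5, Inf)

  n_eval <- 0L
  obj <- function(x) {
    p <- p0
    p[free] <- from_opt(x, free)
    n_eval <<- n_eval + 1L
    res <- try(ofv_prepared(prep, p, init$ce_ref), silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$ofv)) return(1e10)
    res$ofv
  }
  if (length(free)) {
    opt <- stats::nlminb(x0, obj, lower = lower, upper = upper,
                         control = list(rel.tol = ctrl$rel_tol,
                                        iter.max = ctrl$maxit,
                                        eval.max = 10 * ctrl$maxit,
                                        trace = ctrl$trace))
  } else {
    # nothing to estimate: evaluate at the initial values
    opt <- list(par = x0, convergence = 0L, message = "all parameters fixed",
                iterations = 0L)
  }
  p_hat <- p0
  p_hat[free] <- from_opt(opt$par, free)
  final <- ofv_prepared(prep, p_hat, init$ce_ref)
  if (!all(final$converged)) {
    warning("inner optimisation not fully converged for subject(s): ",
            paste(prep$ids[!final$converged], collapse = ", "))
  }

  se <- rse <- stats::setNames(rep(NA_real_, length(p_hat)), names(p_hat))
  if (compute_se && length(free)) {
    h <- try(stats::optimHess(opt$par, obj), silent = TRUE)
    if (!inherits(h, "try-error")) {
      cov_t <- try(solve(h / 2), silent = TRUE) # OFV = -2 logL
      if (!inherits(cov_t, "try-error") && all(diag(cov_t) > 0)) {
        se_t <- sqrt(diag(cov_t))
        # delta method back to natural scale for log-parameterised entries
        jac <- ifelse(free %in% log_scale, p_hat[free], 1)
        se[free] <- se_t * jac
        rse[free] <- 100 * se[free] / abs(p_hat[free])
      }
    }
  }

  ebe <- data.frame(id = prep$ids, eta_cl = final$eta_hat[, 1],
                    eta_vc = final$eta_hat[, 2], eta_vp = final$eta_hat[, 3])
  fit <- structure(list(
    model = model_from_params(p_hat, init),
    ofv = final$ofv,
    estimates = p_hat, se = se, rse = rse,
    ebe = ebe,
    shrinkage = shrinkage_from_ebe(ebe, p_hat),
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations, n_eval = n_eval,
                       inner_ok = all(final$converged)),
    fixed = fixed, n_obs = final$n_obs, n_blq = prep$n_blq,
    n_subjects = length(prep$ids),
    data = dataset), class = "est_result")
  fit
}

shrinkage_from_ebe <- function(ebe, p) {
  om <- c(eta_cl = p[["omega_cl"]], eta_vc = p[["omega_vc"]],
          eta_vp = p[["omega_vp"]])
  out <- stats::setNames(rep(NA_real_, 3), names(om))
  for (nm in names(om)) {
    if (om[nm] > 0) out[nm] <- 100 * (1 - stats::sd(ebe[[nm]]) / om[nm])
  }
  out
}

#' @export
print.est_result <- function(x, ...) {
  cat("NLME fit (Laplace)\n")
  cat(sprintf("  OFV %.3f | %d subjects, %d observations (%d BLQ dropped)\n",
              x$ofv, x$n_subjects, x$n_obs, x$n_blq))
  cat(sprintf("  convergence code %d (%s)\n", x$convergence$code,
              x$convergence$message))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = signif(x$rse, 3))
  tab$fixed <- ifelse(names(x$estimates) %in% x$fixed, "yes", "")
  print(tab)
  sh <- x$shrinkage[!is.na(x$shrinkage)]
  if (length(sh)) {
    cat("  shrinkage (%):",
        paste(sprintf("%s %.1f", names(sh), sh), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' Delta-OFV = OFV(reduced) - OFV(full), compared (strict inequality)
#' against the chi-square thresholds used in stepwise covariate modelling:
#' 3.84 (1 df) / 5.99 (2 df) for p < 0.05, 6.635 (1 df) for forward
#' inclusion at p < 0.01 and 10.83 (1 df) for backward exclusion at
#' p < 0.001.
#'
#' @param full,reduced `est_result` objects (or bare OFV numbers); the
#'   reduced model must be nested in the full one.
#' @param df Degrees-of-freedom difference (>= 1).
#' @return List with `delta_ofv` and logical flags `significant_p05`,
#'   `forward_p01`, `backward_p001`.
#' @export
compare_nested <- function(full, reduced, df = 1) {
  if (df < 1) stop("compare_nested: df must be >= 1")
  ofv_f <- if (inherits(full, "est_result")) full$ofv else as.numeric(full)
  ofv_r <- if (inherits(reduced, "est_result")) reduced$ofv else as.numeric(reduced)
  d <- ofv_r - ofv_f
  crit05 <- if (df == 1) 3.84 else if (df == 2) 5.99 else stats::qchisq(0.95, df)
  eps <- 1e-9 # strict inequality, robust to floating-point ties
  list(delta_ofv = d,
       significant_p05 = d > crit05 + eps,
       forward_p01 = df == 1 && d > 6.635 + eps,
       backward_p001 = df == 1 && d > 10.83 + eps)
}

#' Univariate covariate scan on clearance
#'
#' For each candidate column, fits `CL = theta_cl * (1 + theta_cov * (x -
#' median(x)))` and reports the OFV drop against the no-covariate base
#' model. A full stepwise search is a loop over this with the
#' [compare_nested()] thresholds.
#'
#' @param dataset A PK dataset containing the candidate columns.
#' @param candidates Character vector of covariate column names.
#' @param init Initial [pk_model]; its `theta_cov` is zeroed for the base.
#' @param control Passed to [fit_nlme()].
#' @return data.frame with one row per candidate: `delta_ofv`,
#'   `theta_cov_hat`, `ce_ref` (the centering median) and the forward
#'   p < 0.01 flag. Constant columns are skipped with a warning.
#' @export
covariate_scan <- function(dataset, candidates, init = meropenem_model(),
                           control = list()) {
  miss <- setdiff(candidates, names(dataset))
  if (length(miss)) stop("candidate column(s) not in dataset: ",
                         paste(miss, collapse = ", "))
  base_init <- init
  base_init$theta_cov <- 0
  base <- fit_nlme(dataset, base_init, fixed = "theta_cov",
                   compute_se = FALSE, control = control)
  rows <- list()
  for (cand in candidates) {
    x <- dataset[[cand]][!duplicated(dataset$id)]
    if (anyNA(x)) stop("candidate '", cand, "' has missing values")
    if (stats::sd(x) == 0) {
      warning("candidate '", cand, "' is constant; skipped")
      next
    }
    d2 <- dataset
    d2$ce <- dataset[[cand]]
    cand_init <- base$model
    cand_init$ce_ref <- stats::median(x)
    cand_init$theta_cov <- 0.001
    f <- fit_nlme(d2, cand_init, compute_se = FALSE, control = control)
    cmp <- compare_nested(f, base, df = 1)
    rows[[cand]] <- data.frame(
      covariate = cand, delta_ofv = cmp$delta_ofv,
      theta_cov_hat = f$estimates[["theta_cov"]],
      ce_ref = cand_init$ce_ref, forward_p01 = cmp$forward_p01)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- diagnostics ------------------------------------------------------------

#' Conditional weighted residuals
#'
#' FOCE-linearised CWRES: the observation vector minus the linearised
#' population prediction `f(eta_hat) - G eta_hat`, decorrelated by the
#' Cholesky factor of the linearised covariance `G Omega G' + V(eta_hat)`.
#' Approximately standard normal under a correct model.
#'
#' @param fit An `est_result`, or a [pk_model] (evaluated without fitting).
#' @param dataset Dataset to residual-ise; defaults to the fit's data.
#' @return data.frame with `id`, `time`, `dv`, `pred` (linearised
#'   population prediction) and `cwres`.
#' @export
cwres <- function(fit, dataset = NULL) {
  if (inherits(fit, "pk_model")) {
    model <- fit
    if (is.null(dataset)) stop("cwres: dataset required with a bare model")
  } else {
    model <- fit$model
    if (is.null(dataset)) dataset <- fit$data
  }
  prep <- prepare_subjects(dataset)
  p <- param_vector(model)
  res <- ofv_prepared(prep, p, model$ce_ref, detail = TRUE)
  om2 <- diag(c(p[["omega_cl"]], p[["omega_vc"]], p[["omega_vp"]])^2, 3)
  out <- vector("list", length(prep$ids))
  for (k in seq_along(prep$ids)) {
    det <- res$detail[[k]]
    eta <- res$eta_hat[k, ]
    G <- det$G
    v <- G %*% om2 %*% t(G) + diag(det$v_hat, length(det$v_hat))
    ch <- try(chol(v), silent = TRUE)
    if (inherits(ch, "try-error")) {
      stop("cwres: singular linearised covariance for subject ", prep$ids[k])
    }
    epred <- det$f_hat - as.vector(G %*% eta)
    w <- backsolve(ch, prep$subjects[[k]]$y - epred, transpose = TRUE)
    out[[k]] <- data.frame(id = prep$ids[k], time = prep$subjects[[k]]$time,
                           dv = prep$subjects[[k]]$y, pred = epred, cwres = w)
  }
  do.call(rbind, out)
}

#' Eta shrinkage
#'
#' `100 * (1 - sd(eta_hat) / omega)` per random effect; 100% when the data
#' carry no individual information, 0% when the EBE spread matches the
#' population SD. Undefined (NA) for omegas fixed at 0.
#'
#' @param fit An `est_result`.
#' @return Named vector of shrinkage percentages for `eta_cl`, `eta_vc`,
#'   `eta_vp`.
#' @export
eta_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "est_result"))
  if (nrow(fit$ebe) < 2) stop("eta_shrinkage: need >= 2 subjects")
  fit$shrinkage
}

# --- bootstrap --------------------------------------------------------------

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits each replicate and reports
#' the percentile median and 95% CI per parameter. Non-converged replicates
#' (outer code != 0 or non-finite OFV) are counted and excluded.
#'
#' @param dataset A PK dataset.
#' @param init Initial [pk_model] for every replicate fit.
#' @param n_reps Number of bootstrap replicates (>= 1; 2000 at study
#'   scale, far fewer for desk use).
#' @param fixed,control Passed to [fit_nlme()].
#' @return Object of class `boot_result`: `summary` data.frame (median,
#'   ci_lo, ci_hi per parameter), `estimates` matrix, `n_failed`.
#' @export
bootstrap_nlme <- function(dataset, init = meropenem_model(), n_reps = 200,
                           fixed = character(), control = list()) {
  if (n_reps < 1) stop("bootstrap_nlme: n_reps must be >= 1")
  ids <- unique(dataset$id)
  est <- matrix(NA_real_, n_reps, length(param_vector(init)),
                dimnames = list(NULL, names(param_vector(init))))
  failed <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(j) {
      d <- dataset[dataset$id == take[j], , drop = FALSE]
      d$id <- j
      d
    })
    rep_data <- do.call(rbind, pieces)
    f <- try(fit_nlme(rep_data, init, fixed = fixed, compute_se = FALSE,
                      control = control), silent = TRUE)
    if (inherits(f, "try-error") || !is.finite(f$ofv)) {
      failed[r] <- TRUE
    } else {
      est[r, ] <- f$estimates
    }
  }
  if (mean(failed) > 0.2) {
    warning(sprintf("bootstrap: %.0f%% of replicates failed to converge",
                    100 * mean(failed)))
  }
  ok <- est[!failed, , drop = FALSE]
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(ok, 2, stats::median),
    ci_lo = apply(ok, 2, stats::quantile, 0.025),
    ci_hi = apply(ok, 2, stats::quantile, 0.975))
  rownames(summ) <- NULL
  structure(list(summary = summ, estimates = ok, n_failed = sum(failed),
                 n_reps = n_reps), class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d replicates (%d failed)\n",
              x$n_reps, x$n_failed))
  print(transform(x$summary, median = signif(median, 4),
                  ci_lo = signif(ci_lo, 4), ci_hi = signif(ci_hi, 4)))
  invisible(x)
}

# --- visual predictive check ------------------------------------------------

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the fitted model at the
#' observed design, normalises observed and simulated values by the
#' bin-median population prediction (prediction correction; with the
#' power-proportional residual model this also corrects the residual
#' variability), and compares observed 10/50/90th percentiles per time bin
#' with the 95% CI of the corresponding simulated percentiles.
#'
#' @param fit An `est_result` (or a bare [pk_model] with `dataset` given).
#' @param dataset Dataset defining design and observations; defaults to the
#'   fit's data.
#' @param n_sim Number of simulated replicates (>= 2; 1000 at study scale).
#' @param bins Optional numeric vector of bin edges on the time axis; by
#'   default one bin per distinct nominal sampling time. Bins with no
#'   observations are merged with their left neighbour.
#' @param correct Apply prediction correction (TRUE); FALSE gives a
#'   classical VPC.
#' @return Object of class `vpc_result`: data.frame `bins` with, per bin,
#'   observed percentiles (`obs_p10/50/90`) and simulated 95% CI bounds for
#'   each percentile (`sim_p50_lo` etc.), plus `n_sim`.
#' @export
vpc_pvc <- function(fit, dataset = NULL, n_sim = 1000, bins = NULL,
                    correct = TRUE) {
  if (inherits(fit, "pk_model")) {
    model <- fit
    if (is.null(dataset)) stop("vpc_pvc: dataset required with a bare model")
  } else {
    model <- fit$model
    if (is.null(dataset)) dataset <- fit$data
  }
  if (n_sim < 2) stop("vpc_pvc: n_sim must be >= 2")
  prep <- prepare_subjects(dataset)
  p <- param_vector(model)
  tvcl <- pmax(p[["theta_cl"]] * (1 + p[["theta_cov"]] * (prep$ce - model$ce_ref)),
               0.01)
  nobs <- vapply(prep$subjects, function(s) length(s$y), integer(1))
  sub_idx <- rep(seq_along(prep$subjects), nobs)
  times <- unlist(lapply(prep$subjects, `[[`, "time"))
  y_obs <- unlist(lapply(prep$subjects, `[[`, "y"))

  # population prediction (eta = 0) per observation
  pred <- unlist(lapply(seq_along(prep$subjects), function(k) {
    s <- prep$subjects[[k]]
    .conc_design_cpp(tvcl[k], p[["vc"]], p[["vp"]], p[["q"]],
                     s$tsd, s$tinf, s$rate)
  }))

  if (is.null(bins)) {
    nominal <- sort(unique(round(times, 6)))
    edges <- c(-Inf, utils::head(nominal, -1) + diff(nominal) / 2, Inf)
  } else {
    edges <- unique(sort(c(-Inf, bins, Inf)))
  }
  bin <- cut(times, edges, labels = FALSE)
  # merge empty/singleton bins leftwards
  tab <- table(factor(bin, levels = seq_len(length(edges) - 1)))
  if (any(tab == 0)) {
    keep <- as.integer(names(tab)[tab > 0])
    bin <- match(bin, keep)
  }
  nb <- max(bin)

  pred_med <- tapply(pred, bin, stats::median)
  cf <- if (correct) pred_med[bin] / pred else rep(1, length(pred))

  qs <- c(0.1, 0.5, 0.9)
  obs_q <- t(vapply(seq_len(nb), function(b)
    stats::quantile(y_obs[bin == b] * cf[bin == b], qs, names = FALSE),
    numeric(3)))

  sim_q <- array(NA_real_, c(n_sim, nb, 3))
  for (s in seq_len(n_sim)) {
    eta <- cbind(stats::rnorm(length(tvcl), 0, p[["omega_cl"]]),
                 stats::rnorm(length(tvcl), 0, p[["omega_vc"]]),
                 stats::rnorm(length(tvcl), 0, p[["omega_vp"]]))
    ysim <- unlist(lapply(seq_along(prep$subjects), function(k) {
      su <- prep$subjects[[k]]
      f <- .conc_design_cpp(tvcl[k] * exp(eta[k, 1]),
                            p[["vc"]] * exp(eta[k, 2]),
                            p[["vp"]] * exp(eta[k, 3]), p[["q"]],
                            su$tsd, su$tinf, su$rate)
      f <- pmax(f, 1e-12)
      pmax(f + f^p[["power"]] * stats::rnorm(length(f), 0, p[["sigma_prop"]]), 0)
    }))
    ysim <- ysim * cf
    for (b in seq_len(nb)) {
      sim_q[s, b, ] <- stats::quantile(ysim[bin == b], qs, names = FALSE)
    }
  }
  ci <- apply(sim_q, c(2, 3), stats::quantile, c(0.025, 0.5, 0.975))
  out <- data.frame(
    bin = seq_len(nb),
    time_mid = as.numeric(tapply(times, bin, stats::median)),
    n_obs = as.integer(table(bin)),
    obs_p10 = obs_q[, 1], obs_p50 = obs_q[, 2], obs_p90 = obs_q[, 3],
    sim_p10_lo = ci[1, , 1], sim_p10_hi = ci[3, , 1],
    sim_p50_lo = ci[1, , 2], sim_p50_med = ci[2, , 2], sim_p50_hi = ci[3, , 2],
    sim_p90_lo = ci[1, , 3], sim_p90_hi = ci[3, , 3])
  structure(list(bins = out, n_sim = n_sim, corrected = correct),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("%s visual predictive check, %d simulated replicates\n",
              if (x$corrected) "Prediction-corrected" else "Classical",
              x$n_sim))
  print(x$bins, digits = 4)
  invisible(x)
}
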