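# Closed-form two-compartment IV-infusion kinetics.
#
# Hybrid rate constants: with k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp,
#   alpha + beta = k10 + k12 + k21,  alpha * beta = k10 * k21,
# the unit-bolus central concentration is (A e^{-alpha t} + B e^{-beta t})/Vc
# with A = (alpha - k21)/(alpha - beta), B = (k21 - beta)/(alpha - beta).
# Constant-rate infusion and multiple dosing follow by convolution and
# superposition; steady state closes the geometric series on each
# exponential term.

micro_constants <- function(cl, vc, vp, q) {
  k10 <- cl / vc
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  disc2 <- s * s - 4 * k10 * k21
  # alpha = beta only in the degenerate repeated-root case; nudge the
  # discriminant so the generic expressions remain valid (relative error
  # of the nudge ~1e-9, far below the 1e-6 accuracy contract)
  disc <- sqrt(pmax(disc2, (1e-9 * s)^2))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(alpha = alpha, beta = beta,
       A = (alpha - k21) / (alpha - beta),
       B = (k21 - beta) / (alpha - beta))
}

#' Concentration after a single IV infusion
#'
#' Analytic central-compartment concentration of a two-compartment model
#' after one constant-rate infusion starting at time 0.
#'
#' @param p Individual parameters: a list or one-row data.frame with
#'   elements `cl` (L/h), `vc` (L), `vp` (L), `q` (L/h), e.g. a row of
#'   [individual_from_eta()].
#' @param dose Dose in mg.
#' @param tinf Infusion duration in h.
#' @param t Times since infusion start in h (vectorised); `t < 0` gives 0.
#' @return Total concentration in mg/L at each `t`.
#' @examples
#' p <- individual_from_eta(meropenem_model(), 91.57)
#' conc_single_dose(p, 1000, 0.5, c(0.5, 1, 4, 8))
#' @export
conc_single_dose <- function(p, dose, tinf, t) {
  stopifnot(dose > 0, tinf > 0, all(is.finite(t)))
  mc <- micro_constants(p$cl, p$vc, p$vp, p$q)
  r0 <- dose / tinf
  ca <- mc$A / mc$alpha
  cb <- mc$B / mc$beta
  out <- numeric(length(t))
  dur <- t >= 0 & t <= tinf
  if (any(dur)) {
    td <- t[dur]
    out[dur] <- (r0 / p$vc) * (ca * (1 - exp(-mc$alpha * td)) +
                               cb * (1 - exp(-mc$beta * td)))
  }
  post <- t > tinf
  if (any(post)) {
    tp <- t[post] - tinf
    out[post] <- (r0 / p$vc) *
      (ca * (1 - exp(-mc$alpha * tinf)) * exp(-mc$alpha * tp) +
       cb * (1 - exp(-mc$beta * tinf)) * exp(-mc$beta * tp))
  }
  out
}

#' Steady-state concentration at arbitrary times within a dosing interval
#'
#' Closed-form steady-state concentration under repeated dosing, obtained by
#' summing the geometric series of the single-dose exponential terms.
#'
#' @inheritParams conc_single_dose
#' @param regimen A [dosing_regimen()].
#' @param t Times within the dosing interval, `0 <= t <= interval` (h).
#' @return Total concentration in mg/L.
#' @export
ss_conc <- function(p, regimen, t) {
  stopifnot(all(t >= 0), all(t <= regimen$interval + 1e-12))
  single <- conc_single_dose(p, regimen$dose, regimen$tinf, t)
  mc <- micro_constants(p$cl, p$vc, p$vp, p$q)
  r0 <- regimen$dose / regimen$tinf
  ra <- exp(-mc$alpha * regimen$interval)
  rb <- exp(-mc$beta * regimen$interval)
  tail <- (r0 / p$vc) *
    ((mc$A / mc$alpha) * (1 - exp(-mc$alpha * regimen$tinf)) *
       exp(-mc$alpha * (t - regimen$tinf)) * ra / (1 - ra) +
     (mc$B / mc$beta) * (1 - exp(-mc$beta * regimen$tinf)) *
       exp(-mc$beta * (t - regimen$tinf)) * rb / (1 - rb))
  single + tail
}

#' Steady-state concentration-time profile over one dosing interval
#'
#' @inheritParams ss_conc
#' @param grid_step Grid spacing in h (default 0.02); the end-of-infusion
#'   breakpoint is inserted exactly.
#' @return An object of class `concentration_profile`: list with `times`
#'   (h, strictly increasing, spanning `[0, interval]`) and `conc` (mg/L).
#' @export
steady_state_profile <- function(p, regimen, grid_step = 0.02) {
  stopifnot(grid_step > 0)
  times <- profile_grid(regimen$interval, regimen$tinf, grid_step)
  structure(list(times = times, conc = ss_conc(p, regimen, times)),
            class = "concentration_profile")
}

profile_grid <- function(interval, tinf, grid_step) {
  times <- seq(0, interval, by = grid_step)
  if (times[length(times)] < interval) times <- c(times, interval)
  sort(unique(c(times, tinf)))
}

# Steady-state profiles for a whole cohort at once: one row per individual.
# pars is a data.frame with columns cl, vc, vp, q.
ss_profile_matrix <- function(pars, regimen, grid_step = 0.02) {
  t <- profile_grid(regimen$interval, regimen$tinf, grid_step)
  mc <- micro_constants(pars$cl, pars$vc, pars$vp, pars$q)
  r0 <- regimen$dose / regimen$tinf
  ca <- mc$A / mc$alpha
  cb <- mc$B / mc$beta
  ea_inf <- 1 - exp(-mc$alpha * regimen$tinf)
  eb_inf <- 1 - exp(-mc$beta * regimen$tinf)
  ra <- exp(-mc$alpha * regimen$interval)
  rb <- exp(-mc$beta * regimen$interval)
  # n x nt exponential kernels (vector * matrix recycles by row)
  ea_t <- exp(-outer(mc$alpha, t))
  eb_t <- exp(-outer(mc$beta, t))
  ea_post <- exp(-outer(mc$alpha, t - regimen$tinf))
  eb_post <- exp(-outer(mc$beta, t - regimen$tinf))
  during <- t <= regimen$tinf
  conc <- (ca * ea_inf * ra / (1 - ra)) * ea_post +
          (cb * eb_inf * rb / (1 - rb)) * eb_post
  conc[, during] <- conc[, during] +
    ca * (1 - ea_t[, during, drop = FALSE]) +
    cb * (1 - eb_t[, during, drop = FALSE])
  if (any(!during)) {
    conc[, !during] <- conc[, !during] +
      (ca * ea_inf) * ea_post[, !during, drop = FALSE] +
      (cb * eb_inf) * eb_post[, !during, drop = FALSE]
  }
  conc <- conc * (r0 / pars$vc)
  attr(conc, "times") <- t
  conc
}

#' Percentage of the dosing interval with free concentration above a threshold
#'
#' Computes fT>MIC for a steady-state profile: the percentage of the dosing
#' interval during which the unbound concentration `f_unbound * C(t)`
#' exceeds `multiplier * mic`. Threshold crossings between grid points are
#' located by linear interpolation. At steady state this equals the 24-h
#' fraction for any interval dividing 24 h.
#'
#' @param profile A `concentration_profile` (see [steady_state_profile()]).
#' @param mic Minimum inhibitory concentration in mg/L (> 0).
#' @param f_unbound Free fraction of drug (default 0.98).
#' @param multiplier MIC multiplier (1 for fT>MIC, 4 for fT>4xMIC).
#' @return Percentage of the interval (0-100).
#' @export
ftmic <- function(profile, mic, f_unbound = 0.98, multiplier = 1) {
  if (is.null(profile$times) || length(profile$times) < 2) {
    stop("ftmic: profile must carry at least two grid points")
  }
  if (mic <= 0) stop("ftmic: mic must be > 0")
  thr <- multiplier * mic / f_unbound
  drop(ftmic_matrix(matrix(profile$conc, nrow = 1), profile$times, thr))
}

# Vectorised fT>threshold on an n x nt concentration matrix. thr is the
# total-concentration threshold (mic * multiplier / f_unbound).
ftmic_matrix <- function(conc, times, thr) {
  nt <- length(times)
  dt <- diff(times)
  fa <- conc[, -nt, drop = FALSE] - thr
  fb <- conc[, -1, drop = FALSE] - thr
  frac <- matrix(0, nrow(conc), nt - 1L)
  both <- fa > 0 & fb > 0
  frac[both] <- 1
  cross_down <- fa > 0 & fb <= 0
  frac[cross_down] <- fa[cross_down] / (fa[cross_down] - fb[cross_down])
  cross_up <- fa <= 0 & fb > 0
  frac[cross_up] <- fb[cross_up] / (fb[cross_up] - fa[cross_up])
  above <- as.vector(frac %*% dt)
  100 * above / (times[nt] - times[1])
}

# Trapezoidal AUC of a profile (used for diagnostics; exact mass-balance
# checks integrate ss_conc adaptively instead).
profile_auc <- function(profile) {
  sum(diff(profile$times) *
        (utils::head(profile$conc, -1) + utils::tail(profile$conc, -1)) / 2)
}
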