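#' Construct a population pharmacokinetic model
#'
#' Two-compartment IV-infusion model with a linear renal covariate on
#' clearance, log-normal inter-individual variability (IIV) on CL, Vc and
#' Vp, and a power-scaled proportional residual error
#' `Y = F + F^power * eps`, `eps ~ N(0, sigma^2)`.
#'
#' Typical clearance follows
#' `TVCL = theta_cl * (1 + theta_cov * (CE - ce_ref))`
#' where CE is the CKD-EPI eGFR (mL/min/1.73 m^2) and `ce_ref` its centering
#' value.
#'
#' @param theta_cl Typical clearance at the reference eGFR (L/h).
#' @param theta_cov Covariate slope per mL/min/1.73 m^2 of eGFR.
#' @param ce_ref Centering eGFR (mL/min/1.73 m^2).
#' @param vc Central volume of distribution (L).
#' @param q Inter-compartmental clearance (L/h); carries no IIV.
#' @param vp Peripheral volume of distribution (L).
#' @param omega_cl,omega_vc,omega_vp SDs of the log-normal IIV terms
#'   (dimensionless; 0.314 is approximately a 31.4% CV).
#' @param sigma_prop SD of the residual error term (dimensionless).
#' @param power Exponent scaling the residual with the prediction;
#'   `power = 1` recovers a pure proportional error.
#' @param f_unbound Unbound (free) fraction of drug in plasma.
#' @return An object of class `pk_model`.
#' @seealso [meropenem_model()] for the packaged fitted estimates.
#' @export
pk_model <- function(theta_cl, theta_cov = 0, ce_ref = 91.57,
                     vc, q, vp,
                     omega_cl = 0, omega_vc = 0, omega_vp = 0,
                     sigma_prop, power = 1, f_unbound = 0.98) {
  m <- list(theta_cl = theta_cl, theta_cov = theta_cov, ce_ref = ce_ref,
            vc = vc, q = q, vp = vp,
            omega_cl = omega_cl, omega_vc = omega_vc, omega_vp = omega_vp,
            sigma_prop = sigma_prop, power = power, f_unbound = f_unbound)
  validate_pk_model(m)
  structure(m, class = "pk_model")
}

validate_pk_model <- function(m) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(m)) {
    if (!num1(m[[nm]])) stop("pk_model: '", nm, "' must be a finite scalar")
  }
  if (m$theta_cl <= 0 || m$vc <= 0 || m$q <= 0 || m$vp <= 0) {
    stop("pk_model: theta_cl, vc, q, vp must be > 0")
  }
  if (m$omega_cl < 0 || m$omega_vc < 0 || m$omega_vp < 0) {
    stop("pk_model: omega terms must be >= 0")
  }
  if (m$sigma_prop < 0) stop("pk_model: sigma_prop must be >= 0")
  if (m$f_unbound <= 0 || m$f_unbound > 1) {
    stop("pk_model: f_unbound must be in (0, 1]")
  }
  invisible(m)
}

#' Packaged meropenem population model
#'
#' The fitted population estimates for meropenem in critically ill adults:
#' CL 6.37 L/h at the reference CKD-EPI eGFR of 91.57 mL/min/1.73 m^2 with
#' slope 0.00925 per unit eGFR, Vc 9.07 L, Q 10.7 L/h, Vp 7.91 L, IIV SDs
#' 0.314/0.436/0.366 on CL/Vc/Vp, residual SD 0.246 with power 0.865, and a
#' free fraction of 0.98.
#'
#' @return A [pk_model] carrying the packaged estimates.
#' @examples
#' m <- meropenem_model()
#' typical_cl(m, 91.57)
#' @export
meropenem_model <- function() {
  cfg <- system.file("extdata", "meropenem_model.yaml", package = "meropk")
  read_model_config(cfg)
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Two-compartment infusion population PK model\n")
  cat(sprintf("  CL  = %.4g * (1 + %.4g * (CE - %.4g)) L/h\n",
              x$theta_cl, x$theta_cov, x$ce_ref))
  cat(sprintf("  Vc  = %.4g L   Q = %.4g L/h   Vp = %.4g L\n",
              x$vc, x$q, x$vp))
  cat(sprintf("  IIV SD (CL, Vc, Vp) = %.3g, %.3g, %.3g\n",
              x$omega_cl, x$omega_vc, x$omega_vp))
  cat(sprintf("  residual: Y = F + F^%.3g * N(0, %.3g^2)\n",
              x$power, x$sigma_prop))
  cat(sprintf("  unbound fraction f = %.3g\n", x$f_unbound))
  invisible(x)
}

#' Typical (population) clearance at a given eGFR
#'
#' Evaluates the linear covariate model
#' `TVCL = theta_cl * (1 + theta_cov * (CE - ce_ref))`. The linear form can
#' go non-positive for extreme slope/eGFR combinations (e.g. inside
#' bootstrap replicates); the value is floored at 0.01 L/h with a warning.
#'
#' @param model A [pk_model].
#' @param ce CKD-EPI eGFR (mL/min/1.73 m^2), vectorised.
#' @return Typical clearance in L/h.
#' @export
typical_cl <- function(model, ce) {
  if (any(ce < 0)) stop("typical_cl: ce must be >= 0")
  cl <- model$theta_cl * (1 + model$theta_cov * (ce - model$ce_ref))
  if (any(cl < 0.01)) {
    warning("typical_cl: non-positive clearance floored at 0.01 L/h")
    cl <- pmax(cl, 0.01)
  }
  cl
}

#' Individual parameters from fixed random effects
#'
#' Applies the log-normal IIV link `P_i = TVP * exp(eta)` to clearance and
#' the two volumes; Q carries no IIV.
#'
#' @inheritParams typical_cl
#' @param eta_cl,eta_vc,eta_vp Random effects (finite, vectorised together).
#' @return A data.frame with columns `cl`, `vc`, `vp`, `q`, `vss` (all
#'   subjects in rows); `vss = vc + vp`.
#' @export
individual_from_eta <- function(model, ce, eta_cl = 0, eta_vc = 0, eta_vp = 0) {
  stopifnot(all(is.finite(eta_cl)), all(is.finite(eta_vc)), all(is.finite(eta_vp)))
  cl <- typical_cl(model, ce) * exp(eta_cl)
  vc <- model$vc * exp(eta_vc)
  vp <- model$vp * exp(eta_vp)
  out <- data.frame(cl = cl, vc = vc, vp = vp, q = model$q)
  out$vss <- out$vc + out$vp
  out
}

#' Sample individual parameters from the population model
#'
#' Draws `eta ~ N(0, omega^2)` independently for CL, Vc and Vp and applies
#' [individual_from_eta()]. Uses R's global random stream; set a seed for
#' reproducibility.
#'
#' @inheritParams typical_cl
#' @param n Number of individuals per eGFR value (recycled against `ce`).
#' @return A data.frame of individual parameters (see [individual_from_eta()]).
#' @export
sample_individual <- function(model, ce, n = length(ce)) {
  ce <- rep_len(ce, n)
  individual_from_eta(model, ce,
                      eta_cl = stats::rnorm(n, 0, model$omega_cl),
                      eta_vc = stats::rnorm(n, 0, model$omega_vc),
                      eta_vp = stats::rnorm(n, 0, model$omega_vp))
}

#' Apply the residual-error model to noise-free predictions
#'
#' `Y = F + F^power * eps`, `eps ~ N(0, sigma^2)`. Draws that fall below
#' zero are truncated to 0 and flagged.
#'
#' @inheritParams typical_cl
#' @param pred Noise-free predicted concentrations (mg/L, > 0).
#' @return Numeric vector of observations with attribute `truncated`
#'   (logical, TRUE where a draw was truncated to zero).
#' @export
apply_residual_error <- function(model, pred) {
  if (any(pred <= 0)) stop("apply_residual_error: pred must be > 0")
  y <- pred + pred^model$power * stats::rnorm(length(pred), 0, model$sigma_prop)
  trunc <- y < 0
  y[trunc] <- 0
  attr(y, "truncated") <- trunc
  y
}

#' Dosing regimen
#'
#' @param dose Dose in mg (> 0).
#' @param interval Dosing interval tau in h.
#' @param tinf Infusion duration in h, `0 < tinf <= interval`.
#' @return An object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(1000, 8, 0.5)
#' @export
dosing_regimen <- function(dose, interval, tinf = 0.5) {
  stopifnot(dose > 0, interval > 0, tinf > 0, tinf <= interval)
  structure(list(dose = dose, interval = interval, tinf = tinf),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("%g mg q%gh, %g h infusion\n", x$dose, x$interval, x$tinf))
  invisible(x)
}
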