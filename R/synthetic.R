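# Synthetic study generator.
#
# Emulates the sparse ICU sampling design the model was developed on:
# 26 adult subjects (a fraction on ECMO), 0.5/1 g doses every 8 or 12 h as
# 30-min infusions, five samples after the first dose plus a trough/peak
# pair at steady state (dose 4 or 5), power-proportional residual noise and
# a 0.2 mg/L lower limit of quantitation. Covariates are drawn from
# truncated log-normals moment-matched to the study's published medians and
# IQRs; eGFR is always computed from the sampled creatinine/age/sex through
# the renal-function equations, never sampled independently.

#' Study design description
#'
#' @param n_subjects Number of subjects.
#' @param ecmo_fraction Fraction of subjects on ECMO.
#' @param infusion_duration Infusion duration (h).
#' @param ss_dose_options Dose number (4 or 5) at which the steady-state
#'   trough/peak pair is drawn.
#' @param lloq Lower limit of quantitation (mg/L).
#' @return List of class `study_design`. First-dose nominal sampling times
#'   are 0 (pre-dose), 0.5, 1, 4, 8 h for q8h subjects and 0, 0.5, 1, 6,
#'   12 h for q12h subjects.
#' @export
study_design <- function(n_subjects = 26, ecmo_fraction = 8 / 26,
                         infusion_duration = 0.5, ss_dose_options = c(4, 5),
                         lloq = 0.2) {
  stopifnot(n_subjects >= 1, ecmo_fraction >= 0, ecmo_fraction <= 1, lloq > 0)
  structure(list(
    n_subjects = n_subjects, ecmo_fraction = ecmo_fraction,
    dose_options = c(500, 1000), interval_options = c(8, 12),
    infusion_duration = infusion_duration,
    first_dose_times_q8 = c(0, 0.5, 1, 4, 8),
    first_dose_times_q12 = c(0, 0.5, 1, 6, 12),
    ss_dose_options = ss_dose_options, lloq = lloq), class = "study_design")
}

#' Generate a synthetic ICU covariate cohort
#'
#' Demographics are sampled from truncated log-normal/normal marginals
#' centred on the study population (age ~ 70 y, weight ~ 58 kg, serum
#' creatinine ~ 0.7 mg/dL, CKD-EPI eGFR median near 90 mL/min/1.73 m^2);
#' all renal estimates derive from the sampled creatinine via
#' [renal_estimates()]. ECMO is assigned to the configured fraction with
#' VA:VV odds 7:1.
#'
#' @param design A [study_design()].
#' @return data.frame with one row per subject: demographics, `ecmo_type`
#'   (`none`/`VA`/`VV`), `crrt`, every renal estimate and `ce` (the
#'   CKD-EPI eGFR consumed by the covariate model).
#' @export
generate_cohort <- function(design = study_design()) {
  n <- design$n_subjects
  demo <- data.frame(
    id = seq_len(n),
    sex = ifelse(stats::runif(n) < 18 / 26, "male", "female"),
    age = rlnorm_truncated(n, log(69), 0.17, 25, 95),
    height = pmin(pmax(stats::rnorm(n, 164, 8), 140), 190),
    weight = rlnorm_truncated(n, log(58), 0.16, 35, 110),
    scr = rlnorm_truncated(n, log(0.72), 0.45, 0.2, 5),
    cysc = rlnorm_truncated(n, log(1.4), 0.28, 0.4, 5),
    albumin = pmin(pmax(stats::rnorm(n, 2.8, 0.35), 1.5), 4.5))
  n_ecmo <- round(design$ecmo_fraction * n)
  ecmo_ids <- sample(n, n_ecmo)
  demo$ecmo_type <- "none"
  demo$ecmo_type[ecmo_ids] <- ifelse(stats::runif(n_ecmo) < 7 / 8, "VA", "VV")
  demo$crrt <- stats::runif(n) < 2 / 26
  demo <- renal_estimates(demo)
  demo$ce <- demo$egfr_ckd_epi
  demo
}

# Concentration at arbitrary times for one subject's dose history, by
# superposition of the closed-form single-dose solution.
conc_dose_history <- function(p, dose_times, amounts, tinfs, t) {
  out <- numeric(length(t))
  for (j in seq_along(dose_times)) {
    out <- out + conc_single_dose(p, amounts[j], tinfs[j], t - dose_times[j])
  }
  out
}

#' Generate a synthetic concentration study
#'
#' For each cohort subject: the regimen follows the renal banding of
#' [recommended_regimen()] restricted to the study's q8/q12 design (the
#' q24h band is dosed 0.5 g q12h), true parameters come from
#' [sample_individual()], observations get power-proportional residual
#' noise, and values below the LLOQ are flagged (retained, not dropped).
#' The pre-dose sample before the first dose is recorded at time 0 with
#' concentration 0 and flagged `predose` and `blq`. Five first-dose samples
#' form the development split; the steady-state trough/peak pair (dose 4 or
#' 5, chosen at random per subject) forms the validation split.
#'
#' @param model A [pk_model].
#' @param cohort A cohort from [generate_cohort()].
#' @param design A [study_design()].
#' @return A PK dataset data.frame (see [read_pk_dataset()] for the
#'   dialect) with `purpose` (`development`/`validation`), `predose` and
#'   `blq` flags and the cohort covariates joined per row. True individual
#'   parameters are attached as attribute `true_params`.
#' @export
generate_study <- function(model = meropenem_model(),
                           cohort = generate_cohort(design),
                           design = study_design()) {
  rows <- list()
  true_pars <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sub <- cohort[i, ]
    reg <- recommended_regimen(sub$ce)
    if (reg$interval == 24) reg <- dosing_regimen(reg$dose, 12, reg$tinf)
    reg$tinf <- design$infusion_duration
    p <- sample_individual(model, sub$ce, 1)
    true_pars[[i]] <- cbind(id = sub$id, p)
    ss_dose <- if (length(design$ss_dose_options) == 1) design$ss_dose_options
               else sample(design$ss_dose_options, 1)
    dose_times <- (seq_len(ss_dose) - 1) * reg$interval
    first_times <- if (reg$interval == 8) design$first_dose_times_q8
                   else design$first_dose_times_q12
    obs <- data.frame(
      time = c(first_times, dose_times[ss_dose], dose_times[ss_dose] + 0.5),
      purpose = c(rep("development", length(first_times)),
                  "validation", "validation"))
    obs$predose <- obs$time == 0 & obs$purpose == "development"
    amounts <- rep(reg$dose, ss_dose)
    tinfs <- rep(reg$tinf, ss_dose)
    ctrue <- conc_dose_history(p, dose_times, amounts, tinfs, obs$time)
    dv <- numeric(nrow(obs))
    pos <- ctrue > 0
    if (any(pos)) dv[pos] <- apply_residual_error(model, ctrue[pos])
    obs$dv <- dv
    obs$blq <- obs$dv < design$lloq
    dose_rows <- data.frame(
      id = sub$id, time = dose_times, evid = 1L, amt = amounts, tinf = tinfs,
      dv = NA_real_, blq = NA, predose = NA, purpose = NA_character_)
    obs_rows <- data.frame(
      id = sub$id, time = obs$time, evid = 0L, amt = NA_real_,
      tinf = NA_real_, dv = obs$dv, blq = obs$blq, predose = obs$predose,
      purpose = obs$purpose)
    d <- rbind(dose_rows, obs_rows)
    d <- d[order(d$time, -d$evid), ]
    cov_cols <- c("ce", "age", "sex", "weight", "height", "scr", "cysc",
                  "albumin", "ecmo_type", "crrt")
    d[cov_cols] <- sub[cov_cols]
    rows[[i]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_params") <- do.call(rbind, true_pars)
  validate_pk_dataset(out)
  out
}

#' Inject a timing-documentation error
#'
#' Shifts the *recorded* time of chosen observation rows while leaving the
#' concentration (simulated at the true time) untouched — the
#' mis-documented sampling time scenario that inflates external-validation
#' errors.
#'
#' @param dataset A PK dataset.
#' @param n_records Number of observation records to corrupt.
#' @param shift Hours added to the recorded time.
#' @param purpose Restrict candidates to this split (default
#'   `"validation"`).
#' @return The dataset with shifted `time` on the chosen rows and a logical
#'   `time_corrupted` column.
#' @export
inject_timing_error <- function(dataset, n_records = 2, shift = 0.5,
                                purpose = "validation") {
  cand <- which(dataset$evid == 0L & !is.na(dataset$purpose) &
                  dataset$purpose == purpose)
  if (length(cand) < n_records) stop("not enough candidate observations")
  pick <- sample(cand, n_records)
  dataset$time_corrupted <- FALSE
  dataset$time_corrupted[pick] <- TRUE
  dataset$time[pick] <- dataset$time[pick] + shift
  dataset
}

#' Write the deterministic test fixtures
#'
#' Two small datasets used by the test suite: a 4-subject noise-free,
#' IIV-free dataset (round-trips exactly through the closed-form model) and
#' a 26-subject noisy dataset at the packaged model parameters; both from
#' fixed seeds.
#'
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
make_fixtures <- function(dir = tempdir()) {
  m <- meropenem_model()
  noiseless <- m
  noiseless$omega_cl <- noiseless$omega_vc <- noiseless$omega_vp <- 0
  noiseless$sigma_prop <- 0
  withr_seed(104, {
    coh4 <- generate_cohort(study_design(n_subjects = 4, ecmo_fraction = 0))
    ds4 <- generate_study(noiseless, coh4)
  })
  withr_seed(2026, {
    coh26 <- generate_cohort(study_design())
    ds26 <- generate_study(m, coh26)
  })
  p4 <- file.path(dir, "fixture_noisefree_4subj.csv")
  p26 <- file.path(dir, "fixture_noisy_26subj.csv")
  write_pk_dataset(ds4, p4)
  write_pk_dataset(ds26, p26)
  invisible(c(p4, p26))
}

# run expr under a local seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
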