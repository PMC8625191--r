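#' Body surface area by the Du Bois formula
#'
#' BSA (m^2) = 0.007184 x height^0.725 x weight^0.425.
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return Body surface area in m^2.
#' @examples
#' bsa_dubois(170, 68)
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("bsa_dubois: height and weight must be finite and > 0")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Creatinine clearance by Cockcroft-Gault
#'
#' CrCl (mL/min) = (140 - age) x weight / (72 x Scr), multiplied by 0.85
#' for females.
#'
#' @param age Age in years (0 < age < 140).
#' @param weight_kg Actual body weight in kg.
#' @param scr Serum creatinine in mg/dL.
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Creatinine clearance in mL/min.
#' @examples
#' crcl_cockcroft_gault(40, 72, 1.0, "male")
#' @export
crcl_cockcroft_gault <- function(age, weight_kg, scr, sex) {
  sex <- check_sex(sex)
  if (any(age <= 0) || any(age >= 140)) {
    stop("crcl_cockcroft_gault: age must be in (0, 140) years")
  }
  if (any(weight_kg <= 0) || any(scr <= 0)) {
    stop("crcl_cockcroft_gault: weight and serum creatinine must be > 0")
  }
  cg <- (140 - age) * weight_kg / (72 * scr)
  ifelse(sex == "female", 0.85 * cg, cg)
}

#' eGFR by the 2009 CKD-EPI creatinine equation
#'
#' Sex-specific kappa (0.7 female / 0.9 male) and alpha (-0.329 / -0.411)
#' terms with the 0.993^age factor. The race coefficient of the published
#' equation is intentionally omitted: the model this package implements was
#' developed in an all-Korean cohort and never applies it.
#'
#' @inheritParams crcl_cockcroft_gault
#' @return eGFR in mL/min/1.73 m^2 (indexed to body surface area).
#' @examples
#' egfr_ckd_epi(60, 0.7, "female")
#' @export
egfr_ckd_epi <- function(age, scr, sex) {
  sex <- check_sex(sex)
  if (any(age <= 0) || any(scr <= 0)) {
    stop("egfr_ckd_epi: age and serum creatinine must be > 0")
  }
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  mult  <- ifelse(sex == "female", 144, 141)
  r <- scr / kappa
  mult * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age
}

#' eGFR by the 4-variable MDRD equation
#'
#' 175 x Scr^-1.154 x age^-0.203 (x 0.742 for females), the IDMS-traceable
#' form. The race coefficient is omitted (see [egfr_ckd_epi()]); the leading
#' coefficient is exposed for the non-IDMS 186 variant.
#'
#' @inheritParams crcl_cockcroft_gault
#' @param coefficient Leading coefficient, 175 (IDMS, default) or 186.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_mdrd <- function(age, scr, sex, coefficient = 175) {
  sex <- check_sex(sex)
  if (any(age <= 0) || any(scr <= 0)) {
    stop("egfr_mdrd: age and serum creatinine must be > 0")
  }
  g <- coefficient * scr^-1.154 * age^-0.203
  ifelse(sex == "female", 0.742 * g, g)
}

#' De-index a BSA-normalised GFR to absolute mL/min
#'
#' GFR (mL/min) = GFR (mL/min/1.73 m^2) x BSA / 1.73.
#'
#' @param egfr_indexed eGFR indexed to 1.73 m^2.
#' @param bsa Individual body surface area in m^2 (> 0).
#' @return Absolute GFR in mL/min.
#' @export
deindex_gfr <- function(egfr_indexed, bsa) {
  if (any(bsa <= 0)) stop("deindex_gfr: bsa must be > 0")
  egfr_indexed * bsa / 1.73
}

#' All renal-function and body-size covariates for a set of subjects
#'
#' Convenience wrapper computing every renal estimate the covariate analysis
#' uses from a demographic table.
#'
#' @param demo Data frame with columns `age` (years), `sex`
#'   (`"male"`/`"female"`), `weight` (kg), `height` (cm), `scr` (mg/dL).
#' @return `demo` with columns `bsa` (m^2), `crcl_cg` (mL/min), `egfr_mdrd`
#'   and `egfr_ckd_epi` (mL/min/1.73 m^2), and their de-indexed
#'   `egfr_mdrd_deindexed` / `egfr_ckd_epi_deindexed` (mL/min) appended.
#' @export
renal_estimates <- function(demo) {
  req <- c("age", "sex", "weight", "height", "scr")
  miss <- setdiff(req, names(demo))
  if (length(miss)) {
    stop("renal_estimates: missing columns: ", paste(miss, collapse = ", "))
  }
  demo$bsa <- bsa_dubois(demo$height, demo$weight)
  demo$crcl_cg <- crcl_cockcroft_gault(demo$age, demo$weight, demo$scr, demo$sex)
  demo$egfr_mdrd <- egfr_mdrd(demo$age, demo$scr, demo$sex)
  demo$egfr_ckd_epi <- egfr_ckd_epi(demo$age, demo$scr, demo$sex)
  demo$egfr_mdrd_deindexed <- deindex_gfr(demo$egfr_mdrd, demo$bsa)
  demo$egfr_ckd_epi_deindexed <- deindex_gfr(demo$egfr_ckd_epi, demo$bsa)
  demo
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  sex
}
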