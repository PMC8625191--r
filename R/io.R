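# Dataset and configuration I/O, and the seeded simulation orchestrator.
#
# Tabular interchange is long-format CSV throughout. Dataset dialect:
#   id    subject identifier
#   time  h since first dose
#   evid  1 = dose record, 0 = observation record
#   amt   dose amount, mg (dose rows only)
#   tinf  infusion duration, h (dose rows only)
#   dv    observed concentration, mg/L (observation rows only)
#   blq   TRUE when dv is below the LLOQ (flagged, not removed)
#   ce    CKD-EPI eGFR covariate, mL/min/1.73 m^2
# plus the optional covariate columns age, sex, weight, height, scr, cysc,
# albumin, ecmo_type, crrt, purpose, predose, time_corrupted.

pk_mandatory_cols <- c("id", "time", "evid", "amt", "tinf", "dv", "blq", "ce")
pk_optional_cols <- c("age", "sex", "weight", "height", "scr", "cysc",
                      "albumin", "ecmo_type", "crrt", "purpose", "predose",
                      "time_corrupted")

#' Validate a PK dataset
#'
#' Checks the documented dialect: mandatory columns present, dose rows
#' carry `amt > 0` and no concentration, observation rows the reverse, and
#' times non-decreasing within subject. Extra columns are tolerated here
#' (candidate covariates travel as columns); [read_pk_dataset()]
#' additionally rejects columns outside the documented dialect. Errors name
#' the offending row.
#'
#' @param dataset data.frame to validate.
#' @return The dataset, invisibly, on success.
#' @export
validate_pk_dataset <- function(dataset) {
  miss <- setdiff(pk_mandatory_cols, names(dataset))
  if (length(miss)) {
    stop("pk dataset missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(dataset$evid %in% c(0L, 1L))) {
    stop("evid must be 0 (observation) or 1 (dose); first bad row ",
         which(!dataset$evid %in% c(0L, 1L))[1])
  }
  dose <- dataset$evid == 1L
  bad <- dose & (is.na(dataset$amt) | dataset$amt <= 0 | is.na(dataset$tinf) |
                   dataset$tinf <= 0)
  if (any(bad)) stop("dose row without positive amt/tinf at row ", which(bad)[1])
  bad <- dose & !is.na(dataset$dv)
  if (any(bad)) stop("concentration on a dose row at row ", which(bad)[1])
  bad <- !dose & (is.na(dataset$dv) | !is.na(dataset$amt))
  if (any(bad)) stop("observation row must carry dv and no amt; row ", which(bad)[1])
  if (any(!is.finite(dataset$ce)) || any(dataset$ce < 0)) {
    stop("ce must be finite and >= 0; first bad row ",
         which(!is.finite(dataset$ce) | dataset$ce < 0)[1])
  }
  for (sid in unique(dataset$id)) {
    tt <- dataset$time[dataset$id == sid]
    if (is.unsorted(tt)) {
      stop("non-monotone times within subject ", sid, " at row ",
           which(dataset$id == sid)[which(diff(tt) < 0)[1] + 1L])
    }
  }
  invisible(dataset)
}

#' Read / write a PK dataset CSV
#'
#' @param path CSV file in the documented dialect (see
#'   [validate_pk_dataset()]).
#' @return A validated PK dataset data.frame.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  unknown <- setdiff(names(d), c(pk_mandatory_cols, pk_optional_cols))
  if (length(unknown)) {
    stop("pk dataset file has unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  for (col in c("time", "amt", "tinf", "dv", "ce")) {
    if (col %in% names(d)) d[[col]] <- as.numeric(d[[col]])
  }
  if ("evid" %in% names(d)) d$evid <- as.integer(d$evid)
  for (col in c("blq", "predose", "crrt", "time_corrupted")) {
    if (col %in% names(d)) d[[col]] <- as.logical(d[[col]])
  }
  validate_pk_dataset(d)
  d
}

#' @rdname read_pk_dataset
#' @param dataset A validated PK dataset.
#' @export
write_pk_dataset <- function(dataset, path) {
  validate_pk_dataset(dataset)
  utils::write.csv(dataset, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a population model configuration (YAML)
#'
#' The YAML carries the [pk_model()] fields verbatim; the packaged default
#' (`system.file("extdata", "meropenem_model.yaml", package = "meropk")`)
#' holds the fitted meropenem estimates.
#'
#' @param path YAML file.
#' @return A [pk_model].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(pk_model, cfg)
}

#' @rdname read_model_config
#' @param model A [pk_model].
#' @export
write_model_config <- function(model, path) {
  validate_pk_model(model)
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}

#' Default simulation run configuration
#'
#' @param out_dir Output directory for [run_paper_simulations()].
#' @param seed Integer seed governing every stochastic stage.
#' @param n_empirical Virtual patients in the empirical-therapy simulation.
#' @param n_per_band Virtual patients per renal band in the dose-finding
#'   grids.
#' @param mic_table Path to an MIC frequency CSV; defaults to the packaged
#'   synthetic illustration.
#' @return List of class `run_config`; round-trips losslessly through
#'   [write_run_config()] / [read_run_config()].
#' @export
default_run_config <- function(out_dir = tempfile("meropk_run_"),
                               seed = 20211861, n_empirical = 10000,
                               n_per_band = 1000, mic_table = NULL) {
  if (is.null(mic_table)) {
    mic_table <- system.file("extdata", "mic_distribution_synthetic.csv",
                             package = "meropk")
  }
  structure(list(
    model = unclass(meropenem_model()),
    seed = as.integer(seed),
    n_empirical = n_empirical,
    n_per_band = n_per_band,
    doses = c(500, 1000, 2000),
    intervals = c(8, 12),
    infusions = c(0.5, 1, 2, 3),
    mics = c(0.06, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16),
    bands = renal_bands()[, c("lower", "upper")],
    targets = c("FT40", "FT100", "FT100_4X"),
    grid_step = 0.02,
    mic_table = mic_table,
    out_dir = out_dir), class = "run_config")
}

#' @rdname default_run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$bands <- as.data.frame(cfg$bands)
  structure(cfg, class = "run_config")
}

#' @rdname default_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$bands <- as.list(cfg$bands)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full simulation study
#'
#' Executes the empirical-therapy simulation (renally banded recommended
#' regimen, MIC-distribution-weighted) and the three dose-finding PTA
#' grids (one per target), writes every table as long-format CSV plus an
#' adequacy summary (cells with PTA >= 90%) and a reproducibility manifest
#' (seed, config, package version) to `config$out_dir`.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @return Invisibly, a list with `empirical` (the [simulate_empirical_cohort()]
#'   result), `grids` (named list of [pta_grid()] results), `adequacy`
#'   (data.frame) and `files` (paths written).
#' @export
run_paper_simulations <- function(config = default_run_config()) {
  if (length(config$mics) == 0) stop("empty MIC grid")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- do.call(pk_model, config$model)
  mic_dist <- read_mic_distribution(config$mic_table)
  set.seed(config$seed)
  message("simulation 1: empirical therapy cohort (n = ", config$n_empirical, ")")
  empirical <- simulate_empirical_cohort(model, n = config$n_empirical,
                                         mic_dist = mic_dist,
                                         targets = config$targets,
                                         grid_step = config$grid_step)
  grids <- list()
  bands <- as.data.frame(config$bands)
  for (tg in config$targets) {
    message("dose-finding grid for target ", tg)
    grids[[tg]] <- pta_grid(model, bands = bands, doses = config$doses,
                            intervals = config$intervals,
                            infusions = config$infusions, mics = config$mics,
                            target = tg, n_per_band = config$n_per_band,
                            grid_step = config$grid_step)
  }
  all_grids <- do.call(rbind, lapply(grids, as.data.frame))
  adequacy <- all_grids[all_grids$adequate, , drop = FALSE]
  files <- c(
    empirical = file.path(config$out_dir, "empirical_pta_by_mic.csv"),
    grids = file.path(config$out_dir, "pta_grids.csv"),
    adequacy = file.path(config$out_dir, "adequate_cells.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  utils::write.csv(empirical$by_mic, files["empirical"], row.names = FALSE)
  utils::write.csv(all_grids, files["grids"], row.names = FALSE)
  utils::write.csv(adequacy, files["adequacy"], row.names = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("meropk")),
                   r_version = R.version.string,
                   config = unclass(write_safe_config(config)))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(empirical = empirical, grids = grids, adequacy = adequacy,
                 files = files))
}

write_safe_config <- function(config) {
  cfg <- unclass(config)
  cfg$bands <- as.list(as.data.frame(cfg$bands))
  cfg
}

#' Serialise a fit report
#'
#' Writes the parameter table (estimate, RSE%, shrinkage%), OFV and
#' convergence status of an `est_result` as JSON.
#'
#' @param fit An `est_result`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "est_result"))
  shr <- c(theta_cl = NA, theta_cov = NA, vc = NA, q = NA, vp = NA,
           omega_cl = unname(fit$shrinkage["eta_cl"]),
           omega_vc = unname(fit$shrinkage["eta_vc"]),
           omega_vp = unname(fit$shrinkage["eta_vp"]),
           sigma_prop = NA, power = NA)
  tab <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    rse_pct = unname(fit$rse),
                    shrinkage_pct = unname(shr[names(fit$estimates)]),
                    fixed = names(fit$estimates) %in% fit$fixed)
  rep <- list(ofv = fit$ofv, n_subjects = fit$n_subjects, n_obs = fit$n_obs,
              n_blq_dropped = fit$n_blq, convergence = fit$convergence,
              parameters = tab)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
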