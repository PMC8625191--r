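# External-validation error metrics: relative prediction error, relative
# bias (accuracy) and relative root-mean-square error (precision).

#' Relative prediction error
#'
#' `rPE = (C_P - C_O) / C_O` elementwise, with predicted `C_P` and observed
#' `C_O` concentrations.
#'
#' @param observed Observed concentrations (> 0).
#' @param predicted Predicted concentrations, same length.
#' @return Dimensionless vector of relative prediction errors.
#' @examples
#' rpe(c(1, 2), c(2, 2))
#' @export
rpe <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("rpe: observed and predicted must have equal length")
  }
  if (length(observed) == 0) stop("rpe: empty input")
  if (any(observed <= 0)) stop("rpe: observed concentrations must be > 0")
  (predicted - observed) / observed
}

#' Relative bias (accuracy), percent
#'
#' `rBias = 100 * mean(rPE)`.
#' @inheritParams rpe
#' @return Percent.
#' @export
rbias <- function(observed, predicted) 100 * mean(rpe(observed, predicted))

#' Relative root-mean-square error (precision), percent
#'
#' `rRMSE = 100 * sqrt(mean(rPE^2))`. Always satisfies
#' `(rRMSE/100)^2 >= (rBias/100)^2` (mean-square >= square-of-mean).
#' @inheritParams rpe
#' @return Percent.
#' @export
rrmse <- function(observed, predicted) 100 * sqrt(mean(rpe(observed, predicted)^2))

#' External validation of a fitted model
#'
#' Computes population predictions (random effects at zero; no empirical
#' Bayes feedback from the validation samples, the stricter
#' external-validation convention) for the observations of a validation
#' dataset and reports rBias/rRMSE with and without a set of excluded
#' subjects, plus the per-observation rPE table.
#'
#' @param fit An `est_result` or a [pk_model].
#' @param dataset Validation PK dataset (BLQ-flagged rows are excluded).
#' @param exclusion_ids Subject ids to exclude in the secondary metric set
#'   (e.g. documented outliers).
#' @param prediction `"population"` (default) or `"individual"` (empirical
#'   Bayes conditional predictions; uses the validation data to locate the
#'   conditional mode).
#' @return Object of class `prediction_performance`: `rbias`, `rrmse`, `n`,
#'   the same after exclusions (`rbias_excl` etc.), `excluded_ids`, and the
#'   `rpe_table` data.frame (id, time, observed, predicted, rpe).
#' @export
validate_predictions <- function(fit, dataset, exclusion_ids = integer(),
                                 prediction = c("population", "individual")) {
  prediction <- match.arg(prediction)
  model <- if (inherits(fit, "est_result")) fit$model else fit
  prep <- prepare_subjects(dataset)
  p <- param_vector(model)
  if (prediction == "individual") {
    det <- ofv_prepared(prep, p, model$ce_ref, detail = TRUE)
    preds <- lapply(det$detail, `[[`, "f_hat")
  } else {
    tvcl <- pmax(p[["theta_cl"]] *
                   (1 + p[["theta_cov"]] * (prep$ce - model$ce_ref)), 0.01)
    preds <- lapply(seq_along(prep$subjects), function(k) {
      s <- prep$subjects[[k]]
      .conc_design_cpp(tvcl[k], p[["vc"]], p[["vp"]], p[["q"]],
                       s$tsd, s$tinf, s$rate)
    })
  }
  tab <- do.call(rbind, lapply(seq_along(prep$subjects), function(k) {
    s <- prep$subjects[[k]]
    data.frame(id = prep$ids[k], time = s$time, observed = s$y,
               predicted = preds[[k]])
  }))
  tab$rpe <- rpe(tab$observed, tab$predicted)
  if (length(exclusion_ids) && !any(exclusion_ids %in% tab$id)) {
    warning("validate_predictions: no exclusion id present in the dataset")
  }
  keep <- !(tab$id %in% exclusion_ids)
  structure(list(
    rbias = rbias(tab$observed, tab$predicted),
    rrmse = rrmse(tab$observed, tab$predicted),
    n = nrow(tab),
    rbias_excl = rbias(tab$observed[keep], tab$predicted[keep]),
    rrmse_excl = rrmse(tab$observed[keep], tab$predicted[keep]),
    n_excl = sum(keep),
    excluded_ids = intersect(exclusion_ids, tab$id),
    prediction = prediction,
    rpe_table = tab), class = "prediction_performance")
}

#' @export
print.prediction_performance <- function(x, ...) {
  cat(sprintf("Prediction performance (%s predictions), n = %d\n",
              x$prediction, x$n))
  cat(sprintf("  rBias %.3g%%, rRMSE %.3g%%\n", x$rbias, x$rrmse))
  if (length(x$excluded_ids)) {
    cat(sprintf("  excluding id(s) %s (n = %d): rBias %.3g%%, rRMSE %.3g%%\n",
                paste(x$excluded_ids, collapse = ", "), x$n_excl,
                x$rbias_excl, x$rrmse_excl))
  }
  invisible(x)
}
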