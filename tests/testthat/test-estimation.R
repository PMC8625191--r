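test_that("Laplace OFV matches 64-node Gauss-Hermite on single-subject toys", {
  # IIV on CL only so the marginal likelihood is a 1-D integral
  m <- default_model
  m$omega_vc <- m$omega_vp <- 0
  set.seed(41)
  for (rep in 1:4) {
    ds <- make_rich_dataset(m, 1, obs_times = c(0.5, 1.5, 6),
                            regimen = dosing_regimen(1000, 8, 0.5),
                            n_doses = 1, ce = runif(1, 40, 130))
    ofv <- ofv_nlme(m, ds)
    expect_equal(as.numeric(ofv), gh_ofv_single(m, ds), tolerance = 0.1)
  }
})

test_that("OFV degenerates to the naive-pooled -2LL when all omegas are zero", {
  m <- noiseless_model
  m$sigma_prop <- 0.2
  set.seed(43)
  ds <- make_rich_dataset(m, 3, obs_times = c(0.5, 1, 4, 7.5),
                          regimen = dosing_regimen(1000, 8, 0.5))
  ofv <- ofv_nlme(m, ds)
  obs <- ds[ds$evid == 0 & !ds$blq, ]
  pooled <- 0
  for (sid in unique(obs$id)) {
    d <- ds[ds$id == sid, ]
    doses <- d[d$evid == 1, ]
    o <- d[d$evid == 0 & !d$blq, ]
    f <- conc_dose_history_test(
      list(cl = typical_cl(m, d$ce[1]), vc = m$vc, vp = m$vp, q = m$q),
      doses$time, doses$amt, doses$tinf, o$time)
    v <- m$sigma_prop^2 * f^(2 * m$power)
    pooled <- pooled + sum(log(v) + (o$dv - f)^2 / v)
  }
  expect_equal(as.numeric(ofv), pooled, tolerance = 1e-6)
})

test_that("freeing a parameter never increases the OFV (nested monotonicity)", {
  set.seed(47)
  ds <- generate_study(default_model, generate_cohort(study_design(n_subjects = 12)))
  init <- default_model
  fit_fixed <- fit_nlme(ds, init, fixed = c("theta_cov", "power"),
                        compute_se = FALSE, control = fast_ctrl)
  init2 <- fit_fixed$model
  fit_free <- fit_nlme(ds, init2, fixed = "power", compute_se = FALSE,
                       control = fast_ctrl)
  expect_lte(fit_free$ofv, fit_fixed$ofv + 1e-3)
  cmp <- compare_nested(fit_free, fit_fixed, df = 1)
  expect_equal(cmp$delta_ofv, fit_fixed$ofv - fit_free$ofv)
})

test_that("noise-free rich data recover the generating parameters", {
  m <- noiseless_model
  m$sigma_prop <- 1e-4 # essentially noise-free; keeps the likelihood defined
  set.seed(53)
  ds <- make_rich_dataset(m, 6, obs_times = c(0.25, 0.5, 0.75, 1, 2, 3, 5, 8),
                          regimen = dosing_regimen(1000, 8, 0.5))
  init <- m
  init$theta_cl <- 5; init$vc <- 7; init$vp <- 10; init$q <- 8
  fit <- fit_nlme(ds, init,
                  fixed = c("theta_cov", "power", "sigma_prop",
                            "omega_cl", "omega_vc", "omega_vp"),
                  compute_se = FALSE, control = list(rel_tol = 1e-8))
  expect_equal(fit$estimates[["theta_cl"]], m$theta_cl, tolerance = 5e-3)
  expect_equal(fit$estimates[["vc"]], m$vc, tolerance = 5e-3)
  expect_equal(fit$estimates[["vp"]], m$vp, tolerance = 2e-2)
  # stationarity: refitting from the optimum barely moves the OFV
  refit <- fit_nlme(ds, fit$model,
                    fixed = c("theta_cov", "power", "sigma_prop",
                              "omega_cl", "omega_vc", "omega_vp"),
                    compute_se = FALSE, control = list(rel_tol = 1e-8))
  expect_lt(abs(refit$ofv - fit$ofv), 0.01)
})

test_that("nested-model significance thresholds use strict inequalities", {
  expect_true(compare_nested(100, 106.64, df = 1)$forward_p01)
  expect_false(compare_nested(100, 106.635, df = 1)$forward_p01)
  expect_false(compare_nested(100, 103.84, df = 1)$significant_p05)
  expect_true(compare_nested(100, 103.85, df = 1)$significant_p05)
  expect_false(compare_nested(100, 100, df = 1)$significant_p05)
  expect_true(compare_nested(100, 106, df = 2)$significant_p05)
  expect_error(compare_nested(100, 100, df = 0), "df")
})

test_that("covariate scan flags a true eGFR effect and not a noise column", {
  set.seed(59)
  coh <- generate_cohort(study_design())
  ds <- generate_study(default_model, coh)
  ds$noise <- rep(rnorm(nrow(coh), 100, 20), table(factor(ds$id, unique(ds$id))))
  scan <- covariate_scan(ds, c("ce", "noise"), init = default_model,
                         control = fast_ctrl)
  expect_true(scan$forward_p01[scan$covariate == "ce"])
  expect_gt(scan$delta_ofv[scan$covariate == "ce"], 6.635)
  expect_lt(scan$delta_ofv[scan$covariate == "noise"], 6.635)
  expect_warning(
    covariate_scan(transform(ds, const = 1), "const", control = fast_ctrl),
    "constant")
})

test_that("CWRES are approximately standard normal under the true model", {
  set.seed(61)
  m <- default_model
  ds <- make_rich_dataset(m, 50, obs_times = c(0.5, 1, 2, 4, 6, 7.5),
                          regimen = dosing_regimen(1000, 8, 0.5))
  res <- cwres(m, ds)
  expect_gte(nrow(res), 250)
  expect_lt(abs(mean(res$cwres)), 0.15)
  expect_gt(sd(res$cwres), 0.8)
  expect_lt(sd(res$cwres), 1.2)
  expect_gte(mean(abs(res$cwres) < 3), 0.95)
})

test_that("eta shrinkage is 100% with no information and 0% at full spread", {
  set.seed(67)
  ds <- generate_study(default_model, generate_cohort(study_design(n_subjects = 8)))
  fit <- fit_nlme(ds, default_model, fixed = names(param_vec <- meropk:::param_vector(default_model)),
                  compute_se = FALSE)
  sh <- eta_shrinkage(fit)
  expect_true(all(sh[!is.na(sh)] <= 100))
  # definition check: sd(ebe)/omega fixes the value exactly
  expect_equal(unname(sh["eta_cl"]),
               100 * (1 - sd(fit$ebe$eta_cl) / default_model$omega_cl))
})

test_that("bootstrap is reproducible, excludes failures, and rejects n_reps=0", {
  set.seed(71)
  ds <- generate_study(default_model, generate_cohort(study_design(n_subjects = 8)))
  init <- default_model
  fixed <- c("theta_cov", "power", "omega_vc", "omega_vp")
  set.seed(123)
  b1 <- bootstrap_nlme(ds, init, n_reps = 8, fixed = fixed, control = fast_ctrl)
  set.seed(123)
  b2 <- bootstrap_nlme(ds, init, n_reps = 8, fixed = fixed, control = fast_ctrl)
  expect_identical(b1$summary, b2$summary)
  expect_true(all(b1$summary$ci_lo <= b1$summary$median &
                    b1$summary$median <= b1$summary$ci_hi))
  # point estimate of theta_cl sits inside the replicate central range
  fit <- fit_nlme(ds, init, fixed = fixed, compute_se = FALSE,
                  control = fast_ctrl)
  qs <- quantile(b1$estimates[, "theta_cl"], c(0.025, 0.975))
  expect_gte(fit$estimates[["theta_cl"]], qs[1])
  expect_lte(fit$estimates[["theta_cl"]], qs[2])
  expect_error(bootstrap_nlme(ds, init, n_reps = 0), "n_reps")
})

test_that("pcVPC covers self-simulated data and reduces to classical VPC
           under a homogeneous design with correction off", {
  set.seed(73)
  m <- default_model
  ds <- make_rich_dataset(m, 30, obs_times = c(0.5, 1, 2, 4, 6, 7.5),
                          regimen = dosing_regimen(1000, 8, 0.5),
                          ce = rep(90, 30)) # homogeneous design
  set.seed(74)
  v1 <- vpc_pvc(m, ds, n_sim = 120)
  set.seed(74)
  v2 <- vpc_pvc(m, ds, n_sim = 120, correct = FALSE)
  # percentile ordering within bins
  expect_true(all(v1$bins$obs_p10 <= v1$bins$obs_p50 &
                    v1$bins$obs_p50 <= v1$bins$obs_p90))
  # homogeneous design: identical population prediction within each bin, so
  # prediction correction is a bin-wise identity
  expect_equal(v1$bins$obs_p50, v2$bins$obs_p50, tolerance = 1e-10)
  # observed medians fall inside the simulated 95% CI in most bins
  inside <- with(v1$bins, obs_p50 >= sim_p50_lo & obs_p50 <= sim_p50_hi)
  expect_gte(mean(inside), 0.8)
  expect_error(vpc_pvc(m, ds, n_sim = 1), "n_sim")
})

test_that("BLQ observations are dropped from the likelihood and counted", {
  set.seed(79)
  ds <- generate_study(default_model, generate_cohort(study_design(n_subjects = 6)))
  o <- ofv_nlme(default_model, ds)
  expect_equal(attr(o, "n_blq"), sum(ds$blq, na.rm = TRUE))
  # removing the flagged rows changes nothing
  ds2 <- ds[!(ds$evid == 0 & ds$blq), ]
  expect_equal(as.numeric(ofv_nlme(default_model, ds2)), as.numeric(o))
})
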