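test_that("generated cohorts are reproducible and calibrated to the study
           population", {
  set.seed(107)
  coh <- generate_cohort(study_design())
  expect_equal(nrow(coh), 26)
  expect_gte(median(coh$egfr_ckd_epi), 60)
  expect_lte(median(coh$egfr_ckd_epi), 110)
  expect_gte(median(coh$age), 55); expect_lte(median(coh$age), 85)
  expect_gte(median(coh$weight), 45); expect_lte(median(coh$weight), 75)
  expect_gte(median(coh$scr), 0.4); expect_lte(median(coh$scr), 1.5)
  expect_equal(sum(coh$ecmo_type != "none"), 8)
  # eGFR always derives from creatinine, never sampled independently
  expect_equal(coh$ce, egfr_ckd_epi(coh$age, coh$scr, coh$sex))
  set.seed(107)
  expect_identical(generate_cohort(study_design()), coh)
  # no ECMO when the fraction is zero
  set.seed(1)
  expect_true(all(generate_cohort(study_design(ecmo_fraction = 0))$ecmo_type
                  == "none"))
})

test_that("generated studies satisfy the dataset invariants across seeds", {
  for (seed in c(3, 17, 91)) {
    set.seed(seed)
    ds <- generate_study(default_model, generate_cohort(study_design()))
    expect_silent(validate_pk_dataset(ds))
    obs <- ds[ds$evid == 0, ]
    dose <- ds[ds$evid == 1, ]
    expect_true(all(dose$amt %in% c(500, 1000)))
    expect_true(all(dose$tinf == 0.5))
    expect_true(all(obs$dv >= 0))
    expect_true(all(obs$blq == (obs$dv < 0.2)))
    # pre-dose first sample: time 0, concentration 0, flagged
    pre <- obs[obs$predose, ]
    expect_true(all(pre$time == 0 & pre$dv == 0 & pre$blq))
    # sampling design: 5 development + 2 validation samples per subject
    expect_true(all(table(obs$id[obs$purpose == "development"]) == 5))
    expect_true(all(table(obs$id[obs$purpose == "validation"]) == 2))
  }
})

test_that("development/validation split approximates the intended sample
           counts after BLQ flagging", {
  set.seed(42)
  ds <- generate_study(default_model, generate_cohort(study_design()))
  obs <- ds[ds$evid == 0 & !ds$blq, ]
  n_dev <- sum(obs$purpose == "development")
  n_val <- sum(obs$purpose == "validation")
  expect_gte(n_dev, 95); expect_lte(n_dev, 130)
  expect_gte(n_val, 30); expect_lte(n_val, 52)
})

test_that("noise-free generation round-trips through the closed-form model", {
  set.seed(109)
  coh <- generate_cohort(study_design(n_subjects = 3, ecmo_fraction = 0))
  ds <- generate_study(noiseless_model, coh)
  true_pars <- attr(ds, "true_params")
  for (sid in coh$id) {
    d <- ds[ds$id == sid, ]
    doses <- d[d$evid == 1, ]
    obs <- d[d$evid == 0, ]
    p <- true_pars[true_pars$id == sid, ]
    expect_equal(obs$dv,
                 conc_dose_history_test(p, doses$time, doses$amt, doses$tinf,
                                        obs$time),
                 tolerance = 1e-12)
  }
})

test_that("replicate concentration CV at fixed prediction matches the
           residual noise law", {
  m <- default_model
  set.seed(113)
  pred <- 12
  reps <- apply_residual_error(m, rep(pred, 1e4))
  expect_equal(sd(reps), m$sigma_prop * pred^m$power, tolerance = 0.03)
})

test_that("timing corruption shifts recorded times but not values", {
  set.seed(127)
  ds <- generate_study(default_model, generate_cohort(study_design(n_subjects = 6)))
  set.seed(1)
  bad <- inject_timing_error(ds, n_records = 2, shift = 0.5)
  moved <- which(bad$time_corrupted)
  expect_length(moved, 2)
  expect_equal(bad$time[moved], ds$time[moved] + 0.5)
  expect_equal(bad$dv[moved], ds$dv[moved])
  # rPE computed at the corrupted record time differs from the truth-time rPE
  sid <- bad$id[moved[1]]
  d <- ds[ds$id == sid, ]
  p <- attr(ds, "true_params")
  p <- p[p$id == sid, ]
  doses <- d[d$evid == 1, ]
  f_true <- conc_dose_history_test(p, doses$time, doses$amt, doses$tinf,
                                   ds$time[moved[1]])
  f_rec <- conc_dose_history_test(p, doses$time, doses$amt, doses$tinf,
                                  bad$time[moved[1]])
  expect_false(isTRUE(all.equal(f_true, f_rec)))
})

test_that("fixtures regenerate byte-identically and refit to the truth", {
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  f1 <- make_fixtures(d1)
  f2 <- make_fixtures(d2)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
  ds4 <- read_pk_dataset(f1[1])
  expect_equal(length(unique(ds4$id)), 4)
  # noise-free fixture refits to the generating clearance within 1%
  init <- noiseless_model
  init$sigma_prop <- 0.02
  init$theta_cl <- 5
  fit <- fit_nlme(ds4, init,
                  fixed = c("theta_cov", "power", "sigma_prop",
                            "omega_cl", "omega_vc", "omega_vp"),
                  compute_se = FALSE, control = list(rel_tol = 1e-8))
  expect_equal(fit$estimates[["theta_cl"]], 6.37, tolerance = 0.01)
})
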