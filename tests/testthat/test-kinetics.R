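test_that("single-dose solution matches the ODE oracle and basic limits", {
  p <- individual_from_eta(default_model, 91.57)
  tt <- c(0.25, 0.5, 0.75, 1, 2, 4, 8, 12)
  ode <- ode_conc_2cmt(p, 1000, 0.5, tt)
  ana <- conc_single_dose(p, 1000, 0.5, tt)
  expect_equal(ana, unname(ode[as.character(tt)]), tolerance = 1e-8)
  # no drug before or at the start of the infusion
  expect_identical(conc_single_dose(p, 1000, 0.5, c(-1, 0)), c(0, 0))
  # continuous-infusion limit: conc -> rate / cl
  rate <- 500 # mg/h over a very long infusion, observed late
  expect_equal(conc_single_dose(p, rate * 2000, 2000, 1500), rate / p$cl,
               tolerance = 1e-6)
})

test_that("steady state equals brute-force superposition and is periodic", {
  set.seed(21)
  pars <- sample_individual(default_model, runif(5, 20, 150), 5)
  reg <- dosing_regimen(1000, 8, 0.5)
  tq <- seq(0, 8, by = 0.25)
  for (i in 1:5) {
    p <- pars[i, ]
    ss <- ss_conc(p, reg, tq)
    brute <- Reduce(`+`, lapply(0:39, function(k)
      conc_single_dose(p, reg$dose, reg$tinf, tq + k * reg$interval)))
    expect_equal(ss, brute, tolerance = 1e-6)
    expect_equal(ss[1], ss[length(ss)], tolerance = 1e-9) # periodicity
  }
})

test_that("steady-state average concentration obeys dose/(cl tau)", {
  p <- individual_from_eta(default_model, 91.57)
  reg <- dosing_regimen(1000, 8, 0.5)
  prof <- steady_state_profile(p, reg)
  expect_equal(profile_grid(8, 0.5, 0.02), prof$times)
  expect_equal(profile_auc(prof) / 8, 1000 / (p$cl * 8), tolerance = 1e-4)
  expect_true(all(prof$conc >= 0))
  expect_true(all(diff(prof$times) > 0))
})

test_that("cohort profile matrix agrees with the per-subject path", {
  set.seed(5)
  pars <- sample_individual(default_model, runif(4, 30, 150), 4)
  reg <- dosing_regimen(500, 12, 2)
  mat <- meropk:::ss_profile_matrix(pars, reg)
  for (i in 1:4) {
    prof <- steady_state_profile(pars[i, ], reg)
    expect_equal(unname(mat[i, ]), prof$conc, tolerance = 1e-12)
  }
  expect_equal(attr(mat, "times"), profile_grid(12, 2, 0.02))
})

test_that("profiles are continuous at the end-of-infusion breakpoint", {
  set.seed(31)
  pars <- sample_individual(default_model, runif(20, 10, 160), 20)
  reg <- dosing_regimen(2000, 12, 3)
  for (i in 1:20) {
    p <- pars[i, ]
    eps <- 1e-7
    left <- ss_conc(p, reg, reg$tinf - eps)
    right <- ss_conc(p, reg, reg$tinf + eps)
    expect_equal(left, right, tolerance = 1e-5)
  }
})

test_that("repeated-root (alpha == beta) parameter sets stay accurate", {
  # equal hybrid rates arise when (k10+k12+k21)^2 = 4 k10 k21; build one
  # nearby: vc = vp and q chosen so the discriminant nearly vanishes
  p <- list(cl = 4, vc = 10, vp = 10, q = 1e-6)
  tt <- c(0.5, 1, 4, 8)
  ode <- ode_conc_2cmt(p, 1000, 0.5, tt)
  expect_equal(conc_single_dose(p, 1000, 0.5, tt),
               unname(ode[as.character(tt)]), tolerance = 1e-6)
})

test_that("fT>MIC handles constant, crossing and closed-form cases", {
  # constant profile: always or never above
  flat <- structure(list(times = seq(0, 8, 0.5), conc = rep(10, 17)),
                    class = "concentration_profile")
  expect_equal(ftmic(flat, mic = 4, f_unbound = 0.98), 100)
  expect_equal(ftmic(flat, mic = 16, f_unbound = 0.98), 0)
  # mono-exponential toy with known crossing time: 100*ln(5)/(k*tau)
  k <- 0.3466; tau <- 8
  tgrid <- seq(0, tau, by = 0.01)
  mono <- structure(list(times = tgrid, conc = 10 * exp(-k * tgrid)),
                    class = "concentration_profile")
  expect_equal(ftmic(mono, mic = 2, f_unbound = 1),
               100 * log(5) / (k * tau), tolerance = 1e-3)
  # 4x multiplier shifts the threshold
  expect_equal(ftmic(mono, mic = 0.5, f_unbound = 1, multiplier = 4),
               100 * log(5) / (k * tau), tolerance = 1e-3)
  expect_error(ftmic(list(times = 1, conc = 1), 4), "grid")
  expect_error(ftmic(flat, mic = 0), "mic")
})

test_that("closed form matches the ODE oracle over a random parameter sweep", {
  set.seed(17)
  for (i in 1:20) {
    p <- list(cl = exp(runif(1, log(0.5), log(20))),
              vc = exp(runif(1, log(3), log(30))),
              vp = exp(runif(1, log(2), log(30))),
              q = exp(runif(1, log(2), log(30))))
    tinf <- sample(c(0.5, 1, 2, 3), 1)
    tt <- sort(runif(6, 0.1, 12))
    ana <- conc_single_dose(p, 1000, tinf, tt)
    ode <- ode_conc_2cmt(p, 1000, tinf, tt)
    expect_equal(ana, unname(ode[as.character(tt)]), tolerance = 1e-6)
  }
})
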