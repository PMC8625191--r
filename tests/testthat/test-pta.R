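test_that("PD targets carry the correct thresholds and multipliers", {
  expect_equal(pd_target("FT40")$threshold_fraction, 0.40)
  expect_equal(pd_target("FT100")$mic_multiplier, 1)
  expect_equal(pd_target("FT100_4X")$mic_multiplier, 4)
  expect_error(pd_target("FT50"))
})

test_that("recommended regimen follows the renal banding", {
  r <- recommended_regimen(70)
  expect_equal(c(r$dose, r$interval, r$tinf), c(1000, 8, 0.5))
  expect_equal(recommended_regimen(30)$interval, 12)
  expect_equal(recommended_regimen(30)$dose, 1000)
  expect_equal(recommended_regimen(15)$dose, 500)
  expect_equal(recommended_regimen(5)$interval, 24)
  # band edges: 50 belongs to 26-50, 25 to 10-25, 10 to 10-25
  expect_equal(recommended_regimen(50)$interval, 12)
  expect_equal(recommended_regimen(25)$dose, 500)
  expect_equal(recommended_regimen(10)$dose, 500)
  expect_equal(recommended_regimen(10)$interval, 12)
  expect_error(recommended_regimen(-1), "clcr")
})

test_that("PTA limits: tiny MIC attains, degenerate population is 0/100", {
  m <- default_model
  set.seed(83)
  expect_equal(as.numeric(pta(m, 90, dosing_regimen(1000, 8, 0.5),
                              mic = 1e-6, target = "FT40", n = 200)), 100)
  # omega = 0 and a single eGFR: deterministic population
  p <- pta(noiseless_model, 90, dosing_regimen(1000, 8, 0.5),
           mic = 4, target = "FT100", n = 200)
  expect_true(as.numeric(p) %in% c(0, 100))
  expect_error(pta(m, 90, dosing_regimen(1000, 8, 0.5), 4, "FT40", n = 50),
               "n must be")
})

test_that("PTA grid is monotone in MIC, dose and target stringency", {
  m <- default_model
  bands <- data.frame(lower = c(25, 90), upper = c(50, 130))
  mics <- c(0.5, 2, 8)
  run_grid <- function(tg) {
    set.seed(401) # shared cohort => paired comparisons
    pta_grid(m, bands = bands, doses = c(500, 2000), intervals = 8,
             infusions = 0.5, mics = mics, target = tg, n_per_band = 300)
  }
  g40 <- run_grid("FT40"); g100 <- run_grid("FT100"); g4x <- run_grid("FT100_4X")
  # non-increasing in MIC within each regimen x band cell
  for (key in split(g40, g40[c("band", "dose")])) {
    expect_true(all(diff(key$pta[order(key$mic)]) <= 0))
  }
  # non-decreasing in dose at fixed band/MIC
  merged <- merge(subset(g40, dose == 500), subset(g40, dose == 2000),
                  by = c("band", "mic"))
  expect_true(all(merged$pta.y >= merged$pta.x))
  # target stringency ordering on the same virtual cohorts
  expect_true(all(g40$pta >= g100$pta))
  expect_true(all(g100$pta >= g4x$pta))
  # seeded grids are identical across runs
  expect_identical(run_grid("FT40"), g40)
})

test_that("longer infusions never hurt trough-driven (100% fT) attainment", {
  m <- default_model
  bands <- data.frame(lower = 50, upper = 90)
  set.seed(409)
  g <- pta_grid(m, bands = bands, doses = 1000, intervals = 8,
                infusions = c(0.5, 3), mics = c(1, 2), target = "FT100",
                n_per_band = 400)
  wide <- merge(subset(g, tinf == 0.5), subset(g, tinf == 3), by = "mic")
  expect_true(all(wide$pta.y >= wide$pta.x))
})

test_that("MIC distribution I/O validates and normalises", {
  path <- system.file("extdata", "mic_distribution_synthetic.csv",
                      package = "meropk")
  md <- read_mic_distribution(path)
  expect_s3_class(md, "mic_distribution")
  expect_equal(sum(md$frequency), 1)
  expect_true(all(diff(md$mic_mg_per_L) > 0))
  expect_error(mic_distribution(c(1, 1), c(0.5, 0.5)), "increasing")
  expect_error(mic_distribution(c(1, 2), c(0.7, 0.7)), "sum to 1")
})

test_that("empirical cohort attainment obeys the law of total probability", {
  m <- default_model
  md <- mic_distribution(c(1, 4), c(0.25, 0.75))
  set.seed(419)
  sim <- simulate_empirical_cohort(m, n = 2000, mic_dist = md,
                                   targets = "FT40")
  by_mic <- sim$by_mic
  expect_equal(unname(sim$overall["FT40"]),
               sum(md$frequency * by_mic$pta), tolerance = 1e-9)
  # degenerate distribution: overall equals the conditional PTA at that MIC
  md1 <- mic_distribution(4, 1)
  set.seed(419)
  sim1 <- simulate_empirical_cohort(m, n = 2000, mic_dist = md1,
                                    targets = "FT40")
  expect_equal(unname(sim1$overall["FT40"]), sim1$by_mic$pta[1])
  expect_error(simulate_empirical_cohort(m, n = 500, mic_dist = md),
               "n must be")
})

test_that("truncated log-normal eGFR sampler respects its bounds", {
  set.seed(421)
  x <- meropk:::rlnorm_truncated(5000, log(90), 0.5, 0, 130)
  expect_true(all(x > 0 & x <= 130))
  # median of the truncated law, from the closed-form quantile
  med_expected <- qlnorm(0.5 * plnorm(130, log(90), 0.5), log(90), 0.5)
  expect_equal(median(x), med_expected, tolerance = 0.05)
})
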