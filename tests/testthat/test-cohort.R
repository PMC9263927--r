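test_that("degenerate probabilities switch features off completely", {
  cfg <- scenario_config(long_survivor_prob = 0, dropout_fraction = 0)
  set.seed(11)
  p <- generate_participants(cfg, 2000)
  expect_true(all(p$long_survivor == 0L))
  expect_true(all(is.infinite(p$dropout_time)))
})

test_that("dropout calibration hits the configured 18-month fraction", {
  cfg <- scenario_config(dropout_fraction = 0.10)
  set.seed(21)
  p <- generate_participants(cfg, 10000)
  frac <- mean(p$dropout_time < 18)
  se <- sqrt(0.10 * 0.90 / 10000)
  expect_lt(abs(frac - 0.10), 3 * se)
})

test_that("placebo survival matches the exponential quantile oracle", {
  cfg <- scenario_config(median_survival_placebo = 24)
  set.seed(31)
  p <- generate_participants(cfg, 10000)
  expect_lt(abs(median(p$death_time) - 24) / 24, 0.05)
  # hazard-ratio scaling: HR 0.5 doubles the median
  scaled <- apply_arm_hazard(p$death_time, 0.5)
  expect_equal(median(scaled), 2 * median(p$death_time))
})

test_that("covariate prevalences are honoured independently", {
  cfg <- scenario_config(
    covariate_prevalences = c(riluzole = 0.7, niv_gastrostomy = 0.15))
  set.seed(41)
  p <- generate_participants(cfg, 10000)
  expect_lt(abs(mean(p$riluzole) - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
  expect_lt(abs(mean(p$niv_gastrostomy) - 0.15),
            3 * sqrt(0.15 * 0.85 / 10000))
})

test_that("accrual matches the gamma-sum oracle and is reproducible", {
  # last of 531 arrivals at 10/month: mean 53.1, sd sqrt(531)/10
  set.seed(51)
  last <- replicate(50, max(generate_accrual(531, 10)))
  se <- sqrt(531) / 10 / sqrt(50)
  expect_lt(abs(mean(last) - 53.1), 3 * se)

  set.seed(52)
  one <- generate_accrual(1, 10)
  expect_gt(one, 0)

  set.seed(53); a1 <- generate_accrual(100, 5)
  set.seed(53); a2 <- generate_accrual(100, 5)
  expect_identical(a1, a2)
  expect_false(is.unsorted(a1))
  expect_error(generate_accrual(10, 0), "accrual_rate")
})

test_that("noise-free trajectories follow the configured line, with clamping", {
  cfg <- scenario_config(residual_sd = 1e-9, visit_months = seq(0, 12, 2))
  base <- data.frame(id = 1:3, entry_time = 0,
                     true_intercept = c(40, 40, 5),
                     true_slope = c(-1, -1, -1),
                     death_time = Inf, dropout_time = Inf)
  v <- simulate_trajectories(base, arm_effect = c(0, 0.25, 0), cfg)
  score_at <- function(id, m) v$alsfrs_r[v$participant_id == id &
                                           v$visit_month == m]
  expect_identical(score_at(1, 10), 30L)   # 40 - 1*10
  expect_identical(score_at(2, 12), 31L)   # 40 - 0.75*12, 25% shallower
  expect_identical(score_at(3, 10), 0L)    # floor of the instrument
  expect_error(simulate_trajectories(base, arm_effect = 1.5, cfg),
               "arm_effect")
})

test_that("records stop at death, dropout and data cut; baseline always observed", {
  cfg <- scenario_config(residual_sd = 1e-9, visit_months = seq(0, 24, 2))
  base <- data.frame(id = 1:3, entry_time = c(0, 0, 10),
                     true_intercept = 40, true_slope = -0.5,
                     death_time = c(7, Inf, Inf),
                     dropout_time = c(Inf, 9, Inf))
  v <- simulate_trajectories(base, 0, cfg, cut_date = 20)
  expect_identical(max(v$visit_month[v$participant_id == 1]), 6)
  expect_identical(max(v$visit_month[v$participant_id == 2]), 8)
  # entry 10, cut 20: last visit at month 10 on study
  expect_identical(max(v$visit_month[v$participant_id == 3]), 10)
  expect_true(all(1:3 %in% v$participant_id[v$visit_month == 0]))
})

test_that("per-participant OLS slope recovers the effective slope exactly without noise", {
  # integer-friendly grid so rounding is a no-op
  cfg <- scenario_config(residual_sd = 1e-9, visit_months = seq(0, 16, 4))
  set.seed(61)
  for (i in 1:20) {
    slope <- sample(c(-0.5, -1, -1.5), 1)
    eff <- sample(c(0, 0.5), 1)
    base <- data.frame(id = 1L, entry_time = 0,
                       true_intercept = sample(25:45, 1),
                       true_slope = slope,
                       death_time = Inf, dropout_time = Inf)
    v <- simulate_trajectories(base, eff, cfg)
    fit <- per_subject_slopes(v$participant_id, v$time, v$alsfrs_r)
    expect_equal(fit$slope, slope * (1 - eff), tolerance = 1e-9)
  }
})

test_that("every generated score is an integer within the instrument range", {
  cfg <- scenario_config(seed = 71L, n_randomise_per_arm = 60L,
                         stage_n = c(20L, 40L, 60L))
  cohort <- simulate_cohort(cfg)
  expect_true(all(cohort$visits$alsfrs_r >= 0L))
  expect_true(all(cohort$visits$alsfrs_r <= 48L))
  expect_true(all(cohort$visits$alsfrs_r == round(cohort$visits$alsfrs_r)))
})

test_that("identical seed and config give byte-identical cohort tables", {
  cfg <- small_trial_config(seed = 81L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$survival, c2$survival)
})

test_that("cohort CSVs are written long-format with headers", {
  cfg <- small_trial_config(seed = 91L)
  cohort <- simulate_cohort(cfg)
  vp <- file.path(tempdir(), "visits.csv")
  sp <- file.path(tempdir(), "survival.csv")
  write_cohort_csv(cohort, vp, sp)
  visits <- read.csv(vp)
  expect_true(all(c("participant_id", "arm", "entry_time", "riluzole",
                    "niv_gastrostomy", "visit_month", "alsfrs_r") %in%
                    names(visits)))
  surv <- read.csv(sp)
  expect_true(all(c("participant_id", "time", "event", "arm") %in%
                    names(surv)))
  expect_identical(nrow(surv), nrow(cohort$participants))
})
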