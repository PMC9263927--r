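# build a balanced complete two-arm dataset: n per arm, visits `tms`,
# placebo slope -1, active arm 25% shallower
balanced_data <- function(n_per_arm = 40, tms = seq(0, 18, 2),
                          residual_sd = 2.5, slope_sd = 0.6,
                          reduction = 0.25) {
  n <- 2L * n_per_arm
  arm <- rep(c("placebo", "A"), each = n_per_arm)
  b0 <- rnorm(n, 38, 6)
  b1 <- rnorm(n, -1, slope_sd) * ifelse(arm == "A", 1 - reduction, 1)
  visits <- data.frame(
    participant_id = rep(seq_len(n), each = length(tms)),
    time = rep(tms, n),
    alsfrs_r = rep(b0, each = length(tms)) +
      rep(b1, each = length(tms)) * rep(tms, n) +
      rnorm(n * length(tms), 0, residual_sd)
  )
  participants <- data.frame(id = seq_len(n), arm = arm,
                             riluzole = rbinom(n, 1, 0.7),
                             niv_gastrostomy = rbinom(n, 1, 0.15),
                             long_survivor = 0L)
  list(visits = visits, participants = participants)
}

test_that("noise-free limit recovers delta and relative reduction exactly", {
  set.seed(201)
  d <- balanced_data(n_per_arm = 20, residual_sd = 1e-8, slope_sd = 1e-8)
  for (m in c("twostage", "reml")) {
    fit <- fit_slope_model(d$visits, d$participants, method = m)
    expect_equal(fit[["A"]]$delta, 0.25, tolerance = 1e-5)
    expect_equal(fit[["A"]]$relative_reduction, 0.25, tolerance = 1e-5)
    expect_equal(attr(fit, "placebo_slope"), -1, tolerance = 1e-5)
  }
})

test_that("mixed-model contrast equals the two-stage OLS oracle on balanced complete data", {
  set.seed(211)
  d <- balanced_data(n_per_arm = 50)
  # independent oracle: per-participant least-squares slope by the
  # closed-form covariance ratio, then difference of arm means
  sl <- tapply(seq_len(nrow(d$visits)), d$visits$participant_id, function(i) {
    t <- d$visits$time[i]; y <- d$visits$alsfrs_r[i]
    sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  })
  sl <- sl[match(d$participants$id, as.integer(names(sl)))]
  oracle_delta <- mean(sl[d$participants$arm == "A"]) -
    mean(sl[d$participants$arm == "placebo"])

  reml <- fit_slope_model(d$visits, d$participants, method = "reml",
                          covariate_adjust = FALSE)
  expect_equal(reml[["A"]]$delta, oracle_delta, tolerance = 1e-6)
  two <- fit_slope_model(d$visits, d$participants, method = "twostage",
                         covariate_adjust = FALSE)
  expect_equal(two[["A"]]$delta, oracle_delta, tolerance = 1e-10)
})

test_that("relative reduction has the documented scale and sign convention", {
  expect_identical(relative_reduction(0.25, -1.0), 0.25)
  expect_identical(relative_reduction(0, -0.7), 0)
  expect_identical(relative_reduction(-0.2, -1.0), -0.2)
  expect_warning(rr <- relative_reduction(0.1, 0.2), "non-declining")
  expect_true(is.na(rr))
})

test_that("contrast intervals are coherent and the CI divides onto the relative scale", {
  cc <- slope_contrast("A", delta = 0.10, se = 0.2 / qnorm(0.975),
                       placebo_slope = -1)
  expect_lt(cc$ci95_low, cc$ci95_high)
  expect_true(cc$delta > cc$ci95_low && cc$delta < cc$ci95_high)
  expect_equal(c(cc$rr_low, cc$rr_high), c(-0.10, 0.30), tolerance = 1e-10)
  expect_true(cc$p_one_sided > 0 && cc$p_one_sided < 1)
  # placebo declining twice as fast halves the relative reduction
  cc2 <- slope_contrast("A", 0.10, 0.05, placebo_slope = -2)
  expect_equal(cc2$relative_reduction, 0.05)
})

test_that("delta CI attains nominal coverage within Monte Carlo error", {
  set.seed(221)
  reps <- 300
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    d <- balanced_data(n_per_arm = 30, tms = seq(0, 12, 2))
    fit <- fit_slope_model(d$visits, d$participants, method = "twostage")
    cc <- fit[["A"]]
    covered[r] <- cc$ci95_low <= 0.25 && 0.25 <= cc$ci95_high
  }
  se <- sqrt(0.95 * 0.05 / reps)
  expect_lt(abs(mean(covered) - 0.95), 3 * se)
})

test_that("one-sided 2.5% test keeps its level under the null at stage-3 size", {
  set.seed(231)
  reps <- 1000
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    d <- balanced_data(n_per_arm = 150, reduction = 0)
    fit <- fit_slope_model(d$visits, d$participants, method = "twostage")
    rej[r] <- fit[["A"]]$p_one_sided < 0.025
  }
  expect_lte(mean(rej), 0.025 + 3 * sqrt(0.025 * 0.975 / reps))
})

test_that("contrasts ignore relabelling of an uninvolved arm", {
  set.seed(241)
  cfg <- small_trial_config(seed = 241L)
  cohort <- simulate_cohort(cfg)
  f1 <- fit_slope_model(cohort$visits, cohort$participants,
                        arms = c("placebo", "A"))
  p2 <- cohort$participants
  p2$arm[p2$arm == "B"] <- "Z"
  f2 <- fit_slope_model(cohort$visits, p2, arms = c("placebo", "A"))
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("long survivors and scoreless participants are excluded from the analysis set", {
  set.seed(251)
  d <- balanced_data(n_per_arm = 20)
  d$participants$long_survivor[1:5] <- 1L
  drop_id <- d$participants$id[6]
  d$visits <- d$visits[d$visits$participant_id != drop_id, ]
  fit <- fit_slope_model(d$visits, d$participants)
  expect_identical(attr(fit, "n_analysed"), nrow(d$participants) - 6L)
})

test_that("contrasts round-trip through the CSV writer", {
  set.seed(271)
  d <- balanced_data(n_per_arm = 15)
  fit <- fit_slope_model(d$visits, d$participants)
  path <- file.path(tempdir(), "contrasts.csv")
  write_contrasts_csv(fit, path)
  back <- read.csv(path)
  expect_identical(back$arm, "A")
  expect_equal(back$delta, fit[["A"]]$delta, tolerance = 1e-9)
  expect_equal(back$rr_high, fit[["A"]]$rr_high, tolerance = 1e-9)
})

test_that("degenerate designs are signalled, not silently fitted", {
  set.seed(261)
  d <- balanced_data(n_per_arm = 10)
  one_time <- d$visits[d$visits$time == 0, ]
  expect_error(fit_slope_model(one_time, d$participants), "singular")
  expect_error(fit_slope_model(d$visits,
                               d$participants[d$participants$arm == "A", ],
                               arms = "A"),
               "control")
})
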