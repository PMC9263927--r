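test_that("with low noise truly effective arms reach stage 3", {
  cfg <- low_noise_config(relative_reduction = c(0, 0.25, 0.25))
  tr <- run_trial(cfg, seed = 401)
  d <- tr$decisions
  for (a in c("A", "B")) {
    expect_identical(d$decision[d$arm == a & d$stage == "1"], "continue")
    expect_identical(d$decision[d$arm == a & d$stage == "2"], "continue")
    expect_identical(d$decision[d$arm == a & d$stage == "3"], "significant")
  }
  expect_false(tr$all_dropped)
  # null survival effect: the gatekept test opens but does not reject both
  expect_true(all(d$decision[d$stage == "survival"] %in%
                    c("significant", "not-significant")))
})

test_that("a fixed seed reproduces the whole trial decision-for-decision", {
  cfg <- small_trial_config()
  t1 <- run_trial(cfg, seed = 411)
  t2 <- run_trial(cfg, seed = 411)
  expect_identical(t1$decisions, t2$decisions)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$trigger_dates, t2$trigger_dates)
  expect_identical(t1$survival_date, t2$survival_date)
})

test_that("stage triggers fire exactly when the threshold count qualifies", {
  cfg <- small_trial_config()
  tr <- run_trial(cfg, seed = 421, keep_data = TRUE)
  p <- tr$participants
  for (a in c("A", "B")) {
    t1 <- tr$trigger_dates[a, "stage1"]
    if (is.na(t1)) next
    qual_arm <- sum(p$arm == a & p$long_survivor == 0L &
                      p$entry_time + cfg$stage_months[1] <= t1)
    cont <- p[p$id %in% tr$cont_ids[[a]] & p$long_survivor == 0L, ]
    qual_cont <- sum(cont$entry_time + cfg$stage_months[1] <= t1)
    # both groups have reached the threshold, and the later of the two
    # reaches it exactly at the trigger (the binding group recount)
    expect_gte(qual_arm, cfg$stage_n[1])
    expect_gte(qual_cont, cfg$stage_n[1])
    expect_identical(min(qual_arm, qual_cont), cfg$stage_n[1])
  }
})

test_that("sample-size accounting respects the randomisation caps", {
  cfg <- scenario_config()  # default: 177/arm, 531 total
  tr <- run_trial(cfg, seed = 431)
  expect_true(all(tr$counts$randomised <= cfg$n_randomise_per_arm))
  expect_lte(tr$total_randomised, 3L * cfg$n_randomise_per_arm)
  expect_identical(sum(tr$counts$randomised), tr$total_randomised)
})

test_that("operating characteristics are reproducible and internally coherent", {
  cfg <- small_trial_config(relative_reduction = c(0, 0.5, 0))
  oc1 <- suppressWarnings(estimate_oc(cfg, reps = 40, seed = 441))
  oc2 <- suppressWarnings(estimate_oc(cfg, reps = 40, seed = 441))
  expect_identical(oc1$per_arm, oc2$per_arm)
  expect_identical(oc1$expected_n, oc2$expected_n)
  get_p <- function(oc, arm, q) {
    oc$per_arm$probability[oc$per_arm$arm == arm & oc$per_arm$quantity == q]
  }
  for (a in c("A", "B")) {
    expect_lte(get_p(oc1, a, "pass_stage2"), get_p(oc1, a, "pass_stage1"))
    expect_lte(get_p(oc1, a, "survival_significant"),
               get_p(oc1, a, "stage3_significant"))
  }
  expect_true(all(oc1$per_arm$probability >= 0 &
                    oc1$per_arm$probability <= 1))
  expect_equal(oc1$per_arm$mc_se,
               sqrt(oc1$per_arm$probability *
                      (1 - oc1$per_arm$probability) / 40))
})

test_that("an arm added later uses only contemporaneous controls", {
  cfg <- small_trial_config()
  cfg <- add_arm(cfg, "C", relative_reduction = 0.5, start_month = 4)
  expect_error(add_arm(cfg, "C"), "duplicate")
  tr <- run_trial(cfg, seed = 451, keep_data = TRUE)
  cont_c <- tr$participants[tr$participants$id %in% tr$cont_ids[["C"]], ]
  expect_true(all(cont_c$entry_time >= 4))
  expect_true(all(cont_c$arm == "placebo"))
})

test_that("an arm added after the others closed runs as a fresh two-arm comparison", {
  cfg <- small_trial_config(n_randomise_per_arm = 12L,
                            stage_n = c(4L, 8L, 12L),
                            placebo_death_threshold = 5L)
  # A and B fill quickly; C opens well after their accrual has finished
  cfg <- add_arm(cfg, "C", relative_reduction = 0, start_month = 10)
  # at 12/arm the Cox fit can hit a monotone likelihood; irrelevant here
  tr <- suppressWarnings(run_trial(cfg, seed = 461, keep_data = TRUE))
  p <- tr$participants
  close_ab <- max(p$entry_time[p$arm %in% c("A", "B")])
  expect_gt(min(p$entry_time[p$arm == "C"]), close_ab)
  cont_c <- p[p$id %in% tr$cont_ids[["C"]], ]
  expect_true(all(cont_c$entry_time >= 10))
  # C progressed through its own staged comparison
  expect_true(any(tr$decisions$arm == "C" & tr$decisions$stage == "1"))
})

test_that("a dropped arm's records do not leak into another arm's comparison", {
  cfg <- small_trial_config(seed = 471L)
  tr <- run_trial(cfg, keep_data = TRUE)
  parts <- tr$participants
  vis <- tr$visits
  # full tables (arm B's records present) versus tables with B removed
  f_full <- fit_slope_model(vis, parts, arms = c("placebo", "A"))
  no_b <- parts[parts$arm != "B", ]
  f_no_b <- fit_slope_model(vis[vis$participant_id %in% no_b$id, ],
                            no_b, arms = c("placebo", "A"))
  expect_identical(as.data.frame(f_full), as.data.frame(f_no_b))
})

test_that("allocation log audits every randomisation", {
  cfg <- small_trial_config()
  tr <- run_trial(cfg, seed = 491, keep_data = TRUE)
  log <- tr$allocation_log
  expect_identical(nrow(log), tr$total_randomised)
  expect_identical(log$arm,
                   tr$participants$arm[match(log$participant_id,
                                             tr$participants$id)])
  expect_true(all(c("placebo", "A", "B", "followed_minimiser") %in%
                    names(log)))
  path <- file.path(tempdir(), "alloc.csv")
  write_allocation_log_csv(tr, path)
  expect_identical(nrow(read.csv(path)), nrow(log))
  tr2 <- run_trial(cfg, seed = 491)
  expect_error(write_allocation_log_csv(tr2, path), "keep_data")
})

test_that("decisions CSV is written with headers", {
  cfg <- small_trial_config()
  tr <- run_trial(cfg, seed = 481)
  path <- file.path(tempdir(), "decisions.csv")
  write_decisions_csv(tr, path)
  d <- read.csv(path)
  expect_true(all(c("arm", "stage", "decision", "statistic", "threshold")
                  %in% names(d)))
  expect_identical(nrow(d), nrow(tr$decisions))
})
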