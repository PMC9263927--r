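# Shared scenario builders for the test suite. The default scenario_config()
# is the study condition; these helpers only shrink problem sizes or switch
# off noise sources where a test targets a deterministic limit.

# small, fast trial used where the test is about mechanics, not power
small_trial_config <- function(...) {
  args <- modifyList(list(
    n_randomise_per_arm = 36L,
    stage_n = c(10L, 20L, 30L),
    accrual_rate = 30,
    placebo_death_threshold = 10L,
    visit_months = seq(0, 30, by = 2)
  ), list(...))
  do.call(scenario_config, args)
}

# strong-signal limit: noise small relative to the effect (the instrument's
# integer rounding makes an exactly noise-free cohort degenerate, so "low"
# rather than zero), no dropout, no long survivors
low_noise_config <- function(...) {
  args <- modifyList(list(
    slope_sd = 0.01,
    residual_sd = 0.6,
    intercept_sd = 1,
    dropout_fraction = 0,
    long_survivor_prob = 0
  ), list(...))
  do.call(small_trial_config, args)
}

# a two-arm balanced cohort at a given size, complete follow-up
balanced_cohort_config <- function(n_per_arm, relative_reduction = 0.25,
                                   ...) {
  args <- modifyList(list(
    n_arms = 2L,
    arm_labels = c("placebo", "A"),
    relative_reduction = c(0, relative_reduction),
    hazard_ratio = c(1, 1),
    n_randomise_per_arm = as.integer(n_per_arm),
    stage_n = as.integer(round(n_per_arm * c(1, 2, 3) / 3)),
    dropout_fraction = 0,
    long_survivor_prob = 0,
    visit_months = seq(0, 18, by = 2),
    accrual_rate = 50
  ), list(...))
  do.call(scenario_config, args)
}

# minimal slope-contrast stub for gate tests that specify the statistic
# directly rather than a fitted model
contrast_stub <- function(arm = "A", ...) {
  structure(c(list(arm = arm), list(...)), class = "slope_contrast")
}
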