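#' Scenario configuration for a simulated MAMS trial
#'
#' Builds and validates the full set of data-generating and design
#' parameters for one simulated trial scenario. The defaults describe a
#' three-arm (two active, one placebo) platform trial in motor neuron
#' disease: linear ALSFRS-R decline with per-participant random intercepts
#' and slopes, treatment effects expressed as a relative reduction in the
#' rate of decline, exponential survival with per-arm hazard ratios,
#' non-informative dropout calibrated to about 10% by 18 months, 5% long
#' survivors, staggered exponential accrual, and two-monthly visits.
#'
#' Arm 1 is always the placebo/control arm: its `relative_reduction` must
#' be exactly 0 and its `hazard_ratio` exactly 1.
#'
#' @param n_arms total number of arms including placebo (>= 2).
#' @param arm_labels character labels; first label is the control arm.
#' @param alloc_ratio positive per-arm allocation weights (default equal).
#' @param n_randomise_per_arm randomisation target per arm (default 177,
#'   the 150-per-arm primary analysis requirement inflated for dropout and
#'   long-survivor exclusion; see [required_randomised()]).
#' @param accrual_rate expected participants randomised per month.
#' @param placebo_slope_mean mean ALSFRS-R slope in the control arm,
#'   points/month (negative; default -1.0).
#' @param slope_sd between-participant SD of the latent slope, points/month.
#' @param intercept_mean,intercept_sd baseline ALSFRS-R mean and SD, points.
#' @param residual_sd within-participant residual SD, points.
#' @param relative_reduction per-arm fraction of the placebo decline removed
#'   by treatment (0 = null; first entry must be 0).
#' @param median_survival_placebo median survival in the control arm, months.
#' @param hazard_ratio per-arm hazard ratio versus placebo (first entry 1).
#' @param dropout_fraction probability of dropout before month 18.
#' @param long_survivor_prob probability a participant is a long survivor
#'   (>8 years since diagnosis) at baseline.
#' @param covariate_prevalences named numeric with elements `riluzole` and
#'   `niv_gastrostomy`: prevalence of each binary minimisation covariate.
#' @param visit_months scheduled assessment months (must include 0).
#' @param minimisation_prob probability that minimisation follows the
#'   score-minimising arm (the "random element"; default 0.80).
#' @param arm_start_month calendar month each arm opens (0 for arms present
#'   at trial start); used when arms are added to the platform.
#' @param stage_n participants per arm (excluding long survivors) required
#'   at each ALSFRS-R stage (default 50, 100, 150).
#' @param stage_months months of follow-up required at each stage
#'   (default 6, 12, 18).
#' @param stage1_margin relative improvement that the stage-1 CI must reach
#'   (default 0.25).
#' @param alpha_stage2,alpha_stage3,alpha_survival one-sided significance
#'   levels for the stage-2 gate, stage-3 test and gatekept survival test.
#' @param placebo_death_threshold placebo deaths triggering the survival
#'   analysis (default 113).
#' @param analysis_method `"twostage"` (per-participant OLS slopes compared
#'   across arms; exact mixed-model equivalent on balanced complete data and
#'   fast enough for Monte Carlo) or `"reml"` (the hierarchical normal
#'   linear model via [lme4::lmer()]).
#' @param visit_jitter_sd SD (months) of Gaussian jitter on post-baseline
#'   visit times (default 0: visits exactly on schedule).
#' @param informative_dropout_strength log-hazard increase in dropout per SD
#'   of faster-than-average decline (default 0: dropout independent of
#'   trajectory).
#' @param analysis_lag months between a stage trigger and arm closure
#'   (default 0: interim analyses are instantaneous).
#' @param seed optional integer seed stored with the scenario.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @examples
#' cfg <- scenario_config(relative_reduction = c(0, 0.25, 0.25))
#' cfg$n_randomise_per_arm
#' @seealso [load_config()], [run_trial()], [estimate_oc()]
#' @export
scenario_config <- function(n_arms = 3L,
                            arm_labels = NULL,
                            alloc_ratio = NULL,
                            n_randomise_per_arm = 177L,
                            accrual_rate = 10,
                            placebo_slope_mean = -1.0,
                            slope_sd = 0.6,
                            intercept_mean = 38,
                            intercept_sd = 6,
                            residual_sd = 2.5,
                            relative_reduction = NULL,
                            median_survival_placebo = 24,
                            hazard_ratio = NULL,
                            dropout_fraction = 0.10,
                            long_survivor_prob = 0.05,
                            covariate_prevalences = c(riluzole = 0.70,
                                                      niv_gastrostomy = 0.15),
                            visit_months = seq(0, 48, by = 2),
                            minimisation_prob = 0.80,
                            arm_start_month = NULL,
                            stage_n = c(50L, 100L, 150L),
                            stage_months = c(6, 12, 18),
                            stage1_margin = 0.25,
                            alpha_stage2 = 0.10,
                            alpha_stage3 = 0.025,
                            alpha_survival = 0.025,
                            placebo_death_threshold = 113L,
                            analysis_method = c("twostage", "reml"),
                            visit_jitter_sd = 0,
                            informative_dropout_strength = 0,
                            analysis_lag = 0,
                            seed = NULL) {
  n_arms <- as.integer(n_arms)
  if (is.null(arm_labels)) {
    arm_labels <- c("placebo", LETTERS[seq_len(max(n_arms - 1L, 0L))])
  }
  if (is.null(alloc_ratio)) alloc_ratio <- rep(1, n_arms)
  if (is.null(relative_reduction)) relative_reduction <- rep(0, n_arms)
  if (is.null(hazard_ratio)) hazard_ratio <- rep(1, n_arms)
  if (is.null(arm_start_month)) arm_start_month <- rep(0, n_arms)
  analysis_method <- match.arg(analysis_method)

  cfg <- structure(list(
    n_arms = n_arms,
    arm_labels = as.character(arm_labels),
    alloc_ratio = as.numeric(alloc_ratio),
    n_randomise_per_arm = as.integer(n_randomise_per_arm),
    accrual_rate = accrual_rate,
    placebo_slope_mean = placebo_slope_mean,
    slope_sd = slope_sd,
    intercept_mean = intercept_mean,
    intercept_sd = intercept_sd,
    residual_sd = residual_sd,
    relative_reduction = as.numeric(relative_reduction),
    median_survival_placebo = median_survival_placebo,
    hazard_ratio = as.numeric(hazard_ratio),
    dropout_fraction = dropout_fraction,
    long_survivor_prob = long_survivor_prob,
    covariate_prevalences = covariate_prevalences,
    visit_months = as.numeric(visit_months),
    minimisation_prob = minimisation_prob,
    arm_start_month = as.numeric(arm_start_month),
    stage_n = as.integer(stage_n),
    stage_months = as.numeric(stage_months),
    stage1_margin = stage1_margin,
    alpha_stage2 = alpha_stage2,
    alpha_stage3 = alpha_stage3,
    alpha_survival = alpha_survival,
    placebo_death_threshold = as.integer(placebo_death_threshold),
    analysis_method = analysis_method,
    visit_jitter_sd = visit_jitter_sd,
    informative_dropout_strength = informative_dropout_strength,
    analysis_lag = analysis_lag,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "scenario_config")
  validate_scenario_config(cfg)
}

#' Validate a scenario configuration
#'
#' Checks every invariant of a [scenario_config()] object and fails with a
#' message naming the offending parameter, its value and the constraint.
#'
#' @param cfg a `scenario_config` (or plain list with the same fields).
#' @return The validated object, invisibly classed as `scenario_config`.
#' @export
validate_scenario_config <- function(cfg) {
  fail <- function(name, value, constraint) {
    stop(sprintf("invalid scenario parameter `%s` (value: %s): %s",
                 name, paste(format(value), collapse = ", "), constraint),
         call. = FALSE)
  }
  chk_prob <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1))
      fail(name, v, "must lie in [0, 1]")
  }
  if (cfg$n_arms < 2L) fail("n_arms", cfg$n_arms, "need at least 2 arms")
  for (f in c("arm_labels", "alloc_ratio", "relative_reduction",
              "hazard_ratio", "arm_start_month")) {
    if (length(cfg[[f]]) != cfg$n_arms)
      fail(f, cfg[[f]], sprintf("length must equal n_arms (%d)", cfg$n_arms))
  }
  if (anyDuplicated(cfg$arm_labels))
    fail("arm_labels", cfg$arm_labels, "labels must be unique")
  if (any(cfg$alloc_ratio <= 0))
    fail("alloc_ratio", cfg$alloc_ratio, "all weights must be positive")
  if (cfg$relative_reduction[1L] != 0)
    fail("relative_reduction", cfg$relative_reduction,
         "control-arm (first) entry must be exactly 0")
  if (any(cfg$relative_reduction > 1))
    fail("relative_reduction", cfg$relative_reduction, "must be <= 1")
  if (cfg$hazard_ratio[1L] != 1)
    fail("hazard_ratio", cfg$hazard_ratio, "control-arm (first) entry must be 1")
  if (any(cfg$hazard_ratio <= 0))
    fail("hazard_ratio", cfg$hazard_ratio, "must be positive")
  if (cfg$n_randomise_per_arm < 1L)
    fail("n_randomise_per_arm", cfg$n_randomise_per_arm, "must be >= 1")
  if (!is.numeric(cfg$accrual_rate) || cfg$accrual_rate <= 0)
    fail("accrual_rate", cfg$accrual_rate, "must be > 0 participants/month")
  if (cfg$slope_sd <= 0) fail("slope_sd", cfg$slope_sd, "must be > 0")
  if (cfg$residual_sd <= 0) fail("residual_sd", cfg$residual_sd, "must be > 0")
  if (cfg$intercept_sd < 0) fail("intercept_sd", cfg$intercept_sd, "must be >= 0")
  if (cfg$median_survival_placebo <= 0)
    fail("median_survival_placebo", cfg$median_survival_placebo, "must be > 0")
  chk_prob("dropout_fraction")
  chk_prob("long_survivor_prob")
  chk_prob("minimisation_prob")
  cp <- cfg$covariate_prevalences
  if (!all(c("riluzole", "niv_gastrostomy") %in% names(cp)))
    fail("covariate_prevalences", cp,
         "must name `riluzole` and `niv_gastrostomy`")
  chk_prob("covariate_prevalences")
  if (!0 %in% cfg$visit_months)
    fail("visit_months", cfg$visit_months, "must include the baseline month 0")
  if (is.unsorted(cfg$visit_months, strictly = TRUE))
    fail("visit_months", cfg$visit_months, "must be strictly increasing")
  if (length(cfg$stage_n) != 3L || length(cfg$stage_months) != 3L)
    fail("stage_n", cfg$stage_n,
         "the design has exactly 3 ALSFRS-R stages")
  if (any(cfg$stage_n < 1L)) fail("stage_n", cfg$stage_n, "must be >= 1")
  if (any(diff(cfg$stage_n) <= 0) || any(diff(cfg$stage_months) <= 0))
    fail("stage_n", cfg$stage_n, "stage sizes and months must be increasing")
  if (any(cfg$stage_n > cfg$n_randomise_per_arm))
    fail("stage_n", cfg$stage_n,
         "stage sizes cannot exceed n_randomise_per_arm")
  for (a in c("alpha_stage2", "alpha_stage3", "alpha_survival")) {
    if (cfg[[a]] <= 0 || cfg[[a]] >= 0.5)
      fail(a, cfg[[a]], "one-sided level must lie in (0, 0.5)")
  }
  if (cfg$stage1_margin <= 0 || cfg$stage1_margin >= 1)
    fail("stage1_margin", cfg$stage1_margin, "must lie in (0, 1)")
  if (cfg$placebo_death_threshold < 1L)
    fail("placebo_death_threshold", cfg$placebo_death_threshold, "must be >= 1")
  if (cfg$visit_jitter_sd < 0)
    fail("visit_jitter_sd", cfg$visit_jitter_sd, "must be >= 0")
  if (cfg$analysis_lag < 0)
    fail("analysis_lag", cfg$analysis_lag, "must be >= 0")
  if (cfg$arm_start_month[1L] != 0)
    fail("arm_start_month", cfg$arm_start_month,
         "control arm must open at month 0")
  if (any(cfg$arm_start_month < 0))
    fail("arm_start_month", cfg$arm_start_month, "must be >= 0")
  class(cfg) <- "scenario_config"
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  active <- x$arm_labels[-1L]
  cat("MAMS trial scenario\n")
  cat(sprintf("  arms: %s (control: %s)\n",
              paste(x$arm_labels, collapse = ", "), x$arm_labels[1L]))
  cat(sprintf("  randomise/arm: %d; accrual %.1f/month\n",
              x$n_randomise_per_arm, x$accrual_rate))
  cat(sprintf("  relative reduction: %s; hazard ratio: %s\n",
              paste(x$relative_reduction[-1L], collapse = ", "),
              paste(x$hazard_ratio[-1L], collapse = ", ")))
  cat(sprintf("  placebo slope %.2f pts/month (slope sd %.2f, residual sd %.2f)\n",
              x$placebo_slope_mean, x$slope_sd, x$residual_sd))
  cat(sprintf("  stages: %s/arm at %s months; survival at %d placebo deaths\n",
              paste(x$stage_n, collapse = "/"),
              paste(x$stage_months, collapse = "/"),
              x$placebo_death_threshold))
  invisible(x)
}

#' Randomisation target inflated for dropout and long-survivor exclusion
#'
#' Number of participants to randomise per arm so that the primary-analysis
#' requirement is met after losing a fraction to dropout and a fraction to
#' the long-survivor exclusion (additive loss, ceiling). With the defaults
#' (150 analysed, 10% dropout, 5% long survivors) this gives 177 per arm.
#'
#' @param n_analysis participants per arm required in the primary analysis.
#' @param dropout_fraction expected dropout fraction.
#' @param long_survivor_prob expected long-survivor fraction.
#' @return Integer participants to randomise per arm.
#' @examples
#' required_randomised(150, 0.10, 0.05)  # 177
#' @export
required_randomised <- function(n_analysis = 150,
                                dropout_fraction = 0.10,
                                long_survivor_prob = 0.05) {
  loss <- dropout_fraction + long_survivor_prob
  if (loss >= 1) stop("combined loss fraction must be < 1", call. = FALSE)
  as.integer(ceiling(n_analysis / (1 - loss)))
}
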