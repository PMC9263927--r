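#' Staggered accrual times
#'
#' Entry times (months since trial start) for `n` participants with
#' exponential inter-arrival times at the configured accrual rate.
#'
#' @param n number of participants.
#' @param accrual_rate expected participants per month (> 0).
#' @return Sorted numeric vector of entry times.
#' @export
generate_accrual <- function(n, accrual_rate) {
  if (!is.numeric(accrual_rate) || accrual_rate <= 0) {
    stop("invalid scenario parameter `accrual_rate` (value: ",
         format(accrual_rate), "): must be > 0 participants/month",
         call. = FALSE)
  }
  if (n < 1) return(numeric(0))
  cumsum(rexp(n, rate = accrual_rate))
}

#' Generate virtual participants
#'
#' Draws baseline covariates, latent trajectory parameters and latent event
#' times for `n` participants. Covariate flags are independent Bernoulli
#' draws at the configured prevalences. The latent ALSFRS-R slope is drawn
#' on the placebo scale (arm-agnostically); the treatment effect is applied
#' later, at trajectory time, so that randomisation stays causally prior to
#' the effect. Survival is exponential at the placebo median; the per-arm
#' hazard ratio is applied multiplicatively to the hazard after arm
#' assignment (see [apply_arm_hazard()]). Dropout time is exponential,
#' calibrated so that the probability of dropout before month 18 equals
#' `dropout_fraction`; when `informative_dropout_strength` is non-zero the
#' dropout hazard increases with faster-than-average decline.
#'
#' @param config a validated [scenario_config()].
#' @param n number of participants to generate.
#' @param entry_times optional entry times (defaults to
#'   [generate_accrual()]).
#' @return A data frame with one row per participant: `id`, `entry_time`,
#'   `arm` (`NA` until randomised), `riluzole`, `niv_gastrostomy`,
#'   `long_survivor`, `true_intercept`, `true_slope` (placebo scale,
#'   points/month), `death_time` (placebo scale until an arm hazard is
#'   applied) and `dropout_time`, both in months since randomisation.
#' @export
generate_participants <- function(config, n, entry_times = NULL) {
  validate_scenario_config(config)
  n <- as.integer(n)
  if (is.null(entry_times)) entry_times <- generate_accrual(n, config$accrual_rate)
  stopifnot(length(entry_times) == n)
  cp <- config$covariate_prevalences
  slope <- rnorm(n, config$placebo_slope_mean, config$slope_sd)

  death_rate <- log(2) / config$median_survival_placebo
  if (config$dropout_fraction > 0) {
    base_drop_rate <- -log(1 - config$dropout_fraction) / 18
    z <- (config$placebo_slope_mean - slope) / config$slope_sd
    drop_rate <- base_drop_rate * exp(config$informative_dropout_strength * z)
    dropout_time <- rexp(n, rate = 1) / drop_rate
  } else {
    dropout_time <- rep(Inf, n)
  }

  data.frame(
    id = seq_len(n),
    entry_time = entry_times,
    arm = rep(NA_character_, n),
    riluzole = rbinom(n, 1L, cp[["riluzole"]]),
    niv_gastrostomy = rbinom(n, 1L, cp[["niv_gastrostomy"]]),
    long_survivor = rbinom(n, 1L, config$long_survivor_prob),
    true_intercept = rnorm(n, config$intercept_mean, config$intercept_sd),
    true_slope = slope,
    death_time = rexp(n, rate = death_rate),
    dropout_time = dropout_time,
    stringsAsFactors = FALSE
  )
}

#' Apply an arm's hazard ratio to placebo-scale death times
#'
#' An exponential time with hazard `lambda`, divided by `hr`, is
#' exponential with hazard `lambda * hr`; dividing the placebo-scale death
#' time by the arm's hazard ratio is therefore exactly the multiplicative
#' hazard model.
#'
#' @param death_time placebo-scale death times.
#' @param hazard_ratio the assigned arm's hazard ratio versus placebo.
#' @return Arm-scale death times.
#' @export
apply_arm_hazard <- function(death_time, hazard_ratio) {
  stopifnot(all(hazard_ratio > 0))
  death_time / hazard_ratio
}

#' Simulate ALSFRS-R trajectories
#'
#' Generates the scheduled visit records for randomised participants. The
#' mean trajectory is `true_intercept + true_slope * (1 - arm_effect) * t`;
#' each observation adds Normal residual noise, is rounded to the nearest
#' integer and clamped to the instrument range 0-48 (round first, then
#' clamp: the instrument is an integer scale). Records stop at death,
#' dropout and the data-cut date; the baseline visit is always observed.
#' Observations simply stop at death (the outcome model treats them as
#' missing): no post-death imputation.
#'
#' @param participants randomised participants (rows of
#'   [generate_participants()] output with `arm` assigned and `death_time`
#'   on the arm scale).
#' @param arm_effect relative reduction in decline for each participant's
#'   arm (vector recycled to participants; each in `[0, 1]`).
#' @param config a validated [scenario_config()].
#' @param cut_date calendar data-cut in months since trial start
#'   (default `Inf`: no cut).
#' @return A long-format data frame: `participant_id`, `visit_month`
#'   (scheduled), `time` (actual assessment time, equal to the schedule
#'   unless jitter is configured), `alsfrs_r`.
#' @export
simulate_trajectories <- function(participants, arm_effect, config,
                                  cut_date = Inf) {
  validate_scenario_config(config)
  n <- nrow(participants)
  arm_effect <- rep_len(arm_effect, n)
  if (any(arm_effect < 0 | arm_effect > 1)) {
    stop("arm_effect must lie in [0, 1]", call. = FALSE)
  }
  vm <- config$visit_months
  nv <- length(vm)
  sched <- matrix(vm, nrow = n, ncol = nv, byrow = TRUE)
  tt <- sched
  if (config$visit_jitter_sd > 0 && nv > 1L) {
    jit <- matrix(rnorm(n * (nv - 1L), 0, config$visit_jitter_sd),
                  nrow = n)
    tt[, -1L] <- pmax(tt[, -1L] + jit, 1e-8)
  }
  mean_score <- participants$true_intercept +
    participants$true_slope * (1 - arm_effect) * tt
  score <- mean_score + matrix(rnorm(n * nv, 0, config$residual_sd), nrow = n)
  score <- pmin(pmax(round(score), 0L), 48L)

  horizon <- pmin(participants$death_time, participants$dropout_time,
                  cut_date - participants$entry_time)
  keep <- tt <= horizon
  keep[, 1L] <- TRUE  # baseline always observed
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(
    participant_id = participants$id[idx[, 1L]],
    visit_month = sched[idx],
    time = tt[idx],
    alsfrs_r = as.integer(score[idx])
  )
  out[order(out$participant_id, out$visit_month), , drop = FALSE]
}

#' Simulate a complete randomised cohort
#'
#' Convenience wrapper that accrues, generates and minimisation-randomises
#' a full cohort (all arms open for its duration), applies arm effects to
#' trajectories and survival, and returns analysis-ready tables. All
#' stochastic draws flow from a single seeded generator: identical seed and
#' configuration give byte-identical tables.
#'
#' @param config a validated [scenario_config()]; `config$seed`, if set,
#'   seeds the generator.
#' @param cut_date calendar data-cut in months since trial start (default
#'   `Inf`: every death observed, no administrative censoring).
#' @return A list of class `mams_cohort`: `participants`, `visits`
#'   (long format), `survival` (`participant_id`, `time`, `event`, `arm`,
#'   covariates, `entry_time`) and the `config`.
#' @export
simulate_cohort <- function(config, cut_date = Inf) {
  validate_scenario_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_arms * config$n_randomise_per_arm
  participants <- generate_participants(config, n)
  state <- minimisation_state(config$arm_labels, config$alloc_ratio)
  arm_idx <- integer(n)
  cap <- config$n_randomise_per_arm
  for (i in seq_len(n)) {
    a <- allocate_minimised(
      covariates = c(participants$riluzole[i], participants$niv_gastrostomy[i],
                     participants$long_survivor[i]),
      state = state,
      minimisation_prob = config$minimisation_prob
    )
    state <- a$state
    arm_idx[i] <- a$arm_index
    if (state$totals[a$arm_index] >= cap) {
      state <- close_arm(state, config$arm_labels[a$arm_index])
    }
  }
  participants$arm <- config$arm_labels[arm_idx]
  participants$death_time <- apply_arm_hazard(
    participants$death_time, config$hazard_ratio[arm_idx])
  effect <- config$relative_reduction[arm_idx]
  visits <- simulate_trajectories(participants, effect, config, cut_date)
  survival <- survival_table(participants, cut_date)
  structure(list(participants = participants, visits = visits,
                 survival = survival, config = config),
            class = "mams_cohort")
}

# Survival table at a calendar cut. Dropout does not censor survival
# (vital status follow-up continues from medical records); only the
# administrative cut censors.
survival_table <- function(participants, cut_date = Inf) {
  fu <- cut_date - participants$entry_time
  event <- as.integer(participants$death_time <= fu)
  time <- pmin(participants$death_time, fu)
  data.frame(
    participant_id = participants$id,
    time = time,
    event = event,
    arm = participants$arm,
    riluzole = participants$riluzole,
    niv_gastrostomy = participants$niv_gastrostomy,
    long_survivor = participants$long_survivor,
    entry_time = participants$entry_time,
    stringsAsFactors = FALSE
  )
}

#' @export
print.mams_cohort <- function(x, ...) {
  cat("Simulated MAMS cohort\n")
  cat(sprintf("  %d participants, %d visit records\n",
              nrow(x$participants), nrow(x$visits)))
  print(table(arm = x$participants$arm))
  invisible(x)
}
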