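#' Kaplan-Meier, log-rank and Cox comparison of one active arm with control
#'
#' Product-limit survival estimates with median and 95% CI per arm, the
#' two-sample log-rank test with a one-sided p-value in the benefit
#' direction (fewer deaths than expected in the active arm), and a Cox
#' proportional-hazards model (Efron tie handling) adjusted for the
#' baseline minimisation covariates. Unlike the ALSFRS-R analysis, the
#' survival analysis set includes baseline long survivors, so the
#' long-survivor flag enters the Cox model as a covariate.
#'
#' @param surv survival table: `time`, `event` (0/1), `arm`, and covariate
#'   columns `riluzole`, `niv_gastrostomy`, `long_survivor`.
#' @param arms length-2 character vector: control first, active second.
#' @param covariate_adjust adjust the Cox model for the minimisation
#'   covariates (default `TRUE`).
#' @return A list of class `survival_result`: `medians` (per-arm KM median
#'   with 95% CI), `deaths` (per-arm event counts), `logrank_chisq`,
#'   `logrank_z`, `logrank_p_one_sided`, `cox_loghr`, `cox_se`,
#'   `cox_hr_ci`, `cox_p_one_sided`, `tests_defined`.
#' @export
km_logrank_cox <- function(surv, arms, covariate_adjust = TRUE) {
  stopifnot(length(arms) == 2L)
  d <- surv[surv$arm %in% arms, , drop = FALSE]
  if (any(d$time <= 0)) stop("survival times must be positive", call. = FALSE)
  d$arm <- factor(d$arm, levels = arms)
  deaths <- vapply(split(d$event, d$arm), sum, numeric(1))
  deaths <- setNames(as.integer(deaths), arms)

  km <- survival::survfit(survival::Surv(time, event) ~ arm, data = d,
                          conf.type = "log-log")
  qt <- quantile(km, probs = 0.5)
  medians <- data.frame(arm = arms,
                        median = as.numeric(qt$quantile),
                        ci_low = as.numeric(qt$lower),
                        ci_high = as.numeric(qt$upper))

  if (sum(d$event) == 0) {
    return(structure(list(medians = medians, deaths = deaths,
                          logrank_chisq = NA_real_, logrank_z = NA_real_,
                          logrank_p_one_sided = NA_real_,
                          cox_loghr = NA_real_, cox_se = NA_real_,
                          cox_hr_ci = c(NA_real_, NA_real_),
                          cox_p_one_sided = NA_real_,
                          tests_defined = FALSE),
                     class = "survival_result"))
  }

  lr <- survival::survdiff(survival::Surv(time, event) ~ arm, data = d)
  # z signed so that fewer active-arm deaths than expected (benefit) is
  # negative; one-sided p is the lower tail
  z <- (lr$obs[2L] - lr$exp[2L]) / sqrt(lr$var[2L, 2L])
  p_lr <- pnorm(z)

  cox_form <- if (covariate_adjust) {
    survival::Surv(time, event) ~ arm + riluzole + niv_gastrostomy +
      long_survivor
  } else {
    survival::Surv(time, event) ~ arm
  }
  cox <- tryCatch(
    survival::coxph(cox_form, data = d, ties = "efron"),
    error = function(e) NULL
  )
  if (is.null(cox) && covariate_adjust) {
    cox <- survival::coxph(survival::Surv(time, event) ~ arm, data = d,
                           ties = "efron")
  }
  nm <- paste0("arm", arms[2L])
  loghr <- unname(coef(cox)[nm])
  se <- sqrt(diag(vcov(cox)))[[nm]]
  structure(list(
    medians = medians,
    deaths = deaths,
    logrank_chisq = unname(lr$chisq),
    logrank_z = unname(z),
    logrank_p_one_sided = unname(p_lr),
    cox_loghr = loghr,
    cox_se = se,
    cox_hr_ci = exp(loghr + c(-1, 1) * qnorm(0.975) * se),
    cox_p_one_sided = pnorm(loghr / se),
    tests_defined = TRUE
  ), class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("Survival comparison\n")
  print(x$medians, row.names = FALSE)
  cat(sprintf("  deaths: %s\n",
              paste(names(x$deaths), x$deaths, sep = "=", collapse = ", ")))
  if (isTRUE(x$tests_defined)) {
    cat(sprintf("  log-rank chisq %.3f, one-sided p %.4g\n",
                x$logrank_chisq, x$logrank_p_one_sided))
    cat(sprintf("  Cox HR %.3f (95%% CI %.3f-%.3f), one-sided p %.4g\n",
                exp(x$cox_loghr), x$cox_hr_ci[1], x$cox_hr_ci[2],
                x$cox_p_one_sided))
  } else {
    cat("  no events: tests undefined\n")
  }
  invisible(x)
}

#' Schoenfeld approximation to log-rank power
#'
#' Power of the one-sided log-rank test as a function of the number of
#' events: `power = pnorm(sqrt(D/4) * |log(HR)| - z_(1-alpha))` with
#' `D = 2 * deaths_per_arm` under 1:1 allocation. With 113 deaths per arm
#' and HR 0.65 at one-sided 2.5% this gives 90% power.
#'
#' @param deaths_per_arm expected deaths in each of the two arms.
#' @param hazard_ratio hazard ratio under the alternative (0 < HR <= 1;
#'   HR = 1 returns `alpha`).
#' @param alpha_one_sided one-sided significance level in (0, 0.5).
#' @return Power as a fraction in (0, 1).
#' @examples
#' schoenfeld_power(113, 0.65, 0.025)  # ~0.90
#' @export
schoenfeld_power <- function(deaths_per_arm, hazard_ratio,
                             alpha_one_sided = 0.025) {
  if (deaths_per_arm <= 0) stop("deaths_per_arm must be > 0", call. = FALSE)
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (hazard_ratio > 1) stop("hazard_ratio must be <= 1 (benefit direction)",
                             call. = FALSE)
  if (alpha_one_sided <= 0 || alpha_one_sided >= 0.5) {
    stop("alpha_one_sided must lie in (0, 0.5)", call. = FALSE)
  }
  D <- 2 * deaths_per_arm
  pnorm(sqrt(D / 4) * abs(log(hazard_ratio)) - qnorm(1 - alpha_one_sided))
}

#' Calendar date of the event-driven survival trigger
#'
#' The survival analysis is triggered when a pre-specified number of deaths
#' has accrued in the control arm. Deaths are located in calendar time as
#' entry time plus time to death; dropout does not censor survival (vital
#' status continues to be followed from medical records).
#'
#' @param surv survival table with `arm`, `entry_time`, `time`, `event`.
#' @param placebo_arm control-arm label.
#' @param threshold number of control-arm deaths required (>= 1).
#' @return A list: `reached` (logical) and `date` (calendar month of the
#'   threshold-th control death, `NA` if not yet reached).
#' @export
event_trigger <- function(surv, placebo_arm = "placebo", threshold = 113L) {
  if (threshold < 1L) stop("threshold must be >= 1", call. = FALSE)
  p <- surv[surv$arm == placebo_arm & surv$event == 1L, , drop = FALSE]
  if (nrow(p) < threshold) {
    return(list(reached = FALSE, date = NA_real_, n_deaths = nrow(p)))
  }
  dates <- sort(p$entry_time + p$time)
  list(reached = TRUE, date = dates[threshold], n_deaths = nrow(p))
}
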