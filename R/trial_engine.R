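#' Run one virtual MAMS trial end-to-end
#'
#' Simulates a complete trial under one scenario: staggered accrual,
#' minimisation randomisation to the arms open at each arrival, the
#' three-stage ALSFRS-R decision procedure (each stage triggered at the
#' calendar date when the required number of non-long-survivor
#' participants per arm has the required follow-up), arm dropping with
#' reallocation of their share to the remaining open arms, and the
#' event-driven, gatekept survival comparison.
#'
#' Stage triggers are evaluated per comparison in calendar time:
#' stage `k` for an arm fires when both that arm and its contemporaneous
#' controls have `stage_n[k]` non-long-survivor participants with at least
#' `stage_months[k]` months since randomisation ("completed k months of
#' treatment" counts calendar time since randomisation: discontinuers
#' still count, per the treatment-policy estimand). Each analysis uses all
#' visits observed on or before its trigger date, not only the first
#' `stage_months[k]` months. Arms added later (see [add_arm()]) are
#' compared against contemporaneous controls only: control participants
#' randomised while that arm was open to recruitment.
#'
#' The survival analysis is performed at the later of the last stage-3
#' data-collection date and the calendar date of the
#' `placebo_death_threshold`-th control-arm death; participants alive then
#' are censored. Dropout does not censor survival.
#'
#' @param config a validated [scenario_config()].
#' @param seed optional integer seed (falls back to `config$seed`).
#' @param keep_data also return the generated participant and visit tables
#'   and each arm's contemporaneous-control ids (default `FALSE`).
#' @return A list of class `trial_result`: `decisions` (data frame: arm,
#'   stage, decision, statistic, threshold), `contrasts` (per arm/stage
#'   [slope_contrast()]s), `survival_results` (per-arm
#'   [km_logrank_cox()] results, or `NULL` if no arm reached stage 3),
#'   `counts` (CONSORT-style per-arm accounting), `trigger_dates`,
#'   `survival_date`, `total_randomised`, `duration`, `all_dropped`,
#'   `seed`, `config`.
#' @export
run_trial <- function(config, seed = NULL, keep_data = FALSE) {
  validate_scenario_config(config)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }

  labels <- config$arm_labels
  control <- labels[1L]
  active <- labels[-1L]
  k_arms <- config$n_arms
  cap <- config$n_randomise_per_arm
  nstage <- length(config$stage_n)
  lag <- config$analysis_lag

  # --- participant pool, grown in chunks along one accrual stream -------
  pool <- new.env(parent = emptyenv())
  pool$entry <- numeric(0); pool$ril <- integer(0); pool$niv <- integer(0)
  pool$ls <- integer(0); pool$b0 <- numeric(0); pool$b1 <- numeric(0)
  pool$death <- numeric(0); pool$dropw <- numeric(0)
  pool$n <- 0L
  grow_pool <- function(chunk = 256L) {
    last <- if (pool$n > 0L) pool$entry[pool$n] else 0
    entries <- last + cumsum(rexp(chunk, rate = config$accrual_rate))
    p <- generate_participants(config, chunk, entry_times = entries)
    pool$entry <- c(pool$entry, p$entry_time)
    pool$ril <- c(pool$ril, p$riluzole)
    pool$niv <- c(pool$niv, p$niv_gastrostomy)
    pool$ls <- c(pool$ls, p$long_survivor)
    pool$b0 <- c(pool$b0, p$true_intercept)
    pool$b1 <- c(pool$b1, p$true_slope)
    pool$death <- c(pool$death, p$death_time)
    pool$dropw <- c(pool$dropw, p$dropout_time)
    pool$n <- pool$n + chunk
  }
  grow_pool()

  # --- allocation / bookkeeping state -----------------------------------
  arm_status <- setNames(ifelse(config$arm_start_month <= 0, "open",
                                "waiting"), labels)
  arm_status[control] <- "open"
  stage_idx <- setNames(rep(1L, k_arms), labels)      # next stage, active arms
  trigger_dates <- matrix(NA_real_, nrow = k_arms, ncol = nstage,
                          dimnames = list(labels, paste0("stage", 1:nstage)))
  arm_entries <- setNames(vector("list", k_arms), labels)  # non-LS entries
  cont_entries <- setNames(vector("list", k_arms), labels) # contemp. control
  cont_ids <- setNames(vector("list", k_arms), labels)     # control ids
  for (a in labels) {
    arm_entries[[a]] <- numeric(0)
    cont_entries[[a]] <- numeric(0)
    cont_ids[[a]] <- integer(0)
  }
  arm_of <- integer(0)          # arm index per allocated participant id
  alloc_ids <- integer(0)       # pool ids, in allocation order
  alloc_log <- if (keep_data) vector("list", 0L) else NULL
  n_alloc <- setNames(integer(k_arms), labels)
  mstate <- minimisation_state(labels, config$alloc_ratio)
  decisions <- list()
  contrasts_log <- list()
  n_analysed <- matrix(NA_integer_, nrow = k_arms, ncol = nstage,
                       dimnames = dimnames(trigger_dates))

  visits <- vector("list", 0L)   # materialised trajectory batches
  materialised_upto <- 0L        # allocation-order index
  materialise <- function() {
    idx <- seq_len(length(alloc_ids))
    idx <- idx[idx > materialised_upto]
    if (length(idx) == 0L) return(invisible())
    ids <- alloc_ids[idx]
    parts <- data.frame(
      id = ids, entry_time = pool$entry[ids],
      true_intercept = pool$b0[ids], true_slope = pool$b1[ids],
      death_time = pool$death[ids] / config$hazard_ratio[arm_of[idx]],
      dropout_time = pool$dropw[ids]
    )
    eff <- config$relative_reduction[arm_of[idx]]
    visits[[length(visits) + 1L]] <<- simulate_trajectories(
      parts, eff, config, cut_date = Inf)
    materialised_upto <<- length(alloc_ids)
  }

  participants_df <- function(ids) {
    ord <- match(ids, alloc_ids)
    data.frame(
      id = ids, entry_time = pool$entry[ids],
      arm = labels[arm_of[ord]],
      riluzole = pool$ril[ids], niv_gastrostomy = pool$niv[ids],
      long_survivor = pool$ls[ids],
      death_time = pool$death[ids] / config$hazard_ratio[arm_of[ord]],
      dropout_time = pool$dropw[ids],
      stringsAsFactors = FALSE
    )
  }

  # date at which arm a's next stage analysis can be performed
  next_analysis_date <- function(a, accrual_done) {
    s <- stage_idx[[a]]
    if (s > nstage || arm_status[[a]] %in% c("dropped", "waiting"))
      return(NA_real_)
    n_s <- config$stage_n[s]
    m_s <- config$stage_months[s]
    ea <- arm_entries[[a]]
    ep <- cont_entries[[a]]
    if (length(ea) >= n_s && length(ep) >= n_s) {
      return(max(ea[n_s], ep[n_s]) + m_s + lag)
    }
    if (accrual_done && length(ea) >= 2L && length(ep) >= 2L) {
      # accrual ended short of the threshold: analyse what there is
      return(max(ea[length(ea)], ep[length(ep)]) + m_s + lag)
    }
    NA_real_
  }

  do_analysis <- function(a, date) {
    s <- stage_idx[[a]]
    materialise()
    arm_ids <- alloc_ids[arm_of == match(a, labels)]
    ids <- c(arm_ids, cont_ids[[a]])
    parts <- participants_df(ids)
    vis <- do.call(rbind, visits)
    vis <- vis[vis$participant_id %in% ids, , drop = FALSE]
    calendar <- pool$entry[vis$participant_id] + vis$time
    vis <- vis[calendar <= date, , drop = FALSE]
    contrast <- tryCatch({
      fit <- fit_slope_model(vis, parts, arms = c(control, a),
                             method = config$analysis_method)
      n_analysed[match(a, labels), s] <<- attr(fit, "n_analysed")
      fit[[a]]
    }, error = function(e) NULL)
    dec <- if (is.null(contrast)) {
      # inestimable contrast: never drop an arm on an undefined statistic,
      # but a final analysis that cannot be estimated is not significant
      if (s < nstage) stage_decision(s, a, "continue",
                                     basis = list(inestimable = TRUE))
      else stage_decision(s, a, "not-significant",
                          basis = list(inestimable = TRUE))
    } else if (s == 1L) {
      stage1_gate(contrast, margin = config$stage1_margin)
    } else if (s == 2L) {
      stage2_gate(contrast, alpha = config$alpha_stage2)
    } else {
      stage3_test(contrast, alpha = config$alpha_stage3)
    }
    trigger_dates[match(a, labels), s] <<- date
    decisions[[length(decisions) + 1L]] <<- dec
    if (!is.null(contrast)) {
      contrasts_log[[paste0(a, ".stage", s)]] <<- contrast
    }
    if (dec$decision == "drop") {
      arm_status[[a]] <<- "dropped"
    } else {
      stage_idx[[a]] <<- s + 1L
    }
  }

  # --- chronological accrual / analysis loop ----------------------------
  next_arrival <- 1L
  accrual_done <- FALSE
  repeat {
    # next pending analysis over alive arms
    dates <- vapply(active, next_analysis_date, numeric(1),
                    accrual_done = accrual_done)
    pending <- active[!is.na(dates)]
    t_analysis <- if (length(pending)) min(dates[pending]) else Inf
    t_arrival <- if (accrual_done) Inf else {
      if (next_arrival > pool$n) grow_pool()
      pool$entry[next_arrival]
    }
    if (is.infinite(t_analysis) && is.infinite(t_arrival)) break

    if (t_analysis <= t_arrival) {
      a <- pending[which.min(dates[pending])]
      do_analysis(a, dates[[a]])
      next
    }

    # --- process one arrival at time t_arrival --------------------------
    t <- t_arrival
    opening <- labels[arm_status == "waiting" & config$arm_start_month <= t]
    if (length(opening)) arm_status[opening] <- "open"
    open_active <- active[arm_status[active] == "open"]
    if (length(open_active) == 0L) {
      if (any(arm_status[active] == "waiting")) {
        next_arrival <- next_arrival + 1L   # recruitment paused
        next
      }
      accrual_done <- TRUE
      next
    }
    control_open <- any(
      vapply(open_active,
             function(a) length(cont_ids[[a]]) < cap, logical(1)))
    eligible <- c(if (control_open) control, open_active)
    mstate$open[] <- FALSE
    mstate$open[eligible] <- TRUE
    i <- next_arrival
    al <- allocate_minimised(
      c(pool$ril[i], pool$niv[i], pool$ls[i]), mstate,
      config$minimisation_prob)
    mstate <- al$state
    arm <- al$arm
    if (keep_data) {
      sc <- setNames(rep(NA_real_, k_arms), labels)
      sc[names(al$scores)] <- al$scores
      alloc_log[[length(alloc_log) + 1L]] <- data.frame(
        participant_id = i, arm = arm, t(sc),
        followed_minimiser = al$followed_minimiser)
    }
    alloc_ids <- c(alloc_ids, i)
    arm_of <- c(arm_of, al$arm_index)
    n_alloc[arm] <- n_alloc[arm] + 1L
    if (pool$ls[i] == 0L) arm_entries[[arm]] <- c(arm_entries[[arm]], t)
    if (arm == control) {
      for (a in open_active) {
        cont_ids[[a]] <- c(cont_ids[[a]], i)
        if (pool$ls[i] == 0L) cont_entries[[a]] <- c(cont_entries[[a]], t)
      }
    } else if (n_alloc[arm] >= cap) {
      arm_status[arm] <- "full"
    }
    next_arrival <- next_arrival + 1L
  }

  # --- survival stage ---------------------------------------------------
  materialise()
  stage3_arms <- active[vapply(active, function(a) {
    any(vapply(decisions, function(d) d$arm == a && d$stage == "3",
               logical(1)))
  }, logical(1))]
  all_parts <- participants_df(alloc_ids)
  surv_all <- survival_table(all_parts, cut_date = Inf)
  trig <- event_trigger(surv_all, placebo_arm = control,
                        threshold = min(config$placebo_death_threshold,
                                        max(sum(surv_all$arm == control), 1L)))
  survival_results <- NULL
  survival_date <- NA_real_
  if (length(stage3_arms) > 0L) {
    stage3_dates <- trigger_dates[stage3_arms, nstage]
    survival_date <- max(c(stage3_dates, trig$date), na.rm = TRUE)
    survival_results <- list()
    for (a in stage3_arms) {
      ids <- c(alloc_ids[arm_of == match(a, labels)], cont_ids[[a]])
      sv <- survival_table(participants_df(ids), cut_date = survival_date)
      sres <- km_logrank_cox(sv, arms = c(control, a))
      survival_results[[a]] <- sres
      s3 <- Filter(function(d) d$arm == a && d$stage == "3", decisions)[[1L]]
      decisions[[length(decisions) + 1L]] <-
        survival_gatekeeper(s3, sres, alpha = config$alpha_survival)
    }
  }

  # --- CONSORT-style accounting -----------------------------------------
  randomised <- n_alloc
  arm_fac <- factor(labels[arm_of], levels = labels)
  long_surv <- tapply(pool$ls[alloc_ids], arm_fac, sum, default = 0L)
  dropped_out <- tapply(
    pool$dropw[alloc_ids] < pmin(18, all_parts$death_time),
    arm_fac, sum, default = 0L)
  dec_df <- do.call(rbind, lapply(decisions, function(d) {
    stat <- if (!is.null(d$basis$p_one_sided)) d$basis$p_one_sided
      else if (!is.null(d$basis$rr_ci)) d$basis$rr_ci[2L] else NA_real_
    thr <- if (!is.null(d$basis$alpha)) d$basis$alpha
      else if (!is.null(d$basis$margin)) d$basis$margin else NA_real_
    data.frame(arm = d$arm, stage = d$stage, decision = d$decision,
               statistic = stat, threshold = thr, stringsAsFactors = FALSE)
  }))

  last_dates <- c(trigger_dates[!is.na(trigger_dates)], survival_date)
  duration <- if (any(!is.na(last_dates))) max(last_dates, na.rm = TRUE)
    else NA_real_

  structure(list(
    decisions = dec_df,
    decision_objects = decisions,
    contrasts = contrasts_log,
    survival_results = survival_results,
    counts = data.frame(arm = labels,
                        randomised = as.integer(randomised),
                        long_survivors = as.integer(long_surv),
                        dropouts = as.integer(dropped_out),
                        stringsAsFactors = FALSE),
    n_analysed = n_analysed,
    trigger_dates = trigger_dates,
    survival_date = survival_date,
    placebo_deaths_trigger = trig,
    total_randomised = length(alloc_ids),
    duration = duration,
    all_dropped = length(stage3_arms) == 0L,
    seed = seed,
    config = config,
    participants = if (keep_data) all_parts else NULL,
    visits = if (keep_data) do.call(rbind, visits) else NULL,
    cont_ids = if (keep_data) cont_ids else NULL,
    allocation_log = if (keep_data) do.call(rbind, alloc_log) else NULL
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Virtual MAMS trial\n")
  cat(sprintf("  total randomised: %d; duration %.1f months\n",
              x$total_randomised, x$duration))
  print(x$counts, row.names = FALSE)
  cat("  decisions:\n")
  print(x$decisions, row.names = FALSE)
  if (x$all_dropped) {
    cat("  all active arms dropped before stage 3;",
        "survival summarised descriptively only\n")
  }
  invisible(x)
}

#' Write the minimisation allocation log to CSV
#'
#' Audit trail of every allocation: the imbalance score of each arm at
#' the moment of allocation (`NA` for arms closed to allocation), the
#' chosen arm, and whether the random element followed the minimiser.
#' Available from trials run with `keep_data = TRUE`.
#'
#' @param trial a `trial_result` from [run_trial()] with `keep_data = TRUE`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_allocation_log_csv <- function(trial, path) {
  if (is.null(trial$allocation_log)) {
    stop("trial was run without keep_data = TRUE: no allocation log",
         call. = FALSE)
  }
  write_table_csv(trial$allocation_log, path)
}

#' Write per-trial decisions to CSV
#' @param trial a `trial_result`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_decisions_csv <- function(trial, path) {
  write_table_csv(trial$decisions, path)
}

#' Add a new experimental arm to a scenario
#'
#' Platform adaptation: appends an arm that opens at `start_month`. Its
#' comparisons use only contemporaneous controls (control participants
#' randomised while the new arm is open) and its stage thresholds count
#' from its own accrual. No multiplicity adjustment is made across
#' distinct treatments.
#'
#' @param config a validated [scenario_config()].
#' @param label new arm label (must not duplicate an existing label).
#' @param relative_reduction true relative reduction for the new arm.
#' @param hazard_ratio true hazard ratio for the new arm.
#' @param start_month calendar month the arm opens.
#' @param alloc_weight allocation weight (default 1).
#' @return The updated `scenario_config`.
#' @export
add_arm <- function(config, label, relative_reduction = 0,
                    hazard_ratio = 1, start_month = 0, alloc_weight = 1) {
  validate_scenario_config(config)
  if (label %in% config$arm_labels) {
    stop("duplicate arm label: ", label, call. = FALSE)
  }
  config$n_arms <- config$n_arms + 1L
  config$arm_labels <- c(config$arm_labels, label)
  config$alloc_ratio <- c(config$alloc_ratio, alloc_weight)
  config$relative_reduction <- c(config$relative_reduction,
                                 relative_reduction)
  config$hazard_ratio <- c(config$hazard_ratio, hazard_ratio)
  config$arm_start_month <- c(config$arm_start_month, start_month)
  validate_scenario_config(config)
  config
}

#' Monte Carlo operating characteristics
#'
#' Estimates the design's operating characteristics by independent
#' replicates of [run_trial()]: per-arm probabilities of passing stage 1,
#' passing stage 2, stage-3 significance and gatekept survival
#' significance, with binomial Monte Carlo standard errors, plus expected
#' total sample size and expected trial duration. Per-replicate seeds are
#' derived from the master seed with [derive_rep_seeds()], so any
#' replicate can be reproduced in isolation.
#'
#' @param config a validated [scenario_config()].
#' @param reps number of replicates (>= 100 for meaningful estimates; a
#'   lower value is allowed but warns).
#' @param seed master integer seed.
#' @return A list of class `operating_characteristics`: `per_arm` (data
#'   frame of probabilities and SEs), `expected_n`, `expected_duration`,
#'   `reps`, `seed`, `config`, and the per-replicate decision table
#'   `replicates`.
#' @export
estimate_oc <- function(config, reps = 1000L, seed = 1L) {
  validate_scenario_config(config)
  reps <- as.integer(reps)
  if (reps < 100L) {
    warning("fewer than 100 replicates: Monte Carlo error will be large",
            call. = FALSE)
  }
  seeds <- derive_rep_seeds(seed, reps)
  active <- config$arm_labels[-1L]
  res <- matrix(FALSE, nrow = reps, ncol = 4L * length(active),
                dimnames = list(NULL, paste0(
                  rep(active, each = 4L),
                  c(".pass1", ".pass2", ".sig3", ".sig_survival"))))
  total_n <- numeric(reps)
  duration <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- run_trial(config, seed = seeds[r])
    d <- tr$decisions
    for (a in active) {
      res[r, paste0(a, ".pass1")] <-
        any(d$arm == a & d$stage == "1" & d$decision == "continue")
      res[r, paste0(a, ".pass2")] <-
        any(d$arm == a & d$stage == "2" & d$decision == "continue")
      res[r, paste0(a, ".sig3")] <-
        any(d$arm == a & d$stage == "3" & d$decision == "significant")
      res[r, paste0(a, ".sig_survival")] <-
        any(d$arm == a & d$stage == "survival" &
              d$decision == "significant")
    }
    total_n[r] <- tr$total_randomised
    duration[r] <- tr$duration
  }
  p <- colMeans(res)
  per_arm <- data.frame(
    arm = rep(active, each = 4L),
    quantity = rep(c("pass_stage1", "pass_stage2", "stage3_significant",
                     "survival_significant"), length(active)),
    probability = unname(p),
    mc_se = unname(sqrt(p * (1 - p) / reps)),
    stringsAsFactors = FALSE
  )
  structure(list(per_arm = per_arm,
                 expected_n = mean(total_n),
                 expected_duration = mean(duration, na.rm = TRUE),
                 reps = reps, seed = seed,
                 replicates = as.data.frame(res),
                 config = config),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics (%d replicates, seed %s)\n",
              x$reps, format(x$seed)))
  df <- x$per_arm
  df$probability <- sprintf("%.3f", df$probability)
  df$mc_se <- sprintf("%.4f", df$mc_se)
  print(df, row.names = FALSE)
  cat(sprintf("  expected randomised N: %.1f\n", x$expected_n))
  cat(sprintf("  expected duration: %.1f months\n", x$expected_duration))
  invisible(x)
}

#' Write operating characteristics to CSV
#' @param oc an `operating_characteristics` object.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_oc_csv <- function(oc, path) {
  write_table_csv(oc$per_arm, path)
}
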