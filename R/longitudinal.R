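#' Relative reduction in the rate of decline
#'
#' Expresses a treatment-minus-placebo slope difference as a fraction of
#' the placebo decline: `delta / |placebo_slope|`. The scale is only
#' defined when the control arm is estimated to decline; a non-negative
#' placebo slope estimate is flagged and `NA` returned (downstream stage
#' rules treat the undefined scale conservatively, as continue).
#'
#' @param delta treatment-minus-placebo slope difference, points/month
#'   (positive = benefit, since the placebo slope is negative).
#' @param placebo_slope_estimate estimated control-arm slope, points/month.
#' @return The relative reduction (positive = benefit), or `NA` if the
#'   control arm is not declining.
#' @examples
#' relative_reduction(0.25, -1.0)  # 0.25
#' @export
relative_reduction <- function(delta, placebo_slope_estimate) {
  if (is.na(placebo_slope_estimate) || placebo_slope_estimate >= 0) {
    warning("non-declining control: placebo slope estimate is non-negative; ",
            "relative-reduction scale undefined", call. = FALSE)
    return(NA_real_)
  }
  delta / abs(placebo_slope_estimate)
}

#' Construct a slope contrast
#'
#' A treatment-versus-placebo contrast on the ALSFRS-R slope: the slope
#' difference with its Wald 95% CI, the corresponding relative reduction in
#' the rate of decline (CI obtained by dividing the delta CI endpoints by
#' the magnitude of the estimated placebo slope), and the one-sided p-value
#' in the benefit direction.
#'
#' @param arm active-arm label.
#' @param delta slope difference, treatment minus placebo (points/month).
#' @param se standard error of `delta`.
#' @param placebo_slope estimated placebo slope (points/month).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return A list of class `slope_contrast` with fields `arm`, `delta`,
#'   `se`, `ci95_low`, `ci95_high`, `relative_reduction`, `rr_low`,
#'   `rr_high`, `p_one_sided`, `placebo_slope`, `nondeclining_control`.
#' @export
slope_contrast <- function(arm, delta, se, placebo_slope,
                           conf_level = 0.95) {
  stopifnot(se > 0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  lo <- delta - z * se
  hi <- delta + z * se
  nondecl <- is.na(placebo_slope) || placebo_slope >= 0
  if (nondecl) {
    rr <- rr_lo <- rr_hi <- NA_real_
  } else {
    denom <- abs(placebo_slope)
    rr <- delta / denom
    rr_lo <- lo / denom
    rr_hi <- hi / denom
  }
  structure(list(
    arm = arm, delta = delta, se = se,
    ci95_low = lo, ci95_high = hi,
    relative_reduction = rr, rr_low = rr_lo, rr_high = rr_hi,
    p_one_sided = pnorm(delta / se, lower.tail = FALSE),
    placebo_slope = placebo_slope,
    nondeclining_control = nondecl
  ), class = "slope_contrast")
}

#' @export
print.slope_contrast <- function(x, ...) {
  cat(sprintf("Slope contrast %s vs control\n", x$arm))
  cat(sprintf("  delta %.4f (SE %.4f), 95%% CI (%.4f, %.4f) pts/month\n",
              x$delta, x$se, x$ci95_low, x$ci95_high))
  if (!x$nondeclining_control) {
    cat(sprintf("  relative reduction %.1f%% (95%% CI %.1f%%, %.1f%%)\n",
                100 * x$relative_reduction, 100 * x$rr_low, 100 * x$rr_high))
  } else {
    cat("  relative reduction undefined (control not declining)\n")
  }
  cat(sprintf("  one-sided p (benefit) = %.4g\n", x$p_one_sided))
  invisible(x)
}

#' Per-participant OLS slopes
#'
#' Ordinary least-squares slope of score on time for each participant;
#' participants with fewer than two distinct assessment times get `NA`.
#'
#' @param id participant identifier vector.
#' @param time assessment times (months).
#' @param score ALSFRS-R scores.
#' @return A data frame `id`, `slope`, `n_obs`.
#' @export
per_subject_slopes <- function(id, time, score) {
  f <- factor(id)
  ones <- rep(1, length(time))
  n <- rowsum(ones, f)
  st <- rowsum(time, f)
  sy <- rowsum(score, f)
  stt <- rowsum(time * time, f)
  sty <- rowsum(time * score, f)
  den <- stt - st * st / n
  slope <- ifelse(den > 1e-10, (sty - st * sy / n) / den, NA_real_)
  data.frame(id = rownames(n), slope = as.numeric(slope),
             n_obs = as.integer(n), stringsAsFactors = FALSE)
}

#' Fit the ALSFRS-R decline model and extract slope contrasts
#'
#' Compares the rate of ALSFRS-R decline in each active arm with the
#' control arm. Two estimation routes are provided:
#'
#' * `"reml"` - the hierarchical normal linear model: per-arm fixed
#'   intercepts and slopes (arm main effect plus arm-by-time interaction),
#'   baseline minimisation covariate main effects (riluzole,
#'   NIV/gastrostomy), and correlated per-participant random intercepts
#'   and slopes, fitted by REML with [lme4::lmer()]. The arm-by-time
#'   coefficient is the slope contrast.
#' * `"twostage"` - per-participant OLS slopes regressed on arm (and the
#'   same covariates). On balanced complete data this reproduces the
#'   mixed-model contrast exactly, and it is fast enough for large Monte
#'   Carlo runs.
#'
#' The analysis set excludes participants who were long survivors at
#' baseline and requires at least one recorded score. Wald 95% CIs use a
#' Normal reference. The relative-reduction CI divides the delta CI
#' endpoints by the magnitude of the estimated control slope.
#'
#' @param visits long-format visit table: `participant_id`, `time` (or
#'   `visit_month`), `alsfrs_r`.
#' @param participants participant table: `id`, `arm`, `riluzole`,
#'   `niv_gastrostomy`, `long_survivor`.
#' @param arms arms in the comparison, control first (default: control
#'   `"placebo"` if present, else first seen, plus all other arms).
#' @param method `"twostage"` or `"reml"`.
#' @param covariate_adjust adjust for the baseline minimisation covariates
#'   (default `TRUE`).
#' @param exclude_long_survivors drop baseline long survivors from the
#'   analysis set (default `TRUE`, the primary-analysis convention).
#' @return A list of class `slope_contrasts`: one [slope_contrast()] per
#'   active arm, plus attributes `placebo_slope`, `method`, `n_analysed`.
#' @export
fit_slope_model <- function(visits, participants, arms = NULL,
                            method = c("twostage", "reml"),
                            covariate_adjust = TRUE,
                            exclude_long_survivors = TRUE) {
  method <- match.arg(method)
  if (is.null(arms)) {
    seen <- unique(participants$arm)
    seen <- seen[!is.na(seen)]
    control <- if ("placebo" %in% seen) "placebo" else seen[1L]
    arms <- c(control, setdiff(seen, control))
  }
  if (length(arms) < 2L) stop("need a control and at least one active arm",
                              call. = FALSE)
  control <- arms[1L]

  keep <- participants$arm %in% arms
  if (exclude_long_survivors) keep <- keep & participants$long_survivor == 0L
  p <- participants[keep, , drop = FALSE]
  tcol <- if ("time" %in% names(visits)) "time" else "visit_month"
  v <- visits[visits$participant_id %in% p$id, , drop = FALSE]
  # at least one recorded score
  p <- p[p$id %in% v$participant_id, , drop = FALSE]
  v <- v[v$participant_id %in% p$id, , drop = FALSE]
  if (nrow(v) == 0L) stop("empty analysis set", call. = FALSE)
  if (length(unique(v[[tcol]])) < 2L) {
    stop("singular design: fewer than 2 distinct assessment times",
         call. = FALSE)
  }

  if (method == "twostage") {
    res <- fit_slope_twostage(v, p, arms, tcol, covariate_adjust)
  } else {
    res <- fit_slope_reml(v, p, arms, tcol, covariate_adjust)
  }
  contrasts <- lapply(arms[-1L], function(a) {
    slope_contrast(a, res$delta[[a]], res$se[[a]], res$placebo_slope)
  })
  names(contrasts) <- arms[-1L]
  structure(contrasts, class = "slope_contrasts",
            placebo_slope = res$placebo_slope, method = method,
            n_analysed = nrow(p), control = control)
}

fit_slope_twostage <- function(v, p, arms, tcol, covariate_adjust) {
  sl <- per_subject_slopes(v$participant_id, v[[tcol]], v$alsfrs_r)
  sl <- sl[!is.na(sl$slope), , drop = FALSE]
  dat <- merge(sl, p, by.x = "id", by.y = "id", sort = FALSE)
  dat$arm <- factor(dat$arm, levels = arms)
  if (any(table(dat$arm) < 2L)) {
    stop("singular design: an arm has fewer than 2 participants with ",
         "estimable slopes", call. = FALSE)
  }
  form <- if (covariate_adjust) {
    slope ~ arm + riluzole + niv_gastrostomy
  } else {
    slope ~ arm
  }
  fit <- lm(form, data = dat)
  cf <- coef(fit)
  se_all <- sqrt(diag(vcov(fit)))
  nm <- paste0("arm", arms[-1L])
  delta <- as.list(setNames(cf[nm], arms[-1L]))
  se <- as.list(setNames(se_all[nm], arms[-1L]))
  list(delta = delta, se = se,
       placebo_slope = mean(dat$slope[dat$arm == arms[1L]]))
}

fit_slope_reml <- function(v, p, arms, tcol, covariate_adjust) {
  dat <- merge(v, p, by.x = "participant_id", by.y = "id", sort = FALSE)
  dat$arm <- factor(dat$arm, levels = arms)
  dat$t <- dat[[tcol]]
  form <- if (covariate_adjust) {
    alsfrs_r ~ t * arm + riluzole + niv_gastrostomy +
      (t | participant_id)
  } else {
    alsfrs_r ~ t * arm + (t | participant_id)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- tryCatch(
    lme4::lmer(form, data = dat, REML = TRUE, control = ctrl),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(fit)) {
    # fall back to independent random effects on non-convergence
    warning("unstructured random-effects fit did not converge; ",
            "falling back to independent random intercept and slope",
            call. = FALSE)
    form2 <- if (covariate_adjust) {
      alsfrs_r ~ t * arm + riluzole + niv_gastrostomy +
        (1 | participant_id) + (0 + t | participant_id)
    } else {
      alsfrs_r ~ t * arm + (1 | participant_id) + (0 + t | participant_id)
    }
    fit <- lme4::lmer(form2, data = dat, REML = TRUE, control = ctrl)
  }
  cf <- lme4::fixef(fit)
  se_all <- sqrt(diag(as.matrix(vcov(fit))))
  nm <- paste0("t:arm", arms[-1L])
  delta <- as.list(setNames(cf[nm], arms[-1L]))
  se <- as.list(setNames(se_all[nm], arms[-1L]))
  list(delta = delta, se = se, placebo_slope = unname(cf[["t"]]))
}

#' @export
print.slope_contrasts <- function(x, ...) {
  cat(sprintf("ALSFRS-R slope contrasts (%s fit, %d participants analysed)\n",
              attr(x, "method"), attr(x, "n_analysed")))
  cat(sprintf("  control slope estimate: %.4f pts/month\n",
              attr(x, "placebo_slope")))
  for (cc in x) print(cc)
  invisible(x)
}

#' @export
as.data.frame.slope_contrasts <- function(x, ...) {
  do.call(rbind, lapply(x, function(cc) {
    data.frame(arm = cc$arm, delta = cc$delta, se = cc$se,
               ci95_low = cc$ci95_low, ci95_high = cc$ci95_high,
               relative_reduction = cc$relative_reduction,
               rr_low = cc$rr_low, rr_high = cc$rr_high,
               p_one_sided = cc$p_one_sided,
               placebo_slope = cc$placebo_slope,
               stringsAsFactors = FALSE)
  }))
}

#' Write slope contrasts to CSV
#' @param contrasts a `slope_contrasts` object.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_contrasts_csv <- function(contrasts, path) {
  write_table_csv(as.data.frame(contrasts), path)
}
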