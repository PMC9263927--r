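#' Stage decisions
#'
#' Constructor for the outcome of one interim gate or test: the stage, the
#' arm, the decision, and the basis statistic used. Decisions are pure
#' functions of their input contrast or survival result.
#'
#' @param stage one of `"1"`, `"2"`, `"3"`, `"survival"`.
#' @param arm arm label.
#' @param decision one of `"continue"`, `"drop"`, `"significant"`,
#'   `"not-significant"`, `"gated-out"`.
#' @param basis named list or vector of the statistic(s) the decision used.
#' @return A list of class `stage_decision`.
#' @export
stage_decision <- function(stage, arm, decision, basis = NULL) {
  stage <- as.character(stage)
  stopifnot(stage %in% c("1", "2", "3", "survival"),
            decision %in% c("continue", "drop", "significant",
                            "not-significant", "gated-out"))
  structure(list(stage = stage, arm = arm, decision = decision,
                 basis = basis), class = "stage_decision")
}

#' @export
print.stage_decision <- function(x, ...) {
  cat(sprintf("stage %s, arm %s: %s\n", x$stage, x$arm, x$decision))
  invisible(x)
}

#' Stage-1 continuation gate
#'
#' An experimental arm continues past the first interim analysis if the
#' 95% CI of its relative reduction in the rate of ALSFRS-R decline still
#' includes (or exceeds) a 25% relative improvement, i.e. the upper CI
#' bound is at least the margin. A CI of (-10%, 30%) continues; (-20%, 15%)
#' drops. If the control arm is not estimated to decline the relative
#' scale is undefined and the arm continues (an arm is never dropped on an
#' undefined statistic).
#'
#' @param contrast a [slope_contrast()].
#' @param margin required relative improvement (default 0.25).
#' @return A [stage_decision()] with decision `"continue"` or `"drop"`.
#' @export
stage1_gate <- function(contrast, margin = 0.25) {
  if (isTRUE(contrast$nondeclining_control) || is.na(contrast$rr_high)) {
    return(stage_decision("1", contrast$arm, "continue",
                          basis = list(rr_ci = c(NA_real_, NA_real_),
                                       margin = margin,
                                       nondeclining_control = TRUE)))
  }
  decision <- if (contrast$rr_high >= margin) "continue" else "drop"
  stage_decision("1", contrast$arm, decision,
                 basis = list(rr_ci = c(contrast$rr_low, contrast$rr_high),
                              margin = margin))
}

#' Stage-2 continuation gate
#'
#' Continues an arm if the slope benefit over placebo is significant at
#' the pairwise one-sided 10% level (equivalently two-sided 20%), in the
#' benefit direction, with strict inequality at the boundary.
#'
#' @param contrast a [slope_contrast()].
#' @param alpha one-sided level (default 0.10).
#' @return A [stage_decision()] with decision `"continue"` or `"drop"`.
#' @export
stage2_gate <- function(contrast, alpha = 0.10) {
  decision <- if (contrast$p_one_sided < alpha) "continue" else "drop"
  stage_decision("2", contrast$arm, decision,
                 basis = list(p_one_sided = contrast$p_one_sided,
                              alpha = alpha))
}

#' Stage-3 (final ALSFRS-R) significance test
#'
#' The primary pairwise comparison, tested one-sided at 2.5% in the
#' benefit direction, with strict inequality at the boundary.
#'
#' @param contrast a [slope_contrast()].
#' @param alpha one-sided level (default 0.025).
#' @return A [stage_decision()] with decision `"significant"` or
#'   `"not-significant"`.
#' @export
stage3_test <- function(contrast, alpha = 0.025) {
  decision <- if (contrast$p_one_sided < alpha) "significant" else
    "not-significant"
  stage_decision("3", contrast$arm, decision,
                 basis = list(p_one_sided = contrast$p_one_sided,
                              alpha = alpha))
}

#' Gatekept survival test
#'
#' Survival is analysed inferentially for an arm only if that arm showed a
#' statistically significant ALSFRS-R benefit at stage 3; otherwise the
#' survival comparison is gated out (summarised descriptively only). This
#' hierarchy keeps the pairwise one-sided error at 2.5%.
#'
#' @param stage3 the arm's stage-3 [stage_decision()].
#' @param surv_result the arm's [km_logrank_cox()] result (may be `NULL`
#'   when gated out).
#' @param alpha one-sided level for the survival test (default 0.025).
#' @param use one-sided p to use: `"logrank"` (default) or `"cox"`.
#' @return A [stage_decision()] with decision `"significant"`,
#'   `"not-significant"` or `"gated-out"`.
#' @export
survival_gatekeeper <- function(stage3, surv_result = NULL, alpha = 0.025,
                                use = c("logrank", "cox")) {
  use <- match.arg(use)
  if (stage3$decision != "significant") {
    return(stage_decision("survival", stage3$arm, "gated-out",
                          basis = list(stage3 = stage3$decision)))
  }
  if (is.null(surv_result) || !isTRUE(surv_result$tests_defined)) {
    return(stage_decision("survival", stage3$arm, "not-significant",
                          basis = list(tests_defined = FALSE)))
  }
  p <- if (use == "logrank") surv_result$logrank_p_one_sided else
    surv_result$cox_p_one_sided
  decision <- if (p < alpha) "significant" else "not-significant"
  stage_decision("survival", stage3$arm, decision,
                 basis = list(p_one_sided = p, alpha = alpha, test = use))
}
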