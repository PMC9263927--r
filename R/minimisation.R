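#' Create an empty minimisation state
#'
#' State for Pocock-Simon minimisation over the three binary baseline
#' variables (riluzole use, NIV/gastrostomy use, long survival): per-arm
#' allocation counts at each covariate level, per-arm totals, and the set
#' of arms open to allocation.
#'
#' @param arm_labels arm labels; the first is the control arm.
#' @param alloc_ratio positive per-arm allocation weights (counts are
#'   divided by these weights when scoring imbalance).
#' @return A list of class `minimisation_state`.
#' @export
minimisation_state <- function(arm_labels, alloc_ratio = NULL) {
  k <- length(arm_labels)
  if (k < 2L) stop("need at least 2 arms", call. = FALSE)
  if (is.null(alloc_ratio)) alloc_ratio <- rep(1, k)
  if (length(alloc_ratio) != k || any(alloc_ratio <= 0)) {
    stop("alloc_ratio must be positive and match the number of arms",
         call. = FALSE)
  }
  counts <- matrix(0L, nrow = k, ncol = 6L,
                   dimnames = list(arm_labels,
                                   c("riluzole0", "riluzole1",
                                     "niv_gastrostomy0", "niv_gastrostomy1",
                                     "long_survivor0", "long_survivor1")))
  structure(list(labels = arm_labels,
                 ratio = as.numeric(alloc_ratio),
                 counts = counts,
                 totals = setNames(integer(k), arm_labels),
                 open = setNames(rep(TRUE, k), arm_labels)),
            class = "minimisation_state")
}

#' Close an arm to new allocation
#' @param state a `minimisation_state`.
#' @param label arm label to close.
#' @return The updated state.
#' @export
close_arm <- function(state, label) {
  if (!label %in% state$labels) stop("unknown arm: ", label, call. = FALSE)
  state$open[label] <- FALSE
  state
}

#' Open (or re-open) an arm to allocation
#' @inheritParams close_arm
#' @return The updated state.
#' @export
open_arm <- function(state, label) {
  if (!label %in% state$labels) stop("unknown arm: ", label, call. = FALSE)
  state$open[label] <- TRUE
  state
}

#' Allocate one participant by minimisation with a random element
#'
#' Pocock-Simon range method with equal variable weights. For each open
#' candidate arm the imbalance score is the sum, over the participant's
#' three covariate levels, of the range (max minus min across open arms)
#' of the ratio-adjusted allocation counts after a hypothetical allocation
#' to that arm. The score-minimising arm is chosen with probability
#' `minimisation_prob`; otherwise one of the remaining open arms is chosen
#' uniformly (the random element that keeps the sequence unpredictable).
#' Ties among minimisers are broken uniformly at random.
#'
#' @param covariates length-3 0/1 vector: riluzole, NIV/gastrostomy,
#'   long-survivor status.
#' @param state a `minimisation_state`.
#' @param minimisation_prob probability of following the minimising arm.
#' @return A list: `arm` (label), `arm_index`, updated `state`, the
#'   per-open-arm imbalance `scores`, and `followed_minimiser`.
#' @export
allocate_minimised <- function(covariates, state, minimisation_prob = 0.8) {
  open_idx <- unname(which(state$open))
  if (length(open_idx) == 0L) {
    stop("trial closed: no arms open to allocation", call. = FALSE)
  }
  cols <- c(1L, 3L, 5L) + as.integer(covariates)
  if (length(open_idx) == 1L) {
    pick <- open_idx
    scores <- setNames(0, state$labels[open_idx])
    followed <- TRUE
  } else {
    cnt <- state$counts[open_idx, cols, drop = FALSE] / state$ratio[open_idx]
    inc <- 1 / state$ratio[open_idx]
    m <- length(open_idx)
    scores <- numeric(m)
    for (a in seq_len(m)) {
      s <- 0
      for (v in 1:3) {
        col <- cnt[, v]
        col[a] <- col[a] + inc[a]
        s <- s + (max(col) - min(col))
      }
      scores[a] <- s
    }
    minimisers <- which(scores == min(scores))
    others <- setdiff(seq_len(m), minimisers)
    followed <- length(others) == 0L || runif(1) < minimisation_prob
    pool <- if (followed) minimisers else others
    pick <- open_idx[pool[sample.int(length(pool), 1L)]]
    names(scores) <- state$labels[open_idx]
  }
  state$counts[pick, cols] <- state$counts[pick, cols] + 1L
  state$totals[pick] <- state$totals[pick] + 1L
  list(arm = state$labels[pick], arm_index = pick, state = state,
       scores = scores, followed_minimiser = followed)
}

#' Marginal covariate imbalance of an allocation
#'
#' Sum over covariate levels of the range (max minus min across arms) of
#' allocation counts: the quantity minimisation keeps small.
#'
#' @param arms character vector of assigned arm labels.
#' @param covariates matrix or data frame of 0/1 covariates (one column per
#'   minimisation variable).
#' @param arm_labels all arm labels (so empty arms count as zero).
#' @return Total imbalance (numeric scalar).
#' @export
marginal_imbalance <- function(arms, covariates, arm_labels = unique(arms)) {
  covariates <- as.matrix(covariates)
  total <- 0
  arms <- factor(arms, levels = arm_labels)
  for (j in seq_len(ncol(covariates))) {
    for (lev in c(0L, 1L)) {
      cnt <- table(arms[covariates[, j] == lev])
      total <- total + (max(cnt) - min(cnt))
    }
  }
  total
}
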