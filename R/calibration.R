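# Assay calibration against control standards: sensitivity/specificity with
# exact binomial intervals, and OddsPath mapping assay performance to
# ACMG/AMP evidence strength per the ClinGen SVI functional-evidence
# recommendation.

#' Control-standard set
#'
#' @param variant_id Character vector of control ids.
#' @param truth `"pathogenic"` or `"benign"` per control.
#' @param held_out Logical; TRUE for controls not used in the original
#'   threshold identification.
#' @return data.frame with the three columns; counts are validated.
#' @export
control_set <- function(variant_id, truth, held_out = FALSE) {
  stopifnot(length(variant_id) == length(truth),
            all(truth %in% c("pathogenic", "benign")))
  data.frame(variant_id = variant_id, truth = truth,
             held_out = rep_len(held_out, length(variant_id)),
             stringsAsFactors = FALSE)
}

# Resolve a per-variant call for every control; errors name missing ones.
control_calls <- function(controls, calls) {
  if (is.data.frame(calls)) {
    calls <- stats::setNames(calls$call, calls$variant_id)
  }
  missing <- setdiff(controls$variant_id, names(calls))
  if (length(missing) > 0) {
    stop("controls without a functional call: ", paste(missing, collapse = ", "))
  }
  unname(calls[controls$variant_id])
}

#' Confusion counts of functional calls on control standards
#'
#' An abnormal readout (NonFunctional) on a pathogenic control is a true
#' positive; a normal readout (Functional) on a benign control a true
#' negative. Indeterminate calls are counted separately and excluded from
#' the sensitivity/specificity denominators.
#'
#' @param calls Named character vector (or data.frame with `variant_id`,
#'   `call`) of calls from [classify_function()].
#' @param controls data.frame from [control_set()].
#' @return List with `TP`, `FN`, `TN`, `FP`, `n_indeterminate`, and the ids
#'   of misclassified controls.
#' @export
confusion_counts <- function(calls, controls) {
  cl <- control_calls(controls, calls)
  path <- controls$truth == "pathogenic"
  indet <- cl == "Indeterminate"
  list(
    TP = sum(path & cl == "NonFunctional"),
    FN = sum(path & cl == "Functional"),
    TN = sum(!path & cl == "Functional"),
    FP = sum(!path & cl == "NonFunctional"),
    n_indeterminate = sum(indet),
    misclassified = controls$variant_id[!indet &
      ((path & cl == "Functional") | (!path & cl == "NonFunctional"))]
  )
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Closed-form beta-quantile evaluation of the exact interval; by convention
#' the lower bound is 0 at zero successes and the upper bound 1 at
#' `successes == trials`.
#'
#' @param successes,trials Non-negative integers, `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  stopifnot(length(successes) == 1, length(trials) == 1)
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials) stop("successes must be in 0..trials")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else stats::qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - a, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Evidence-strength map on the OddsPath scale
#'
#' Pathogenic cutoffs (strict `>`): 350 very strong, 18.7 strong, 4.3
#' moderate, 2.1 supporting; benign strengths use the reciprocal cutoffs.
#' Only the 18.7/strong bar is taken from the assay validation itself; the
#' remaining tiers follow the ClinGen SVI recommendation and are
#' configurable.
#'
#' @param pathogenic Named numeric vector of decreasing cutoffs.
#' @return List with `pathogenic` and reciprocal `benign` cutoffs.
#' @export
default_strength_map <- function(pathogenic = c(very_strong = 350, strong = 18.7,
                                                moderate = 4.3, supporting = 2.1)) {
  if (is.unsorted(rev(pathogenic), strictly = TRUE)) {
    stop("pathogenic cutoffs must be strictly decreasing")
  }
  list(pathogenic = pathogenic, benign = 1 / pathogenic)
}

#' Map an OddsPath value to an evidence strength
#'
#' Returns the highest tier whose cutoff is strictly exceeded (pathogenic
#' direction), or whose reciprocal cutoff is strictly undercut (benign
#' direction); values between the weakest cutoffs map to `"insufficient"`.
#'
#' @param oddspath Non-negative number.
#' @param map From [default_strength_map()].
#' @return List with `direction` (`"pathogenic"`, `"benign"` or `"none"`)
#'   and `strength`.
#' @export
oddspath_to_strength <- function(oddspath, map = default_strength_map()) {
  stopifnot(oddspath >= 0)
  hit <- which(oddspath > map$pathogenic)
  if (length(hit) > 0) {
    return(list(direction = "pathogenic", strength = names(map$pathogenic)[hit[1]]))
  }
  hit <- which(oddspath < sort(map$benign))
  if (length(hit) > 0) {
    return(list(direction = "benign", strength = names(sort(map$benign))[hit[1]]))
  }
  list(direction = "none", strength = "insufficient")
}

#' OddsPath from control-standard performance
#'
#' In the pathogenic direction, P1 is the prior proportion of pathogenic
#' variants among the (determinate) controls and P2 the proportion
#' pathogenic among controls with an abnormal (NonFunctional) readout.
#' Under perfect separation P2 would be 1, so the next-variant-misclassified
#' correction `P2 = TP / (TP + 1)` is applied; OddsPath is then
#' `P2 (1 - P1) / ((1 - P2) P1)`, which under perfect separation equals the
#' number of benign controls exactly. The benign direction mirrors the
#' computation on normal readouts.
#'
#' @param controls data.frame from [control_set()].
#' @param calls Calls as in [confusion_counts()].
#' @param direction `"pathogenic"` (PS3) or `"benign"` (BS3).
#' @param map Strength map for [oddspath_to_strength()].
#' @return List with `p1`, `p2`, `oddspath`, `direction`, `strength`,
#'   counts, and a `note` for degenerate cases.
#' @export
compute_oddspath <- function(controls, calls,
                             direction = c("pathogenic", "benign"),
                             map = default_strength_map()) {
  direction <- match.arg(direction)
  cc <- confusion_counts(calls, controls)
  n_path <- cc$TP + cc$FN
  n_ben <- cc$TN + cc$FP
  if (n_path + n_ben == 0) stop("no determinate control calls")
  if (direction == "pathogenic") {
    p1 <- n_path / (n_path + n_ben)
    hits <- cc$TP; misses <- cc$FP            # abnormal readouts
  } else {
    p1 <- n_ben / (n_path + n_ben)
    hits <- cc$TN; misses <- cc$FN            # normal readouts
  }
  if (hits + misses == 0) {
    stop("OddsPath undefined: no ", if (direction == "pathogenic") "abnormal"
         else "normal", " readouts among controls")
  }
  note <- NA_character_
  eff_misses <- misses
  if (misses == 0) {
    eff_misses <- 1            # next-variant-misclassified correction
    note <- "perfect separation: next-variant-misclassified correction applied"
  }
  p2 <- hits / (hits + eff_misses)
  if (p2 == 0) {
    return(list(p1 = p1, p2 = 0, oddspath = 0, direction = direction,
                strength = "insufficient", counts = cc,
                note = "P2 = 0: evidence points in the benign direction"))
  }
  # OddsPath = [P2 (1 - P1)] / [(1 - P2) P1]; evaluated as the equivalent
  # integer-count ratio so perfect separation yields the benign count
  # exactly (no floating-point drift through the proportions)
  n_same <- if (direction == "pathogenic") n_path else n_ben
  n_other <- if (direction == "pathogenic") n_ben else n_path
  oddspath <- (hits * n_other) / (eff_misses * n_same)
  list(p1 = p1, p2 = p2, oddspath = oddspath, direction = direction,
       strength = oddspath_to_strength(oddspath, map)$strength,
       counts = cc, note = note)
}

#' Full calibration report for a control run
#'
#' Confusion counts, sensitivity and specificity with exact 95% intervals,
#' and OddsPath (both directions) on the full set and on the held-out
#' subset.
#'
#' @param controls data.frame from [control_set()].
#' @param calls Calls as in [confusion_counts()].
#' @param level Confidence level for the exact intervals.
#' @param map Strength map.
#' @return Nested list, JSON-serializable.
#' @export
calibration_report <- function(controls, calls, level = 0.95,
                               map = default_strength_map()) {
  cc <- confusion_counts(calls, controls)
  sens_ci <- if (cc$TP + cc$FN > 0) exact_binomial_ci(cc$TP, cc$TP + cc$FN, level)
             else c(lower = NA_real_, upper = NA_real_)
  spec_ci <- if (cc$TN + cc$FP > 0) exact_binomial_ci(cc$TN, cc$TN + cc$FP, level)
             else c(lower = NA_real_, upper = NA_real_)
  held <- controls[controls$held_out, , drop = FALSE]
  list(
    counts = cc,
    sensitivity = list(
      estimate = if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_,
      ci = as.list(sens_ci)),
    specificity = list(
      estimate = if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA_real_,
      ci = as.list(spec_ci)),
    oddspath_full = compute_oddspath(controls, calls, "pathogenic", map),
    oddspath_full_benign = compute_oddspath(controls, calls, "benign", map),
    oddspath_held_out = if (nrow(held) > 0)
      compute_oddspath(held, calls, "pathogenic", map) else NULL
  )
}
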