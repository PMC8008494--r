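# ClinVar-style assertion mining and cross-assay concordance tabulation.
# Works on offline snapshot-style tables; no live queries.

tier_group <- function(tier) {
  ifelse(tier %in% c("LP", "P"), "LPP",
         ifelse(tier %in% c("LB", "B"), "LBB", "VUS"))
}

#' Filter an assertion table per the mining rules
#'
#' Keeps only submitters meeting the minimum data-sharing requirements, then
#' excludes variants where the collaborating laboratory is the sole
#' qualifying submitter or the sole classification outlier (its tier group
#' — LP/P vs VUS vs LB/B — is unrepresented among the other qualifying
#' submitters while all the others share one group). A lab tied with at
#' least one agreeing submitter is not an outlier.
#'
#' @param records data.frame with columns `variant_id`, `submitter_id`,
#'   `classification`, `meets_sharing_requirements`, `is_collaborating_lab`.
#' @return List with `retained` (records) and `excluded` (data.frame
#'   `variant_id`, `reason`).
#' @export
filter_assertions <- function(records) {
  needed <- c("variant_id", "submitter_id", "classification",
              "meets_sharing_requirements", "is_collaborating_lab")
  stopifnot(all(needed %in% names(records)))
  stopifnot(all(records$classification %in% classification_tiers()))
  excluded <- data.frame(variant_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  keep <- logical(nrow(records))
  for (vid in unique(records$variant_id)) {
    idx <- which(records$variant_id == vid)
    qual <- idx[records$meets_sharing_requirements[idx]]
    if (length(qual) == 0) {
      excluded <- rbind(excluded, data.frame(
        variant_id = vid, reason = "no qualifying submitter"))
      next
    }
    collab <- records$is_collaborating_lab[qual]
    if (all(collab)) {
      excluded <- rbind(excluded, data.frame(
        variant_id = vid, reason = "collaborating-lab sole submitter"))
      next
    }
    if (any(collab)) {
      grp <- tier_group(records$classification[qual])
      own <- unique(grp[collab])
      others <- grp[!collab]
      sole_outlier <- length(unique(others)) == 1 &&
        !any(own %in% others)
      if (sole_outlier) {
        excluded <- rbind(excluded, data.frame(
          variant_id = vid, reason = "collaborating-lab sole outlier"))
        next
      }
    }
    keep[qual] <- TRUE
  }
  list(retained = records[keep, , drop = FALSE], excluded = excluded)
}

#' Conflict status of one variant's retained assertions
#'
#' LP is grouped with P and LB with B. All assertions in one group gives
#' `no_conflict_<group>`; VUS mixed with exactly one non-VUS group gives
#' `conflicting_<group>`; LP/P mixed with LB/B is `opposing` (reported
#' distinctly so its absence can be verified).
#'
#' @param tiers Character vector of classification tiers (>= 1).
#' @return Status string.
#' @export
conflict_status <- function(tiers) {
  stopifnot(length(tiers) >= 1, all(tiers %in% classification_tiers()))
  groups <- unique(tier_group(tiers))
  if ("LPP" %in% groups && "LBB" %in% groups) return("opposing")
  if (length(groups) == 1) return(paste0("no_conflict_", groups))
  paste0("conflicting_", setdiff(groups, "VUS"))
}

#' Cross-tabulate assertion statuses against internal classifications
#'
#' @param statuses data.frame with `variant_id`, `status` (from
#'   [conflict_status()]).
#' @param internal_finals data.frame with `variant_id`, `tier`.
#' @return List with `counts` (final-class group in rows, status in
#'   columns), `proportions` (within-row, with the row totals as explicit
#'   denominators in `row_n`).
#' @export
concordance_table <- function(statuses, internal_finals) {
  if (nrow(statuses) == 0) {
    warning("empty concordance input")
    return(list(counts = table(character(0), character(0)),
                proportions = NULL, row_n = integer(0)))
  }
  mism <- union(setdiff(statuses$variant_id, internal_finals$variant_id),
                setdiff(internal_finals$variant_id, statuses$variant_id))
  if (length(mism) > 0) {
    stop("variants present in only one input: ", paste(mism, collapse = ", "))
  }
  mrg <- merge(statuses, internal_finals, by = "variant_id")
  counts <- table(final = tier_group(mrg$tier), status = mrg$status)
  row_n <- rowSums(counts)
  list(counts = unclass(counts),
       proportions = sweep(unclass(counts), 1, pmax(row_n, 1), "/"),
       row_n = row_n)
}

#' Cross-tabulate HDR calls against an external assay's classes
#'
#' @param calls data.frame with `variant_id`, `call`.
#' @param external_classes data.frame with `variant_id`, `class` (e.g.
#'   drug-sensitivity fClass 1-5 or a prior study's label).
#' @param discordant_when Function of (call, class) returning TRUE for a
#'   discordant pair. The default flags HDR-functional variants with a
#'   non-functional external class (fClass 4/5) and HDR-non-functional
#'   variants with a resistant class (fClass 1/2).
#' @return List with `table` (call x class contingency) and `discordant`
#'   (variant ids).
#' @export
external_assay_crosstab <- function(calls, external_classes,
                                    discordant_when = NULL) {
  mrg <- merge(calls, external_classes, by = "variant_id")
  if (is.null(discordant_when)) {
    discordant_when <- function(call, cls) {
      (call == "Functional" & cls %in% c("4", "5")) |
        (call == "NonFunctional" & cls %in% c("1", "2"))
    }
  }
  disc <- discordant_when(mrg$call, as.character(mrg$class))
  list(table = table(call = mrg$call, class = mrg$class),
       discordant = mrg$variant_id[disc])
}
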