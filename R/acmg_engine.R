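# Tailored ACMG/AMP evidence engine: derive PS3/BS3, PP3/BP4 and
# frequency codes from quantitative inputs, accept curated codes (PM1, PM5,
# PP1, PM3, BP2) with strength modifiers, and combine a code set into a
# five-tier classification.

STRENGTH_LEVELS <- c("supporting", "moderate", "strong", "very_strong",
                     "stand_alone")

# Base strength and direction follow the code prefix. BA1 is the only
# stand-alone code.
KNOWN_CODES <- c(PS3 = "strong", BS3 = "strong",
                 PM1 = "moderate", PM2 = "moderate", PM3 = "moderate",
                 PM5 = "moderate",
                 PP1 = "supporting", PP3 = "supporting",
                 BA1 = "stand_alone", BS1 = "strong",
                 BP2 = "supporting", BP4 = "supporting")

code_direction <- function(code_id) {
  ifelse(substr(code_id, 1, 1) == "P", "pathogenic", "benign")
}

# Strength-modifier suffixes as printed in curation tables.
SUFFIX_STRENGTH <- c(supp = "supporting", supporting = "supporting",
                     mod = "moderate", moderate = "moderate",
                     st = "strong", strong = "strong",
                     vst = "very_strong", very_strong = "very_strong")

#' Parse an evidence-code label with optional strength modifier
#'
#' Accepts labels like `"PS3"`, `"PM1_supp"`, `"PP1_moderate"`,
#' `"PM3_strong"`. Without a modifier the code's base strength applies.
#'
#' @param label Character vector of code labels.
#' @return data.frame with `code_id`, `direction`, `base_strength`,
#'   `applied_strength`.
#' @export
parse_evidence_code <- function(label) {
  stopifnot(is.character(label))
  parts <- regmatches(label, regexec("^([A-Z]{2}[0-9])(?:_([a-z_]+))?$", label))
  bad <- vapply(parts, length, 1L) == 0L |
    !vapply(parts, function(p) length(p) >= 2 && p[2] %in% names(KNOWN_CODES), TRUE)
  if (any(bad)) stop("unknown evidence code: ", paste(label[bad], collapse = ", "))
  code_id <- vapply(parts, `[[`, "", 2L)
  suffix <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "", "")
  applied <- unname(KNOWN_CODES[code_id])
  has_suffix <- nzchar(suffix)
  if (any(has_suffix & !(suffix %in% names(SUFFIX_STRENGTH)))) {
    stop("unknown strength modifier in: ",
         paste(label[has_suffix & !(suffix %in% names(SUFFIX_STRENGTH))],
               collapse = ", "))
  }
  applied[has_suffix] <- unname(SUFFIX_STRENGTH[suffix[has_suffix]])
  data.frame(code_id = code_id,
             direction = code_direction(code_id),
             base_strength = unname(KNOWN_CODES[code_id]),
             applied_strength = applied,
             stringsAsFactors = FALSE)
}

#' Build a validated evidence profile for one variant
#'
#' Enforces the profile invariants: no duplicate code ids, at most one of
#' PP3/BP4, at most one of BA1/BS1/PM2.
#'
#' @param variant_id Variant identifier.
#' @param codes Character vector of code labels (see
#'   [parse_evidence_code()]); empty for no evidence.
#' @param splice_impact_predicted TRUE when an in-silico splice effect is
#'   predicted; gates BS3 from supporting a benign classification.
#' @return List with `variant_id`, `codes` (parsed data.frame) and
#'   `splice_impact_predicted`.
#' @export
evidence_profile <- function(variant_id, codes = character(0),
                             splice_impact_predicted = FALSE) {
  parsed <- if (length(codes) > 0) parse_evidence_code(codes) else
    parse_evidence_code(character(0))[0, ]
  if (anyDuplicated(parsed$code_id)) {
    stop("duplicate evidence codes for ", variant_id, ": ",
         paste(parsed$code_id[duplicated(parsed$code_id)], collapse = ", "))
  }
  if (sum(parsed$code_id %in% c("PP3", "BP4")) > 1) {
    stop("profile for ", variant_id, " carries both PP3 and BP4")
  }
  if (sum(parsed$code_id %in% c("BA1", "BS1", "PM2")) > 1) {
    stop("profile for ", variant_id, " carries more than one frequency code")
  }
  list(variant_id = variant_id, codes = parsed,
       splice_impact_predicted = isTRUE(splice_impact_predicted))
}

#' In-silico score thresholds
#'
#' BayesDel gene-specific cutoffs: below 0.0560 tolerated (BP4), above
#' 0.431 deleterious (PP3), in between inconclusive. Non-SNV variants use
#' PROVEAN with deleterious below -6.
#'
#' @param bayesdel_benign,bayesdel_deleterious,provean_deleterious Cutoffs.
#' @return List of thresholds.
#' @export
insilico_thresholds <- function(bayesdel_benign = 0.0560,
                                bayesdel_deleterious = 0.431,
                                provean_deleterious = -6) {
  stopifnot(bayesdel_benign < bayesdel_deleterious)
  list(bayesdel_benign = bayesdel_benign,
       bayesdel_deleterious = bayesdel_deleterious,
       provean_deleterious = provean_deleterious)
}

#' Population-frequency thresholds (filtering allele frequency)
#'
#' BA1 at 0.1%, BS1 at 0.01%; PM2 (applied only as supporting) requires at
#' most one heterozygote, equivalent to < 0.001% at the maximum gnomAD
#' allele count of 282,912.
#'
#' @param ba1,bs1,pm2_supporting Frequency cutoffs (proportions).
#' @return List of thresholds.
#' @export
frequency_thresholds <- function(ba1 = 0.001, bs1 = 0.0001,
                                 pm2_supporting = 0.00001) {
  stopifnot(pm2_supporting < bs1, bs1 < ba1)
  list(ba1 = ba1, bs1 = bs1, pm2_supporting = pm2_supporting)
}

#' Derive the functional-evidence code from an assay call
#'
#' NonFunctional yields PS3 (strong); Functional yields BS3 (strong), but
#' when a splice impact is predicted the BS3 is marked gated: it is emitted
#' yet cannot contribute toward an LB/B classification, since the assay
#' cannot assess splicing. Indeterminate yields no code.
#'
#' @param call `"Functional"`, `"NonFunctional"` or `"Indeterminate"`.
#' @param splice_impact_predicted Logical.
#' @return List with `code_id`, `applied_strength`, `gated`, or NULL.
#' @export
assign_functional_code <- function(call, splice_impact_predicted = FALSE) {
  stopifnot(call %in% c("Functional", "NonFunctional", "Indeterminate"))
  if (call == "Indeterminate") return(NULL)
  if (call == "NonFunctional") {
    return(list(code_id = "PS3", applied_strength = "strong", gated = FALSE))
  }
  list(code_id = "BS3", applied_strength = "strong",
       gated = isTRUE(splice_impact_predicted))
}

#' Derive the in-silico code from a BayesDel or PROVEAN score
#'
#' Exactly one of the two scores must be supplied (PROVEAN only for
#' non-SNV variants). Comparisons are strict; between-cutoff scores are
#' inconclusive and contribute no code.
#'
#' @param bayesdel,provean Numeric score (supply one).
#' @param thresholds From [insilico_thresholds()].
#' @return `"PP3"`, `"BP4"` or `"inconclusive"`.
#' @export
assign_insilico_code <- function(bayesdel = NULL, provean = NULL,
                                 thresholds = insilico_thresholds()) {
  if (!is.null(bayesdel) && !is.null(provean)) {
    stop("supply exactly one of bayesdel or provean, not both")
  }
  if (!is.null(bayesdel)) {
    if (bayesdel > thresholds$bayesdel_deleterious) return("PP3")
    if (bayesdel < thresholds$bayesdel_benign) return("BP4")
    return("inconclusive")
  }
  if (!is.null(provean)) {
    if (provean < thresholds$provean_deleterious) return("PP3")
    return("inconclusive")
  }
  stop("supply exactly one of bayesdel or provean")
}

#' Derive the population-frequency code
#'
#' The filtering allele frequency (lower of genome/exome, selected
#' upstream) is checked against the BA1 then BS1 cutoffs; rarer variants
#' receive PM2_supporting when carried by at most one heterozygote.
#'
#' @param faf Filtering allele frequency in `[0, 1]`.
#' @param carrier_count Observed heterozygote count.
#' @param thresholds From [frequency_thresholds()].
#' @return `"BA1"`, `"BS1"`, `"PM2_supp"` or `"none"`.
#' @export
assign_frequency_code <- function(faf, carrier_count,
                                  thresholds = frequency_thresholds()) {
  if (faf < 0 || faf > 1 || carrier_count < 0) {
    stop("negative or out-of-range frequency inputs")
  }
  if (faf >= thresholds$ba1) return("BA1")
  if (faf >= thresholds$bs1) return("BS1")
  if (carrier_count <= 1) return("PM2_supp")
  "none"
}

#' Combiner configuration
#'
#' @param backend `"categorical"` (enumerated ACMG/AMP combining rules, the
#'   default) or `"points"` (signed point sum cross-check).
#' @param conflict_policy `"pathogenic_dominant"` (a P/LP result stands when
#'   the only benign evidence is a single supporting code) or `"strict_vus"`
#'   (any two-directional evidence yields VUS with a conflict flag).
#' @param svi_bs3_sufficient Recognize a single strong benign code (BS3) as
#'   sufficient for LB (default TRUE).
#' @param weights Points per strength for the points backend (benign codes
#'   count negative; stand-alone weighs as very strong).
#' @param cutoffs Tier bands for the points backend: P at or above `P`, LP
#'   from `LP` to `P - 1`, B at or below `B`, LB from `B + 1` to `LB`,
#'   VUS in between.
#' @return Config list.
#' @export
combiner_config <- function(backend = c("categorical", "points"),
                            conflict_policy = c("pathogenic_dominant", "strict_vus"),
                            svi_bs3_sufficient = TRUE,
                            weights = c(supporting = 1, moderate = 2,
                                        strong = 4, very_strong = 8,
                                        stand_alone = 8),
                            cutoffs = c(P = 10, LP = 6, LB = -1, B = -7)) {
  stopifnot(all(weights > 0), cutoffs["P"] > cutoffs["LP"],
            cutoffs["LB"] > cutoffs["B"])
  list(backend = match.arg(backend),
       conflict_policy = match.arg(conflict_policy),
       svi_bs3_sufficient = isTRUE(svi_bs3_sufficient),
       weights = weights, cutoffs = cutoffs)
}

# Strength tallies for one direction; gated BS3 rows are excluded upstream.
strength_tally <- function(codes) {
  tab <- table(factor(codes$applied_strength, levels = STRENGTH_LEVELS))
  as.list(tab)
}

# Enumerated pathogenic combining rules (five-tier framework).
pathogenic_tier <- function(t) {
  vs <- t$very_strong; st <- t$strong; mo <- t$moderate; su <- t$supporting
  p <- (vs >= 1 && (st >= 1 || mo >= 2 || (mo == 1 && su >= 1) || su >= 2)) ||
    st >= 2 ||
    (st == 1 && (mo >= 3 || (mo == 2 && su >= 2) || (mo == 1 && su >= 4)))
  if (p) return("P")
  lp <- (vs == 1 && mo == 1) ||
    (st == 1 && mo >= 1 && mo <= 2) ||
    (st == 1 && su >= 2) ||
    mo >= 3 || (mo == 2 && su >= 2) || (mo == 1 && su >= 4)
  if (lp) return("LP")
  "VUS"
}

# Benign combining rules, including the SVI modification that one strong
# benign code alone suffices for LB.
benign_tier <- function(t, svi_bs3_sufficient) {
  if (t$stand_alone >= 1) return("B")
  st <- t$strong; su <- t$supporting
  if (st >= 2) return("B")
  if ((st == 1 && su >= 1) || su >= 2) return("LB")
  if (st == 1 && svi_bs3_sufficient) return("LB")
  "VUS"
}

# Split a profile's parsed codes into contributing pathogenic / benign sets,
# removing a gated BS3 from the benign side.
split_codes <- function(profile) {
  codes <- profile$codes
  gated_bs3 <- profile$splice_impact_predicted & codes$code_id == "BS3"
  list(path = codes[codes$direction == "pathogenic", , drop = FALSE],
       benign = codes[codes$direction == "benign" & !gated_bs3, , drop = FALSE],
       any_benign = any(codes$direction == "benign"),
       any_path = any(codes$direction == "pathogenic"))
}

#' Combine an evidence profile into a five-tier classification
#'
#' The categorical backend applies the enumerated ACMG/AMP combining rules
#' to the applied strengths, with the two stated modifications (PM2 capped
#' at supporting happens upstream in the code assignment; one strong benign
#' code alone yields LB). When evidence fires in both directions the
#' conflict policy decides: `strict_vus` always returns VUS with the
#' conflict flag; `pathogenic_dominant` lets a decisive result on either
#' side stand when the opposing side totals no more than one supporting
#' code (a P/LP over a lone BP4, an LB/B over a lone PM2). A gated BS3 never
#' contributes toward LB/B. The points backend is available via
#' `config$backend` or directly through [combine_evidence_points()].
#'
#' @param profile From [evidence_profile()].
#' @param config From [combiner_config()].
#' @return List with `tier`, `conflict_flag`, `basis` (contributing code
#'   ids).
#' @export
combine_evidence <- function(profile, config = combiner_config()) {
  if (identical(config$backend, "points")) {
    return(combine_evidence_points(profile, config))
  }
  sp <- split_codes(profile)
  conflict <- sp$any_path && sp$any_benign
  pt <- pathogenic_tier(strength_tally(sp$path))
  bt <- benign_tier(strength_tally(sp$benign), config$svi_bs3_sufficient)
  basis <- c(sp$path$code_id, sp$benign$code_id)

  tier <- if (nrow(sp$benign) == 0 && !sp$any_benign) {
    pt
  } else if (!sp$any_path) {
    bt
  } else if (config$conflict_policy == "strict_vus") {
    "VUS"
  } else {
    # pathogenic_dominant: a decisive result on one side stands when the
    # opposing evidence totals no more than a single supporting code (e.g.
    # PS3-driven P over a lone BP4, or BS3-driven LB over a lone
    # PM2_supporting); anything stronger on both sides is a true conflict.
    benign_minor <- nrow(sp$benign) <= 1 &&
      all(sp$benign$applied_strength == "supporting")
    path_minor <- nrow(sp$path) <= 1 &&
      all(sp$path$applied_strength == "supporting")
    if (pt %in% c("P", "LP") && benign_minor) pt
    else if (bt %in% c("LB", "B") && path_minor) bt
    else "VUS"
  }
  # a gated BS3 with no other evidence leaves the variant unresolved
  if (tier %in% c("LB", "B") && nrow(sp$benign) == 0) tier <- "VUS"
  list(tier = tier, conflict_flag = conflict, basis = basis)
}

#' Points-backend evidence combination
#'
#' Signed point sum (supporting 1, moderate 2, strong 4, very strong 8;
#' benign negative; stand-alone as very strong) with tier cutoff bands.
#' A cross-check backend, not the primary one.
#'
#' @inheritParams combine_evidence
#' @return List with `tier`, `conflict_flag`, `basis`, `points`.
#' @export
combine_evidence_points <- function(profile, config = combiner_config(backend = "points")) {
  sp <- split_codes(profile)
  w <- config$weights
  pts <- sum(w[sp$path$applied_strength]) - sum(w[sp$benign$applied_strength])
  if (length(pts) == 0 || is.na(pts)) pts <- 0
  cut <- config$cutoffs
  tier <- if (pts >= cut["P"]) "P"
  else if (pts >= cut["LP"]) "LP"
  else if (pts <= cut["B"]) "B"
  else if (pts <= cut["LB"]) "LB"
  else "VUS"
  list(tier = tier, conflict_flag = sp$any_path && sp$any_benign,
       basis = c(sp$path$code_id, sp$benign$code_id), points = unname(pts))
}

#' Classify a batch of variants from an evidence table
#'
#' Convenience wrapper: builds a profile per row of a wide evidence table
#' (one column per code label, empty/"-"/"inc"/"none"/"N/A" meaning absent)
#' and combines it.
#'
#' @param evidence data.frame with a `variant_id` column, code columns, and
#'   optionally `splice_impact` (0/1).
#' @param code_columns Names of the columns holding code labels.
#' @param config From [combiner_config()].
#' @return data.frame with `variant_id`, `tier`, `conflict_flag`, `codes`.
#' @export
classify_evidence_table <- function(evidence,
                                    code_columns = setdiff(names(evidence),
                                      c("variant_id", "splice_impact")),
                                    config = combiner_config()) {
  absent <- c("", "-", "inc", "inconclusive", "none", "N/A", "N/O")
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    labs <- unlist(evidence[i, code_columns], use.names = FALSE)
    labs <- labs[!is.na(labs) & !(labs %in% absent)]
    prof <- evidence_profile(evidence$variant_id[i], labs,
                             splice_impact_predicted =
                               isTRUE(evidence$splice_impact[i] == 1))
    res <- combine_evidence(prof, config)
    data.frame(variant_id = evidence$variant_id[i], tier = res$tier,
               conflict_flag = res$conflict_flag,
               codes = paste(res$basis, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Before/after reclassification summary
#'
#' Builds the 5x5 transition matrix of classifications before and after the
#' functional evidence, the VUS-resolution rate, and the per-direction
#' counts of resolved VUSs.
#'
#' @param before,after Character vectors of tiers (equal length).
#' @return List with `matrix` (before in rows, after in columns),
#'   `n_vus_before`, `n_resolved`, `resolution_rate`, `to_lp_p`, `to_lb_b`.
#' @export
reclassification_summary <- function(before, after) {
  stopifnot(length(before) == length(after))
  tiers <- classification_tiers()
  stopifnot(all(before %in% tiers), all(after %in% tiers))
  m <- table(factor(before, levels = tiers), factor(after, levels = tiers))
  vus <- before == "VUS"
  resolved <- vus & after != "VUS"
  list(
    matrix = unclass(m),
    n_vus_before = sum(vus),
    n_resolved = sum(resolved),
    resolution_rate = if (sum(vus) > 0) sum(resolved) / sum(vus) else NA_real_,
    to_lp_p = sum(vus & after %in% c("LP", "P")),
    to_lb_b = sum(vus & after %in% c("LB", "B"))
  )
}
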