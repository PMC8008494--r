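# Seedable generators emulating the statistical structure the analysis
# assumes: lognormal replicate noise around true HDR scores anchored at 1
# (pathogenic control) and 5 (wild type), clone-level effects, control
# standard sets with known labels, evidence-code profiles, and
# multi-submitter assertion tables with conflicts.
#
# Every generator is a pure function of (config, seed): identical inputs
# give identical output. Stage-specific sub-seeds are derived from the
# master seed so the stages stay reproducible when run standalone.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 252 assayed variants of which 90
#' are truly non-functional; true scores at the anchor modes 1 and 5 with a
#' small lognormal spread; replicate noise and clone effects on the log
#' scale; four independently derived clones analyzed in duplicate (the
#' assay floor is two clones in duplicate); 20 pathogenic and 46 benign
#' control standards with 10/32 held out.
#'
#' @param seed Integer master seed (required).
#' @param n_variants Number of assayed variants.
#' @param n_nonfunctional Number with a true non-functional score.
#' @param score_nonfunctional,score_functional True-score modes.
#' @param true_score_sd Lognormal sd of true scores around their mode.
#' @param noise_sd Replicate noise sd on the log scale.
#' @param clone_sd Clone-effect sd on the log scale.
#' @param clones_per_variant,replicates_per_clone Assay design.
#' @param n_control_measurements Measurements per normalization anchor.
#' @param n_pathogenic,n_benign Control-standard counts.
#' @param n_pathogenic_heldout,n_benign_heldout Held-out subset sizes.
#' @param evidence_rates Named list of per-code generation rates.
#' @param submitters_per_variant Mean submitter count for assertion tables.
#' @param conflict_rate Probability a submitter deviates to VUS.
#' @return Validated config list.
#' @export
sim_config <- function(seed,
                       n_variants = 252L, n_nonfunctional = 90L,
                       score_nonfunctional = 1, score_functional = 5,
                       true_score_sd = 0.08,
                       noise_sd = 0.15, clone_sd = 0.05,
                       clones_per_variant = 4L, replicates_per_clone = 2L,
                       n_control_measurements = 24L,
                       n_pathogenic = 20L, n_benign = 46L,
                       n_pathogenic_heldout = 10L, n_benign_heldout = 32L,
                       evidence_rates = list(pp3 = 0.25, bp4 = 0.10,
                                             pm1 = 0.10, pm1_supp = 0.08,
                                             pm5 = 0.08, pp1 = 0.06,
                                             pp1_mod = 0.03, pm3 = 0.02,
                                             pm3_st = 0.02, bp2 = 0.02,
                                             splice = 0.05,
                                             faf_ba1 = 0.02, faf_bs1 = 0.05,
                                             faf_common = 0.10),
                       submitters_per_variant = 3L,
                       conflict_rate = 0.15) {
  if (missing(seed)) stop("seed is required")
  stopifnot(noise_sd >= 0, clone_sd >= 0, true_score_sd >= 0,
            n_variants >= 1, n_nonfunctional <= n_variants,
            clones_per_variant >= 1, replicates_per_clone >= 1,
            n_pathogenic >= 1, n_benign >= 1,
            n_pathogenic_heldout <= n_pathogenic,
            n_benign_heldout <= n_benign,
            conflict_rate >= 0, conflict_rate <= 1)
  as.list(environment())
}

# Derive a bounded sub-seed per stage from the master seed.
stage_seed <- function(config, stage) {
  offsets <- c(replicates = 11L, controls = 23L, evidence = 37L,
               assertions = 53L)
  (as.integer(config$seed) + offsets[[stage]]) %% 2147483647L
}

# Measurements for a set of (variant_id, true_score) under the noise model
# value = true_score * exp(clone_effect + replicate_noise). RNG state is
# managed by the caller.
sample_measurements <- function(ids, true_scores, config,
                                clones = config$clones_per_variant,
                                reps = config$replicates_per_clone) {
  rows <- lapply(seq_along(ids), function(i) {
    cl_eff <- stats::rnorm(clones, 0, config$clone_sd)
    data.frame(
      variant_id = ids[i],
      clone_id = rep(sprintf("c%d", seq_len(clones)), each = reps),
      replicate_id = rep(seq_len(reps), times = clones),
      fold_change = true_scores[i] *
        exp(rep(cl_eff, each = reps) +
              stats::rnorm(clones * reps, 0, config$noise_sd)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate replicate HDR measurements for the assayed variants
#'
#' Draws true scores from the two-mode mixture, generates replicate
#' measurements under the lognormal noise model with clone effects, and
#' adds control wells for both normalization anchors (pathogenic control at
#' true score 1, wild type at 5). Anchor means are computed from the
#' control wells, so [normalize_fold_change()] maps them exactly to 1/5.
#'
#' @param config From [sim_config()].
#' @return List with `true_scores` (data.frame `variant_id`, `true_score`,
#'   `true_label`), `measurements` (variant rows only), `control_wells`,
#'   and `anchors`.
#' @export
simulate_replicates <- function(config) {
  set.seed(stage_seed(config, "replicates"))
  n <- config$n_variants
  nf <- config$n_nonfunctional
  ids <- sprintf("var%03d", seq_len(n))
  label <- c(rep("nonfunctional", nf), rep("functional", n - nf))
  mode <- ifelse(label == "nonfunctional",
                 config$score_nonfunctional, config$score_functional)
  true_score <- mode * exp(stats::rnorm(n, 0, config$true_score_sd))

  meas <- sample_measurements(ids, true_score, config)

  nctl <- config$n_control_measurements
  ctl <- data.frame(
    variant_id = rep(c("pathogenic_control", "wildtype_control"), each = nctl),
    clone_id = rep(sprintf("c%d", rep(seq_len(2), each = nctl / 2)), 2),
    replicate_id = rep(seq_len(nctl), 2),
    fold_change = c(config$score_nonfunctional *
                      exp(stats::rnorm(nctl, 0, config$noise_sd)),
                    config$score_functional *
                      exp(stats::rnorm(nctl, 0, config$noise_sd))),
    stringsAsFactors = FALSE
  )
  anchors <- hdr_anchors(
    pathogenic_control_mean = mean(ctl$fold_change[ctl$variant_id == "pathogenic_control"]),
    wildtype_mean = mean(ctl$fold_change[ctl$variant_id == "wildtype_control"]))

  list(true_scores = data.frame(variant_id = ids, true_score = true_score,
                                true_label = label, stringsAsFactors = FALSE),
       measurements = meas, control_wells = ctl, anchors = anchors)
}

#' Simulate the control-standard set and its measurements
#'
#' Pathogenic controls carry true scores near the pathogenic anchor, benign
#' controls near wild type; held-out flags mark the configured subset not
#' used for threshold identification.
#'
#' @param config From [sim_config()].
#' @return List with `controls` (data.frame `variant_id`, `truth`,
#'   `held_out`, `true_score`) and `measurements`.
#' @export
simulate_control_sets <- function(config) {
  set.seed(stage_seed(config, "controls"))
  np <- config$n_pathogenic; nb <- config$n_benign
  ids <- c(sprintf("pctl%02d", seq_len(np)), sprintf("bctl%02d", seq_len(nb)))
  truth <- c(rep("pathogenic", np), rep("benign", nb))
  held <- c(seq_len(np) <= np - config$n_pathogenic_heldout,
            seq_len(nb) <= nb - config$n_benign_heldout)
  mode <- ifelse(truth == "pathogenic",
                 config$score_nonfunctional, config$score_functional)
  true_score <- mode * exp(stats::rnorm(np + nb, 0, config$true_score_sd))
  controls <- data.frame(variant_id = ids, truth = truth, held_out = !held,
                         true_score = true_score, stringsAsFactors = FALSE)
  meas <- sample_measurements(ids, true_score, config)
  list(controls = controls, measurements = meas)
}

#' Simulate per-variant evidence profiles
#'
#' BayesDel scores are drawn by band (deleterious / tolerated /
#' inconclusive at the configured rates), filtering allele frequencies span
#' the BA1/BS1/PM2 bands, and curated codes (PM1, PM5, PP1, PM3, BP2) are
#' sprinkled at the configured rates with valid strength modifiers. The
#' emitted rows always satisfy the profile invariants by construction.
#'
#' @param config From [sim_config()].
#' @param calls data.frame with `variant_id` (the variants to cover).
#' @return data.frame in the wide evidence layout: `variant_id`,
#'   `bayesdel`, `faf`, `carrier_count`, `splice_impact`, plus one column
#'   per curated code family.
#' @export
simulate_evidence_profiles <- function(config, calls) {
  set.seed(stage_seed(config, "evidence"))
  r <- config$evidence_rates
  n <- nrow(calls)
  th <- insilico_thresholds()
  band <- sample(c("pp3", "bp4", "inc"), n, replace = TRUE,
                 prob = c(r$pp3, r$bp4, 1 - r$pp3 - r$bp4))
  bayesdel <- ifelse(band == "pp3",
                     stats::runif(n, th$bayesdel_deleterious + 1e-6, 1),
                     ifelse(band == "bp4",
                            stats::runif(n, -1, th$bayesdel_benign - 1e-6),
                            stats::runif(n, th$bayesdel_benign,
                                         th$bayesdel_deleterious)))
  fb <- frequency_thresholds()
  fband <- sample(c("ba1", "bs1", "common", "rare"), n, replace = TRUE,
                  prob = c(r$faf_ba1, r$faf_bs1, r$faf_common,
                           1 - r$faf_ba1 - r$faf_bs1 - r$faf_common))
  faf <- ifelse(fband == "ba1", stats::runif(n, fb$ba1, 0.01),
                ifelse(fband == "bs1", stats::runif(n, fb$bs1, fb$ba1 * 0.99),
                       ifelse(fband == "common",
                              stats::runif(n, fb$pm2_supporting, fb$bs1 * 0.99),
                              0)))
  carrier <- ifelse(fband == "rare", stats::rbinom(n, 1, 0.5),
                    ifelse(fband == "common", 2 + stats::rpois(n, 3),
                           pmax(2, round(faf * 282912))))
  pick <- function(p) stats::runif(n) < p
  pm1 <- ifelse(pick(r$pm1), "PM1", ifelse(pick(r$pm1_supp), "PM1_supp", "-"))
  pm5 <- ifelse(pick(r$pm5), "PM5", "-")
  pp1 <- ifelse(pick(r$pp1), "PP1", ifelse(pick(r$pp1_mod), "PP1_mod", "-"))
  pm3_bp2 <- ifelse(pick(r$pm3), "PM3",
                    ifelse(pick(r$pm3_st), "PM3_st",
                           ifelse(pick(r$bp2), "BP2", "-")))
  data.frame(variant_id = calls$variant_id, bayesdel = bayesdel, faf = faf,
             carrier_count = carrier,
             splice_impact = as.integer(pick(r$splice)),
             pm1 = pm1, pm5 = pm5, pp1 = pp1, pm3_bp2 = pm3_bp2,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-submitter assertion table
#'
#' Each variant receives one collaborating-laboratory row plus a
#' Poisson-distributed number of other submitters whose classification
#' matches the variant's final class except for conflict-rate deviations to
#' VUS; a small fraction of submitters fail the data-sharing requirement,
#' exercising the exclusion paths.
#'
#' @param config From [sim_config()].
#' @param finals data.frame with `variant_id`, `tier`.
#' @return data.frame of assertion records.
#' @export
simulate_assertion_table <- function(config, finals) {
  set.seed(stage_seed(config, "assertions"))
  rows <- lapply(seq_len(nrow(finals)), function(i) {
    vid <- finals$variant_id[i]
    tier <- finals$tier[i]
    n_other <- stats::rpois(1, config$submitters_per_variant - 1)
    cls <- c(tier, vapply(seq_len(n_other), function(j) {
      if (stats::runif(1) < config$conflict_rate && tier != "VUS") "VUS" else tier
    }, character(1)))
    data.frame(
      variant_id = vid,
      submitter_id = c("collab_lab", sprintf("lab%02d",
                       sample(1:20, n_other, replace = TRUE))),
      classification = cls,
      meets_sharing_requirements = c(TRUE, stats::runif(n_other) < 0.9),
      is_collaborating_lab = c(TRUE, rep(FALSE, n_other)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
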