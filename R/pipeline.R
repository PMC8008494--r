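# End-to-end orchestration: simulate (or load) -> quantify -> calibrate ->
# classify -> concordance, with a machine-readable run manifest.

#' Run the full analysis pipeline on synthetic inputs
#'
#' Stages: generate replicate measurements and control standards, fit the
#' HDR model and call function, calibrate against the controls (sensitivity,
#' specificity, OddsPath), derive and combine ACMG/AMP evidence into before/
#' after classifications, tabulate reclassification, and run the
#' assertion-table concordance. All randomness flows from `config$seed`, so
#' identical configs give identical manifests.
#'
#' @param config From [sim_config()].
#' @param combiner From [combiner_config()].
#' @param thresholds From [function_thresholds()].
#' @param out_dir Optional directory; when given, each stage writes its
#'   table there as TSV and the manifest as JSON.
#' @param quiet Suppress per-stage log lines (default TRUE).
#' @return List with all stage outputs and `manifest`.
#' @export
run_hdr_pipeline <- function(config, combiner = combiner_config(),
                             thresholds = function_thresholds(),
                             out_dir = NULL, quiet = TRUE) {
  log_line <- function(...) if (!quiet) message("[pipeline] ", ...)

  # stage 1: simulate
  sim <- simulate_replicates(config)
  ctl <- simulate_control_sets(config)
  log_line("simulated ", nrow(sim$true_scores), " variants, ",
           nrow(ctl$controls), " controls")

  # stage 2: quantify
  est <- fit_hdr_model(rbind(sim$measurements, ctl$measurements),
                       anchors = sim$anchors)
  est <- classify_function(est, thresholds)
  var_est <- est[est$variant_id %in% sim$true_scores$variant_id, ]
  calls <- stats::setNames(est$call, est$variant_id)
  log_line("quantified ", nrow(est), " variants (thresholds ",
           thresholds$nonfunctional_upper, "/", thresholds$functional_lower, ")")

  # stage 3: calibrate
  calib <- calibration_report(ctl$controls, calls)

  # stage 4: classify (before = without functional code, after = with)
  evid <- simulate_evidence_profiles(config, var_est)
  wide <- build_code_table(var_est, evid)
  before <- classify_evidence_table(
    wide[, setdiff(names(wide), "functional"), drop = FALSE], config = combiner)
  after <- classify_evidence_table(wide, config = combiner)
  recl <- reclassification_summary(before$tier, after$tier)

  # stage 5: concordance
  finals <- after[, c("variant_id", "tier")]
  assertions <- simulate_assertion_table(config, finals)
  filt <- filter_assertions(assertions)
  statuses <- do.call(rbind, lapply(unique(filt$retained$variant_id), function(v) {
    data.frame(variant_id = v,
               status = conflict_status(
                 filt$retained$classification[filt$retained$variant_id == v]),
               stringsAsFactors = FALSE)
  }))
  conc <- if (!is.null(statuses))
    concordance_table(statuses, finals[finals$variant_id %in% statuses$variant_id, ])
  else NULL

  n_call <- table(factor(var_est$call,
                         levels = c("Functional", "NonFunctional", "Indeterminate")))
  manifest <- list(
    seed = config$seed,
    n_variants = nrow(sim$true_scores),
    n_controls = nrow(ctl$controls),
    n_assayed = nrow(var_est),
    n_functional = unname(n_call[["Functional"]]),
    n_nonfunctional = unname(n_call[["NonFunctional"]]),
    n_indeterminate = unname(n_call[["Indeterminate"]]),
    oddspath_full = calib$oddspath_full$oddspath,
    oddspath_held_out = calib$oddspath_held_out$oddspath,
    sensitivity = calib$sensitivity$estimate,
    specificity = calib$specificity$estimate,
    n_vus_before = recl$n_vus_before,
    n_resolved = recl$n_resolved,
    vus_resolution_rate = recl$resolution_rate,
    to_lp_p = recl$to_lp_p,
    to_lb_b = recl$to_lb_b,
    transition_matrix = recl$matrix,
    n_assertions = nrow(assertions),
    n_excluded_assertions = nrow(filt$excluded)
  )

  result <- list(true_scores = sim$true_scores, estimates = var_est,
                 controls = ctl$controls, calibration = calib,
                 evidence = wide, before = before, after = after,
                 reclassification = recl, assertions = assertions,
                 assertion_filter = filt, statuses = statuses,
                 concordance = conc, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Assemble the wide evidence-code table for the combiner
#'
#' Joins per-variant functional calls with quantitative evidence: the
#' functional code from [assign_functional_code()] (a gated BS3 is
#' withheld), the in-silico code from the BayesDel score, the frequency
#' code from FAF and carrier count, and the curated code columns as given.
#'
#' @param estimates data.frame with `variant_id` and `call`.
#' @param evidence data.frame with `variant_id`, `bayesdel`, `faf`,
#'   `carrier_count`, `splice_impact` and curated code columns, row-aligned
#'   with `estimates`.
#' @return Wide data.frame consumable by [classify_evidence_table()].
#' @export
build_code_table <- function(estimates, evidence) {
  stopifnot(identical(estimates$variant_id, evidence$variant_id))
  n <- nrow(estimates)
  functional <- character(n)
  insilico <- character(n)
  freq <- character(n)
  for (i in seq_len(n)) {
    fc <- assign_functional_code(estimates$call[i],
                                 evidence$splice_impact[i] == 1)
    # a gated BS3 is withheld from the combiner table
    functional[i] <- if (is.null(fc) || fc$gated) "-" else fc$code_id
    insilico[i] <- assign_insilico_code(bayesdel = evidence$bayesdel[i])
    freq[i] <- assign_frequency_code(evidence$faf[i],
                                     evidence$carrier_count[i])
  }
  data.frame(variant_id = estimates$variant_id,
             functional = functional,
             pm1 = evidence$pm1, pm5 = evidence$pm5, pp1 = evidence$pp1,
             pm3_bp2 = evidence$pm3_bp2,
             insilico = insilico, freq = freq,
             splice_impact = evidence$splice_impact,
             stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$estimates, "estimates.tsv")
  wt(result$controls, "controls.tsv")
  wt(result$evidence, "evidence.tsv")
  wt(cbind(result$before[, c("variant_id", "tier")],
           after = result$after$tier), "classifications.tsv")
  wt(result$assertions, "assertions.tsv")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable pipeline report
#'
#' Emits the five-tier before/after counts, the transition matrix, and the
#' headline rates as text (and TSV when `out_dir` is given).
#'
#' @param manifest Manifest from [run_hdr_pipeline()].
#' @param out_dir Optional output directory for the TSV tables.
#' @return Character vector of report lines, invisibly printed.
#' @export
pipeline_report <- function(manifest, out_dir = NULL) {
  if (is.null(manifest$n_assayed) || manifest$n_assayed == 0) {
    warning("empty manifest: nothing to report")
    return(invisible(character(0)))
  }
  tiers <- classification_tiers()
  m <- manifest$transition_matrix
  before_counts <- rowSums(m)
  after_counts <- colSums(m)
  lines <- c(
    sprintf("assayed variants: %d (functional %d, non-functional %d, indeterminate %d)",
            manifest$n_assayed, manifest$n_functional,
            manifest$n_nonfunctional, manifest$n_indeterminate),
    sprintf("control standards: %d; sensitivity %.3f, specificity %.3f",
            manifest$n_controls, manifest$sensitivity, manifest$specificity),
    sprintf("OddsPath: %.1f (full set), %.1f (held-out)",
            manifest$oddspath_full, manifest$oddspath_held_out),
    sprintf("VUS before: %d; resolved: %d (%.0f%%); to LP/P: %d; to LB/B: %d",
            manifest$n_vus_before, manifest$n_resolved,
            100 * manifest$vus_resolution_rate,
            manifest$to_lp_p, manifest$to_lb_b),
    "before/after counts:",
    paste(sprintf("  %-4s before %3d after %3d", tiers,
                  before_counts[tiers], after_counts[tiers]), collapse = "\n")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(tier = tiers, before = as.integer(before_counts[tiers]),
                 after = as.integer(after_counts[tiers])),
      file.path(out_dir, "before_after.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame.matrix(m),
                       file.path(out_dir, "transition_matrix.tsv"),
                       sep = "\t", quote = FALSE)
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
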