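#!/usr/bin/env Rscript
# Stage 3 — validate the assay on the control standards: sensitivity and
# specificity with exact binomial intervals, and OddsPath on the full and
# held-out sets, mapped to ACMG/AMP evidence strength.

suppressPackageStartupMessages(library(brca2hdr))

controls <- read.delim("results/sim/controls.tsv")
est <- read.delim("results/estimates.tsv")

rep <- calibration_report(controls, est)
jsonlite::write_json(rep, "results/calibration.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     force = TRUE)

message(sprintf("sensitivity %.3f (95%% CI %.3f-%.3f), specificity %.3f (95%% CI %.3f-%.3f)",
                rep$sensitivity$estimate, rep$sensitivity$ci$lower,
                rep$sensitivity$ci$upper, rep$specificity$estimate,
                rep$specificity$ci$lower, rep$specificity$ci$upper))
message(sprintf("OddsPath %.1f on the full set (%s), %.1f held-out",
                rep$oddspath_full$oddspath, rep$oddspath_full$strength,
                rep$oddspath_held_out$oddspath))
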