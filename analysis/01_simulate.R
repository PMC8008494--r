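#!/usr/bin/env Rscript
# Stage 1 — generate the study-scale synthetic dataset: 252 assayed DBD
# missense variants (90 with a truly non-functional HDR score), replicate
# DR-GFP measurements with clone effects, anchor control wells, and the
# 20/46 control-standard set with its 10/32 held-out subset.

suppressPackageStartupMessages(library(brca2hdr))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20210219)
sim <- simulate_replicates(cfg)
ctl <- simulate_control_sets(cfg)

wt <- function(df, f) write.table(df, file.path(out, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
wt(sim$true_scores, "true_scores.tsv")
wt(sim$measurements, "measurements.tsv")
wt(sim$control_wells, "control_wells.tsv")
wt(ctl$controls, "controls.tsv")
wt(ctl$measurements, "control_measurements.tsv")
jsonlite::write_json(c(sim$anchors, seed = cfg$seed),
                     file.path(out, "anchors.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("simulated %d variants (%d truly non-functional) and %d controls",
                nrow(sim$true_scores),
                sum(sim$true_scores$true_label == "nonfunctional"),
                nrow(ctl$controls)))
message(sprintf("anchor means: pathogenic %.3f, wild type %.3f",
                sim$anchors$pathogenic_control_mean, sim$anchors$wildtype_mean))
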