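#!/usr/bin/env Rscript
# Stage 4 — derive evidence codes (PS3/BS3 from the calls, PP3/BP4 from
# BayesDel, frequency codes from FAF/carriers) plus simulated curated
# codes, combine them into five-tier classifications with and without the
# functional evidence, and tabulate the reclassification.

suppressPackageStartupMessages(library(brca2hdr))

cfg <- sim_config(seed = 20210219)
truth <- read.delim("results/sim/true_scores.tsv")
est <- read.delim("results/estimates.tsv")
var_est <- est[est$variant_id %in% truth$variant_id, ]

evid <- simulate_evidence_profiles(cfg, var_est)
wide <- build_code_table(var_est, evid)
write.table(wide, "results/evidence_codes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

before <- classify_evidence_table(wide[, setdiff(names(wide), "functional")])
after <- classify_evidence_table(wide)
cls <- data.frame(variant_id = wide$variant_id, before = before$tier,
                  after = after$tier, conflict = after$conflict_flag)
write.table(cls, "results/classifications.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

r <- reclassification_summary(cls$before, cls$after)
write.table(as.data.frame.matrix(r$matrix), "results/transition_matrix.tsv",
            sep = "\t", quote = FALSE)
message(sprintf("VUS before: %d; resolved: %d (%.0f%%); to LP/P %d, to LB/B %d",
                r$n_vus_before, r$n_resolved, 100 * r$resolution_rate,
                r$to_lp_p, r$to_lb_b))
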