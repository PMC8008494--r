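#!/usr/bin/env Rscript
# Stage 5 — build a synthetic multi-submitter assertion table over the
# final classifications, apply the mining filters (data-sharing
# requirement, collaborating-lab sole submitter / sole outlier), assign
# conflict statuses, and cross-tabulate against the internal classes.

suppressPackageStartupMessages(library(brca2hdr))

cfg <- sim_config(seed = 20210219)
cls <- read.delim("results/classifications.tsv")
finals <- data.frame(variant_id = cls$variant_id, tier = cls$after)

asr <- simulate_assertion_table(cfg, finals)
filt <- filter_assertions(asr)
statuses <- do.call(rbind, lapply(unique(filt$retained$variant_id), function(v)
  data.frame(variant_id = v, status = conflict_status(
    filt$retained$classification[filt$retained$variant_id == v]))))

write.table(asr, "results/assertions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(statuses, "results/assertion_statuses.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(filt$excluded, "results/assertion_exclusions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

conc <- concordance_table(statuses,
                          finals[finals$variant_id %in% statuses$variant_id, ])
jsonlite::write_json(list(counts = as.data.frame.matrix(conc$counts),
                          row_n = as.list(conc$row_n)),
                     "results/concordance.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

message(sprintf("%d variants retained, %d excluded (%s)",
                length(unique(filt$retained$variant_id)), nrow(filt$excluded),
                paste(names(table(filt$excluded$reason)),
                      table(filt$excluded$reason), collapse = ", ")))
message("status counts: ",
        paste(names(table(statuses$status)), table(statuses$status),
              sep = "=", collapse = ", "))
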