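# Shared builders for the test suite; everything is generated in code.

# A control set with every call correct (perfect assay separation).
perfect_calls <- function(controls) {
  stats::setNames(
    ifelse(controls$truth == "pathogenic", "NonFunctional", "Functional"),
    controls$variant_id)
}

study_control_set <- function(n_pathogenic = 20, n_benign = 46,
                              n_pathogenic_heldout = 10, n_benign_heldout = 32) {
  control_set(
    variant_id = c(sprintf("p%02d", seq_len(n_pathogenic)),
                   sprintf("b%02d", seq_len(n_benign))),
    truth = c(rep("pathogenic", n_pathogenic), rep("benign", n_benign)),
    held_out = c(seq_len(n_pathogenic) > n_pathogenic - n_pathogenic_heldout,
                 seq_len(n_benign) > n_benign - n_benign_heldout))
}

# Random valid code sets for property-style combiner tests. Respects the
# profile invariants (one in-silico code, one frequency code, no
# duplicates).
random_code_set <- function() {
  pool <- list(c("PS3", "BS3", NA), c("PM1", "PM1_supp", NA),
               c("PM5", NA), c("PP1", "PP1_mod", NA),
               c("PM3", "PM3_st", "BP2", NA),
               c("PP3", "BP4", NA),
               c("BA1", "BS1", "PM2_supp", NA))
  picks <- vapply(pool, function(opts) sample(opts, 1), NA_character_)
  picks[!is.na(picks)]
}

# Long-format replicate measurements around a single true score.
make_measurements <- function(variant_id, true_score, n_clones, n_reps,
                              noise_sd, clone_sd = 0) {
  cl_eff <- stats::rnorm(n_clones, 0, clone_sd)
  data.frame(
    variant_id = variant_id,
    clone_id = rep(sprintf("c%d", seq_len(n_clones)), each = n_reps),
    replicate_id = rep(seq_len(n_reps), n_clones),
    fold_change = true_score * exp(rep(cl_eff, each = n_reps) +
                                     stats::rnorm(n_clones * n_reps, 0, noise_sd)),
    stringsAsFactors = FALSE)
}

table1_evidence_columns <- c("ps3", "pm1", "pm5", "pp1", "pm3_bp2",
                             "pp3_bp4", "freq")

# The printed table's observed rows in the wide layout the combiner reads.
table1_observed_wide <- function() {
  tab <- read_table1()
  obs <- tab[tab$final_class != "N/O", ]
  out <- obs[, c("hgvs_p", table1_evidence_columns, "before_class", "final_class")]
  names(out)[1] <- "variant_id"
  out
}
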