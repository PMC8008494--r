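make_assertions <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(variant_id = r[[1]], submitter_id = r[[2]],
               classification = r[[3]],
               meets_sharing_requirements = r[[4]],
               is_collaborating_lab = r[[5]], stringsAsFactors = FALSE)))
}

test_that("assertion filtering applies the three exclusion rules", {
  recs <- make_assertions(
    # v1: collaborating lab is the sole qualifying submitter
    list("v1", "collab", "LP", TRUE, TRUE),
    list("v1", "labA", "VUS", FALSE, FALSE),
    # v2: collaborating lab is the sole classification outlier
    list("v2", "collab", "LP", TRUE, TRUE),
    list("v2", "labA", "VUS", TRUE, FALSE),
    list("v2", "labB", "VUS", TRUE, FALSE),
    # v3: no qualifying submitter at all
    list("v3", "labA", "LB", FALSE, FALSE),
    # v4: retained; collab agrees with one of two groups
    list("v4", "collab", "LP", TRUE, TRUE),
    list("v4", "labA", "P", TRUE, FALSE),
    list("v4", "labB", "VUS", TRUE, FALSE),
    # v5: retained, no collaborating lab at all
    list("v5", "labA", "VUS", TRUE, FALSE))
  out <- filter_assertions(recs)
  expect_equal(sort(out$excluded$variant_id), c("v1", "v2", "v3"))
  expect_equal(out$excluded$reason[out$excluded$variant_id == "v1"],
               "collaborating-lab sole submitter")
  expect_equal(out$excluded$reason[out$excluded$variant_id == "v2"],
               "collaborating-lab sole outlier")
  expect_equal(out$excluded$reason[out$excluded$variant_id == "v3"],
               "no qualifying submitter")
  expect_setequal(unique(out$retained$variant_id), c("v4", "v5"))
  # non-qualifying submitters are dropped from retained rows
  expect_true(all(out$retained$meets_sharing_requirements))
})

test_that("a collaborating lab tied with an agreeing submitter is not an outlier", {
  recs <- make_assertions(
    list("v1", "collab", "LP", TRUE, TRUE),
    list("v1", "labA", "P", TRUE, FALSE),    # same LP/P group as collab
    list("v1", "labB", "VUS", TRUE, FALSE))
  out <- filter_assertions(recs)
  expect_equal(nrow(out$excluded), 0)
})

test_that("conflict status groups LP with P and LB with B", {
  expect_equal(conflict_status(c("LP", "P")), "no_conflict_LPP")
  expect_equal(conflict_status(c("VUS", "LP")), "conflicting_LPP")
  expect_equal(conflict_status(c("VUS", "LB", "B")), "conflicting_LBB")
  expect_equal(conflict_status("VUS"), "no_conflict_VUS")
  expect_equal(conflict_status(c("LB", "B", "LB")), "no_conflict_LBB")
  expect_equal(conflict_status(c("LB", "P")), "opposing")
  expect_equal(conflict_status(c("LB", "VUS", "P")), "opposing")
})

test_that("every variant lands in exactly one status or exclusion bucket", {
  cfg <- sim_config(seed = 31, n_variants = 40, n_nonfunctional = 15)
  finals <- data.frame(variant_id = sprintf("var%03d", 1:40),
                       tier = sample(classification_tiers(), 40, replace = TRUE))
  set.seed(8)
  asr <- simulate_assertion_table(cfg, finals)
  out <- filter_assertions(asr)
  statuses <- vapply(unique(out$retained$variant_id), function(v)
    conflict_status(out$retained$classification[out$retained$variant_id == v]),
    character(1))
  covered <- c(names(statuses), out$excluded$variant_id)
  expect_setequal(covered, finals$variant_id)
  expect_equal(anyDuplicated(covered), 0)
  expect_true(all(out$excluded$reason %in%
    c("no qualifying submitter", "collaborating-lab sole submitter",
      "collaborating-lab sole outlier")))
})

test_that("concordance table recovers constructed marginals", {
  # synthetic table built to the published LP/P-final marginals:
  # 36 finals split 14 no-conflict LP/P, 11 no-conflict VUS, 11 conflicting
  statuses <- data.frame(
    variant_id = sprintf("v%02d", 1:36),
    status = rep(c("no_conflict_LPP", "no_conflict_VUS", "conflicting_LPP"),
                 times = c(14, 11, 11)))
  finals <- data.frame(variant_id = sprintf("v%02d", 1:36), tier = "LP")
  tab <- concordance_table(statuses, finals)
  expect_equal(unname(tab$row_n["LPP"]), 36)
  expect_equal(tab$counts["LPP", "no_conflict_LPP"], 14)
  expect_equal(tab$proportions["LPP", "no_conflict_LPP"], 14 / 36)
  expect_equal(tab$proportions["LPP", "no_conflict_VUS"], 11 / 36)
  expect_equal(tab$proportions["LPP", "conflicting_LPP"], 11 / 36)

  expect_error(concordance_table(statuses, finals[-1, ]), "only one input")
  expect_warning(empty <- concordance_table(statuses[0, ], finals[0, ]), "empty")
  expect_null(empty$proportions)
})

test_that("the filter-status-table pipeline is order-invariant", {
  cfg <- sim_config(seed = 97, n_variants = 25, n_nonfunctional = 10)
  finals <- data.frame(variant_id = sprintf("var%03d", 1:25),
                       tier = sample(classification_tiers(), 25, replace = TRUE))
  asr <- simulate_assertion_table(cfg, finals)
  run <- function(records) {
    out <- filter_assertions(records)
    st <- vapply(sort(unique(out$retained$variant_id)), function(v)
      conflict_status(out$retained$classification[out$retained$variant_id == v]),
      character(1))
    list(st = st, excl = out$excluded[order(out$excluded$variant_id), ])
  }
  set.seed(5)
  shuffled <- asr[sample(nrow(asr)), ]
  expect_equal(run(asr), run(shuffled), ignore_attr = TRUE)
})

test_that("external-assay crosstab finds discordant variants", {
  calls <- data.frame(variant_id = c("a", "b", "c", "d", "e"),
                      call = c("NonFunctional", "NonFunctional", "Functional",
                               "Functional", "Indeterminate"))
  ext <- data.frame(variant_id = c("a", "b", "c", "d", "e"),
                    class = c("4", "3", "1", "5", "2"))
  out <- external_assay_crosstab(calls, ext)
  # non-functional variants sit only in sensitive or inconclusive classes
  expect_equal(sum(out$table["NonFunctional", c("1", "2")]), 0)
  expect_equal(out$discordant, "d")   # HDR-functional, drug-sensitive

  same <- external_assay_crosstab(
    data.frame(variant_id = c("x", "y"), call = c("Functional", "Functional")),
    data.frame(variant_id = c("x", "y"), class = c("1", "2")))
  expect_equal(length(same$discordant), 0)
})
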