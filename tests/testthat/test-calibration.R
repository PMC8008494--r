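test_that("confusion counts separate truth, calls, and indeterminates", {
  ctl <- study_control_set()
  cc <- confusion_counts(perfect_calls(ctl), ctl)
  expect_equal(cc[c("TP", "FN", "TN", "FP", "n_indeterminate")],
               list(TP = 20, FN = 0, TN = 46, FP = 0, n_indeterminate = 0))

  all_ind <- stats::setNames(rep("Indeterminate", nrow(ctl)), ctl$variant_id)
  cc2 <- confusion_counts(all_ind, ctl)
  expect_equal(cc2$n_indeterminate, 66)
  expect_equal(cc2$TP + cc2$FN + cc2$TN + cc2$FP, 0)

  calls <- perfect_calls(ctl)
  calls["p01"] <- "Functional"
  cc3 <- confusion_counts(calls, ctl)
  expect_equal(cc3$FN, 1)
  expect_equal(cc3$misclassified, "p01")

  expect_error(confusion_counts(calls[-1], ctl), "without a functional call")
})

test_that("sensitivity and specificity are invariant to control ordering", {
  ctl <- study_control_set()
  calls <- perfect_calls(ctl)
  calls[c("p03", "b11")] <- c("Functional", "NonFunctional")
  set.seed(2)
  shuffled <- ctl[sample(nrow(ctl)), ]
  expect_equal(confusion_counts(calls, ctl)[1:5],
               confusion_counts(calls, shuffled)[1:5])
})

test_that("exact binomial interval matches closed forms and binom.test", {
  ci <- exact_binomial_ci(20, 20)
  expect_equal(ci[["lower"]], 0.025^(1 / 20), tolerance = 1e-12)
  expect_equal(ci[["upper"]], 1)

  ci0 <- exact_binomial_ci(0, 20)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - 0.025^(1 / 20), tolerance = 1e-12)

  expect_equal(unname(exact_binomial_ci(1, 1)), c(0.025, 1), tolerance = 1e-12)

  # independent oracle: stats::binom.test, across a parameter grid
  for (n in c(1, 5, 20, 46, 100)) {
    for (x in unique(c(0, 1, floor(n / 2), n))) {
      expect_equal(unname(exact_binomial_ci(x, n)),
                   as.numeric(binom.test(x, n)$conf.int),
                   tolerance = 1e-9)
    }
  }
  expect_error(exact_binomial_ci(1, 0), "trials")
  expect_error(exact_binomial_ci(5, 3), "successes")
})

test_that("OddsPath reproduces the published control-set odds", {
  ctl <- study_control_set()
  op <- compute_oddspath(ctl, perfect_calls(ctl))
  expect_equal(op$oddspath, 46.0)
  expect_equal(op$p1, 20 / 66)
  expect_equal(op$p2, 20 / 21)
  expect_equal(op$strength, "strong")

  held <- ctl[ctl$held_out, ]
  expect_equal(nrow(held), 42)
  oph <- compute_oddspath(held, perfect_calls(held))
  expect_equal(oph$oddspath, 32.0)
  expect_equal(oph$strength, "strong")

  tiny <- control_set(c("p", "b"), c("pathogenic", "benign"))
  expect_equal(compute_oddspath(tiny, perfect_calls(tiny))$oddspath, 1.0)
})

test_that("perfect separation makes OddsPath equal the benign count exactly", {
  for (p in c(1, 3, 10, 20, 77)) {
    for (b in c(1, 2, 32, 46, 100)) {
      ctl <- study_control_set(n_pathogenic = p, n_benign = b,
                               n_pathogenic_heldout = 0, n_benign_heldout = 0)
      expect_equal(compute_oddspath(ctl, perfect_calls(ctl))$oddspath, b,
                   tolerance = 1e-12)
      # mirrored benign-direction value equals the pathogenic count
      expect_equal(
        compute_oddspath(ctl, perfect_calls(ctl), "benign")$oddspath, p,
        tolerance = 1e-12)
    }
  }
})

test_that("degenerate OddsPath inputs are reported, not silently computed", {
  ctl <- study_control_set(4, 4, 0, 0)
  all_fn <- stats::setNames(rep("Functional", 8), ctl$variant_id)
  expect_error(compute_oddspath(ctl, all_fn), "no abnormal")
  all_ind <- stats::setNames(rep("Indeterminate", 8), ctl$variant_id)
  expect_error(compute_oddspath(ctl, all_ind), "no determinate")
  # pathogenic controls all called Functional, benign all NonFunctional
  inverted <- stats::setNames(
    ifelse(ctl$truth == "pathogenic", "Functional", "NonFunctional"),
    ctl$variant_id)
  inv <- compute_oddspath(ctl, inverted)
  expect_equal(inv$oddspath, 0)
  expect_match(inv$note, "benign direction")
})

test_that("OddsPath maps to evidence strength with strict cutoffs", {
  expect_equal(oddspath_to_strength(46.0)$strength, "strong")
  expect_equal(oddspath_to_strength(18.7)$strength, "moderate") # boundary
  expect_equal(oddspath_to_strength(400)$strength, "very_strong")
  expect_equal(oddspath_to_strength(3)$strength, "supporting")
  expect_equal(oddspath_to_strength(1.5)$strength, "insufficient")
  b <- oddspath_to_strength(1 / 40)
  expect_equal(b$direction, "benign")
  expect_equal(b$strength, "strong")
  expect_equal(oddspath_to_strength(1 / 400)$strength, "very_strong")
})

test_that("the calibration report assembles counts, intervals and odds", {
  ctl <- study_control_set()
  rep <- calibration_report(ctl, perfect_calls(ctl))
  expect_equal(rep$sensitivity$estimate, 1)
  expect_equal(rep$specificity$estimate, 1)
  expect_equal(rep$sensitivity$ci$lower, 0.025^(1 / 20), tolerance = 1e-12)
  expect_equal(rep$specificity$ci$lower, 0.025^(1 / 46), tolerance = 1e-12)
  expect_equal(rep$oddspath_full$oddspath, 46)
  expect_equal(rep$oddspath_held_out$oddspath, 32)
  expect_equal(rep$oddspath_full_benign$oddspath, 20)
})
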