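# Fold plans, metrics, selection rules, bias correction, nested CV.

test_that("stratified 8-fold plans on a 24+24 cohort are exactly balanced", {
  labs <- toy_labels(24, 24)
  for (seed in c(1, 7, 123, 99991)) {
    plan <- make_folds(labs, k = 8, m = 5, seed = seed)
    expect_length(plan$assignments, 5)
    for (a in plan$assignments) {
      expect_setequal(names(a), names(labs))
      for (f in 1:8) {
        expect_equal(sum(a == f), 6)
        expect_equal(sum(a == f & labs[names(a)] == "AR"), 3)
        expect_equal(sum(a == f & labs[names(a)] == "NR"), 3)
      }
    }
    expect_false(identical(plan$assignments[[1]], plan$assignments[[2]]))
  }
  # dealing arithmetic in the degenerate k = n-per-class case
  small <- toy_labels(8, 8)
  plan <- make_folds(small, k = 8, m = 1, seed = 1)
  expect_true(all(table(plan$assignments[[1]]) == 2))
  expect_error(make_folds(toy_labels(4, 4), k = 8), "fewer samples")
})

test_that("AUC matches the brute-force pair-counting oracle", {
  expect_equal(auc(c(0.9, 0.8), c(AR = "AR", NR = "NR")[c(1, 2)]), 1)
  labs3 <- stats::setNames(c("AR", "AR", "NR"), c("a", "b", "c"))
  expect_equal(auc(c(0.9, 0.4, 0.6), labs3), 0.5)
  expect_equal(auc(rep(0.5, 6), toy_labels(3, 3)), 0.5)
  for (s in 1:1000) {
    set.seed(s)
    n1 <- sample(1:15, 1); n2 <- sample(1:15, 1)
    labs <- stats::setNames(rep(c("AR", "NR"), c(n1, n2)),
                            seq_len(n1 + n2))
    scores <- sample(seq(0, 1, 0.1), n1 + n2, replace = TRUE)
    expect_equal(auc(scores, labs), auc_oracle(scores, labs))
  }
  expect_error(auc(c(0.1, 0.9), c(a = "AR", b = "AR")), "undefined AUC")
})

test_that("confusion metrics count at the 0.5 threshold with >= as case", {
  labs <- toy_labels(3, 3)
  m <- confusion_metrics(c(0.6, 0.4, 0.9, 0.2, 0.7, 0.1), labs)
  expect_equal(unname(m), c(1 / 3, 2 / 3, 2 / 3))
  all_case <- confusion_metrics(rep(1, 6), labs)
  expect_equal(unname(all_case["sensitivity"]), 1)
  expect_equal(unname(all_case["specificity"]), 0)
  perfect <- confusion_metrics(as.numeric(is_case_lab(labs)), labs)
  expect_equal(unname(perfect["error"]), 0)
})

test_that("one-SE selection picks the most regularized candidate within one SE", {
  sel <- markergrid:::select_param
  # grids ordered most -> least regularized
  expect_equal(sel(c(0.80, 0.89, 0.90), c(0.02, 0.02, 0.02), "auc",
                   "one_se"), 2)
  expect_equal(sel(c(0.80, 0.89, 0.90), c(0.02, 0.02, 0.02), "auc",
                   "extreme"), 3)
  expect_equal(sel(c(0.12, 0.10), c(0.03, 0.03), "error", "one_se"), 1)
  expect_equal(sel(c(0.42), c(0.01), "auc", "one_se"), 1)
  expect_equal(sel(c(NA, 0.6, 0.9), c(NA, 0.01, 0.01), "auc", "extreme"), 3)
})

test_that("bias correction reproduces the worked optimism example", {
  # 2 folds, grid {a, b}; overall selection a; fold bests 0.9 and 0.9
  fold_grid <- rbind(c(0.9, 0.7), c(0.8, 0.9))
  out <- bias_correct(fold_grid, selected_index = 1, metric = "auc")
  expect_equal(out$optimism, 0.05)
  expect_equal(out$corrected, 0.80)
  # every fold's best equals the overall best: no correction
  same <- rbind(c(0.9, 0.7), c(0.95, 0.7))
  out2 <- bias_correct(same, 1, "auc")
  expect_equal(out2$optimism, 0)
  expect_equal(out2$corrected, 0.925)
  # single grid value: nothing to select over
  expect_equal(bias_correct(cbind(c(0.8, 0.9)), 1, "auc")$optimism, 0)
  # error orientation: corrected error never below the flat estimate
  err <- rbind(c(0.10, 0.20), c(0.25, 0.15))
  oute <- bias_correct(err, 1, "error")
  expect_equal(oute$optimism, mean(c(0.10 - 0.10, 0.25 - 0.15)))
  expect_equal(oute$corrected, 0.175 + 0.05)
  expect_error(bias_correct(rbind(c(NA, 1)), 1, "auc"), "missing")
})

test_that("flat tuning recomputes panels inside folds and returns an estimate", {
  coh <- small_cohort()
  plan <- make_folds(coh$labels, k = 8, m = 2, seed = 4)
  fl <- tune_flat(classifier_spec("PAM"), coh$expr, coh$labels,
                  standard_rules()$FDR50, plan, seed = 4)
  expect_s3_class(fl$estimate, "performance_estimate")
  expect_equal(nrow(fl$estimate$per_fold), 16)
  expect_true(fl$selected_param %in% classifier_spec("PAM")$grid)
  expect_true(all(fl$estimate$metrics >= 0 & fl$estimate$metrics <= 1))
  # one-SE never selects a less regularized value than the extreme rule
  fe <- tune_flat(classifier_spec("PAM"), coh$expr, coh$labels,
                  standard_rules()$FDR50, plan, rule = "extreme", seed = 4)
  expect_lte(fl$selected_index, fe$selected_index)
})

test_that("RF flat and nested estimates are identical (no tuning)", {
  coh <- small_cohort()
  plan <- make_folds(coh$labels, k = 8, m = 1, seed = 6)
  fl <- tune_flat(classifier_spec("RF-1"), coh$expr, coh$labels,
                  standard_rules()$FDR50, plan, seed = 6)
  nc <- nested_cv(classifier_spec("RF-1"), coh$expr, coh$labels,
                  standard_rules()$FDR50, plan, seed = 6, flat = fl)
  expect_identical(fl$estimate$per_fold, nc$estimate$per_fold)
  expect_equal(fl$estimate$metrics, nc$estimate$metrics)
})

test_that("nested CV is honest on null data while flat tuned CV is optimistic", {
  labs <- toy_labels(8, 8)
  nested_auc <- flat_auc <- numeric(10)
  spec <- classifier_spec("PAM")
  for (s in 1:10) {
    x <- rand_expr(60, labs, seed = 8000 + s)  # global null
    plan <- make_folds(labs, k = 8, m = 1, seed = s)
    fl <- tune_flat(spec, x, labs, standard_rules()$FDR50, plan,
                    rule = "extreme", seed = s)
    nc <- nested_cv(spec, x, labs, standard_rules()$FDR50, plan,
                    inner_k = 7, rule = "extreme", seed = s, flat = fl)
    flat_auc[s] <- unname(fl$estimate$metrics["auc"])
    nested_auc[s] <- unname(nc$estimate$metrics["auc"])
  }
  se <- sd(nested_auc) / sqrt(10)
  expect_lt(abs(mean(nested_auc) - 0.5), 2 * se + 0.05)
  expect_gt(mean(flat_auc - nested_auc), 0)
})

test_that("no leakage: test-fold content does not affect the trained fold models", {
  coh <- small_cohort()
  sub <- coh$expr[1:80, ]
  plan <- make_folds(coh$labels, k = 8, m = 1, seed = 9)
  ctxs <- markergrid:::plan_contexts(plan, coh$labels)
  spec <- classifier_spec("PAM")
  r1 <- markergrid:::eval_contexts(spec, sub, coh$labels,
                                   standard_rules()$FDR50, ctxs[1],
                                   seed = 9)
  # shuffling the test-fold labels must not change the trained model:
  # held-out probabilities are identical even though metrics would differ
  labs2 <- coh$labels
  labs2[ctxs[[1]]$test] <- rev(labs2[ctxs[[1]]$test])
  r2 <- markergrid:::eval_contexts(spec, sub, labs2,
                                   standard_rules()$FDR50, ctxs[1],
                                   seed = 9)
  expect_identical(r1[[1]]$probs, r2[[1]]$probs)
})
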