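# Classifier contract: probability of case, feature selection behavior,
# shrunken-centroid arithmetic, determinism.

train_ctx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- small_cohort()
      de <- moderated_t(coh$expr, coh$labels)
      cache <<- list(coh = coh, de = de, panel = rule_fdr50(de),
                     ord = de$feature_id[order(de$fdr, de$p)])
    }
    cache
  }
})

test_that("every method round-trips training data at AUC >= 0.5 with sane probabilities", {
  ctx <- train_ctx()
  for (m in c("EN-0.10", "EN-0.50", "EN-0.90", "LDA", "PAM", "RF-1",
              "SVM", "XGBoost")) {
    sp <- classifier_spec(m)
    pv <- if (length(sp$grid)) sp$grid[ceiling(length(sp$grid) / 2)] else NULL
    fit <- train_classifier(sp, ctx$coh$expr, ctx$coh$labels, ctx$panel,
                            pv, seed = 3, fdr_order = ctx$ord)
    pr <- predict_proba(fit, ctx$coh$expr)
    expect_true(all(pr >= 0 & pr <= 1), info = m)
    expect_gte(auc(pr, ctx$coh$labels), 0.5)
    expect_true(all(fit$selected_feature_ids %in% ctx$panel$feature_ids),
                info = m)
  }
})

test_that("shrunken-centroid scores match a hand-computed toy instance", {
  # 2 features, 2 classes; engineered so s_i = 1 and m_k equal
  x <- rbind(c(-1, -1), c(-3, -3), c(1, 1), c(3, 3))
  colnames(x) <- c("f1", "f2")
  y <- factor(c("NR", "NR", "AR", "AR"), levels = c("NR", "AR"))
  st <- markergrid:::pam_stats(x, y)
  # within-class sd: sqrt(((-1+2)^2+(-3+2)^2+(1-2)^2+(3-2)^2)/(4-2)) = sqrt(2)
  expect_equal(unname(st$s), rep(sqrt(2), 2))
  expect_equal(unname(st$s0), sqrt(2))
  expect_equal(unname(st$m), rep(sqrt(1 / 2 - 1 / 4), 2))
  # d_ik = (centroid - overall) / (m (s + s0)); centroids -2/+2, overall 0
  d_expected <- 2 / (sqrt(0.25) * 2 * sqrt(2))
  expect_equal(unname(st$d["AR", ]), rep(d_expected, 2))
  expect_equal(unname(st$d["NR", ]), rep(-d_expected, 2))
  # delta = 0.5 shrinks both deviations by 0.5
  cent <- markergrid:::pam_shrunken_centroids(st, 0.5)
  shrunk <- (d_expected - 0.5) * sqrt(0.25) * 2 * sqrt(2)
  expect_equal(unname(cent["AR", ]), rep(shrunk, 2))
  # discriminant at a probe point, by direct formula
  xnew <- matrix(c(1, 0), 1, dimnames = list(NULL, c("f1", "f2")))
  sc <- markergrid:::pam_score(xnew, st, 0.5)
  delta_manual <- function(c_k) {
    sum((c(1, 0) - c_k)^2 / (2 * sqrt(2))^2) - 2 * log(0.5)
  }
  expect_equal(unname(sc$scores[1, "AR"]), delta_manual(rep(shrunk, 2)))
  expect_equal(unname(sc$scores[1, "NR"]), delta_manual(rep(-shrunk, 2)))
  expect_equal(unname(rowSums(sc$prob)), 1)
  # midpoint between symmetric centroids with equal priors scores 0.5
  mid <- markergrid:::pam_score(matrix(0, 1, 2,
                                       dimnames = list(NULL, c("f1", "f2"))),
                                st, 0.5)
  expect_equal(unname(mid$prob[1, ]), c(0.5, 0.5), ignore_attr = TRUE)
})

test_that("PAM shrinkage spans unshrunk to prior-only prediction", {
  ctx <- train_ctx()
  sp <- classifier_spec("PAM")
  unshrunk <- train_classifier(sp, ctx$coh$expr, ctx$coh$labels, ctx$panel,
                               param_value = 0)
  expect_setequal(unshrunk$selected_feature_ids, ctx$panel$feature_ids)
  total <- train_classifier(sp, ctx$coh$expr, ctx$coh$labels, ctx$panel,
                            param_value = 1)
  pr <- predict_proba(total, ctx$coh$expr)
  # at full shrinkage every centroid collapses to the overall mean:
  # predictions are driven by the (equal) class priors alone
  expect_true(all(abs(pr - 0.5) < 1e-9))
  expect_length(total$selected_feature_ids, 0)
})

test_that("elastic-net sparsity is monotone in alpha at matched lambda", {
  labs <- toy_labels(10, 10)
  wins <- 0
  for (s in 1:100) {
    x <- rand_expr(40, labs, seed = 7000 + s, effect = 1, n_de = 5)
    de_ord <- sprintf("F%04d", 1:40)
    lam <- 0.05
    n10 <- length(train_classifier(classifier_spec("EN-0.10"), x, labs,
                                   de_ord, lam)$selected_feature_ids)
    n90 <- length(train_classifier(classifier_spec("EN-0.90"), x, labs,
                                   de_ord, lam)$selected_feature_ids)
    if (n90 <= n10) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("LDA saturates on separated toy data and probabilities sum to one", {
  labs <- toy_labels(10, 10)
  x <- rand_expr(20, labs, seed = 15)
  x["F0001", ] <- c(rep(3, 10), rep(-3, 10)) + rnorm(20, 0, 0.05)
  fit <- train_classifier(classifier_spec("LDA"), x, labs,
                          sprintf("F%04d", 1:20), 1,
                          fdr_order = sprintf("F%04d", 1:20))
  pr <- predict_proba(fit, x)
  expect_true(all(pr[labs == "AR"] > 0.99))
  expect_true(all(pr[labs == "NR"] < 0.01))
})

test_that("stochastic learners are reproducible under a fixed seed", {
  ctx <- train_ctx()
  for (m in c("RF-1", "XGBoost")) {
    sp <- classifier_spec(m)
    pv <- if (length(sp$grid)) 100 else NULL
    p1 <- predict_proba(train_classifier(sp, ctx$coh$expr, ctx$coh$labels,
                                         ctx$panel, pv, seed = 11),
                        ctx$coh$expr)
    p2 <- predict_proba(train_classifier(sp, ctx$coh$expr, ctx$coh$labels,
                                         ctx$panel, pv, seed = 11),
                        ctx$coh$expr)
    expect_identical(p1, p2, info = m)
  }
})

test_that("default grids are ordered most to least regularized and RF is untuned", {
  g <- default_grids()
  expect_named(g, c("EN-0.10", "EN-0.50", "EN-0.90", "LDA", "PAM", "RF-1",
                    "SVM", "XGBoost"))
  expect_length(g[["RF-1"]]$grid, 0)
  expect_true(all(diff(g[["EN-0.50"]]$grid) < 0))   # lambda decreasing
  expect_true(all(diff(g[["PAM"]]$grid) < 0))       # delta decreasing
  expect_true(all(diff(g[["LDA"]]$grid) > 0))       # n increasing
  expect_true(all(diff(g[["SVM"]]$grid) > 0))       # cost increasing
  expect_true(all(diff(g[["XGBoost"]]$grid) > 0))   # rounds increasing
  expect_equal(min(g[["PAM"]]$grid), 0)             # unshrunk endpoint
})

test_that("degenerate inputs are rejected", {
  ctx <- train_ctx()
  expect_error(train_classifier(classifier_spec("PAM"), ctx$coh$expr,
                                ctx$coh$labels, character(0), 0),
               "empty panel")
  one_class <- ctx$coh$labels
  one_class[] <- "AR"
  expect_error(train_classifier(classifier_spec("PAM"), ctx$coh$expr,
                                one_class, ctx$panel, 0), "single class")
  fit <- train_classifier(classifier_spec("PAM"), ctx$coh$expr,
                          ctx$coh$labels, ctx$panel, 0.5)
  expect_error(predict_proba(fit, ctx$coh$expr[1:3, ]), "missing features")
})
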