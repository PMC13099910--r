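# Multiple-partition stratified k-fold cross-validation, one-standard-error
# model selection, performance metrics, optimism bias correction, and nested
# cross-validation for unbiased performance estimation.

#' Stratified multi-partition fold plan
#'
#' Per partition, samples are shuffled within class with a seeded stream and
#' dealt round-robin into k folds, so each fold's class counts differ from
#' perfect balance by at most one. A balanced 24 + 24 cohort at k = 8 yields
#' folds of exactly 3 cases and 3 controls.
#'
#' @param labels named AR/NR labels.
#' @param k folds per partition.
#' @param m number of partitions.
#' @param seed master seed; partition p uses a derived sub-seed.
#' @return object of class `fold_plan`: list of m integer vectors (fold id
#'   per sample).
#' @export
make_folds <- function(labels, k = 8, m = 5, seed = 1) {
  labels <- check_labels(labels)
  classes <- unique(as.character(labels))
  for (cl in classes)
    if (sum(labels == cl) < k)
      stop(sprintf("class %s has fewer samples than folds", cl))
  parts <- lapply(seq_len(m), function(p) {
    assign <- integer(length(labels))
    names(assign) <- names(labels)
    with_stream(seed, paste0("folds", p), {
      for (cl in classes) {
        ids <- names(labels)[labels == cl]
        ids <- sample(ids)
        assign[ids] <- rep_len(seq_len(k), length(ids))
      }
    })
    assign
  })
  structure(list(assignments = parts, k = k, m = m, seed = seed),
            class = "fold_plan")
}

#' Area under the ROC curve (case-control pair concordance)
#'
#' Mann-Whitney formulation: concordant case-control pairs count 1, ties 0.5.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels AR/NR labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  case <- is_case(labels)
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 == 0 || n2 == 0) stop("undefined AUC: a class is missing")
  r <- rank(scores)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Error, sensitivity and specificity at a probability threshold
#'
#' Scores at or above the threshold classify as case (AR).
#'
#' @param scores probabilities of case.
#' @param labels AR/NR labels.
#' @param threshold decision threshold (default 0.5).
#' @return named vector: error, sensitivity, specificity.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  case <- is_case(labels)
  pred <- scores >= threshold
  tp <- sum(pred & case); fn <- sum(!pred & case)
  tn <- sum(!pred & !case); fp <- sum(pred & !case)
  c(error = (fp + fn) / length(scores),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

fold_metrics <- function(scores, labels) {
  cm <- confusion_metrics(scores, labels)
  c(auc = auc(scores, labels), cm)
}

# All four metrics for every column of a samples x grid probability matrix;
# vectorized because this sits inside the fold x grid x combination loop.
fold_metrics_cols <- function(probs, labels) {
  case <- is_case(labels)
  n1 <- sum(case); n2 <- sum(!case)
  G <- ncol(probs)
  out <- matrix(NA_real_, G, 4, dimnames = list(NULL, METRICS))
  if (n1 == 0 || n2 == 0) return(out)
  pred <- probs >= 0.5
  tp <- colSums(pred & case); fp <- colSums(pred & !case)
  fn <- n1 - tp; tn <- n2 - fp
  ranks <- apply(probs, 2, rank)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = nrow(probs))
  aucs <- (colSums(ranks[case, , drop = FALSE]) - n1 * (n1 + 1) / 2) /
    (n1 * n2)
  out[, "auc"] <- aucs
  out[, "error"] <- (fp + fn) / (n1 + n2)
  out[, "sensitivity"] <- tp / n1
  out[, "specificity"] <- tn / n2
  bad <- colSums(is.na(probs)) > 0
  out[bad, ] <- NA_real_
  out
}

METRICS <- c("auc", "error", "sensitivity", "specificity")
MAXIMIZED <- c(auc = TRUE, error = FALSE, sensitivity = TRUE,
               specificity = TRUE)

# Apply the selection rule to per-grid means and standard errors.
# Grids are ordered most -> least regularized, so the one-SE rule picks the
# earliest index among candidates within one SE of the best.
select_param <- function(means, ses, metric, rule) {
  ok <- which(!is.na(means))
  if (length(ok) == 0) stop("no usable grid value")
  if (MAXIMIZED[[metric]]) {
    best <- ok[which.max(means[ok])]
    if (rule == "extreme") return(best)
    cand <- ok[means[ok] >= means[best] - ses[best]]
  } else {
    best <- ok[which.min(means[ok])]
    if (rule == "extreme") return(best)
    cand <- ok[means[ok] <= means[best] + ses[best]]
  }
  min(cand)
}

# Enumerate (partition, fold) train/test splits of a fold plan.
plan_contexts <- function(plan, labels) {
  ctxs <- list()
  for (p in seq_len(plan$m)) {
    a <- plan$assignments[[p]]
    for (f in seq_len(plan$k)) {
      test <- names(a)[a == f]
      train <- names(a)[a != f]
      ctxs[[length(ctxs) + 1]] <- list(partition = p, fold = f,
                                       train = train, test = test)
    }
  }
  ctxs
}

# Evaluate one classifier over one set of train/test contexts, recomputing
# differential expression and the panel rule inside every training fold.
# Returns per-fold x per-grid metric arrays and per-fold probability
# matrices for every grid value.
eval_contexts <- function(spec, expr, labels, panel_fn, ctxs, seed = 1,
                          de_cache = NULL, panel_cache = NULL,
                          cache_key = NULL) {
  res <- vector("list", length(ctxs))
  for (i in seq_along(ctxs)) {
    ctx <- ctxs[[i]]
    key <- if (!is.null(cache_key)) cache_key(ctx) else NULL
    de <- NULL
    if (!is.null(de_cache) && !is.null(key)) de <- de_cache[[key]]
    if (is.null(de)) {
      de <- moderated_t(expr[, ctx$train, drop = FALSE], labels[ctx$train])
      if (!is.null(de_cache) && !is.null(key)) de_cache[[key]] <- de
    }
    panel <- NULL
    if (!is.null(panel_cache) && !is.null(key)) panel <- panel_cache[[key]]
    if (is.null(panel)) {
      panel <- panel_fn(de, expr[, ctx$train, drop = FALSE],
                        labels[ctx$train])
      if (!is.null(panel_cache) && !is.null(key)) panel_cache[[key]] <- panel
    }
    ids <- panel$feature_ids
    if (length(ids) == 0) {
      res[[i]] <- list(failed = TRUE, reason = "empty panel")
      next
    }
    fdr_order <- NULL
    if (spec$method == "LDA") {  # only LDA consumes the significance order
      fdr_order <- attr(de, "fdr_order")
      if (is.null(fdr_order)) {
        fdr_order <- de$feature_id[de_order(de)]
        if (!is.null(de_cache) && !is.null(key)) {
          attr(de, "fdr_order") <- fdr_order
          de_cache[[key]] <- de
        }
      }
      fdr_order <- fdr_order[fdr_order %in% ids]
    }
    fg <- tryCatch(
      fit_grid_clf(spec, t(expr[ids, ctx$train, drop = FALSE]),
                   factor(labels[ctx$train], c("NR", "AR")),
                   seed = sub_seed(seed, paste0("ctx", i)),
                   fdr_order = fdr_order),
      error = function(e) NULL)
    if (is.null(fg)) {
      res[[i]] <- list(failed = TRUE, reason = "fit failed")
      next
    }
    probs <- fg$predict(t(expr[ids, ctx$test, drop = FALSE]))
    rownames(probs) <- ctx$test
    mets <- fold_metrics_cols(probs, labels[ctx$test])
    # retain summaries only: fits are closures over training data and would
    # dominate memory across thousands of contexts
    res[[i]] <- list(failed = FALSE, grid = fg$grid_keys, metrics = mets,
                     probs = probs, n_panel = length(ids))
  }
  res
}

# Collapse per-fold results into per-grid means and SEs for one metric.
grid_summary <- function(fold_res, metric) {
  ok <- !vapply(fold_res, `[[`, logical(1), "failed")
  if (!any(ok)) stop("all folds failed")
  G <- nrow(fold_res[[which(ok)[1]]]$metrics)
  vals <- vapply(fold_res[ok], function(r) r$metrics[, metric], numeric(G))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = G)
  means <- rowMeans(vals, na.rm = TRUE)
  nf <- rowSums(!is.na(vals))
  ses <- apply(vals, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(nf, 1))
  list(means = means, ses = ses, per_fold = t(vals))
}

new_performance_estimate <- function(per_fold, mode, partial = FALSE,
                                     bias_corrected = NULL) {
  means <- colMeans(per_fold, na.rm = TRUE)
  nf <- colSums(!is.na(per_fold))
  ses <- apply(per_fold, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nf, 1))
  structure(list(metrics = means, se = ses, per_fold = per_fold,
                 mode = mode, partial = partial,
                 bias_corrected = bias_corrected),
            class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("<%s CV estimate over %d folds%s>\n", x$mode,
              nrow(x$per_fold), if (x$partial) ", partial" else ""))
  print(round(rbind(mean = x$metrics, se = x$se), 4))
  invisible(x)
}

#' Flat cross-validated tuning with extreme-value or one-SE selection
#'
#' For each grid value the chosen metric is averaged over all k * m held-out
#' folds; differential expression and the panel rule are recomputed inside
#' every training fold (no leakage). The extreme rule picks the best mean;
#' the one-SE rule picks the most regularized grid value whose mean is
#' within one standard error of the best.
#'
#' @param spec a [classifier_spec()].
#' @param expr analysis expression matrix (features x samples).
#' @param labels AR/NR labels.
#' @param panel_fn function `(de, expr_train, labels_train) -> marker_panel`.
#' @param plan a [make_folds()] plan.
#' @param metric one of auc, error, sensitivity, specificity.
#' @param rule `"one_se"` or `"extreme"`.
#' @param seed seed for stochastic learners.
#' @return list of class `flat_cv`: selected parameter and index, the
#'   flat-CV `performance_estimate` at the selection, bias-corrected values,
#'   per-grid summaries and retained per-fold results.
#' @export
tune_flat <- function(spec, expr, labels, panel_fn, plan, metric = "auc",
                      rule = c("one_se", "extreme"), seed = 1) {
  rule <- match.arg(rule)
  metric <- match.arg(metric, METRICS)
  labels <- check_labels(labels, colnames(expr))
  ctxs <- plan_contexts(plan, labels)
  fold_res <- eval_contexts(spec, expr, labels, panel_fn, ctxs, seed = seed)
  flat_from_folds(spec, fold_res, metric, rule, ctxs)
}

flat_from_folds <- function(spec, fold_res, metric, rule, ctxs) {
  ok <- !vapply(fold_res, `[[`, logical(1), "failed")
  gs <- grid_summary(fold_res, metric)
  sel <- select_param(gs$means, gs$ses, metric, rule)
  grid <- fold_res[[which(ok)[1]]]$grid
  per_fold <- t(vapply(fold_res, function(r) {
    if (r$failed) rep(NA_real_, 4) else r$metrics[sel, ]
  }, numeric(4)))
  colnames(per_fold) <- METRICS
  bc <- bias_correct_all(fold_res, sel)
  est <- new_performance_estimate(per_fold, mode = "flat",
                                  partial = any(!ok), bias_corrected = bc)
  structure(list(spec = spec, selected_index = sel,
                 selected_param = grid[sel], grid = grid,
                 metric = metric, rule = rule, estimate = est,
                 grid_means = gs$means, grid_ses = gs$ses,
                 fold_res = fold_res, ctxs = ctxs),
            class = "flat_cv")
}

#' Optimism bias correction for cross-validated selection
#'
#' Estimates the selection-induced optimism as the mean over folds of the
#' difference between each fold's best grid value and the overall selection,
#' and shifts the flat estimate towards pessimism: corrected = estimate - B
#' for maximized metrics (AUC, sensitivity, specificity), corrected =
#' estimate + B for error, with B clipped at zero from below.
#'
#' @param fold_grid_metrics folds x grid matrix of a single metric.
#' @param selected_index index of the overall selection in the grid.
#' @param metric metric name (fixes the orientation).
#' @return list with `optimism` and `corrected` applied to the flat mean.
#' @export
bias_correct <- function(fold_grid_metrics, selected_index, metric = "auc") {
  metric <- match.arg(metric, METRICS)
  m <- fold_grid_metrics
  if (any(is.na(m))) stop("missing fold entries in grid metrics")
  at_sel <- m[, selected_index]
  if (MAXIMIZED[[metric]]) {
    best <- apply(m, 1, max)
    b <- max(mean(best - at_sel), 0)
    list(optimism = b, corrected = mean(at_sel) - b)
  } else {
    best <- apply(m, 1, min)
    b <- max(mean(at_sel - best), 0)
    list(optimism = b, corrected = mean(at_sel) + b)
  }
}

bias_correct_all <- function(fold_res, sel) {
  ok <- !vapply(fold_res, `[[`, logical(1), "failed")
  out <- list()
  for (met in METRICS) {
    vals <- t(vapply(fold_res[ok], function(r) r$metrics[, met],
                     numeric(nrow(fold_res[[which(ok)[1]]]$metrics))))
    if (any(is.na(vals))) { out[[met]] <- list(optimism = NA_real_,
                                               corrected = NA_real_); next }
    out[[met]] <- bias_correct(vals, sel, met)
  }
  out
}

#' Multiple-partition nested cross-validation
#'
#' Per outer fold, tuning runs entirely on the outer-training samples using
#' an inner stratified fold plan; the model trained at the inner selection is
#' then scored on the outer test fold. k * m outer-fold metrics are
#' aggregated. Methods without a tuning grid (RF) skip the inner loop, so
#' their flat and nested estimates coincide.
#'
#' @inheritParams tune_flat
#' @param inner_k,inner_m inner fold plan shape (default 8 folds, 1
#'   partition).
#' @return list of class `nested_cv`: the nested `performance_estimate`,
#'   per-outer-fold selected parameters, and the per-sample outer-fold
#'   scores averaged over partitions.
#' @export
nested_cv <- function(spec, expr, labels, panel_fn, plan, inner_k = 8,
                      inner_m = 1, metric = "auc",
                      rule = c("one_se", "extreme"), seed = 1,
                      flat = NULL) {
  rule <- match.arg(rule)
  metric <- match.arg(metric, METRICS)
  labels <- check_labels(labels, colnames(expr))
  if (is.null(flat))
    flat <- tune_flat(spec, expr, labels, panel_fn, plan, metric, rule,
                      seed = seed)
  ctxs <- flat$ctxs
  fold_res <- flat$fold_res
  n_grid <- length(flat$grid)
  sel_by_fold <- integer(length(ctxs))
  per_fold <- matrix(NA_real_, length(ctxs), 4,
                     dimnames = list(NULL, METRICS))
  scores <- matrix(NA_real_, length(labels), plan_m(ctxs),
                   dimnames = list(names(labels), NULL))
  partial <- FALSE
  for (i in seq_along(ctxs)) {
    ctx <- ctxs[[i]]
    r <- fold_res[[i]]
    if (r$failed) { partial <- TRUE; next }
    if (n_grid <= 1) {
      sel <- 1L
    } else {
      inner_plan <- make_folds(labels[ctx$train], k = inner_k, m = inner_m,
                               seed = sub_seed(seed, paste0(
                                 "inner", ctx$partition, ".", ctx$fold)))
      inner_ctxs <- plan_contexts(inner_plan, labels[ctx$train])
      inner_res <- eval_contexts(spec, expr[, ctx$train, drop = FALSE],
                                 labels[ctx$train], panel_fn, inner_ctxs,
                                 seed = sub_seed(seed, paste0("in", i)))
      okc <- !vapply(inner_res, `[[`, logical(1), "failed")
      if (!any(okc)) { partial <- TRUE; next }
      gsm <- grid_summary(inner_res, metric)
      sel <- select_param(gsm$means, gsm$ses, metric, rule)
    }
    sel_by_fold[i] <- sel
    per_fold[i, ] <- r$metrics[sel, ]
    scores[rownames(r$probs), ctx$partition] <- r$probs[, sel]
  }
  est <- new_performance_estimate(per_fold, mode = "nested",
                                  partial = partial)
  structure(list(spec = spec, estimate = est, selected_by_fold = sel_by_fold,
                 scores = rowMeans(scores, na.rm = TRUE),
                 scores_by_partition = scores, metric = metric, rule = rule),
            class = "nested_cv")
}

plan_m <- function(ctxs) max(vapply(ctxs, `[[`, integer(1), "partition"))
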