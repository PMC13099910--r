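# Full factorial evaluation: pre-filters x ranking rules x classifiers,
# each combination assessed by flat (tuning) and nested (unbiased)
# multiple-partition stratified 8-fold cross-validation. This is the
# package's top-level fit; it returns a classed object with print, summary
# and plot methods.

#' Evaluate the full pre-filter x ranking-rule x classifier grid
#'
#' For every combination, a flat multi-partition CV tunes the classifier's
#' single parameter (one-SE rule on the chosen metric by default), a nested
#' CV re-tunes inside every outer training fold for unbiased performance
#' estimation, the optimism bias correction is computed from the flat fold x
#' grid metrics, and a final model is trained on all samples at the
#' flat-selected parameter. Differential expression and panel rules are
#' recomputed inside every training fold; pre-filters are label-blind and
#' applied once, up front. Per-sample held-out probabilities (averaged over
#' partitions) are collected for both CV modes.
#'
#' @param expr probe-set expression matrix (features x samples).
#' @param labels named AR/NR labels.
#' @param probes optional probe-level collection (needed for the PVAC and
#'   FARMS pre-filters).
#' @param annotation optional feature annotation (needed for PROOF1).
#' @param prefilters character vector of pre-filter names, or a pre-computed
#'   named list of `prefilter_result` objects.
#' @param rules named list of panel rule functions
#'   (default [standard_rules()]).
#' @param specs named list of [classifier_spec()] objects
#'   (default [default_grids()]).
#' @param k,m outer fold plan shape (default 8-fold, 5 partitions).
#' @param inner_k,inner_m inner (nested tuning) plan shape.
#' @param metric,rule selection metric and rule (default max AUC, one-SE).
#' @param seed master seed.
#' @param verbose print progress.
#' @return object of class `marker_grid`; see [summary.marker_grid()].
#' @export
marker_grid <- function(expr, labels, probes = NULL, annotation = NULL,
                        prefilters = c("ECMR", "PVAC", "BI2005", "FARMS",
                                       "PROOF1"),
                        rules = standard_rules(), specs = default_grids(),
                        k = 8, m = 5, inner_k = 8, inner_m = 1,
                        metric = "auc", rule = c("one_se", "extreme"),
                        seed = 1, verbose = FALSE) {
  rule <- match.arg(rule)
  metric <- match.arg(metric, METRICS)
  check_expr_matrix(expr)
  labels <- check_labels(labels, colnames(expr))

  pf_results <- resolve_prefilters(prefilters, expr, probes, annotation,
                                   labels)
  plan <- make_folds(labels, k = k, m = m, seed = sub_seed(seed, "outer"))
  ctxs <- plan_contexts(plan, labels)
  # inner plans are shared across pre-filters, rules and classifiers
  inner_ctxs <- lapply(seq_along(ctxs), function(i) {
    ctx <- ctxs[[i]]
    ip <- make_folds(labels[ctx$train], k = inner_k, m = inner_m,
                     seed = sub_seed(seed, paste0("inner", ctx$partition,
                                                  ".", ctx$fold)))
    plan_contexts(ip, labels[ctx$train])
  })

  rows <- list(); panels_out <- list()
  nsamp <- length(labels)
  n_combo <- length(pf_results) * length(rules) * length(specs)
  scores_nested <- matrix(NA_real_, nsamp, 0)
  scores_flat <- matrix(NA_real_, nsamp, 0)
  failures <- character(0)

  for (pf_name in names(pf_results)) {
    pf <- pf_results[[pf_name]]
    base_expr <- if (!is.null(pf$expr)) pf$expr else expr
    dataf <- base_expr[pf$retained_ids, , drop = FALSE]
    de_cache <- new.env(parent = emptyenv())
    de_full <- moderated_t(dataf, labels)
    for (rule_name in names(rules)) {
      panel_fn <- rules[[rule_name]]
      panel_cache <- new.env(parent = emptyenv())
      panel_full <- tryCatch(panel_fn(de_full, dataf, labels),
                             error = function(e) NULL)
      for (spec_name in names(specs)) {
        spec <- specs[[spec_name]]
        combo <- paste(pf_name, rule_name, spec$method, sep = "|")
        if (verbose) message(combo)
        res <- tryCatch(
          eval_one_combo(spec, dataf, labels, panel_fn, ctxs, inner_ctxs,
                         metric, rule, seed, de_cache, panel_cache),
          error = function(e) conditionMessage(e))
        if (is.character(res)) {
          failures <- c(failures, stats::setNames(res, combo))
          rows[[combo]] <- combo_row(pf_name, rule_name, spec$method)
          scores_nested <- cbind(scores_nested, NA_real_)
          scores_flat <- cbind(scores_flat, NA_real_)
          next
        }
        final <- NULL
        if (!is.null(panel_full) && length(panel_full$feature_ids) > 0)
          final <- tryCatch(
            train_classifier(spec, dataf, labels, panel_full,
                             param_value = res$flat$selected_param,
                             seed = sub_seed(seed, combo),
                             fdr_order = de_full$feature_id[de_order(de_full)]),
            error = function(e) NULL)
        rows[[combo]] <- combo_row(
          pf_name, rule_name, spec$method,
          n_prefilter = length(pf$retained_ids),
          n_panel = if (!is.null(panel_full)) length(panel_full$feature_ids)
          else NA_integer_,
          n_selected = if (!is.null(final))
            length(final$selected_feature_ids) else NA_integer_,
          selected_param = if (length(spec$grid)) res$flat$selected_param
          else NA_real_,
          flat = res$flat$estimate, nested = res$nested_est,
          bias = res$flat$estimate$bias_corrected)
        panels_out[[combo]] <- if (!is.null(final))
          final$selected_feature_ids else character(0)
        scores_nested <- cbind(scores_nested, res$nested_scores)
        scores_flat <- cbind(scores_flat, res$flat_scores)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  colnames(scores_nested) <- results$combination
  colnames(scores_flat) <- results$combination
  rownames(scores_nested) <- rownames(scores_flat) <- names(labels)
  structure(list(results = results, scores_nested = scores_nested,
                 scores_flat = scores_flat, panels = panels_out,
                 labels = labels, plan = plan,
                 prefilter_sizes = vapply(pf_results, function(p)
                   length(p$retained_ids), integer(1)),
                 metric = metric, rule = rule, seed = seed,
                 failures = failures, n_combinations = n_combo),
            class = "marker_grid")
}

#' @rdname marker_grid
#' @export
run_grid <- marker_grid

resolve_prefilters <- function(prefilters, expr, probes, annotation,
                               labels) {
  if (is.list(prefilters)) return(prefilters)
  out <- list()
  for (pf in prefilters) {
    out[[pf]] <- switch(
      pf,
      ECMR = ecmr(expr),
      BI2005 = bi2005(expr),
      PVAC = pvac(probes),
      FARMS = farms(probes),
      PROOF1 = proof1(expr, annotation, labels = labels),
      stop(sprintf("unknown pre-filter '%s'", pf)))
  }
  out
}

# Flat + nested evaluation of one combination, sharing DE and panel caches.
eval_one_combo <- function(spec, dataf, labels, panel_fn, ctxs, inner_ctxs,
                           metric, rule, seed, de_cache, panel_cache) {
  outer_res <- eval_contexts(spec, dataf, labels, panel_fn, ctxs,
                             seed = seed, de_cache = de_cache,
                             panel_cache = panel_cache,
                             cache_key = function(ctx)
                               paste0("o", ctx$partition, ".", ctx$fold))
  flat <- flat_from_folds(spec, outer_res, metric, rule, ctxs)
  n_grid <- length(flat$grid)
  nsamp <- length(labels)
  m <- plan_m(ctxs)
  nested_pf <- matrix(NA_real_, length(ctxs), 4,
                      dimnames = list(NULL, METRICS))
  sc_nested <- matrix(NA_real_, nsamp, m,
                      dimnames = list(names(labels), NULL))
  sc_flat <- matrix(NA_real_, nsamp, m, dimnames = list(names(labels), NULL))
  partial <- FALSE
  for (i in seq_along(ctxs)) {
    ctx <- ctxs[[i]]
    r <- outer_res[[i]]
    if (r$failed) { partial <- TRUE; next }
    sc_flat[rownames(r$probs), ctx$partition] <-
      r$probs[, flat$selected_index]
    if (n_grid <= 1) {
      sel <- 1L
    } else {
      inner_res <- eval_contexts(
        spec, dataf[, ctx$train, drop = FALSE], labels[ctx$train], panel_fn,
        inner_ctxs[[i]], seed = sub_seed(seed, paste0("in", i)),
        de_cache = de_cache, panel_cache = panel_cache,
        cache_key = function(ic) paste0("i", i, ".", ic$partition, ".",
                                        ic$fold))
      okc <- !vapply(inner_res, `[[`, logical(1), "failed")
      if (!any(okc)) { partial <- TRUE; next }
      gsm <- grid_summary(inner_res, metric)
      sel <- select_param(gsm$means, gsm$ses, metric, rule)
    }
    nested_pf[i, ] <- r$metrics[sel, ]
    sc_nested[rownames(r$probs), ctx$partition] <- r$probs[, sel]
  }
  nested_est <- new_performance_estimate(nested_pf, mode = "nested",
                                         partial = partial)
  list(flat = flat, nested_est = nested_est,
       nested_scores = rowMeans(sc_nested, na.rm = TRUE),
       flat_scores = rowMeans(sc_flat, na.rm = TRUE))
}

combo_row <- function(prefilter, rule, method, n_prefilter = NA_integer_,
                      n_panel = NA_integer_, n_selected = NA_integer_,
                      selected_param = NA_real_, flat = NULL, nested = NULL,
                      bias = NULL) {
  row <- data.frame(
    combination = paste(prefilter, rule, method, sep = "|"),
    prefilter = prefilter, rule = rule, classifier = method,
    n_prefilter = n_prefilter, n_panel = n_panel, n_selected = n_selected,
    selected_param = selected_param, stringsAsFactors = FALSE)
  for (met in METRICS) {
    row[[paste0("flat_", met)]] <- if (!is.null(flat))
      unname(flat$metrics[met]) else NA_real_
    row[[paste0("nested_", met)]] <- if (!is.null(nested))
      unname(nested$metrics[met]) else NA_real_
    row[[paste0("corrected_", met)]] <- if (!is.null(bias))
      bias[[met]]$corrected else NA_real_
  }
  row$flat_se_auc <- if (!is.null(flat)) unname(flat$se["auc"]) else NA_real_
  row$nested_se_auc <- if (!is.null(nested)) unname(nested$se["auc"])
  else NA_real_
  row
}

#' @export
print.marker_grid <- function(x, ...) {
  cat(sprintf("<marker_grid> %d combinations (%d pre-filters x %d rules x %d classifiers implied), %d samples\n",
              nrow(x$results), length(unique(x$results$prefilter)),
              length(unique(x$results$rule)),
              length(unique(x$results$classifier)), nrow(x$scores_nested)))
  cat(sprintf("selection: max %s, %s rule; %d partitions x %d folds\n",
              x$metric, x$rule, x$plan$m, x$plan$k))
  if (length(x$failures))
    cat(sprintf("%d combination(s) failed\n", length(x$failures)))
  ok <- !is.na(x$results$nested_auc)
  if (any(ok))
    cat(sprintf("nested AUC: median %.3f, range %.3f-%.3f\n",
                stats::median(x$results$nested_auc[ok]),
                min(x$results$nested_auc[ok]),
                max(x$results$nested_auc[ok])))
  invisible(x)
}

#' Summarize a marker grid by pre-filter and classifier
#'
#' @param object a `marker_grid`.
#' @param ... unused.
#' @return list with the per-combination table and mean nested/flat AUC by
#'   pre-filter and by classifier.
#' @export
summary.marker_grid <- function(object, ...) {
  r <- object$results
  by_pf <- stats::aggregate(cbind(nested_auc, flat_auc) ~ prefilter,
                            data = r, FUN = mean, na.rm = TRUE)
  by_clf <- stats::aggregate(cbind(nested_auc, flat_auc) ~ classifier,
                             data = r, FUN = mean, na.rm = TRUE)
  out <- list(results = r, by_prefilter = by_pf, by_classifier = by_clf,
              mean_optimism = mean(r$flat_auc - r$nested_auc, na.rm = TRUE))
  class(out) <- "summary.marker_grid"
  out
}

#' @export
print.summary.marker_grid <- function(x, ...) {
  cat("Mean AUC by pre-filter:\n"); print(x$by_prefilter, digits = 3)
  cat("Mean AUC by classifier:\n"); print(x$by_classifier, digits = 3)
  cat(sprintf("Mean flat - nested AUC (optimism): %.4f\n", x$mean_optimism))
  invisible(x)
}

#' Plot nested-CV AUC by combination
#'
#' Base-graphics strip of nested AUC per combination, colored by pre-filter,
#' in the spirit of grid performance comparisons.
#'
#' @param x a `marker_grid`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.marker_grid <- function(x, ...) {
  r <- x$results
  pf <- factor(r$prefilter, unique(r$prefilter))
  graphics::plot(seq_len(nrow(r)), r$nested_auc, col = as.integer(pf),
                 pch = 19, xlab = "method combination",
                 ylab = "nested CV AUC", ...)
  graphics::legend("bottomleft", legend = levels(pf),
                   col = seq_along(levels(pf)), pch = 19, cex = 0.8)
  invisible(x)
}
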