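# The five ranking-and-filtering rules producing candidate feature panels
# from a differential-expression table (plus expression data for the
# SVM-weight step). FDR cuts are strict (<); fold-change cuts inclusive (>=).

new_panel <- function(rule, ids, provenance) {
  structure(list(rule = rule, feature_ids = ids, provenance = provenance),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<panel %s>: %d features\n", x$rule, length(x$feature_ids)))
  invisible(x)
}

# Canonical significance order: fdr ascending, then p ascending, then
# |logFC| descending, then feature id.
de_order <- function(de) {
  order(de$fdr, de$p, -abs(de$logFC), de$feature_id)
}

#' FDR50 rule: top 50 features by FDR
#'
#' @param de a `de_result`.
#' @param top panel size cap.
#' @return a `marker_panel`.
#' @export
rule_fdr50 <- function(de, top = 50) {
  if (nrow(de) == 0) stop("empty differential-expression table")
  ids <- de$feature_id[de_order(de)]
  ids <- ids[seq_len(min(top, length(ids)))]
  new_panel("FDR50", ids, list(top = top, n_input = nrow(de)))
}

#' COMBO rule: FDR cut with enforced minimum and maximum panel size
#'
#' Starts from all features with fdr < `fdr_cut`, pads with the
#' next-most-significant features up to `min_n`, and truncates to the
#' `max_n` most significant.
#'
#' @param de a `de_result`.
#' @param fdr_cut,min_n,max_n rule parameters.
#' @return a `marker_panel`.
#' @export
rule_combo <- function(de, fdr_cut = 0.05, min_n = 50, max_n = 500) {
  if (nrow(de) == 0) stop("empty differential-expression table")
  ord <- de_order(de)
  ids <- de$feature_id[ord]
  n_pass <- sum(de$fdr < fdr_cut)
  n_take <- min(max(n_pass, min_n), max_n, length(ids))
  new_panel("COMBO0.05", ids[seq_len(n_take)],
            list(fdr_cut = fdr_cut, min_n = min_n, max_n = max_n,
                 n_pass = n_pass, n_input = nrow(de)))
}

#' FDR + fold-change rule
#'
#' Features with fdr < `fdr_cut` and |logFC| >= `lfc_cut` (boundary
#' inclusive), ordered by significance.
#'
#' @param de a `de_result`.
#' @param fdr_cut,lfc_cut rule parameters.
#' @return a `marker_panel` (possibly empty).
#' @export
rule_fdr_fc <- function(de, fdr_cut = 0.10, lfc_cut = 0.5) {
  if (nrow(de) == 0) stop("empty differential-expression table")
  keep <- de$fdr < fdr_cut & (de$logFC >= lfc_cut | de$logFC <= -lfc_cut)
  sub <- de[keep, , drop = FALSE]
  ids <- sub$feature_id[de_order(sub)]
  new_panel("FDR0.10.FC0.5", ids,
            list(fdr_cut = fdr_cut, lfc_cut = lfc_cut,
                 n_pass = length(ids), n_input = nrow(de)))
}

#' Fold-change filter followed by top-50-by-FDR rule
#'
#' @param de a `de_result`.
#' @param lfc_cut absolute log2 fold-change threshold (inclusive).
#' @param top panel size cap (fewer accepted if fewer pass the FC filter).
#' @return a `marker_panel`.
#' @export
rule_fc_top50 <- function(de, lfc_cut = 0.5, top = 50) {
  if (nrow(de) == 0) stop("empty differential-expression table")
  sub <- de[abs(de$logFC) >= lfc_cut, , drop = FALSE]
  ids <- sub$feature_id[de_order(sub)]
  ids <- ids[seq_len(min(top, length(ids)))]
  new_panel("FC0.5.TOP50", ids,
            list(lfc_cut = lfc_cut, top = top,
                 n_fc_pass = nrow(sub), n_input = nrow(de)))
}

#' FDR filter followed by one-shot SVM-weight reduction
#'
#' Restricts the expression data to features with fdr < `fdr_cut`,
#' standardizes each feature on the supplied (training) samples, fits a
#' linear-kernel soft-margin SVM at the given cost, and keeps the `top`
#' features with the largest absolute weight (all of them when no more than
#' `top` pass the FDR filter). The reduction is one-shot, not iterative.
#'
#' @param de a `de_result` computed on the same training samples.
#' @param expr expression matrix (training samples only).
#' @param labels AR/NR labels for the training samples.
#' @param fdr_cut,top,cost rule parameters.
#' @return a `marker_panel`, ordered by decreasing weight (ties by fdr then
#'   id).
#' @export
rule_fdr_rfe50 <- function(de, expr, labels, fdr_cut = 0.10, top = 50,
                           cost = 1) {
  if (nrow(de) == 0) stop("empty differential-expression table")
  labels <- check_labels(labels, colnames(expr))
  if (length(unique(labels)) < 2) stop("both classes required")
  keep <- de$feature_id[de$fdr < fdr_cut]
  if (length(keep) == 0)
    return(new_panel("FDR0.10.RFE50", character(0),
                     list(fdr_cut = fdr_cut, top = top, cost = cost,
                          n_pass = 0, n_input = nrow(de))))
  x <- t(expr[keep, , drop = FALSE])
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  y <- factor(labels, levels = c("NR", "AR"))
  fit <- tryCatch(
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
               type = "C-classification"),
    error = function(e) stop("SVM fit failed in RFE step: ",
                             conditionMessage(e)))
  w <- abs(as.numeric(crossprod(fit$coefs, fit$SV)))
  names(w) <- colnames(x)
  sub <- de[match(keep, de$feature_id), ]
  ord <- order(-w, sub$fdr, sub$feature_id)
  ids <- keep[ord][seq_len(min(top, length(keep)))]
  new_panel("FDR0.10.RFE50", ids,
            list(fdr_cut = fdr_cut, top = top, cost = cost,
                 n_pass = length(keep), n_input = nrow(de),
                 weights = w[ids]))
}

#' The five standard ranking rules as panel functions
#'
#' Each element is a function `(de, expr, labels) -> marker_panel`, the
#' signature the cross-validation engine expects (the expression matrix and
#' labels are those of the training samples only).
#'
#' @return named list of panel rule functions.
#' @export
standard_rules <- function() {
  list(
    FDR50 = function(de, expr, labels) rule_fdr50(de),
    COMBO0.05 = function(de, expr, labels) rule_combo(de),
    FDR0.10.FC0.5 = function(de, expr, labels) rule_fdr_fc(de),
    FC0.5.TOP50 = function(de, expr, labels) rule_fc_top50(de),
    FDR0.10.RFE50 = function(de, expr, labels)
      rule_fdr_rfe50(de, expr, labels))
}
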