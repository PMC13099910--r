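# Cross-panel aggregation and reporting: feature-inclusion matrices,
# frequency filters, gene-level summary tables, classifier score-matrix
# summaries and hypergeometric gene-set enrichment.

#' Binary feature-inclusion matrix over classifier panels
#'
#' Rows are the union of all panel members (features never selected are
#' absent), columns the combinations; a cell is 1 when the feature is in
#' that combination's final model (post-classifier selection where the
#' method selects features, otherwise the rule panel).
#'
#' @param panels named list of character vectors (final feature ids per
#'   combination).
#' @return list of class `inclusion_matrix`: `matrix` (0/1), `count`,
#'   `fraction`, `n_combinations`.
#' @export
build_inclusion <- function(panels) {
  if (length(panels) == 0) stop("need at least one panel")
  feats <- sort(unique(unlist(panels)))
  m <- vapply(panels, function(p) as.integer(feats %in% p),
              integer(length(feats)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(feats))
  rownames(m) <- feats
  colnames(m) <- names(panels)
  count <- rowSums(m)
  keep <- count >= 1
  m <- m[keep, , drop = FALSE]
  count <- count[keep]
  structure(list(matrix = m, count = count,
                 fraction = count / length(panels),
                 n_combinations = length(panels)),
            class = "inclusion_matrix")
}

#' Frequency filter on an inclusion matrix
#'
#' @param incl an `inclusion_matrix`.
#' @param min_fraction minimum inclusion fraction (inclusive).
#' @return feature ids ordered by count descending, then id.
#' @export
frequency_filter <- function(incl, min_fraction = 0.25) {
  keep <- incl$fraction >= min_fraction
  ids <- names(incl$count)[keep]
  ids[order(-incl$count[keep], ids)]
}

#' Gene-level summary of the most frequently selected features
#'
#' One row per feature in the inclusion matrix: gene symbol and title
#' (unannotated features reported as "---"), group means, natural-scale
#' fold-change magnitude and direction, and the inclusion count and
#' fraction, ordered by count descending.
#'
#' @param incl an `inclusion_matrix`.
#' @param de a `de_result` providing group means.
#' @param annotation feature annotation table.
#' @return data frame.
#' @export
gene_summary <- function(incl, de, annotation) {
  ids <- names(incl$count)
  if (length(ids) == 0)
    return(data.frame(feature_id = character(0)))
  dei <- de[match(ids, de$feature_id), ]
  ann <- annotation[match(ids, annotation$feature_id), ]
  fc <- fold_change_from_means(dei$mean_case, dei$mean_control)
  out <- data.frame(
    feature_id = ids,
    gene_symbol = ifelse(is.na(ann$gene_symbol), "---", ann$gene_symbol),
    gene_title = ifelse(is.na(ann$gene_title), "---", ann$gene_title),
    mean_case = dei$mean_case, mean_control = dei$mean_control,
    fold_change = fc$magnitude, direction = fc$direction,
    count = unname(incl$count), fraction = unname(incl$fraction),
    stringsAsFactors = FALSE)
  out[order(-out$count, out$feature_id), , drop = FALSE]
}

#' Per-sample and per-combination score summaries
#'
#' Summarizes a samples x combinations probability matrix: per-sample
#' median and IQR across combinations, discordance flags (samples whose
#' median falls on the wrong side of 0.5 for their class), and
#' per-combination score distributions in long format for plotting.
#'
#' @param score_matrix samples x combinations probabilities of case.
#' @param labels AR/NR labels for the rows.
#' @return list with `per_sample` (data frame) and `long` (sample,
#'   combination, score).
#' @export
score_summaries <- function(score_matrix, labels) {
  labels <- check_labels(labels, rownames(score_matrix))
  med <- apply(score_matrix, 1, stats::median, na.rm = TRUE)
  iqr <- apply(score_matrix, 1, stats::IQR, na.rm = TRUE)
  discordant <- ifelse(is_case(labels), med < 0.5, med >= 0.5)
  # exact-boundary medians are not discordant for controls scored at 0.5
  discordant[!is_case(labels) & med == 0.5] <- FALSE
  discordant[is_case(labels) & med == 0.5] <- FALSE
  per_sample <- data.frame(sample_id = rownames(score_matrix),
                           class = as.character(labels), median = med,
                           iqr = iqr, discordant = discordant,
                           stringsAsFactors = FALSE)
  long <- data.frame(
    sample_id = rep(rownames(score_matrix), times = ncol(score_matrix)),
    combination = rep(colnames(score_matrix), each = nrow(score_matrix)),
    score = as.numeric(score_matrix), stringsAsFactors = FALSE)
  list(per_sample = per_sample, long = long)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, p is the upper-tail hypergeometric probability of
#' observing at least the overlap between the candidate list and the set
#' when drawing the list from the universe. The gene ratio is the overlap
#' divided by the number of candidate genes mapped to any set.
#' Benjamini-Hochberg correction is applied across the tested sets.
#'
#' @param gene_list candidate gene symbols.
#' @param universe background gene symbols (must contain the list).
#' @param sets named list of gene sets; members outside the universe are
#'   ignored.
#' @param min_size sets with fewer in-universe members are skipped.
#' @return data frame: set, overlap k, set size K, list size n, universe
#'   size N, gene_ratio, p, fdr; ordered by p.
#' @export
enrich <- function(gene_list, universe, sets, min_size = 1) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!all(gene_list %in% universe))
    stop("gene list contains genes outside the universe")
  if (length(gene_list) == 0) stop("empty candidate gene list")
  sets_u <- lapply(sets, intersect, universe)
  sizes <- vapply(sets_u, length, integer(1))
  keep <- sizes >= min_size
  sets_u <- sets_u[keep]
  n_any <- length(intersect(gene_list, unique(unlist(sets_u))))
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(sets_u), function(nm) {
    K <- length(sets_u[[nm]])
    k <- length(intersect(gene_list, sets_u[[nm]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = n,
               universe_size = N,
               gene_ratio = if (n_any > 0) k / n_any else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}
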