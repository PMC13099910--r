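# Five unsupervised (label-blind) pre-filtering strategies, each reducing
# the feature space before any class comparison, plus overlap accounting.
#
# ECMR   - retain the half of features with the largest inter-quartile range.
# BI2005 - clamp log2 values below 5 up to 5, keep features whose clamped
#          maximum is at least 7.25.
# PVAC   - probe-consistency filter: share of a probe-set block's
#          (row-centered) variance captured by its first principal direction.
# FARMS  - informative/non-informative call from a penalized one-factor
#          model of the probe-level block (surrogate for the Bayesian
#          factor-analysis original; same selection contract).
# PROOF1 - ordered conjunction of configurable rules (expression cutoff,
#          annotation whitelist, within-class robustness).

new_prefilter_result <- function(method, retained, scores, params,
                                 expr = NULL) {
  structure(list(method = method, retained_ids = retained, scores = scores,
                 params = params, expr = expr),
            class = "prefilter_result")
}

#' @export
print.prefilter_result <- function(x, ...) {
  cat(sprintf("<prefilter %s>: %d features retained\n",
              x$method, length(x$retained_ids)))
  invisible(x)
}

#' ECMR pre-filter: largest inter-quartile range
#'
#' Computes the per-feature IQR over all samples (classes pooled) and keeps
#' the `floor(retain_fraction * N)` features with the largest IQR. Ties are
#' broken by lexicographic feature id.
#'
#' @param expr expression matrix, features x samples.
#' @param retain_fraction fraction of features to keep.
#' @return a `prefilter_result`.
#' @export
ecmr <- function(expr, retain_fraction = 0.5) {
  check_expr_matrix(expr)
  if (ncol(expr) < 4) stop("ECMR needs at least 4 samples for a usable IQR")
  q <- apply(expr, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  iqr <- q[2, ] - q[1, ]
  names(iqr) <- rownames(expr)
  n_keep <- floor(retain_fraction * nrow(expr))
  ord <- order(-iqr, rownames(expr))
  retained <- rownames(expr)[ord][seq_len(n_keep)]
  new_prefilter_result("ECMR", retained, iqr,
                       list(retain_fraction = retain_fraction))
}

#' BI2005 pre-filter: intensity clamp and maximum-expression threshold
#'
#' Values below `clamp_floor` are raised to the floor; features whose
#' post-clamp maximum is at least `max_threshold` (boundary inclusive) are
#' retained. The clamped matrix is carried in the result (`$expr`) and is the
#' analysis data set for this arm.
#'
#' @param expr expression matrix.
#' @param clamp_floor,max_threshold log2 thresholds.
#' @return a `prefilter_result` with the clamped matrix in `$expr`.
#' @export
bi2005 <- function(expr, clamp_floor = 5, max_threshold = 7.25) {
  check_expr_matrix(expr)
  clamped <- pmax(expr, clamp_floor)
  mx <- apply(clamped, 1, max)
  retained <- rownames(expr)[mx >= max_threshold]
  new_prefilter_result("BI2005", retained, mx,
                       list(clamp_floor = clamp_floor,
                            max_threshold = max_threshold),
                       expr = clamped)
}

#' PVAC-style probe-consistency score
#'
#' Row-centers the probes x arrays block and returns the proportion of total
#' variance captured by the first principal direction across arrays. A block
#' in which every probe tracks a shared array signal scores near 1; a block
#' of independent probe noise scores near 1/min(probes, arrays).
#'
#' @param block numeric matrix, probes x arrays (>= 2 each).
#' @return consistency score in `[0, 1]`.
#' @export
pvac_score <- function(block) {
  if (!is.matrix(block) || nrow(block) < 2 || ncol(block) < 2)
    stop("pvac_score needs a probe block with >= 2 probes and >= 2 arrays")
  centered <- block - rowMeans(block)
  d <- svd(centered, nu = 0, nv = 0)$d
  tot <- sum(d^2)
  if (tot <= .Machine$double.eps) return(1)
  d[1]^2 / tot
}

#' PVAC pre-filter over a probe-level collection
#'
#' @param probes probe-level collection; required (`pvac` cannot run on
#'   summarized data).
#' @param threshold minimum consistency score to retain a probe-set.
#' @return a `prefilter_result`.
#' @export
pvac <- function(probes, threshold = 0.5) {
  if (is.null(probes) || !inherits(probes, "probe_collection"))
    stop("probe-level data required")
  scores <- vapply(probes$blocks, pvac_score, numeric(1))
  retained <- names(scores)[scores >= threshold]
  retained <- retained[order(retained)]
  new_prefilter_result("PVAC", retained, scores,
                       list(threshold = threshold))
}

#' FARMS-style informativeness score of a probe block
#'
#' Fits a one-factor model value(p, j) = mean_p + loading_p * z_j + noise by
#' alternating least squares with a quadratic (ridge) penalty on the
#' loadings, then scores informativeness as
#' var(loading * z) / (var(loading * z) + mean noise variance).
#' Non-convergence within `max_iter` flags the block non-informative.
#'
#' @param block probes x arrays matrix (>= 2 probes).
#' @param penalty ridge penalty on the loadings.
#' @param max_iter,tol alternating least squares controls.
#' @return informativeness score in `[0, 1)`.
#' @export
farms_score <- function(block, penalty = 0.1, max_iter = 100, tol = 1e-6) {
  if (!is.matrix(block) || nrow(block) < 2)
    stop("farms_score needs a probe block with >= 2 probes")
  y <- block - rowMeans(block)
  np <- nrow(y); na <- ncol(y)
  # init: first right singular vector direction
  z <- as.numeric(svd(y, nu = 0, nv = 1)$v[, 1])
  lam <- rep(0, np)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- sum(z^2) + penalty
    lam_new <- as.numeric(y %*% z) / denom
    l2 <- sum(lam_new^2)
    if (l2 <= .Machine$double.eps) { lam <- lam_new; break }
    z_new <- as.numeric(crossprod(y, lam_new)) / l2
    # fix scale: unit variance factor
    s <- stats::sd(z_new)
    if (s > 0) { z_new <- z_new / s; lam_new <- lam_new * s }
    if (max(abs(lam_new - lam)) < tol) { lam <- lam_new; z <- z_new
      converged <- TRUE; break }
    lam <- lam_new; z <- z_new
  }
  fitted <- outer(lam, z)
  resid <- y - fitted
  sig <- stats::var(as.numeric(fitted))
  noise <- mean(apply(resid, 1, stats::var))
  score <- if (sig + noise <= .Machine$double.eps) 0 else sig / (sig + noise)
  attr(score, "converged") <- converged || it == 1
  score
}

#' FARMS-style informative/non-informative pre-filter
#'
#' @param probes probe-level collection.
#' @param threshold minimum informativeness score.
#' @param ... passed to [farms_score()].
#' @return a `prefilter_result`.
#' @export
farms <- function(probes, threshold = 0.5, ...) {
  if (is.null(probes) || !inherits(probes, "probe_collection"))
    stop("probe-level data required")
  res <- lapply(probes$blocks, farms_score, ...)
  conv <- vapply(res, function(s) isTRUE(attr(s, "converged")), logical(1))
  scores <- vapply(res, as.numeric, numeric(1))
  if (any(!conv)) {
    message(sprintf("farms: %d block(s) did not converge; flagged non-informative",
                    sum(!conv)))
    scores[!conv] <- 0
  }
  retained <- names(scores)[scores >= threshold]
  retained <- retained[order(retained)]
  new_prefilter_result("FARMS", retained, scores,
                       list(threshold = threshold))
}

#' PROOF1 rule-chain pre-filter
#'
#' Applies an ordered conjunction of rules. Built-in rule types:
#' \describe{
#'   \item{expression}{`list(type = "expression", cutoff = c, fraction = f)`:
#'     the fraction of samples with value >= c must be >= f.}
#'   \item{annotation}{`list(type = "annotation", field = ..., allowed = ...)`:
#'     the annotation field must match one of the allowed values; the special
#'     value `"*annotated*"` allows anything except `"---"`.}
#'   \item{robustness}{`list(type = "robustness", cv_limit = L)`: the
#'     per-feature within-class coefficient of variation (sd / |mean|) must
#'     be <= L in every class; requires `labels`.}
#' }
#' The shipped default chain (an expression cutoff at log2 = 9.35 in at least
#' half the samples, plus an annotation requirement) targets a retained
#' fraction near 10 percent on default synthetic cohorts. A time-course
#' criterion is not supported for single-timepoint data.
#'
#' @param expr expression matrix.
#' @param annotation feature annotation table.
#' @param rules list of rule specifications (non-empty).
#' @param labels optional AR/NR labels (needed for robustness rules).
#' @return a `prefilter_result`; `$scores` is the number of rules passed.
#' @export
proof1 <- function(expr, annotation,
                   rules = proof1_default_rules(), labels = NULL) {
  check_expr_matrix(expr)
  if (length(rules) == 0) stop("rule chain must be non-empty")
  pass <- matrix(TRUE, nrow(expr), length(rules),
                 dimnames = list(rownames(expr), NULL))
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    if (is.null(r$type)) stop("rule without a type")
    pass[, k] <- switch(
      r$type,
      expression = {
        frac <- rowMeans(expr >= r$cutoff)
        frac >= r$fraction
      },
      annotation = {
        ann <- annotation[match(rownames(expr), annotation$feature_id),
                          r$field]
        if (identical(r$allowed, "*annotated*")) !is.na(ann) & ann != "---"
        else !is.na(ann) & ann %in% r$allowed
      },
      robustness = {
        if (is.null(labels)) stop("robustness rule requires labels")
        lab <- check_labels(labels, colnames(expr))
        ok <- rep(TRUE, nrow(expr))
        for (cl in unique(lab)) {
          sub <- expr[, lab == cl, drop = FALSE]
          cv <- apply(sub, 1, stats::sd) / pmax(abs(rowMeans(sub)),
                                                .Machine$double.eps)
          ok <- ok & cv <= r$cv_limit
        }
        ok
      },
      stop(sprintf("unknown rule type '%s'", r$type)))
  }
  keep <- rowSums(pass) == length(rules)
  retained <- rownames(expr)[keep]
  new_prefilter_result("PROOF1", retained, rowSums(pass),
                       list(rules = rules))
}

#' @rdname proof1
#' @export
proof1_default_rules <- function() {
  list(list(type = "expression", cutoff = 9.35, fraction = 0.5),
       list(type = "annotation", field = "gene_symbol",
            allowed = "*annotated*"))
}

#' Overlap accounting for a list of pre-filter results
#'
#' @param results list (>= 2) of `prefilter_result` objects.
#' @param universe optional vector of all candidate feature ids; needed for
#'   the excluded-by-all count.
#' @return list with `sizes`, `union_size`, `intersection_size`, `pairwise`
#'   (matrix of pairwise overlap counts), `unique_counts` (per method,
#'   features found nowhere else) and `excluded_by_all`.
#' @export
overlap_table <- function(results, universe = NULL) {
  if (length(results) < 2) stop("need at least two pre-filter results")
  sets <- lapply(results, `[[`, "retained_ids")
  names(sets) <- vapply(results, `[[`, character(1), "method")
  k <- length(sets)
  pairwise <- matrix(NA_integer_, k, k, dimnames = list(names(sets),
                                                        names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  uni <- Reduce(union, sets)
  inter <- Reduce(intersect, sets)
  uniq <- vapply(seq_len(k), function(i)
    length(setdiff(sets[[i]], Reduce(union, sets[-i]))), integer(1))
  names(uniq) <- names(sets)
  excluded <- if (!is.null(universe)) length(setdiff(universe, uni)) else NA_integer_
  list(sizes = vapply(sets, length, integer(1)),
       union_size = length(uni), intersection_size = length(inter),
       pairwise = pairwise, unique_counts = uniq,
       excluded_by_all = excluded)
}
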