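# Moderated two-group differential expression with empirical-Bayes variance
# shrinkage and Benjamini-Hochberg adjustment. Produces the per-feature
# table all ranking rules consume.

# Invert the trigamma function by monotone bisection (trigamma is strictly
# decreasing on (0, Inf)).
trigamma_inverse <- function(y, tol = 1e-8) {
  if (y <= 0) return(Inf)
  lo <- 1e-8; hi <- 1e8
  if (trigamma(lo) < y) return(lo)
  if (trigamma(hi) > y) return(hi)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi - lo < tol * lo) break
  }
  sqrt(lo * hi)
}

# Method-of-moments estimate of the variance prior (d0, s0_2) from residual
# variances s2 on df degrees of freedom: matches the mean and variance of
# log s2 to the moments implied by a scaled F distribution.
estimate_variance_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-12)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  ve <- if (length(e) > 1) stats::var(e) else 0
  rhs <- ve - trigamma(df / 2)
  if (rhs <= 1e-10) {
    d0 <- Inf
    s0_2 <- exp(ebar)
  } else {
    half_d0 <- trigamma_inverse(rhs)
    d0 <- 2 * half_d0
    s0_2 <- exp(ebar + digamma(half_d0) - log(half_d0))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' For each feature g a pooled residual variance s_g^2 on d_g = n - 2 degrees
#' of freedom is shrunk towards a common prior value:
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g), with (d0, s0^2) estimated by
#' method of moments on the log residual variances. The moderated t is
#' logFC / (s~_g sqrt(1/n1 + 1/n2)) on d0 + d_g degrees of freedom, two-sided.
#' logFC is case (AR) minus control (NR).
#'
#' @param expr expression matrix, features x samples.
#' @param labels named AR/NR labels covering the samples.
#' @param d0,s0_2 optional prior overrides. `d0 = 0` forces the classical
#'   pooled two-sample t; `d0 = Inf` with fixed `s0_2` forces the fully
#'   shrunk limit.
#' @return data frame of class `de_result` with per-feature columns
#'   feature_id, mean_case, mean_control, logFC, s2, df_residual, t_mod, p,
#'   fdr, direction, and attributes `d0`, `s0_2`.
#' @export
moderated_t <- function(expr, labels, d0 = NULL, s0_2 = NULL) {
  check_expr_matrix(expr)
  labels <- check_labels(labels, colnames(expr))
  case <- is_case(labels)
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2 || n2 < 2) stop("both classes need at least 2 samples")
  xc <- expr[, case, drop = FALSE]
  xn <- expr[, !case, drop = FALSE]
  m1 <- rowMeans(xc); m2 <- rowMeans(xn)
  ss1 <- rowSums((xc - m1)^2)
  ss2 <- rowSums((xn - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  if (is.null(d0) || is.null(s0_2)) {
    prior <- estimate_variance_prior(s2, df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_2)) s0_2 <- prior$s0_2
  }
  if (!is.infinite(d0) && d0 < 0) stop("d0 must be >= 0")
  s2_shrunk <- if (is.infinite(d0)) rep(s0_2, length(s2))
  else (d0 * s0_2 + df * s2) / (d0 + df)
  logfc <- m1 - m2
  se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  tmod <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, Inf * sign(logfc)))
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  p[!is.finite(tmod)] <- 0
  p[tmod == 0] <- 1
  fdr <- bh_adjust(p)
  out <- data.frame(
    feature_id = rownames(expr), mean_case = m1, mean_control = m2,
    logFC = logfc, s2 = s2, df_residual = df, t_mod = tmod, p = p,
    fdr = fdr, direction = ifelse(logfc > 0, "Up", "Down"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "n_case") <- n1
  attr(out, "n_control") <- n2
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: adjusted_(i) = min over j >= i of p_(j) * m / j,
#' capped at 1 and mapped back to input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Natural-scale fold-change magnitude and direction from log2 group means
#'
#' @param mean_case,mean_control log2 group means.
#' @return data frame with `magnitude` (2^|difference|, natural scale) and
#'   `direction` ("Up" when the case mean is larger).
#' @export
fold_change_from_means <- function(mean_case, mean_control) {
  if (any(!is.finite(mean_case)) || any(!is.finite(mean_control)))
    stop("means must be finite")
  diff <- mean_case - mean_control
  data.frame(magnitude = 2^abs(diff),
             direction = ifelse(diff > 0, "Up", "Down"),
             stringsAsFactors = FALSE)
}

#' Volcano-plot table
#'
#' @param de a `de_result`.
#' @param fdr_cut features with fdr strictly below this are flagged.
#' @return data frame with feature_id, logFC, neg_log10_p, significant.
#' @export
volcano_table <- function(de, fdr_cut = 0.05) {
  data.frame(feature_id = de$feature_id, logFC = de$logFC,
             neg_log10_p = -log10(pmax(de$p, .Machine$double.xmin)),
             significant = de$fdr < fdr_cut,
             stringsAsFactors = FALSE)
}

#' Row-standardize an expression matrix for cluster display
#'
#' Each row is centered and scaled to unit variance; constant rows become
#' all-zero.
#'
#' @param expr expression matrix.
#' @param feature_ids optional subset of rows.
#' @return standardized matrix.
#' @export
row_standardize <- function(expr, feature_ids = NULL) {
  check_expr_matrix(expr)
  if (!is.null(feature_ids)) {
    missing <- setdiff(feature_ids, rownames(expr))
    if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
    expr <- expr[feature_ids, , drop = FALSE]
  }
  ctr <- expr - rowMeans(expr)
  sds <- apply(expr, 1, stats::sd)
  out <- ctr / ifelse(sds > 0, sds, 1)
  out[sds == 0, ] <- 0
  out
}
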