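# Eight classifier configurations behind a single contract: fit on
# (features x samples expression, AR/NR labels, panel), return probability
# of the case class (AR). Each method tunes exactly one parameter (random
# forest none); tuning grids are ordered from most to least regularized so
# the one-standard-error rule can prefer the more regularized model.
#
# Methods: EN-0.10 / EN-0.50 / EN-0.90 (elastic net at fixed alpha, tuned
# lambda), LDA (tuned number of top features in FDR order), PAM (native
# shrunken centroids, tuned shrinkage delta), RF-1 (fixed), SVM (linear
# kernel, tuned cost, Platt-style probability calibration), XGBoost (tuned
# boosting rounds; depth 2, learning rate 0.1 fixed).

CLF_METHODS <- c("EN-0.10", "EN-0.50", "EN-0.90", "LDA", "PAM", "RF-1",
                 "SVM", "XGBoost")

#' Classifier specifications with default tuning grids
#'
#' Grids are ordered most- to least-regularized: decreasing lambda (EN),
#' increasing top-n (LDA), decreasing shrinkage delta (PAM, as fractions of
#' the data-resolved maximum), increasing cost (SVM), increasing boosting
#' rounds (XGBoost). RF carries an empty grid (untuned; ntree = 500 fixed).
#'
#' @param method one of `r toString(CLF_METHODS)`.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(method) {
  method <- match.arg(method, CLF_METHODS)
  spec <- switch(
    method,
    "EN-0.10" = list(tuned = "lambda", grid = 10^seq(1, -3, length.out = 30),
                     fixed = list(alpha = 0.10)),
    "EN-0.50" = list(tuned = "lambda", grid = 10^seq(1, -3, length.out = 30),
                     fixed = list(alpha = 0.50)),
    "EN-0.90" = list(tuned = "lambda", grid = 10^seq(1, -3, length.out = 30),
                     fixed = list(alpha = 0.90)),
    "LDA" = list(tuned = "n_features",
                 grid = c(1:6, 8, 10, 15, 20, 30, 50),
                 fixed = list()),
    "PAM" = list(tuned = "delta",
                 grid = seq(1, 0, length.out = 30),  # fractions of max |d|
                 fixed = list()),
    "RF-1" = list(tuned = NA_character_, grid = numeric(0),
                  fixed = list(ntree = 500)),
    "SVM" = list(tuned = "cost", grid = 2^seq(-5, 5, by = 2),
                 fixed = list(kernel = "linear")),
    "XGBoost" = list(tuned = "nrounds",
                     grid = c(10, 25, 50, 100, 200, 300),
                     fixed = list(max_depth = 2, eta = 0.1)))
  structure(c(list(method = method), spec), class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
default_grids <- function() {
  specs <- lapply(CLF_METHODS, classifier_spec)
  names(specs) <- CLF_METHODS
  specs
}

# ---- shrunken centroids (native implementation) -------------------------

# Fit the shrunken-centroid statistics once; deltas are applied afterwards.
pam_stats <- function(x, y, priors = NULL) {
  classes <- levels(y)
  n <- nrow(x); K <- length(classes)
  nk <- table(y)[classes]
  overall <- colMeans(x)
  centroids <- t(vapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x))))
  ss <- 0
  for (cl in classes)
    ss <- ss + colSums((x[y == cl, , drop = FALSE] -
                          rep(centroids[cl, ], each = sum(y == cl)))^2)
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  m <- sqrt(1 / nk - 1 / n)
  d <- sweep(sweep(centroids, 2, overall), 2, s + s0, "/") / as.numeric(m)
  if (is.null(priors)) priors <- as.numeric(nk) / n
  list(classes = classes, overall = overall, centroids = centroids, s = s,
       s0 = s0, m = as.numeric(m), d = d, priors = priors)
}

pam_shrunken_centroids <- function(st, delta) {
  dshr <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  cent <- sweep(dshr * as.numeric(st$m), 2, st$s + st$s0, "*")
  sweep(cent, 2, st$overall, "+")
}

#' Shrunken-centroid class scores and probabilities
#'
#' Implements the nearest shrunken centroid recipe: standardized centroid
#' deviations d_ik = (centroid_ik - overall_i) / (m_k (s_i + s0)) are
#' soft-thresholded at delta, centroids rebuilt, and each sample scored by
#' the discriminant delta_k(x) = sum_i (x_i - centroid'_ik)^2 / (s_i + s0)^2
#' - 2 log prior_k, with class probability proportional to exp(-delta_k / 2).
#' s0 is the median of the pooled within-class standard deviations.
#'
#' @param x matrix of samples x features to score.
#' @param st statistics from the training fit (internal).
#' @param delta shrinkage threshold.
#' @return list with `scores` (samples x classes discriminant) and `prob`.
#' @keywords internal
pam_score <- function(x, st, delta) {
  cent <- pam_shrunken_centroids(st, delta)
  denom <- (st$s + st$s0)^2
  scores <- vapply(seq_along(st$classes), function(k) {
    colSums((t(x) - cent[k, ])^2 / denom) - 2 * log(st$priors[k])
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- st$classes
  ex <- exp(-(scores - apply(scores, 1, min)) / 2)
  prob <- ex / rowSums(ex)
  list(scores = scores, prob = prob)
}

# Platt-style probability calibration: two-parameter logistic regression of
# the class indicator on the decision value, fitted by damped Newton with a
# tiny ridge for stability under complete separation (where the mapping
# saturates, as intended). Monotone in the decision value, so AUC is
# preserved.
platt_fit <- function(dv, y, max_iter = 25, tol = 1e-7) {
  b0 <- 0; b1 <- 0
  yn <- as.numeric(y)
  for (it in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-(b0 + b1 * dv)))
    w <- p * (1 - p)
    w[w < 1e-10] <- 1e-10
    r <- yn - p
    g0 <- sum(r); g1 <- sum(r * dv)
    h00 <- sum(w) + 1e-8; h01 <- sum(w * dv)
    h11 <- sum(w * dv * dv) + 1e-8
    det <- h00 * h11 - h01 * h01
    if (det <= 0) break
    s0 <- (h11 * g0 - h01 * g1) / det
    s1 <- (h00 * g1 - h01 * g0) / det
    s0 <- max(min(s0, 10), -10); s1 <- max(min(s1, 10), -10)
    b0 <- b0 + s0; b1 <- b1 + s1
    if (abs(s0) < tol && abs(s1) < tol) break
  }
  c(b0, b1)
}

# ---- grid fitting engine ------------------------------------------------

# Fit a classifier over its whole tuning grid on one training set.
# x: samples x features (panel order); y: factor NR/AR; fdr_order: feature
# names in significance order (used by LDA). Returns the resolved grid, a
# predict closure (samples x grid probabilities of AR) and per-grid-value
# selected features.
fit_grid_clf <- function(spec, x, y, seed = 1, fdr_order = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (ncol(x) == 0) stop("empty panel")
  if (length(unique(y)) < 2) stop("training data contain a single class")
  y <- factor(as.character(y), levels = c("NR", "AR"))
  p <- ncol(x)
  feats <- colnames(x)

  if (spec$method %in% c("EN-0.10", "EN-0.50", "EN-0.90")) {
    grid <- spec$grid
    fit <- glmnet::glmnet(x, y, family = "binomial",
                          alpha = spec$fixed$alpha, lambda = grid,
                          standardize = TRUE)
    predictf <- function(xnew)
      as.matrix(stats::predict(fit, xnew, s = grid, type = "response"))
    featuresf <- function(gi) {
      b <- as.matrix(stats::predict(fit, s = grid[gi], type = "coefficients"))
      feats[b[-1, 1] != 0]
    }
  } else if (spec$method == "LDA") {
    ord <- if (!is.null(fdr_order)) intersect(fdr_order, feats) else feats
    grid <- spec$grid  # fixed length across folds; n is capped at the panel
    n_eff <- pmin(grid, length(ord))
    fits <- lapply(n_eff, function(n) {
      cols <- ord[seq_len(n)]
      tryCatch(suppressWarnings(
        MASS::lda(x[, cols, drop = FALSE], grouping = y)),
        error = function(e) NULL)
    })
    predictf <- function(xnew) {
      out <- matrix(NA_real_, nrow(xnew), length(grid))
      for (gi in seq_along(grid)) {
        if (is.null(fits[[gi]])) next
        cols <- ord[seq_len(n_eff[gi])]
        out[, gi] <- stats::predict(
          fits[[gi]], xnew[, cols, drop = FALSE])$posterior[, "AR"]
      }
      out
    }
    featuresf <- function(gi) ord[seq_len(n_eff[gi])]
  } else if (spec$method == "PAM") {
    st <- pam_stats(x, y)
    dmax <- max(abs(st$d))
    grid <- spec$grid * dmax
    predictf <- function(xnew) {
      out <- vapply(grid, function(dl)
        pam_score(xnew, st, dl)$prob[, "AR"], numeric(nrow(xnew)))
      if (is.null(dim(out))) out <- matrix(out, nrow = nrow(xnew))
      out
    }
    featuresf <- function(gi)
      feats[colSums(abs(st$d) > grid[gi]) > 0]
  } else if (spec$method == "RF-1") {
    grid <- NA_real_  # single fixed configuration
    set.seed(sub_seed(seed, "rf"))
    fit <- randomForest::randomForest(x, y, ntree = spec$fixed$ntree)
    predictf <- function(xnew)
      matrix(stats::predict(fit, xnew, type = "prob")[, "AR"], ncol = 1)
    featuresf <- function(gi) feats
  } else if (spec$method == "SVM") {
    grid <- spec$grid
    ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    fits <- lapply(grid, function(cost) {
      fit <- tryCatch(
        e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE,
                   type = "C-classification"),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      # linear kernel: decision value is w.x - rho, computed directly
      w <- as.numeric(crossprod(fit$coefs, fit$SV))
      dv <- as.numeric(xs %*% w) - fit$rho
      list(w = w, rho = fit$rho, coef = platt_fit(dv, y == "AR"))
    })
    predictf <- function(xnew) {
      xn <- scale(xnew, center = ctr, scale = scl)
      out <- matrix(NA_real_, nrow(xnew), length(grid))
      for (gi in seq_along(grid)) {
        f <- fits[[gi]]
        if (is.null(f)) next
        dv <- as.numeric(xn %*% f$w) - f$rho
        out[, gi] <- stats::plogis(f$coef[1] + f$coef[2] * dv)
      }
      out
    }
    featuresf <- function(gi) feats
  } else if (spec$method == "XGBoost") {
    grid <- spec$grid
    dm <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "AR"))
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = spec$fixed$max_depth, eta = spec$fixed$eta,
                    nthread = 1, seed = sub_seed(seed, "xgb")),
      data = dm, nrounds = max(grid), verbose = 0)
    predictf <- function(xnew) {
      dnew <- xgboost::xgb.DMatrix(xnew)  # predict on DMatrix: no per-call
      vapply(grid, function(r)           # conversion overhead
        stats::predict(fit, dnew, iterationrange = c(1, r)),
        numeric(nrow(xnew)))
    }
    featuresf <- function(gi) feats
  } else stop("unknown method")

  # grid_keys are the comparable tuning values across training sets (for
  # PAM the delta fractions; elsewhere the resolved grid itself)
  keys <- if (spec$method == "PAM") spec$grid else grid
  list(spec = spec, grid = grid, grid_keys = keys, predict = predictf,
       features = featuresf)
}

#' Train one classifier configuration at a fixed tuning value
#'
#' @param spec a [classifier_spec()].
#' @param expr expression matrix (features x samples, training samples).
#' @param labels AR/NR labels.
#' @param panel a `marker_panel` or character vector of feature ids.
#' @param param_value tuning value (ignored for RF; for PAM a fraction of the
#'   data-resolved maximum deviation, as in the default grid).
#' @param seed seed for the stochastic learners.
#' @param fdr_order optional feature ordering by significance (LDA).
#' @return object of class `trained_clf` with the selected features.
#' @export
train_classifier <- function(spec, expr, labels, panel, param_value = NULL,
                             seed = 1, fdr_order = NULL) {
  ids <- if (inherits(panel, "marker_panel")) panel$feature_ids else panel
  if (length(ids) == 0) stop("empty panel")
  missing <- setdiff(ids, rownames(expr))
  if (length(missing)) stop("panel features absent from expression matrix")
  labels <- check_labels(labels, colnames(expr))
  x <- t(expr[ids, , drop = FALSE])
  fg <- fit_grid_clf(spec, x, factor(labels, c("NR", "AR")), seed = seed,
                     fdr_order = fdr_order)
  if (length(spec$grid) > 0) {
    if (is.null(param_value)) stop("param_value required for tuned methods")
    key_grid <- if (spec$method == "PAM") spec$grid else fg$grid
    gi <- which.min(abs(key_grid - param_value))
  } else gi <- 1L
  structure(list(spec = spec, param = param_value, panel = ids,
                 grid_index = gi, selected_feature_ids = fg$features(gi),
                 fit = fg),
            class = "trained_clf")
}

#' Predict probability of the case class (AR)
#'
#' @param model a `trained_clf`.
#' @param expr_new expression matrix containing all model features.
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, expr_new) {
  stopifnot(inherits(model, "trained_clf"))
  missing <- setdiff(model$panel, rownames(expr_new))
  if (length(missing))
    stop("missing features in new data: ", paste(missing, collapse = ", "))
  xnew <- t(expr_new[model$panel, , drop = FALSE])
  p <- model$fit$predict(xnew)[, model$grid_index]
  stats::setNames(pmin(pmax(p, 0), 1), colnames(expr_new))
}

#' @export
print.trained_clf <- function(x, ...) {
  cat(sprintf("<%s> panel %d features, %d selected%s\n", x$spec$method,
              length(x$panel), length(x$selected_feature_ids),
              if (!is.null(x$param)) sprintf(", %s = %g", x$spec$tuned,
                                             x$param) else ""))
  invisible(x)
}
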