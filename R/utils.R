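# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed for a named random stream from a master seed.
# Keeps results of earlier streams invariant when new streams are added, and
# stays below 2^31 - 1 so it is always a valid R integer seed.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 131 + ch) %% m
  as.integer(((abs(seed) %% m) * 69069 + h) %% m)
}

# Evaluate expr with a local RNG state seeded from (seed, stream).
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, stream))
  expr
}

check_expr_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression data must be a numeric matrix (features x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs feature row names and sample column names")
  if (any(!is.finite(expr))) stop("expression matrix contains non-finite values")
  invisible(expr)
}

# Labels: named character/factor with classes AR (case) and NR (control).
check_labels <- function(labels, samples = NULL) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!all(labels %in% c("AR", "NR")))
    stop("labels must be 'AR' (case) or 'NR' (control)")
  if (!is.null(samples)) {
    if (is.null(names(labels))) stop("labels must be named by sample id")
    if (!all(samples %in% names(labels)))
      stop("labels missing for some samples")
    labels <- labels[samples]
  }
  labels
}

is_case <- function(labels) as.character(labels) == "AR"
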