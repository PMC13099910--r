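# Shared fixtures, built once per test run.

# Small probe-level cohort exercising every stage.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(
        sim_config(n_probesets = 300, probes_per_set = 5, seed = 101))
    cache
  }
})

is_case_lab <- function(labels) as.character(labels) == "AR"

# Minimal prefilter_result for overlap accounting tests.
new_pf <- function(method, ids) {
  structure(list(method = method, retained_ids = ids, scores = NULL,
                 params = list()), class = "prefilter_result")
}

# Labels for a balanced toy design.
toy_labels <- function(n_case = 4, n_control = 4) {
  stats::setNames(rep(c("AR", "NR"), c(n_case, n_control)),
                  sprintf("S%02d", seq_len(n_case + n_control)))
}

# Random expression matrix with named rows/columns.
rand_expr <- function(n_feat, labels, seed = 1, effect = 0,
                      n_de = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * length(labels), 8, 1), n_feat,
              dimnames = list(sprintf("F%04d", seq_len(n_feat)),
                              names(labels)))
  if (n_de > 0)
    m[seq_len(n_de), labels == "AR"] <-
      m[seq_len(n_de), labels == "AR"] + effect
  m
}

# Random de_result-shaped table for panel-rule contract checks.
rand_de_table <- function(n, seed = 1) {
  set.seed(seed)
  p <- runif(n)^2
  d <- data.frame(
    feature_id = sprintf("F%04d", sample(n)),
    mean_case = rnorm(n, 8), mean_control = rnorm(n, 8),
    logFC = rnorm(n, 0, 0.7), s2 = rchisq(n, 5) / 5, df_residual = 46,
    t_mod = rnorm(n), p = p, fdr = p.adjust(p, "BH"),
    direction = "Up", stringsAsFactors = FALSE)
  d$direction <- ifelse(d$logFC > 0, "Up", "Down")
  class(d) <- c("de_result", "data.frame")
  d
}

# Brute-force pair-counting AUC oracle.
auc_oracle <- function(scores, labels) {
  case <- scores[labels == "AR"]
  ctrl <- scores[labels == "NR"]
  tot <- 0
  for (a in case) for (b in ctrl)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(case) * length(ctrl))
}

# Brute-force Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}
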