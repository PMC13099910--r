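# Synthetic case-control microarray cohort generator.
#
# Emulates a balanced whole-blood expression study: 24 cases (AR) and 24
# controls (NR), probe-sets summarizing several probes each, a planted
# fraction of differentially expressed features, and probe-sets whose
# probe-level profiles are deliberately inconsistent so that
# consistency-based pre-filters have something to discriminate.

#' Configuration for the synthetic cohort generator
#'
#' All log-scale parameters are in log2 units. Planted differential features
#' receive baselines from the expressed range (`de_baseline_mean`,
#' `de_baseline_sd`), reflecting that detectable case-control differences on
#' arrays sit well above the intensity floor. `signal_sd` is the shared
#' array-to-array biological variation of a probe-set; inconsistent
#' probe-sets replace this shared component with independent per-probe noise
#' of matched total variance, so intensity-based filters are unaffected while
#' consistency scores separate the two kinds of set.
#'
#' @param n_case,n_control samples per class.
#' @param n_probesets number of probe-sets (features).
#' @param probes_per_set probes per probe-set.
#' @param de_fraction fraction of probe-sets with a planted group effect.
#' @param effect_low,effect_high magnitude bounds of planted log2 effects.
#' @param baseline_mean,baseline_sd baseline log2 level of null features.
#' @param de_baseline_mean,de_baseline_sd baseline level of planted features.
#' @param noise_sd residual (within-array) noise sd.
#' @param signal_sd shared per-array biological signal sd.
#' @param noise_spread sd of the per-feature log-normal amplitude factor
#'   applied to both the shared signal and the noise, giving features
#'   heterogeneous variances (as on real arrays) while leaving
#'   consistency scores untouched.
#' @param het_sd sd of the per-sample latent activation score around the
#'   class value (cases at 1, controls at 0). All planted features express
#'   their effect through this shared axis, mimicking co-regulated disease
#'   modules and variable rejection severity: some cases present weakly and
#'   some controls strongly, which bounds achievable classification
#'   performance the way patient heterogeneity does in real cohorts. At 0
#'   every case carries the full effect deterministically.
#' @param frac_inconsistent fraction of probe-sets with probe-dominated variance.
#' @param probe_affinity_sd sd of per-probe affinity offsets.
#' @param de_up_fraction fraction of planted effects that are positive.
#' @param n_gene_sets,gene_set_size_range,n_enriched_sets gene-set collection shape.
#' @param seed master seed; every random stream derives a sub-seed from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_case = 24, n_control = 24, n_probesets = 2000,
                       probes_per_set = 11, de_fraction = 0.05,
                       effect_low = 0.5, effect_high = 1.5,
                       baseline_mean = 7.5, baseline_sd = 1.5,
                       de_baseline_mean = 8.5, de_baseline_sd = 1.0,
                       noise_sd = 0.7, signal_sd = 1.0, noise_spread = 0.3,
                       frac_inconsistent = 0.3, probe_affinity_sd = 0.5,
                       de_up_fraction = 0.5, het_sd = 0.4,
                       n_gene_sets = 50, gene_set_size_range = c(10, 200),
                       n_enriched_sets = 5, seed = 1) {
  cfg <- list(n_case = n_case, n_control = n_control,
              n_probesets = n_probesets, probes_per_set = probes_per_set,
              de_fraction = de_fraction, effect_low = effect_low,
              effect_high = effect_high, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, de_baseline_mean = de_baseline_mean,
              de_baseline_sd = de_baseline_sd, noise_sd = noise_sd,
              signal_sd = signal_sd, noise_spread = noise_spread,
              frac_inconsistent = frac_inconsistent,
              probe_affinity_sd = probe_affinity_sd,
              de_up_fraction = de_up_fraction, het_sd = het_sd,
              n_gene_sets = n_gene_sets,
              gene_set_size_range = gene_set_size_range,
              n_enriched_sets = n_enriched_sets, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_case < 1 || n_control < 1) stop("need at least one sample per class")
    if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
    if (effect_low > effect_high) stop("effect_low must be <= effect_high")
    if (noise_sd <= 0 || signal_sd <= 0 || baseline_sd <= 0 ||
        probe_affinity_sd <= 0)
      stop("all sd parameters must be positive")
    if (noise_spread < 0) stop("noise_spread must be non-negative")
    if (het_sd < 0) stop("het_sd must be non-negative")
    if (de_fraction > 0 && round(de_fraction * n_probesets) < 1)
      stop("de_fraction * n_probesets < 1: no effect can be planted")
    if (frac_inconsistent < 0 || frac_inconsistent > 1)
      stop("frac_inconsistent must be in [0,1]")
  })
  invisible(cfg)
}

#' Simulate a balanced case-control expression cohort
#'
#' Probe-level model: intensity(probe p, array j) = baseline(set) +
#' affinity(p) + effect(set) * activation(j) + shared_signal(set, j) +
#' noise, where activation(j) = case(j) + latent heterogeneity
#' (`het_sd`; see [sim_config()]).
#' Inconsistent sets replace the shared signal with independent per-probe
#' noise of matched variance, so their probe profiles disagree across
#' arrays while intensity-based filters are unaffected. The probe-set-level
#' matrix is the summarization-free truth (baseline + effect + shared
#' signal + aggregated probe noise): when probe-level data are generated
#' its noise term is the mean of the per-probe noise draws, so it is the
#' exact noise-aggregate the summarization step estimates; with
#' `probe_level = FALSE` an equivalent-variance noise term is drawn
#' directly.
#'
#' @param config a [sim_config()].
#' @param probe_level if `FALSE`, skip generation of the probe-level blocks
#'   (the probe-set matrix and ground truth are unchanged).
#' @return list with `probes` (probe-level collection or `NULL`), `expr`
#'   (probe-set matrix, features x samples), `labels` (named AR/NR vector),
#'   `truth` (planted effects, inconsistent sets), `annotation` (feature to
#'   gene map), and the `config`.
#' @export
simulate_cohort <- function(config, probe_level = TRUE) {
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_probesets
  ns <- cfg$n_case + cfg$n_control
  samples <- sprintf("S%03d", seq_len(ns))
  labels <- stats::setNames(rep(c("AR", "NR"), c(cfg$n_case, cfg$n_control)),
                            samples)
  features <- sprintf("PS%05d_at", seq_len(n))

  n_de <- if (cfg$de_fraction > 0) round(cfg$de_fraction * n) else 0L
  de_idx <- with_stream(cfg$seed, "de_pick",
                        sort(sample.int(n, n_de)))
  effects <- numeric(n)
  if (n_de > 0) {
    mag <- with_stream(cfg$seed, "effects",
                       stats::runif(n_de, cfg$effect_low, cfg$effect_high))
    n_up <- round(cfg$de_up_fraction * n_de)
    sign_vec <- rep(-1, n_de)
    up_pos <- with_stream(cfg$seed, "effect_signs",
                          sample.int(n_de, n_up))
    sign_vec[up_pos] <- 1
    effects[de_idx] <- mag * sign_vec
  }

  n_inc <- round(cfg$frac_inconsistent * n)
  inc_idx <- with_stream(cfg$seed, "inconsistent_pick",
                         sort(sample.int(n, n_inc)))

  baseline <- with_stream(cfg$seed, "baseline",
                          stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd))
  if (n_de > 0)
    baseline[de_idx] <- with_stream(
      cfg$seed, "de_baseline",
      stats::rnorm(n_de, cfg$de_baseline_mean, cfg$de_baseline_sd))

  case_ind <- as.numeric(is_case(labels))
  activation <- case_ind + with_stream(cfg$seed, "activation",
                                       stats::rnorm(ns, 0, cfg$het_sd))
  # per-feature amplitude factor: scales shared signal and noise together
  amp <- with_stream(cfg$seed, "noise_spread",
                     exp(stats::rnorm(n, 0, cfg$noise_spread)))
  shared <- with_stream(cfg$seed, "shared_signal",
                        matrix(stats::rnorm(n * ns), n, ns)) *
    (cfg$signal_sd * amp)
  np <- cfg$probes_per_set
  pn_sd <- cfg$noise_sd * amp
  inc_sd <- sqrt(cfg$signal_sd^2 + cfg$noise_sd^2) * amp
  is_inc <- logical(n); is_inc[inc_idx] <- TRUE

  probes <- NULL
  if (probe_level) {
    affinity <- with_stream(cfg$seed, "affinity",
                            matrix(stats::rnorm(n * np, 0, cfg$probe_affinity_sd),
                                   n, np))
    probe_noise <- with_stream(cfg$seed, "probe_noise",
                               array(stats::rnorm(n * np * ns), c(n, np, ns)))
    blocks <- vector("list", n)
    agg_noise <- matrix(0, n, ns)
    for (i in seq_len(n)) {
      base_i <- baseline[i] + effects[i] * activation         # length ns
      if (is_inc[i]) {
        noise_i <- probe_noise[i, , ] * inc_sd[i]
        m <- matrix(base_i, np, ns, byrow = TRUE) + affinity[i, ] + noise_i
      } else {
        noise_i <- probe_noise[i, , ] * pn_sd[i]
        m <- matrix(base_i + shared[i, ], np, ns, byrow = TRUE) +
          affinity[i, ] + noise_i
      }
      agg_noise[i, ] <- colMeans(noise_i)
      dimnames(m) <- list(sprintf("%s_p%02d", features[i], seq_len(np)),
                          samples)
      blocks[[i]] <- m
    }
    names(blocks) <- features
    probes <- structure(list(blocks = blocks, arrays = samples),
                        class = "probe_collection")
  } else {
    agg_sd <- ifelse(is_inc, inc_sd, pn_sd) / sqrt(np)
    agg_noise <- with_stream(cfg$seed, "set_noise",
                             matrix(stats::rnorm(n * ns), n, ns)) * agg_sd
  }
  expr <- baseline + outer(effects, activation) +
    shared * as.numeric(!is_inc) + agg_noise
  dimnames(expr) <- list(features, samples)

  annotation <- make_annotation(features)
  truth <- list(
    de_feature_ids = features[de_idx],
    de_effects = stats::setNames(effects[de_idx], features[de_idx]),
    inconsistent_set_ids = features[inc_idx],
    enriched_set_ids = character(0))

  structure(list(probes = probes, expr = expr, labels = labels,
                 truth = truth, annotation = annotation, config = cfg),
            class = "sim_cohort")
}

# Feature -> gene annotation; roughly every 7th probe-set shares a gene with
# its neighbour and every 20th is unannotated ("---"), mirroring arrays where
# genes carry multiple probe-sets and some probe-sets have no mapping.
make_annotation <- function(features) {
  n <- length(features)
  gene_idx <- ceiling(seq_len(n) * 6 / 7)
  symbol <- sprintf("GENE%05d", gene_idx)
  title <- sprintf("synthetic gene %05d", gene_idx)
  unann <- seq_len(n) %% 20 == 0
  symbol[unann] <- "---"
  title[unann] <- "---"
  data.frame(feature_id = features, gene_symbol = symbol,
             gene_title = title, stringsAsFactors = FALSE)
}

#' Simulate a gene-set collection matched to a synthetic cohort
#'
#' The first `n_enriched_sets` sets draw at least half of their members from
#' genes carrying a planted effect (when any exist); the remaining sets draw
#' uniformly from the annotated gene universe.
#'
#' @param truth ground truth from [simulate_cohort()].
#' @param annotation feature annotation table.
#' @param config the [sim_config()] used for the cohort.
#' @return list with `sets` (named list of gene vectors, GMT-ready),
#'   `descriptions`, and `enriched_set_ids`.
#' @export
simulate_gene_sets <- function(truth, annotation, config) {
  universe <- unique(annotation$gene_symbol)
  universe <- universe[universe != "---"]
  rng <- config$gene_set_size_range
  if (max(rng) > length(universe))
    stop("gene_set_size_range exceeds the gene universe")
  de_genes <- unique(annotation$gene_symbol[
    annotation$feature_id %in% truth$de_feature_ids])
  de_genes <- de_genes[de_genes != "---"]
  n_enr <- if (length(de_genes) > 0) min(config$n_enriched_sets,
                                         config$n_gene_sets) else 0L
  set_names <- sprintf("SET%03d", seq_len(config$n_gene_sets))
  sets <- with_stream(config$seed, "gene_sets", {
    pool <- seq(rng[1], rng[2])
    lapply(seq_len(config$n_gene_sets), function(k) {
      size <- if (length(pool) == 1) pool else sample(pool, 1)
      if (k <= n_enr) {
        # cap enriched-set size so at least half the members can be drawn
        # from the planted genes
        size <- min(size, max(rng[1], 2 * length(de_genes)))
        n_de_mem <- min(ceiling(size / 2), length(de_genes))
        mem_de <- sample(de_genes, n_de_mem)
        pool <- setdiff(universe, mem_de)
        c(mem_de, sample(pool, size - n_de_mem))
      } else {
        sample(universe, size)
      }
    })
  })
  sets <- lapply(sets, sort)
  names(sets) <- set_names
  list(sets = sets,
       descriptions = stats::setNames(
         rep("synthetic gene set", config$n_gene_sets), set_names),
       enriched_set_ids = set_names[seq_len(n_enr)])
}
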