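# Inclusion matrices, frequency filters, gene summaries, score summaries
# and hypergeometric enrichment.

test_that("inclusion counts and fractions enumerate panel membership", {
  incl <- build_inclusion(list(p1 = c("a", "b"), p2 = "b", p3 = c("b", "c")))
  expect_equal(unname(incl$count[c("a", "b", "c")]), c(1, 3, 1))
  expect_equal(unname(incl$fraction["b"]), 1)
  expect_equal(incl$n_combinations, 3)
  # order of combinations is irrelevant
  incl2 <- build_inclusion(list(p3 = c("c", "b"), p1 = c("a", "b"),
                                p2 = "b"))
  expect_equal(incl2$count[names(incl$count)], incl$count)
  same <- build_inclusion(list(a = c("x", "y"), b = c("x", "y")))
  expect_true(all(same$fraction == 1))
  # a feature in 188 of 200 panels has fraction 0.94
  many <- build_inclusion(c(
    lapply(1:188, function(i) c("hit", "other")),
    lapply(1:12, function(i) "other")))
  expect_equal(unname(many$fraction["hit"]), 0.94)
})

test_that("frequency filter applies the inclusive threshold and ordering", {
  panels <- c(lapply(1:188, function(i) "a"), lapply(1:40, function(i) "b"))
  panels <- lapply(seq_along(panels), function(i)
    c(panels[[i]], if (i <= 200) "c"))
  incl <- build_inclusion(panels[1:200])
  expect_identical(frequency_filter(incl, 0.25),
                   c("c", "a"))  # b at 12/200 + padding is below 25%
  expect_identical(frequency_filter(incl, 0), names(sort(-incl$count)))
  expect_identical(frequency_filter(incl, 1), "c")
})

test_that("gene summary reproduces printed fold-changes and handles '---'", {
  de <- rand_de_table(4, seed = 1)
  de$feature_id <- c("ps1", "ps2", "ps3", "ps4")
  de$mean_case <- c(9.43, 8.10, 7.30, 6.54)
  de$mean_control <- c(8.32, 6.56, 8.23, 7.25)
  ann <- data.frame(feature_id = c("ps1", "ps2", "ps3"),
                    gene_symbol = c("CDC42SE1", "TMEFF2", "TMEM106B"),
                    gene_title = c("t1", "t2", "t3"),
                    stringsAsFactors = FALSE)
  incl <- build_inclusion(list(a = c("ps1", "ps2"), b = c("ps1", "ps3"),
                               c = c("ps1", "ps4")))
  gs <- gene_summary(incl, de, ann)
  expect_identical(gs$feature_id[1], "ps1")  # highest count first
  expect_equal(round(gs$fold_change[match(c("ps1", "ps2", "ps3", "ps4"),
                                          gs$feature_id)], 2),
               c(2.16, 2.91, 1.91, 1.64))
  expect_identical(gs$direction[match(c("ps1", "ps3"), gs$feature_id)],
                   c("Up", "Down"))
  expect_identical(gs$gene_symbol[gs$feature_id == "ps4"], "---")
  empty <- build_inclusion(list(a = "z"))
  expect_equal(nrow(gene_summary(
    build_inclusion(list(a = character(0), b = "ps1")), de, ann)), 1)
})

test_that("score summaries flag discordant samples", {
  labs <- toy_labels(2, 2)
  m <- rbind(c(0.2, 0.6, 0.9), c(0.8, 0.9, 0.7),
             c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.8))
  rownames(m) <- names(labs); colnames(m) <- c("c1", "c2", "c3")
  ss <- score_summaries(m, labs)
  expect_equal(ss$per_sample$median, c(0.6, 0.8, 0.2, 0.7))
  expect_identical(ss$per_sample$discordant, c(FALSE, FALSE, FALSE, TRUE))
  flat <- matrix(0.5, 4, 2, dimnames = list(names(labs), c("a", "b")))
  expect_false(any(score_summaries(flat, labs)$per_sample$discordant))
  expect_equal(nrow(ss$long), 12)
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  uni <- sprintf("g%02d", 1:20)
  sets <- list(S = uni[1:5], T = uni[6:15])
  r <- enrich(uni[1:5], uni, sets)
  expect_equal(r$p[r$set == "S"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$overlap[r$set == "T"], 0)
  expect_equal(r$p[r$set == "T"], 1)
  expect_equal(r$gene_ratio[r$set == "S"], 1)
  # exhaustive enumeration oracle on a small universe
  uni2 <- letters[1:10]
  set2 <- list(A = letters[1:4])
  lst <- c("a", "b", "e")
  combos <- combn(10, 3)
  k_obs <- length(intersect(lst, set2$A))
  tail_p <- mean(apply(combos, 2, function(ix)
    length(intersect(uni2[ix], set2$A)) >= k_obs))
  r2 <- enrich(lst, uni2, set2)
  expect_equal(r2$p, tail_p, tolerance = 1e-12)
  expect_error(enrich(c("zz"), uni2, set2), "outside the universe")
  expect_error(enrich(character(0), uni2, set2), "empty candidate")
})

test_that("planted enriched sets rank first over seeds", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_probesets = 400, probes_per_set = 3,
                      n_gene_sets = 25, gene_set_size_range = c(10, 40),
                      n_enriched_sets = 3, seed = 500 + s)
    coh <- simulate_cohort(cfg, probe_level = FALSE)
    gsets <- simulate_gene_sets(coh$truth, coh$annotation, cfg)
    de_genes <- unique(coh$annotation$gene_symbol[
      coh$annotation$feature_id %in% coh$truth$de_feature_ids])
    de_genes <- setdiff(de_genes, "---")
    universe <- setdiff(unique(coh$annotation$gene_symbol), "---")
    r <- enrich(de_genes, universe, gsets$sets)
    if (r$set[1] %in% gsets$enriched_set_ids) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("uniform gene sets yield no enrichment beyond the nominal rate", {
  fp <- 0; ntest <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_probesets = 300, probes_per_set = 3,
                      n_gene_sets = 20, gene_set_size_range = c(10, 40),
                      n_enriched_sets = 0, seed = 700 + s)
    coh <- simulate_cohort(cfg, probe_level = FALSE)
    gsets <- simulate_gene_sets(coh$truth, coh$annotation, cfg)
    expect_length(gsets$enriched_set_ids, 0)
    # a random candidate list unrelated to the sets
    universe <- setdiff(unique(coh$annotation$gene_symbol), "---")
    set.seed(s)
    lst <- sample(universe, 30)
    r <- enrich(lst, universe, gsets$sets)
    fp <- fp + sum(r$fdr < 0.05)
    ntest <- ntest + nrow(r)
  }
  expect_lte(fp / ntest, 0.05)
})
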